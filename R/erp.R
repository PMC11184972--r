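#' Class-average event-related potential
#'
#' Arithmetic mean across all trials of a stimulus class, per channel and
#' sample: `Y_j[t] = (1/N_C) * sum_{n in C} X_j[n, t]`.
#'
#' @param epochs an `epoch_set`.
#' @param class_members character vector of stimulus ids defining the class
#'   (or a logical/integer trial selector).
#' @return Object of class `erp`: list with `data` (channels x samples
#'   matrix), `n_trials`, `fs`, `window`, `channels`.
#' @export
compute_erp <- function(epochs, class_members) {
  idx <- if (is.character(class_members))
    which(epochs$stimulus_id %in% class_members)
  else if (is.logical(class_members)) which(class_members)
  else as.integer(class_members)
  if (length(idx) == 0) stop("class has no trials in this epoch set")
  sub <- epochs$data[idx, , , drop = FALSE]
  m <- apply(sub, c(2, 3), mean)
  rownames(m) <- epochs$channels
  structure(list(data = m, n_trials = length(idx), fs = epochs$fs,
                 window = epochs$window, channels = epochs$channels),
            class = "erp")
}

#' Select occipital/parietal channels by name
#'
#' Literal, case-insensitive substring rule: channels whose identifier
#' contains an "O" or a "P". Frontal-pole names such as "Fp1" also contain a
#' "P" and are therefore selected; they are flagged in the `ambiguous`
#' attribute so callers can inspect (or drop) them.
#'
#' @param layout a [channel_layout()] or character vector of names.
#' @return Character vector of selected names, with attribute `ambiguous`
#'   (selected names starting with "Fp").
#' @export
select_posterior_channels <- function(layout) {
  nm <- if (is.character(layout)) layout else layout$names
  sel <- nm[grepl("[op]", nm, ignore.case = TRUE)]
  if (length(sel) == 0) {
    warning("no channel name contains 'O' or 'P'; returning all channels")
    return(nm)
  }
  attr(sel, "ambiguous") <- sel[grepl("^Fp", sel, ignore.case = TRUE)]
  sel
}

# pointwise one-way F statistics for all samples at once.
# gsum: M x S matrix of per-group sums; n_g group sizes; sst: per-sample
# total sum of squares about the grand mean.
f_from_sums <- function(gsum, n_g, tot, sst, n) {
  m <- length(n_g)
  ssb <- colSums(gsum^2 / n_g) - tot^2 / n
  ssw <- pmax(sst - ssb, 0)
  (ssb / (m - 1)) / (ssw / (n - m))
}

# max suprathreshold cluster mass per row of a B x S statistic matrix
max_cluster_mass_rows <- function(fm, thr) {
  b <- nrow(fm); s <- ncol(fm)
  a <- ifelse(fm > thr & is.finite(fm), fm, 0)
  v <- as.vector(t(cbind(a, 0)))       # row-major with zero separators
  r <- rle(v > 0)
  ends <- cumsum(r$lengths)
  cs <- c(0, cumsum(v))
  out <- rep(0, b)
  pos <- which(r$values)
  if (length(pos)) {
    masses <- cs[ends[pos] + 1] - cs[ends[pos] - r$lengths[pos] + 1]
    rows <- (ends[pos] - 1) %/% (s + 1) + 1
    mx <- tapply(masses, rows, max)
    out[as.integer(names(mx))] <- mx
  }
  out
}

#' Cluster-based permutation test on one channel
#'
#' Pointwise one-way F statistic across classes at every sample; samples
#' exceeding the F quantile at `cluster_alpha` (df `M - 1`, `N - M`) form
#' contiguous clusters whose mass is the summed F. The null distribution is
#' the maximal cluster mass under random permutations of the class labels,
#' and each observed cluster gets
#' `p = (1 + #\{null >= mass\}) / (1 + n_permutations)`.
#'
#' @param x_by_class list (one element per class) of trials x samples
#'   matrices for a single channel.
#' @param n_permutations number of label permutations (default 1024).
#' @param cluster_alpha cluster-forming threshold probability.
#' @param seed integer seed for the permutations.
#' @return Object of class `cluster_result`: data frame `clusters` with
#'   columns `start`, `end` (1-based sample indices, half-open `[start,
#'   end)`), `mass`, `p`; plus `f`, `threshold`, `n_permutations`,
#'   `n_samples`.
#' @export
cluster_permutation_test <- function(x_by_class, n_permutations = 1024,
                                     cluster_alpha = 0.05, seed = 1L) {
  m <- length(x_by_class)
  if (m < 2) stop("need at least 2 classes")
  n_g <- vapply(x_by_class, nrow, 0L)
  if (any(n_g < 2)) stop("each class needs at least 2 trials")
  x <- do.call(rbind, x_by_class)
  n <- nrow(x); s <- ncol(x)
  if (n <= m) stop("fewer trials than classes")
  labels <- rep(seq_len(m), n_g)
  tot <- colSums(x)
  sst <- colSums(x^2) - tot^2 / n
  gsum <- rowsum(x, labels)
  f_obs <- f_from_sums(gsum, n_g, tot, sst, n)
  thr <- stats::qf(1 - cluster_alpha, m - 1, n - m)
  r <- rle(f_obs > thr & is.finite(f_obs))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  obs <- data.frame(start = starts[r$values], end = ends[r$values] + 1L)
  obs$mass <- vapply(seq_len(nrow(obs)), function(i)
    sum(f_obs[obs$start[i]:(obs$end[i] - 1)]), 0)

  null_max <- with_seed(seed, {
    perm <- t(vapply(seq_len(n_permutations), function(b) sample(labels),
                     integer(n)))
    ssb <- -matrix(rep(tot^2 / n, n_permutations), n_permutations, s,
                   byrow = TRUE)
    for (g in seq_len(m)) {
      ind <- (perm == g) * 1
      ssb <- ssb + (ind %*% x)^2 / n_g[g]
    }
    ssw <- pmax(matrix(rep(sst, n_permutations), n_permutations, s,
                       byrow = TRUE) - ssb, 0)
    fp <- (ssb / (m - 1)) / (ssw / (n - m))
    max_cluster_mass_rows(fp, thr)
  })
  obs$p <- vapply(obs$mass, function(ms)
    (1 + sum(null_max >= ms)) / (1 + n_permutations), 0)
  structure(list(clusters = obs, f = f_obs, threshold = thr,
                 n_permutations = n_permutations, n_samples = s,
                 cluster_alpha = cluster_alpha),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result>", nrow(x$clusters), "cluster(s), F threshold",
      round(x$threshold, 2), "over", x$n_samples, "samples,",
      x$n_permutations, "permutations\n")
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}

#' Per-sample significance-level map
#'
#' Labels every sample with the strictest significance level met by a
#' covering cluster (the colored bands under ERP traces).
#'
#' @param result a [cluster_permutation_test()] result.
#' @param levels significance levels, sorted descending (default
#'   `c(0.05, 0.01, 0.001)`).
#' @return Numeric vector (length `n_samples`); `NA` where no cluster at any
#'   level covers the sample, otherwise the strictest level met.
#' @export
significance_bands <- function(result, levels = c(0.05, 0.01, 0.001)) {
  stopifnot(!is.unsorted(rev(levels)))
  out <- rep(NA_real_, result$n_samples)
  cl <- result$clusters
  for (i in seq_len(nrow(cl))) {
    met <- levels[cl$p[i] < levels]
    if (length(met)) {
      idx <- cl$start[i]:(cl$end[i] - 1)
      lev <- min(met)
      out[idx] <- pmin(out[idx], lev, na.rm = TRUE)
    }
  }
  out
}

#' Cluster table export
#'
#' Writes the clusters of one or more channels as a tab-separated table with
#' columns channel, start_s, end_s, mass, p.
#'
#' @param results named list of `cluster_result` objects (names = channels).
#' @param fs sampling frequency used to convert sample indices to seconds.
#' @param window epoch window (start used as time origin).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(results, fs, window = c(-0.3, 0.75), path) {
  rows <- do.call(rbind, lapply(names(results), function(ch) {
    cl <- results[[ch]]$clusters
    if (nrow(cl) == 0) return(NULL)
    data.frame(channel = ch,
               start_s = window[1] + (cl$start - 1) / fs,
               end_s = window[1] + (cl$end - 1) / fs,
               mass = cl$mass, p = cl$p)
  }))
  if (is.null(rows))
    rows <- data.frame(channel = character(), start_s = numeric(),
                       end_s = numeric(), mass = numeric(), p = numeric())
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
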