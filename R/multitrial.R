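#' Aggregate calibrated probabilities over N trials
#'
#' Combines the calibrated class probabilities of N repeated presentations
#' into a single decision via
#' `p_k = prod_i (p_{i,k}/p_{i,M})^{1/N} / sum_j prod_i (p_{i,j}/p_{i,M})^{1/N}`
#' (reference class M = last column), evaluated in log space after clipping
#' probabilities at `eps` and renormalizing rows. The reference-class factors
#' cancel, so the rule equals the normalized geometric mean of the per-trial
#' probability rows; it is invariant to trial order and to the choice of
#' reference class.
#'
#' @param p trials x M matrix of per-trial class probabilities (rows on the
#'   simplex).
#' @param eps clipping floor applied before taking logs.
#' @return Length-M aggregated probability vector (sums to 1).
#' @export
aggregate_probabilities <- function(p, eps = 1e-12) {
  p <- matrix(p, ncol = ncol(as.matrix(p)))
  if (any(!is.finite(p))) stop("non-finite probabilities")
  p <- pmax(p, eps)
  p <- p / rowSums(p)
  lr <- log(p) - log(p[, ncol(p)])    # log(p_ij / p_iM)
  s <- colMeans(lr)                   # (1/N) sum_i log-ratios
  out <- exp(s - logsumexp(s))
  names(out) <- colnames(p)
  out
}

#' Multi-trial accuracy curve
#'
#' For each fold and each window length N, groups the fold's test trials by
#' true class, shuffles within class, slides an overlapping window of N
#' same-class trials (stride 1), aggregates the calibrated probabilities via
#' [aggregate_probabilities()] and predicts by argmax. Accuracy at each N
#' pools all windows of the fold; N = 1 reproduces single-trial accuracy.
#' Classes with fewer than N test trials are skipped for that N and recorded.
#'
#' @param result a [crossval_decode()] `fold_result` (folds carry `prob` and
#'   `truth`).
#' @param n_range window lengths (default `1:15`).
#' @param seed integer seed for the within-class shuffles.
#' @return Object of class `accuracy_curve`: `accuracy` (folds x N matrix,
#'   `NA` where no class had enough trials), `n_range`, `skipped` (data frame
#'   fold/N/class), plus per-fold window predictions at each N in
#'   `predictions`.
#' @export
multitrial_accuracy <- function(result, n_range = 1:15, seed = 1L) {
  lev <- result$levels
  nf <- length(result$folds)
  acc <- matrix(NA_real_, nf, length(n_range),
                dimnames = list(NULL, paste0("N", n_range)))
  skipped <- list()
  predictions <- vector("list", nf)
  with_seed(seed, {
    for (f in seq_len(nf)) {
      fo <- result$folds[[f]]
      by_class <- lapply(lev, function(cl) {
        idx <- which(fo$truth == cl)
        idx[sample.int(length(idx))]
      })
      names(by_class) <- lev
      predictions[[f]] <- vector("list", length(n_range))
      for (w in seq_along(n_range)) {
        nn <- n_range[w]
        preds <- character(0); truths <- character(0)
        for (cl in lev) {
          idx <- by_class[[cl]]
          if (length(idx) < nn) {
            skipped[[length(skipped) + 1]] <-
              data.frame(fold = f, N = nn, class = cl)
            next
          }
          for (s0 in seq_len(length(idx) - nn + 1)) {
            win <- idx[s0:(s0 + nn - 1)]
            pk <- aggregate_probabilities(fo$prob[win, , drop = FALSE])
            preds <- c(preds, lev[which.max(pk)])
            truths <- c(truths, cl)
          }
        }
        if (length(preds)) acc[f, w] <- mean(preds == truths)
        predictions[[f]][[w]] <- list(pred = preds, truth = truths)
      }
    }
  })
  structure(list(accuracy = acc, n_range = n_range,
                 skipped = if (length(skipped)) do.call(rbind, skipped)
                           else NULL,
                 predictions = predictions, levels = lev,
                 task = result$task),
            class = "accuracy_curve")
}

#' @export
print.accuracy_curve <- function(x, ...) {
  cat("<accuracy_curve>", x$task %||% "", "- mean accuracy by N:\n")
  print(round(colMeans(x$accuracy, na.rm = TRUE), 3))
  invisible(x)
}

#' Regression of multi-trial accuracy gain on single-trial accuracy
#'
#' Ordinary least squares of the accuracy change (N = 15 minus single-trial)
#' on single-trial accuracy, one point per fold/task, with the two-sided
#' t-test p-value for a zero slope.
#'
#' @param single_acc single-trial accuracy per point.
#' @param delta accuracy difference (multi minus single) per point.
#' @return List: `slope`, `intercept`, `p_slope`, `fit` (the `lm` object).
#' @export
accuracy_delta_regression <- function(single_acc, delta) {
  stopifnot(length(single_acc) == length(delta), length(delta) >= 3)
  if (stats::sd(single_acc) == 0)
    stop("single-trial accuracies are constant; slope is undefined")
  fit <- stats::lm(delta ~ single_acc)
  s <- summary(fit)$coefficients
  list(slope = s["single_acc", "Estimate"],
       intercept = s["(Intercept)", "Estimate"],
       p_slope = s["single_acc", "Pr(>|t|)"],
       fit = fit)
}

#' Fold-averaged confusion matrix at a given N
#'
#' Row-normalized per-fold confusion matrices (true class x predicted class)
#' averaged across folds; the diagonal mean is the balanced accuracy.
#'
#' @param curve an [multitrial_accuracy()] result.
#' @param n window length (must be in the curve's `n_range`).
#' @return M x M matrix (rows = true class, averaged over folds with
#'   predictions at this N).
#' @export
confusion_matrices <- function(curve, n = 1) {
  w <- match(n, curve$n_range)
  if (is.na(w)) stop("N = ", n, " was not evaluated")
  lev <- curve$levels
  mats <- list()
  for (f in seq_along(curve$predictions)) {
    pr <- curve$predictions[[f]][[w]]
    if (length(pr$pred) == 0) next
    cm <- table(factor(pr$truth, levels = lev),
                factor(pr$pred, levels = lev))
    rs <- rowSums(cm)
    rs[rs == 0] <- 1
    mats[[length(mats) + 1]] <- unclass(cm / rs)
  }
  if (length(mats) == 0) stop("no predictions at N = ", n)
  Reduce(`+`, mats) / length(mats)
}
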