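#' Vectorize epochs into a trial-by-feature matrix
#'
#' Concatenates the time signal of every channel (channel-major: all samples
#' of channel 1, then channel 2, ...), treating each (channel, sample) pair
#' as an independent feature. All channels are included, not only the
#' posterior ones.
#'
#' @param epochs an `epoch_set`.
#' @return Object of class `feature_matrix`: the trials x (channels *
#'   samples) matrix with attributes `channels`, `n_samples`, `labels`
#'   (stimulus ids) and `map` (feature -> channel index).
#' @export
vectorize <- function(epochs) {
  d <- dim(epochs$data)
  x <- matrix(aperm(epochs$data, c(1, 3, 2)), d[1], d[2] * d[3])
  structure(x, channels = epochs$channels, n_samples = d[3],
            stimulus_id = epochs$stimulus_id,
            map = rep(seq_len(d[2]), each = d[3]),
            class = c("feature_matrix", "matrix", "array"))
}

#' Feature index -> (channel, sample) of a vectorized epoch set
#' @param x a [vectorize()] result.
#' @param feature feature column index (1-based).
#' @return List with `channel` and `sample` (1-based).
#' @export
feature_coords <- function(x, feature) {
  s <- attr(x, "n_samples")
  list(channel = (feature - 1) %/% s + 1L,
       sample = (feature - 1) %% s + 1L)
}

#' Restore the trials x channels x samples array from a feature matrix
#' @param x a [vectorize()] result.
#' @return A 3-d array.
#' @export
unvectorize <- function(x) {
  s <- attr(x, "n_samples")
  nch <- length(attr(x, "channels"))
  aperm(array(as.numeric(x), dim = c(nrow(x), s, nch)), c(1, 3, 2))
}

#' Per-channel z-scoring fitted on the training set
#'
#' For each channel j, the mean and standard deviation are pooled over all
#' training trials and all samples of that channel's features:
#' `mu_j = (1/(Ni*Nn)) sum_t sum_n X_j[n, t]`, with the `Ni*Nn - 1`
#' denominator for the standard deviation. The same parameters standardize
#' both training and test sets.
#'
#' @param train a [vectorize()]d training feature matrix.
#' @return Object of class `zscore_params` (`mu`, `sigma` per channel, plus
#'   the channel map).
#' @export
zscore_fit <- function(train) {
  map <- attr(train, "map")
  nch <- max(map)
  n <- nrow(train)
  mu <- sigma <- numeric(nch)
  for (j in seq_len(nch)) {
    v <- train[, map == j, drop = FALSE]
    mu[j] <- mean(v)
    sigma[j] <- sqrt(sum((v - mu[j])^2) / (length(v) - 1))
    if (sigma[j] <= 0)
      stop("zero variance on channel ",
           attr(train, "channels")[j] %||% j)
  }
  structure(list(mu = mu, sigma = sigma, map = map),
            class = "zscore_params")
}

#' @rdname zscore_fit
#' @param params a `zscore_params` object.
#' @param x feature matrix to standardize (same feature layout as the
#'   training set).
#' @return The standardized matrix (attributes preserved).
#' @export
zscore_apply <- function(params, x) {
  out <- (x - matrix(params$mu[params$map], nrow(x), ncol(x),
                     byrow = TRUE)) /
    matrix(params$sigma[params$map], nrow(x), ncol(x), byrow = TRUE)
  attributes(out) <- attributes(x)
  out
}

platt_fit <- function(dv, y01) {
  # logistic (Platt) scaling of decision values; guard against separation
  fit <- suppressWarnings(stats::glm(y01 ~ dv,
                                     family = stats::binomial()))
  co <- stats::coef(fit)
  if (any(!is.finite(co))) co <- c(0, 1)
  co
}

# RBF Gram / cross-kernel matrices via BLAS (far faster than letting the
# SVM backend evaluate the kernel feature-by-feature at EEG dimensions)
rbf_kernel <- function(x, y = NULL, gamma) {
  if (is.null(y)) y <- x
  d2 <- outer(rowSums(x^2), rep(1, nrow(y))) +
    outer(rep(1, nrow(x)), rowSums(y^2)) - 2 * tcrossprod(x, y)
  exp(-gamma * pmax(d2, 0))
}

# fit one binary C-SVC on a precomputed kernel; returns support indices
# (into the kernel's rows), dual coefficients and offset, oriented so that
# positive decision values favor the positive class
svm_binary_on_kernel <- function(k, y01, cost) {
  yf <- factor(ifelse(y01, "pos", "rest"), levels = c("pos", "rest"))
  m <- kernlab::ksvm(kernlab::as.kernelMatrix(k), yf, type = "C-svc",
                     C = cost)
  ai <- kernlab::SVindex(m)
  a <- unlist(kernlab::coef(m))
  b <- kernlab::b(m)
  f_tr <- as.numeric(k[, ai, drop = FALSE] %*% a - b)
  # kernlab's internal +/-1 coding depends on level bookkeeping; orient
  # empirically against the training labels
  sgn <- if (mean((f_tr > 0) == y01) >= 0.5) 1 else -1
  list(ai = ai, a = sgn * a, b = sgn * b)
}

machine_decision <- function(machine, x) {
  as.numeric(rbf_kernel(x, machine$sv, machine$gamma) %*% machine$a -
               machine$b)
}

#' Fit a calibrated RBF support-vector decoder
#'
#' Maximum-margin RBF-kernel classification with probability calibration on
#' the training set only: one binary SVM per class (one-vs-rest; a single
#' machine for two classes), each calibrated by logistic (Platt) scaling of
#' decision values collected by stratified internal cross-validation on the
#' training data. Predicted class probabilities are the normalized calibrated
#' one-vs-rest probabilities; labels are their argmax. The internal fold
#' assignment draws from R's RNG, so results are reproducible under
#' `set.seed()`.
#'
#' @param x training feature matrix (rows = trials).
#' @param y training labels (coerced to factor; its level order fixes the
#'   class order of all probability output).
#' @param cost SVM regularization parameter C.
#' @param gamma RBF kernel width; default `1 / ncol(x)`.
#' @param calib_folds internal calibration folds (default 5).
#' @return Object of class `calibrated_svm`.
#' @export
fit_calibrated_decoder <- function(x, y, cost = 1, gamma = NULL,
                                   calib_folds = 5) {
  y <- factor(y)
  if (nlevels(y) < 2) stop("training set contains a single class")
  if (is.null(gamma)) gamma <- 1 / ncol(x)
  lev <- levels(y)
  n <- nrow(x)
  x <- as.matrix(x)
  kk <- rbf_kernel(x, gamma = gamma)  # one Gram matrix serves all machines
  # stratified internal folds for calibration
  fold <- integer(n)
  for (cl in lev) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(calib_folds), length(idx))
  }
  fit_one <- function(cl) {
    y01 <- y == cl
    dv_cv <- numeric(n)
    for (k in seq_len(calib_folds)) {
      tr <- which(fold != k); te <- which(fold == k)
      if (length(unique(y01[tr])) < 2) next
      mk <- svm_binary_on_kernel(kk[tr, tr, drop = FALSE], y01[tr], cost)
      dv_cv[te] <- as.numeric(
        kk[te, tr[mk$ai], drop = FALSE] %*% mk$a - mk$b)
    }
    mf <- svm_binary_on_kernel(kk, y01, cost)
    list(sv = x[mf$ai, , drop = FALSE], a = mf$a, b = mf$b, gamma = gamma,
         platt = platt_fit(dv_cv, y01))
  }
  machines <- lapply(if (length(lev) == 2) lev[1] else lev, fit_one)
  structure(list(machines = machines, levels = lev, cost = cost,
                 gamma = gamma, calib_folds = calib_folds,
                 n_features = ncol(x)),
            class = "calibrated_svm")
}

#' @export
print.calibrated_svm <- function(x, ...) {
  cat("<calibrated_svm> RBF SVC,", length(x$levels), "classes (",
      paste(x$levels, collapse = ", "), "), gamma =",
      signif(x$gamma, 3), ", C =", x$cost, "\n")
  invisible(x)
}

#' Predict calibrated class probabilities (and labels)
#'
#' @param object a [fit_calibrated_decoder()] result.
#' @param newdata feature matrix.
#' @param type `"prob"` for the trials x M probability matrix (rows sum to
#'   1, columns in training level order) or `"class"` for argmax labels.
#' @param ... unused.
#' @export
predict.calibrated_svm <- function(object, newdata, type = c("prob", "class"),
                                   ...) {
  type <- match.arg(type)
  lev <- object$levels
  newdata <- as.matrix(newdata)
  raw <- vapply(object$machines, function(mk) {
    dv <- machine_decision(mk, newdata)
    stats::plogis(mk$platt[1] + mk$platt[2] * dv)
  }, numeric(nrow(newdata)))
  raw <- matrix(raw, nrow = nrow(newdata))
  p <- if (length(lev) == 2) cbind(raw[, 1], 1 - raw[, 1])
       else raw / rowSums(raw)
  colnames(p) <- lev
  if (type == "prob") p else factor(lev[max.col(p, ties.method = "first")],
                                    levels = lev)
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated single-trial decoding accuracy
#'
#' Balanced tasks use stratified tenfold cross-validation; unbalanced tasks
#' use 10 Monte Carlo iterations, each subsampling every class without
#' replacement to the size of the least represented class and then taking a
#' stratified 90/10 train/test split. Z-scoring and probability calibration
#' are re-fitted inside every training fold (no information leaks into the
#' test fold).
#'
#' @param features a [vectorize()]d feature matrix.
#' @param labels class label per trial (`NA` = excluded from the task).
#' @param balanced logical; scheme selector (see above). Defaults to the
#'   `balanced` flag of `task` when given.
#' @param task optional [decoding_task()]; when given, `labels` defaults to
#'   [assign_classes()] of the feature matrix's stimulus ids.
#' @param n_folds folds / resamplings (default 10).
#' @param seed integer seed (fold assignment, resampling, calibration folds).
#' @param cost,gamma,calib_folds passed to [fit_calibrated_decoder()].
#' @return Object of class `fold_result`: per-fold accuracies, per-fold test
#'   probabilities/truth (for multi-trial aggregation and the random
#'   decoder), the scheme and class levels.
#' @export
crossval_decode <- function(features, labels = NULL, balanced = NULL,
                            task = NULL, n_folds = 10, seed = 1L, cost = 1,
                            gamma = NULL, calib_folds = 5) {
  if (is.null(labels)) {
    if (is.null(task)) stop("give either labels or a task")
    labels <- assign_classes(task, attr(features, "stimulus_id"))
  }
  if (is.null(balanced))
    balanced <- if (!is.null(task)) task$balanced else TRUE
  keep <- !is.na(labels)
  x <- features[keep, , drop = FALSE]
  attr(x, "map") <- attr(features, "map")
  attr(x, "channels") <- attr(features, "channels")
  y <- factor(labels[keep])
  counts <- table(y)
  if (any(counts < n_folds))
    stop("class '", names(counts)[which.min(counts)], "' has ",
         min(counts), " trials; need at least ", n_folds)
  run_fold <- function(tr_idx, te_idx) {
    xtr <- x[tr_idx, , drop = FALSE]
    attr(xtr, "map") <- attr(x, "map"); attr(xtr, "channels") <- attr(x, "channels")
    zp <- zscore_fit(xtr)
    dec <- fit_calibrated_decoder(zscore_apply(zp, xtr), y[tr_idx],
                                  cost = cost, gamma = gamma,
                                  calib_folds = calib_folds)
    p <- predict(dec, zscore_apply(zp, x[te_idx, , drop = FALSE]))
    pred <- colnames(p)[max.col(p, ties.method = "first")]
    list(accuracy = mean(pred == as.character(y[te_idx])),
         prob = p, truth = as.character(y[te_idx]), pred = pred,
         n_test = length(te_idx), decoder = dec, zscore = zp)
  }
  folds <- with_seed(seed, {
    if (balanced) {
      fold <- stratified_folds(y, n_folds)
      lapply(seq_len(n_folds), function(k)
        run_fold(which(fold != k), which(fold == k)))
    } else {
      n_min <- min(counts)
      lapply(seq_len(n_folds), function(r) {
        sub <- unlist(lapply(levels(y), function(cl)
          sample(which(y == cl), n_min)))
        ys <- y[sub]
        te_local <- unlist(lapply(levels(ys), function(cl) {
          i <- sample(which(ys == cl))
          i[seq_len(max(1, round(0.1 * length(i))))]
        }))
        run_fold(sub[-te_local], sub[te_local])
      })
    }
  })
  structure(list(accuracies = vapply(folds, `[[`, 0, "accuracy"),
                 folds = folds,
                 scheme = if (balanced) "tenfold" else "monte-carlo-resample",
                 levels = levels(y),
                 task = if (!is.null(task)) task$name else NULL,
                 seed = seed),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat("<fold_result>", x$task %||% "", x$scheme, "- mean accuracy",
      round(mean(x$accuracies), 3), "(sd", round(stats::sd(x$accuracies), 3),
      ") over", length(x$accuracies), "folds\n")
  invisible(x)
}

#' Fold-matched random decoder
#'
#' Emits, for each fold, as many labels as the real decoder did, drawn
#' uniformly over the task's classes, and scores them against the same true
#' labels. Its accuracies estimate the empirical chance level `1/M`.
#'
#' @param fold_truths list of per-fold true-label vectors (or a
#'   `fold_result`, whose folds are used).
#' @param levels class labels to draw from.
#' @param seed integer seed.
#' @return A `fold_result` with scheme `"random"`.
#' @export
random_decoder <- function(fold_truths, levels = NULL, seed = 1L) {
  if (inherits(fold_truths, "fold_result")) {
    levels <- levels %||% fold_truths$levels
    fold_truths <- lapply(fold_truths$folds, `[[`, "truth")
  }
  folds <- with_seed(seed, lapply(fold_truths, function(tr) {
    lab <- sample(levels, length(tr), replace = TRUE)
    list(accuracy = mean(lab == tr), truth = tr, pred = lab,
         n_test = length(tr))
  }))
  structure(list(accuracies = vapply(folds, `[[`, 0, "accuracy"),
                 folds = folds, scheme = "random", levels = levels,
                 seed = seed),
            class = "fold_result")
}

#' Compare decoding accuracy to the chance level
#'
#' One-sided Wilcoxon test of "real accuracies exceed random-decoder
#' accuracies" over the matched folds (paired signed-rank by default;
#' rank-sum with `paired = FALSE`), with Bonferroni correction for the
#' number of subjects. Shapiro-Wilk normality of each accuracy set is
#' reported but does not gate the test.
#'
#' @param real,random `fold_result` objects (or plain accuracy vectors) of
#'   equal length.
#' @param n_subjects Bonferroni correction factor (p is multiplied by it and
#'   capped at 1).
#' @param paired use the fold-matched signed-rank variant (default).
#' @return List: `p`, `p_corrected`, `shapiro_p_real`, `shapiro_p_random`,
#'   `ties` flag (exact method unavailable), `method`.
#' @export
compare_to_chance <- function(real, random, n_subjects = 1,
                              paired = TRUE) {
  a <- if (inherits(real, "fold_result")) real$accuracies else real
  b <- if (inherits(random, "fold_result")) random$accuracies else random
  stopifnot(length(a) == length(b))
  wt <- suppressWarnings(stats::wilcox.test(a, b, paired = paired,
                                            alternative = "greater"))
  ties <- if (paired) any(duplicated(abs(a - b))) || any(a == b)
          else any(duplicated(c(a, b)))
  sh <- function(v) if (stats::sd(v) > 0 && length(v) >= 3)
    stats::shapiro.test(v)$p.value else NA_real_
  list(p = wt$p.value, p_corrected = min(1, wt$p.value * n_subjects),
       shapiro_p_real = sh(a), shapiro_p_random = sh(b),
       ties = ties, method = wt$method)
}
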