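#' Gradient of an RBF decision function
#'
#' Analytic gradient of one one-vs-rest machine of a [fit_calibrated_decoder()]
#' decoder. For `f(x) = sum_i a_i K(x, x_i) + b` with
#' `K(x, x_i) = exp(-gamma * ||x - x_i||^2)`,
#' `df/dx = sum_i a_i * (-2 gamma) (x - x_i) * K(x, x_i)`.
#'
#' @param decoder a `calibrated_svm`.
#' @param x a feature vector, or a matrix of row vectors.
#' @param machine index of the one-vs-rest machine (1-based; a binary
#'   decoder has a single machine).
#' @return Gradient vector (or rows x features matrix when `x` is a matrix).
#' @export
decision_gradient <- function(decoder, x, machine = 1L) {
  mk <- decoder$machines[[machine]]
  if (is.null(mk$sv)) stop("fitted model exposes no support vectors")
  x <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  g <- rbf_gradient(x, mk)
  if (nrow(g) == 1) as.numeric(g) else g
}

# batch gradient of one binary RBF machine (fields sv, a, b, gamma) at the
# rows of x; same orientation as machine_decision
rbf_gradient <- function(x, machine) {
  sv <- machine$sv
  a <- machine$a                  # signed dual coefficients alpha_i * y_i
  gamma <- machine$gamma
  k <- rbf_kernel(x, sv, gamma)
  w <- k %*% a                    # sum_i a_i K(x, x_i), per row
  ak <- k * matrix(a, nrow(x), length(a), byrow = TRUE)
  -2 * gamma * (x * as.numeric(w) - ak %*% sv)
}

#' Sensitivity map of a trained decoder
#'
#' Per-feature importance: the mean over data points of the squared partial
#' derivative of the decision function, averaged over the decoder's
#' one-vs-rest machines for multi-class tasks. The map is reshaped to
#' channels x samples through the feature matrix's channel-major layout and
#' reduced to spatial (per-channel) and temporal (per-sample) profiles.
#'
#' @param decoder a `calibrated_svm`.
#' @param data feature matrix of evaluation points (training-fold data by
#'   convention).
#' @param channels,n_samples layout of the feature dimension; default taken
#'   from `data`'s [vectorize()] attributes.
#' @return Object of class `sensitivity_map`: `values` (per feature, >= 0),
#'   `matrix` (channels x samples), `spatial`, `temporal`.
#' @export
sensitivity_map <- function(decoder, data, channels = NULL,
                            n_samples = NULL) {
  if (nrow(data) == 0) stop("no data points")
  channels <- channels %||% attr(data, "channels")
  n_samples <- n_samples %||% attr(data, "n_samples")
  x <- as.matrix(data)
  vals <- 0
  for (m in seq_along(decoder$machines)) {
    g <- rbf_gradient(x, decoder$machines[[m]])
    vals <- vals + colMeans(g^2)
  }
  vals <- vals / length(decoder$machines)
  out <- list(values = vals)
  if (!is.null(channels) && !is.null(n_samples)) {
    mat <- matrix(vals, length(channels), n_samples, byrow = TRUE,
                  dimnames = list(channels, NULL))
    red <- reduce_map_matrix(mat)
    out$matrix <- mat
    out$spatial <- red$spatial
    out$temporal <- red$temporal
  }
  structure(out, class = "sensitivity_map")
}

reduce_map_matrix <- function(mat) {
  list(spatial = rowMeans(mat), temporal = colMeans(mat))
}

#' Reduce a sensitivity map to spatial and temporal profiles
#'
#' Spatial importance = mean over samples per channel; temporal importance =
#' mean over channels per sample. Both share the map's global mean.
#'
#' @param map a [sensitivity_map()] result (with a reshaped `matrix`).
#' @return List with `spatial` (named per-channel) and `temporal`
#'   (per-sample) vectors.
#' @export
reduce_map <- function(map) {
  if (is.null(map$matrix)) stop("map carries no channels x samples view")
  reduce_map_matrix(map$matrix)
}

#' @export
print.sensitivity_map <- function(x, ...) {
  cat("<sensitivity_map>", length(x$values), "features")
  if (!is.null(x$matrix))
    cat(" (", nrow(x$matrix), "channels x", ncol(x$matrix), "samples );",
        "top channel:", names(which.max(x$spatial)))
  cat("\n")
  invisible(x)
}
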