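#' Principal component analysis of a feature matrix
#'
#' Centers the columns (no variance scaling — standardization is a
#' separate, searched classifier hyperparameter) and extracts the
#' eigenvectors of the sample covariance via [stats::prcomp()]. A
#' deterministic sign convention is applied: within each component the
#' largest-magnitude loading entry is made positive.
#'
#' @param x numeric matrix `n x p` (rows = samples), `n >= 2`, no
#'   missing values.
#' @return An object of class `csa_pca`: list with `means` (column
#'   centers), `loadings` (`p x m` orthonormal), `explained_ratio`
#'   (length `m`, non-increasing, sums to 1 over the full rank) and `m`.
#' @export
fit_pca <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stopf("need at least 2 samples for PCA")
  if (anyNA(x)) stopf("missing values in feature matrix")
  if (all(apply(x, 2, function(col) max(col) == min(col))))
    stopf("constant feature matrix")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  load <- pc$rotation
  # sign convention: largest-|.| loading entry positive per component
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  var <- pc$sdev^2
  structure(list(
    means = pc$center,
    loadings = load,
    explained_ratio = var / sum(var),
    m = ncol(load)
  ), class = "csa_pca")
}

#' @export
print.csa_pca <- function(x, ...) {
  cum <- cumsum(x$explained_ratio)
  cat(sprintf("<csa_pca> %d component(s); cumulative variance: %s\n",
              x$m, paste(sprintf("%.1f%%", 100 * head(cum, 6)), collapse = " ")))
  invisible(x)
}

#' Project samples onto principal components
#'
#' @param object a [fit_pca()] model.
#' @param newdata numeric matrix with the same columns as the training
#'   features.
#' @param n_components number of leading components to keep (default:
#'   all).
#' @param ... unused.
#' @return Score matrix `n x n_components`.
#' @export
predict.csa_pca <- function(object, newdata, n_components = object$m, ...) {
  newdata <- as.matrix(newdata)
  scores <- sweep(newdata, 2, object$means) %*% object$loadings
  scores[, seq_len(n_components), drop = FALSE]
}

#' Number of components needed to reach a variance threshold
#'
#' @param model a [fit_pca()] model.
#' @param threshold cumulative explained-variance fraction in `(0, 1]`
#'   (default 0.95, the conventional cutoff for this application).
#' @return The smallest `k` whose cumulative explained ratio reaches the
#'   threshold.
#' @export
select_n_components <- function(model, threshold = 0.95) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stopf("`threshold` must be in (0, 1]")
  ratios <- if (inherits(model, "csa_pca")) model$explained_ratio else model
  cum <- cumsum(ratios)
  k <- which(cum >= threshold - 1e-12)[1]
  if (is.na(k)) length(ratios) else k
}
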