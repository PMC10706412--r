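#' Build an SVM hyperparameter configuration
#'
#' One point in the search space explored by [random_search()]: kernel
#' family, polynomial order (polynomial only), kernel scale (gaussian
#' only), soft-margin box constraint, and whether predictors are
#' standardized before kernel evaluation.
#'
#' @param kernel `"gaussian"`, `"linear"` or `"polynomial"`.
#' @param poly_order polynomial degree in `{2, 3, 4}` (polynomial only).
#' @param kernel_scale positive bandwidth `s` of the gaussian kernel
#'   `exp(-||u - v||^2 / s^2)`.
#' @param box_constraint positive soft-margin penalty cap `C`.
#' @param standardize center and scale each predictor by its training
#'   mean and standard deviation before kernel evaluation.
#' @return An object of class `hyperparam_config`.
#' @export
hyperparam_config <- function(kernel = c("gaussian", "linear", "polynomial"),
                              poly_order = 3, kernel_scale = 1,
                              box_constraint = 1, standardize = TRUE) {
  kernel <- match.arg(kernel)
  if (kernel == "polynomial" && !poly_order %in% 2:4)
    stopf("`poly_order` must be 2, 3 or 4")
  if (kernel == "gaussian" && (!is.numeric(kernel_scale) || kernel_scale <= 0))
    stopf("`kernel_scale` must be positive")
  if (!is.numeric(box_constraint) || box_constraint <= 0)
    stopf("`box_constraint` must be positive")
  structure(list(
    kernel = kernel,
    poly_order = if (kernel == "polynomial") as.integer(poly_order) else NA_integer_,
    kernel_scale = if (kernel == "gaussian") kernel_scale else NA_real_,
    box_constraint = box_constraint,
    standardize = isTRUE(standardize)
  ), class = "hyperparam_config")
}

#' @export
print.hyperparam_config <- function(x, ...) {
  extra <- switch(x$kernel,
    gaussian = sprintf(", scale = %.4g", x$kernel_scale),
    polynomial = sprintf(", order = %d", x$poly_order),
    "")
  cat(sprintf("<hyperparam_config> %s kernel%s, C = %.4g, standardize = %s\n",
              x$kernel, extra, x$box_constraint, x$standardize))
  invisible(x)
}

#' Evaluate a kernel function
#'
#' `linear`: `u . v`; `polynomial` of order `d`: `(1 + u . v)^d`;
#' `gaussian`: `exp(-||u - v||^2 / s^2)` with `s` the kernel scale.
#'
#' @param u,v numeric vectors of equal length.
#' @param config a [hyperparam_config()].
#' @return The kernel value, a scalar.
#' @export
kernel_value <- function(u, v, config) {
  if (length(u) != length(v)) stopf("`u` and `v` must have equal length")
  switch(config$kernel,
    linear = sum(u * v),
    polynomial = (1 + sum(u * v))^config$poly_order,
    gaussian = {
      if (is.na(config$kernel_scale) || config$kernel_scale <= 0)
        stopf("gaussian kernel requires a positive kernel_scale")
      exp(-sum((u - v)^2) / config$kernel_scale^2)
    }
  )
}

#' Train a soft-margin SVM classifier
#'
#' Fits a multiclass support vector machine (one-vs-one, libsvm via
#' \pkg{e1071}) under the given hyperparameter configuration. When
#' `config$standardize` is `TRUE`, each predictor is centered and scaled
#' by its training-set mean and standard deviation before kernel
#' evaluation and the same transform is applied at prediction time; a
#' zero-variance predictor gets scale 1 rather than failing.
#'
#' @param x numeric matrix `n x k` of predictors (typically PCA scores).
#' @param y class labels (factor or character); at least two classes.
#' @param config a [hyperparam_config()].
#' @return An object of class `csa_svm`.
#' @export
train_svm <- function(x, y, config) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stopf("need at least two classes")
  center <- rep(0, ncol(x)); scale_ <- rep(1, ncol(x))
  if (config$standardize) {
    center <- colMeans(x)
    scale_ <- apply(x, 2, stats::sd)
    scale_[scale_ == 0 | !is.finite(scale_)] <- 1
  }
  xs <- sweep(sweep(x, 2, center), 2, scale_, "/")
  args <- list(x = xs, y = y, cost = config$box_constraint, scale = FALSE,
               type = "C-classification")
  args <- c(args, switch(config$kernel,
    linear = list(kernel = "linear"),
    polynomial = list(kernel = "polynomial", degree = config$poly_order,
                      gamma = 1, coef0 = 1),
    gaussian = list(kernel = "radial", gamma = 1 / config$kernel_scale^2)
  ))
  fit <- do.call(e1071::svm, args)
  structure(list(fit = fit, config = config, levels = levels(y),
                 center = center, scale = scale_),
            class = "csa_svm")
}

#' Predict classes with a trained SVM
#'
#' One-vs-one vote counting over libsvm's pairwise decision values;
#' ties are broken by the largest aggregate decision value in the tied
#' class's favor, then by the lowest class index.
#'
#' @param object a [train_svm()] model.
#' @param newdata numeric matrix with the same predictors as training.
#' @param ... unused.
#' @return Factor of predicted class labels.
#' @export
predict.csa_svm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  xs <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  colnames(xs) <- colnames(object$fit$SV)
  p <- predict(object$fit, xs, decision.values = TRUE)
  dv <- attr(p, "decision.values")
  lev <- object$levels
  pairs <- strsplit(colnames(dv), "/", fixed = TRUE)
  votes <- matrix(0, nrow(xs), length(lev), dimnames = list(NULL, lev))
  score <- matrix(0, nrow(xs), length(lev), dimnames = list(NULL, lev))
  for (j in seq_along(pairs)) {
    a <- pairs[[j]][1]; b <- pairs[[j]][2]
    wa <- dv[, j] > 0
    votes[, a] <- votes[, a] + wa
    votes[, b] <- votes[, b] + !wa
    score[, a] <- score[, a] + dv[, j]
    score[, b] <- score[, b] - dv[, j]
  }
  pick <- integer(nrow(xs))
  for (i in seq_len(nrow(xs))) {
    top <- which(votes[i, ] == max(votes[i, ]))
    if (length(top) > 1) top <- top[score[i, top] == max(score[i, top])]
    pick[i] <- top[1]
  }
  factor(lev[pick], levels = lev)
}

#' @export
print.csa_svm <- function(x, ...) {
  cat(sprintf("<csa_svm> %d class(es), %d support vector(s)\n",
              length(x$levels), nrow(x$fit$SV)))
  print(x$config)
  invisible(x)
}

#' Stratified k-fold cross-validated classification error
#'
#' The objective minimized during hyperparameter search: the
#' misclassification fraction over stratified k-fold cross-validation,
#' deterministic for a given seed.
#'
#' @param x predictor matrix.
#' @param y class labels.
#' @param config a [hyperparam_config()].
#' @param folds number of folds (default 10).
#' @param seed RNG seed for the fold assignment (default 0).
#' @return Misclassification fraction in `[0, 1]`.
#' @export
cv_objective <- function(x, y, config, folds = 10, seed = 0) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  n <- nrow(x)
  if (folds > n) stopf("more folds (%d) than samples (%d)", folds, n)
  fold_id <- stratified_folds(y, folds, seed)
  wrong <- 0
  for (f in sort(unique(fold_id))) {
    test <- fold_id == f
    if (nlevels(droplevels(y[!test])) < 2) {
      # degenerate training fold: predict its single class
      only <- levels(droplevels(y[!test]))
      wrong <- wrong + sum(as.character(y[test]) != only)
      next
    }
    m <- train_svm(x[!test, , drop = FALSE], y[!test], config)
    pred <- predict(m, x[test, , drop = FALSE])
    wrong <- wrong + sum(as.character(pred) != as.character(y[test]))
  }
  wrong / n
}

# Per-class cyclic fold assignment after a seeded shuffle: every fold
# gets the same class mix up to rounding.
stratified_folds <- function(y, folds, seed) {
  folds <- as.integer(folds)
  fold_id <- integer(length(y))
  with_seed(seed, {
    offset <- 0L
    for (cl in levels(y)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      fold_id[idx] <- 1L + (offset + seq_along(idx) - 1L) %% folds
      offset <- offset + length(idx)
    }
  })
  fold_id
}
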