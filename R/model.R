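#' Fit the full adulteration classifier
#'
#' The core estimator of the package: from an `n x 18` fingerprint
#' table, fits PCA (centering only), selects the number of components by
#' cumulative explained variance, tunes the SVM hyperparameters by
#' random search with a cross-validated objective, and refits the tuned
#' SVM on all supplied samples.
#'
#' @param x feature matrix `n x 18`, or a feature-table data.frame from
#'   [read_feature_table()]/[make_dataset()] (feature columns are then
#'   taken by name).
#' @param y class labels; defaults to `x$label` when `x` is a
#'   feature-table data.frame.
#' @param n_components principal components kept as classifier inputs;
#'   `NULL` (default) selects the smallest number explaining at least
#'   `var_threshold` of the variance.
#' @param var_threshold cumulative explained-variance cutoff
#'   (default 0.95).
#' @param n_iter random-search evaluations (default 100).
#' @param folds cross-validation folds of the search objective
#'   (default 10).
#' @param seed RNG seed governing the search and its folds (default 0).
#' @return An object of class `csa_model` with components `pca`,
#'   `n_components`, `search` (the [random_search()] trace), `config`
#'   (best hyperparameters), `svm` (the refitted classifier) and
#'   `levels`.
#' @examples
#' \donttest{
#' spec <- synthetic_spec(noise_sd = 1)
#' ds <- make_dataset(spec, n_per_class = 2, seed = 1)
#' fit <- csa_train(ds, n_iter = 5, seed = 1)
#' print(fit)
#' }
#' @export
csa_train <- function(x, y = NULL, n_components = NULL, var_threshold = 0.95,
                      n_iter = 100, folds = 10, seed = 0) {
  if (is.data.frame(x)) {
    if (is.null(y) && "label" %in% names(x)) y <- x$label
    x <- as.matrix(x[, feature_names()])
  }
  if (is.null(y)) stopf("class labels `y` are required")
  y <- droplevels(as.factor(y))
  pca <- fit_pca(x)
  k <- if (is.null(n_components)) select_n_components(pca, var_threshold)
       else n_components
  scores <- predict(pca, x, n_components = k)
  search <- random_search(scores, y, n_iter = n_iter, folds = folds,
                          seed = seed)
  svm <- train_svm(scores, y, search$best_config)
  structure(list(
    pca = pca, n_components = k, search = search,
    config = search$best_config, svm = svm, levels = levels(y),
    n_train = nrow(x), seed = seed
  ), class = "csa_model")
}

#' @export
print.csa_model <- function(x, ...) {
  cat(sprintf("<csa_model> %d training sample(s), %d class(es), %d PC(s)\n",
              x$n_train, length(x$levels), x$n_components))
  print(x$config)
  cat(sprintf("search objective (CV error): %.4f over %d evaluation(s)\n",
              x$search$best_objective, nrow(x$search$evaluations)))
  invisible(x)
}

#' @export
summary.csa_model <- function(object, ...) {
  cum <- cumsum(object$pca$explained_ratio)
  cat("Colorimetric sensor array adulteration classifier\n")
  cat(sprintf("  samples: %d   classes: %d\n", object$n_train,
              length(object$levels)))
  cat(sprintf("  PCs kept: %d (%.1f%% of variance)\n", object$n_components,
              100 * cum[object$n_components]))
  cat("  cumulative variance by PC:",
      paste(sprintf("%.1f%%", 100 * head(cum, object$n_components + 2)),
            collapse = " "), "\n")
  print(object$config)
  cat(sprintf("  tuned CV error: %.2f%%\n", 100 * object$search$best_objective))
  invisible(object)
}

#' Predict adulteration classes for new fingerprints
#'
#' @param object a [csa_train()] model.
#' @param newdata feature matrix or feature-table data.frame.
#' @param ... unused.
#' @return Factor of predicted class labels.
#' @export
predict.csa_model <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) newdata <- as.matrix(newdata[, feature_names()])
  scores <- predict(object$pca, newdata, n_components = object$n_components)
  predict(object$svm, scores)
}

#' Plot a fitted adulteration classifier
#'
#' `which = "scores"` draws the training samples in the first two
#' principal components; `which = "scree"` the cumulative explained
#' variance; `which = "search"` the random-search minimum-observed
#' objective.
#'
#' @param x a `csa_model`.
#' @param which `"scores"`, `"scree"` or `"search"`.
#' @param newdata optional feature table for the score plot (defaults to
#'   nothing; the score plot then requires `newdata`).
#' @param y class labels for coloring the score plot.
#' @param ... passed to the underlying plot call.
#' @export
plot.csa_model <- function(x, which = c("scree", "search", "scores"),
                           newdata = NULL, y = NULL, ...) {
  which <- match.arg(which)
  if (which == "scree") {
    cum <- cumsum(x$pca$explained_ratio)
    graphics::plot(seq_along(cum), 100 * cum, type = "b",
                   xlab = "Principal components",
                   ylab = "Cumulative variance explained (%)", ...)
    graphics::abline(h = 95, lty = 2)
  } else if (which == "search") {
    plot(x$search, ...)
  } else {
    if (is.null(newdata)) stopf("score plot needs `newdata`")
    if (is.data.frame(newdata)) {
      if (is.null(y) && "label" %in% names(newdata)) y <- newdata$label
      newdata <- as.matrix(newdata[, feature_names()])
    }
    s <- predict(x$pca, newdata, n_components = max(2, x$n_components))
    col <- if (is.null(y)) 1 else as.integer(factor(y))
    graphics::plot(s[, 1], s[, 2], col = col, pch = 19,
                   xlab = "PC1", ylab = "PC2", ...)
  }
  invisible(x)
}

#' Serialize a fitted model to JSON
#'
#' Writes the PCA (means, loadings, explained ratios), the tuned
#' hyperparameters and the SVM dual representation (support vectors,
#' coefficients, intercepts, class levels) as plain JSON — no binary
#' artifacts.
#'
#' @param model a `csa_model`.
#' @param path output `.json` path.
#' @export
write_model_json <- function(model, path) {
  fit <- model$svm$fit
  obj <- list(
    schema = "csanose-model/1",
    n_components = model$n_components,
    levels = model$levels,
    pca = list(
      means = unname(model$pca$means),
      loadings = unname(model$pca$loadings),
      explained_ratio = model$pca$explained_ratio
    ),
    config = unclass(model$config),
    svm = list(
      support_vectors = unname(fit$SV),
      dual_coefs = unname(fit$coefs),
      rho = fit$rho,
      center = model$svm$center,
      scale = model$svm$scale
    ),
    search = list(
      best_objective = model$search$best_objective,
      min_observed = model$search$min_observed,
      seed = model$search$seed
    )
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
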