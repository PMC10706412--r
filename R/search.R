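#' Random search over SVM hyperparameters
#'
#' Draws `n_iter` independent configurations — kernel uniform on
#' \{gaussian, linear, polynomial\}, polynomial order uniform on
#' \{2, 3, 4\}, kernel scale and box constraint log-uniform on
#' `[1e-3, 1e3]` (the range spans several orders of magnitude, so a
#' log-uniform draw explores small and large scales evenly),
#' standardization uniform on \{TRUE, FALSE\} — and scores each by
#' stratified k-fold cross-validated error. The same fold partition
#' (derived from `seed`) is reused across iterations so configurations
#' compete on identical splits.
#'
#' @param x predictor matrix (typically PCA scores).
#' @param y class labels.
#' @param n_iter number of function evaluations (default 100).
#' @param folds cross-validation folds for the objective (default 10).
#' @param seed RNG seed (default 0).
#' @param range lower/upper bounds for the log-uniform draws
#'   (default `c(1e-3, 1e3)`).
#' @return An object of class `search_trace`: list with `evaluations`
#'   (data.frame of drawn configurations and objectives), `min_observed`
#'   (running minimum of the objective), `best_config` and
#'   `best_objective` (first-found on ties).
#' @export
random_search <- function(x, y, n_iter = 100, folds = 10, seed = 0,
                          range = c(1e-3, 1e3)) {
  if (!is_count(n_iter)) stopf("`n_iter` must be a positive integer")
  x <- as.matrix(x)
  configs <- with_seed(seed, replicate(n_iter, draw_config(range),
                                       simplify = FALSE))
  objective <- vapply(configs, function(cfg)
    cv_objective(x, y, cfg, folds = folds, seed = seed), numeric(1))
  evaluations <- data.frame(
    iteration = seq_len(n_iter),
    kernel = vapply(configs, `[[`, "", "kernel"),
    poly_order = vapply(configs, `[[`, NA_integer_, "poly_order"),
    kernel_scale = vapply(configs, `[[`, NA_real_, "kernel_scale"),
    box_constraint = vapply(configs, `[[`, NA_real_, "box_constraint"),
    standardize = vapply(configs, `[[`, NA, "standardize"),
    objective = objective
  )
  best <- which.min(objective)  # first minimum on ties
  structure(list(
    evaluations = evaluations,
    min_observed = cummin(objective),
    best_config = configs[[best]],
    best_objective = objective[best],
    seed = seed
  ), class = "search_trace")
}

draw_config <- function(range) {
  kernel <- sample(c("gaussian", "linear", "polynomial"), 1)
  poly_order <- sample(2:4, 1)
  lr <- log(range)
  kernel_scale <- exp(runif(1, lr[1], lr[2]))
  box_constraint <- exp(runif(1, lr[1], lr[2]))
  standardize <- sample(c(TRUE, FALSE), 1)
  hyperparam_config(kernel, poly_order, kernel_scale, box_constraint,
                    standardize)
}

#' @export
print.search_trace <- function(x, ...) {
  cat(sprintf("<search_trace> %d evaluation(s); best objective %.4f\n",
              nrow(x$evaluations), x$best_objective))
  print(x$best_config)
  invisible(x)
}

#' Plot the minimum observed objective of a search
#'
#' @param x a [random_search()] trace.
#' @param ... passed to [graphics::plot()].
#' @export
plot.search_trace <- function(x, ...) {
  graphics::plot(seq_along(x$min_observed), 100 * x$min_observed,
                 type = "s", xlab = "Function evaluations",
                 ylab = "Minimum observed objective (%)", ...)
  invisible(x)
}
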