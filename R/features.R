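#' Per-spot mean RGB color change
#'
#' Averages the difference-map deltas over each labeled spot, per
#' channel. Row `k` is the mean absolute R, G, B change of spot `k`, in
#' 8-bit gray levels.
#'
#' @param dmap a [difference_map()] result.
#' @return A `K x 3` numeric matrix with columns `r`, `g`, `b`.
#' @export
spot_mean_rgb <- function(dmap) {
  if (!inherits(dmap, "difference_map")) stopf("expected a difference_map")
  lab <- label_matrix(dmap$labels)
  k <- spot_count(dmap$labels)
  out <- matrix(NA_real_, k, 3, dimnames = list(NULL, c("r", "g", "b")))
  for (ch in 1:3) {
    v <- dmap$deltas[, , ch]
    sums <- tapply(v[lab > 0], lab[lab > 0], mean)
    if (length(sums) != k || anyNA(sums))
      stopf("label with zero pixels in difference map")
    out[as.integer(names(sums)), ch] <- sums
  }
  out
}

#' Assemble the 18-element fingerprint vector
#'
#' Flattens the `6 x 3` table of per-spot channel means row-major:
#' `(s1_r, s1_g, s1_b, s2_r, ..., s6_b)`. Six dyes with three channels
#' each give the 18 color variables that fingerprint a sample.
#'
#' @param means a `6 x 3` matrix from [spot_mean_rgb()].
#' @return A named numeric vector of length 18.
#' @export
assemble_feature_vector <- function(means) {
  if (!is.matrix(means) || ncol(means) != 3)
    stopf("`means` must be a K x 3 matrix")
  if (nrow(means) != 6)
    stopf("expected 6 spots for the standard array, got %d", nrow(means))
  v <- as.numeric(t(means))
  names(v) <- feature_names()
  v
}

#' Names of the 18 fingerprint features
#'
#' @return `c("s1_r", "s1_g", "s1_b", ..., "s6_b")`.
#' @export
feature_names <- function() {
  paste0(rep(paste0("s", 1:6), each = 3), "_", c("r", "g", "b"))
}

#' Euclidean norm of a feature vector
#'
#' The overall response magnitude of the array: the square root of the
#' sum of squared vector components.
#'
#' @param v numeric vector.
#' @return A non-negative scalar.
#' @export
euclidean_norm <- function(v) sqrt(sum(v^2))

#' Extract the fingerprint of a pre/post image pair
#'
#' Convenience wrapper: segments the pre image, computes the difference
#' map and returns the 18-element feature vector.
#'
#' @inheritParams difference_map
#' @param ... passed to [segment_array()].
#' @return A named numeric vector of length 18.
#' @export
extract_features <- function(pre, post, labels = NULL, ...) {
  if (is.null(labels)) labels <- segment_array(pre, ...)
  dm <- difference_map(pre, post, labels)
  assemble_feature_vector(spot_mean_rgb(dm))
}

#' Response profile over a time-lapse exposure
#'
#' Computes the Euclidean norm of the fingerprint at each sampled time.
#' Used to decide how long the array must stay exposed before its color
#' changes saturate.
#'
#' @param frames list of `(time_min, features)` pairs, i.e. a list whose
#'   elements are lists with elements `time_min` and `features`.
#' @return An object of class `response_profile`: data.frame with
#'   columns `time_min` and `norm`.
#' @export
response_profile <- function(frames) {
  if (length(frames) < 2) stopf("need at least two frames")
  times <- vapply(frames, function(f) f$time_min, numeric(1))
  if (any(diff(times) <= 0)) stopf("frame times must be strictly increasing")
  norms <- vapply(frames, function(f) euclidean_norm(f$features), numeric(1))
  structure(data.frame(time_min = times, norm = norms),
            class = c("response_profile", "data.frame"))
}

#' Earliest steady-state time of a response profile
#'
#' Returns the earliest sampled time `t` such that every later sample
#' within `(t, t + window_min]` differs from `norm(t)` by at most
#' `epsilon * max(norm)`. This makes the usual visual judgment of "no
#' further variation" algorithmic. Only times whose stability window is
#' fully observable (`t + window_min` within the sampled range) are
#' eligible, so a profile that never flattens yields `NA` rather than a
#' vacuous hit at its last sample.
#'
#' @param profile a [response_profile()].
#' @param epsilon relative stability tolerance (default 0.02, i.e. 2% of
#'   the maximum response).
#' @param window_min stability window in minutes (default 10).
#' @return The steady-state time in minutes, or `NA` if the profile
#'   never stabilizes within its sampled range.
#' @export
steady_state_time <- function(profile, epsilon = 0.02, window_min = 10) {
  if (epsilon <= 0 || window_min <= 0)
    stopf("`epsilon` and `window_min` must be positive")
  t <- profile$time_min
  v <- profile$norm
  if (max(v) == 0) stopf("no response: all norms are zero")
  tol <- epsilon * max(v)
  for (i in seq_along(t)) {
    if (t[i] + window_min > t[length(t)]) break  # window not observable
    inwin <- which(t > t[i] & t <= t[i] + window_min)
    if (all(abs(v[inwin] - v[i]) <= tol)) return(t[i])
  }
  NA_real_
}

#' Pick the optimal exposure condition
#'
#' Among candidate conditions (each summarized by a response profile),
#' returns the one whose final-time norm is maximal. Ties are broken by
#' earliest steady-state time, then by input order.
#'
#' @param profiles named list of [response_profile()] objects.
#' @param ... passed to [steady_state_time()] for tie-breaking.
#' @return The name (or index, if unnamed) of the winning condition.
#' @export
optimal_exposure <- function(profiles, ...) {
  if (length(profiles) == 0) stopf("no candidate profiles")
  finals <- vapply(profiles, function(p) p$norm[nrow(p)], numeric(1))
  best <- which(finals == max(finals))
  if (length(best) > 1) {
    ss <- vapply(profiles[best], function(p) {
      s <- steady_state_time(p, ...)
      if (is.na(s)) Inf else s
    }, numeric(1))
    best <- best[which.min(ss)]  # which.min keeps input order on ties
  } else {
    best <- best[1]
  }
  if (!is.null(names(profiles)) && nzchar(names(profiles)[best]))
    names(profiles)[best]
  else best
}

#' Fit saturation kinetics to a response profile
#'
#' Fits `norm(t) = a * (1 - exp(-t / tau)) + c` by nonlinear least
#' squares. The offset `c` absorbs the pixel-noise floor of the
#' difference map at `t = 0`.
#'
#' @param profile a [response_profile()].
#' @return A list with `a`, `tau`, `c` and the `nls` fit.
#' @export
fit_response_kinetics <- function(profile) {
  t <- profile$time_min
  v <- profile$norm
  a0 <- max(v) - min(v)
  tau0 <- max(t[v < min(v) + 0.63 * a0], t[2]) # time to ~63% of the rise
  fit <- stats::nls(v ~ a * (1 - exp(-t / tau)) + c0,
                    start = list(a = a0, tau = tau0, c0 = min(v)),
                    control = stats::nls.control(maxiter = 200, warnOnly = TRUE))
  cf <- coef(fit)
  list(a = unname(cf["a"]), tau = unname(cf["tau"]), c = unname(cf["c0"]),
       fit = fit)
}

#' Read and write fingerprint feature tables
#'
#' The on-disk dialect is a CSV with header
#' `sample_id, label, s1_r, s1_g, s1_b, ..., s6_b`, one row per sample.
#'
#' @param x data.frame with columns `sample_id`, `label` and the 18
#'   feature columns.
#' @param path CSV path.
#' @return `read_feature_table()` returns the data.frame with `label`
#'   as a factor ordered by the 13-class scheme when applicable.
#' @export
write_feature_table <- function(x, path) {
  cols <- c("sample_id", "label", feature_names())
  missing <- setdiff(cols, names(x))
  if (length(missing)) stopf("missing columns: %s", paste(missing, collapse = ", "))
  write.csv(x[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  cols <- c("sample_id", "label", feature_names())
  missing <- setdiff(cols, names(x))
  if (length(missing)) stopf("malformed feature table, missing: %s",
                             paste(missing, collapse = ", "))
  if (all(x$label %in% oil_classes())) {
    x$label <- factor(x$label, levels = oil_classes())
  } else {
    x$label <- factor(x$label)
  }
  x
}

#' Write a response profile as CSV
#'
#' @param profile a [response_profile()].
#' @param path CSV path with columns `time_min, norm`.
#' @export
write_response_profile <- function(profile, path) {
  write.csv(as.data.frame(profile)[, c("time_min", "norm")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_response_profile
#' @export
read_response_profile <- function(path) {
  x <- read.csv(path)
  structure(data.frame(time_min = x$time_min, norm = x$norm),
            class = c("response_profile", "data.frame"))
}
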