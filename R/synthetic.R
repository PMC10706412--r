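#' Specification of a synthetic sensor-array experiment
#'
#' Describes the generative model used to emulate laboratory sensor
#' arrays: a 2 x 3 grid of circular dye spots on a bright plate
#' background, whose post-exposure colors shift by a class-dependent
#' amount. Mixture classes interpolate linearly between the pure-oil
#' shift matrices; each sample gets i.i.d. Gaussian pixel noise and a
#' random linear illumination gradient.
#'
#' Default geometry is a 480 x 640 px image with spot radius 40 px
#' (area about 5000 px, comfortably above the 1000 px cleanup
#' threshold) and 160 px center spacing — a 2 cm plate with 5 mm spot
#' spacing imaged at roughly 80 px/cm. The default shift matrices keep
#' a fixed sign per (spot, channel), so mixture fingerprints move
#' linearly between the pure-oil fingerprints; the three pure oils are
#' mutually at least 40 gray levels apart, with spots 1, 4 and 6 most
#' responsive to sesame.
#'
#' @param image_size `(height, width)` in pixels.
#' @param spot_radius spot radius in pixels; the spot area must exceed
#'   1000 px so real spots survive area opening.
#' @param spacing center-to-center spot spacing in pixels.
#' @param background_color RGB triple of the plate background.
#' @param base_colors `6 x 3` matrix of pre-exposure dye colors (rows =
#'   spots in reading order).
#' @param shift_pure_q,shift_pure_su,shift_pure_se `6 x 3` matrices of
#'   true post-minus-pre color shifts for the three pure oils, entries
#'   in `[-255, 255]`.
#' @param noise_sd per-pixel Gaussian noise SD in gray levels
#'   (default 3).
#' @param illumination_gradient maximum fractional brightness slope of
#'   the per-sample linear illumination field (default 0.03).
#' @param kinetics_tau_min saturation time constant of the color change
#'   in minutes (default 20, putting ~95% of the response at 60 min).
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(image_size = c(480, 640),
                           spot_radius = 40,
                           spacing = 160,
                           background_color = c(225, 222, 215),
                           base_colors = default_base_colors(),
                           shift_pure_q = default_shift("quince"),
                           shift_pure_su = default_shift("sunflower"),
                           shift_pure_se = default_shift("sesame"),
                           noise_sd = 3,
                           illumination_gradient = 0.03,
                           kinetics_tau_min = 20) {
  if (pi * spot_radius^2 <= 1000)
    stopf("spot_radius %g gives area %.0f px <= 1000; spots would be removed by area opening",
          spot_radius, pi * spot_radius^2)
  for (m in list(shift_pure_q, shift_pure_su, shift_pure_se)) {
    if (!is.matrix(m) || !all(dim(m) == c(6, 3)))
      stopf("shift matrices must be 6 x 3")
    if (max(abs(m)) > 255) stopf("shift entries must lie in [-255, 255]")
  }
  if (!is.matrix(base_colors) || !all(dim(base_colors) == c(6, 3)))
    stopf("`base_colors` must be 6 x 3")
  structure(list(
    image_size = image_size, spot_radius = spot_radius, spacing = spacing,
    background_color = background_color, base_colors = base_colors,
    shift_pure_q = shift_pure_q, shift_pure_su = shift_pure_su,
    shift_pure_se = shift_pure_se, noise_sd = noise_sd,
    illumination_gradient = illumination_gradient,
    kinetics_tau_min = kinetics_tau_min
  ), class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("<synthetic_spec> %d x %d px, r = %g px, noise sd = %g, tau = %g min\n",
              x$image_size[1], x$image_size[2], x$spot_radius, x$noise_sd,
              x$kinetics_tau_min))
  invisible(x)
}

# Plausible pre-exposure colors for the six indicator dyes, reading
# order: methyl violet, chlorophenol red, Nile blue, methyl orange,
# alizarin, cresol red.
default_base_colors <- function() {
  matrix(c(
    112,  48, 160,   # S1 methyl violet
    196,  90,  60,   # S2 chlorophenol red
     40,  70, 170,   # S3 Nile blue
    200, 140,  40,   # S4 methyl orange (kept below 205 so the largest
                     # positive shift cannot clip at 255)
    190,  60,  90,   # S5 alizarin
    200, 120,  70    # S6 cresol red
  ), nrow = 6, ncol = 3, byrow = TRUE,
  dimnames = list(paste0("s", 1:6), c("r", "g", "b")))
}

# True post-minus-pre shifts per pure oil. A fixed sign pattern per
# (spot, channel) means mixtures interpolate magnitudes monotonically;
# magnitudes were chosen once so the three pure-oil fingerprints are
# mutually >= 40 gray levels apart and S1/S4/S6 respond most to sesame.
default_shift <- function(oil = c("quince", "sunflower", "sesame")) {
  oil <- match.arg(oil)
  signs <- matrix(c(
     1, -1,  1,
     1,  1, -1,
    -1,  1,  1,
     1,  1,  1,
     1, -1,  1,
     1,  1, -1
  ), nrow = 6, byrow = TRUE)
  mags <- switch(oil,
    quince = c(25, 10,  5,  10, 20,  5,  15,  5, 20,  20, 15,  4,   5, 20, 10,  15, 10, 20),
    sunflower = c(10,  5, 15,  40, 10, 10,   5, 35, 15,  10,  5, 10,  25, 15, 30,   5, 25,  5),
    sesame = c(50, 20, 15,  15, 10,  5,   5, 15, 10,  45, 20, 25,  15,  5,  5,  40, 30, 35))
  m <- signs * matrix(mags, nrow = 6, byrow = TRUE)
  dimnames(m) <- list(paste0("s", 1:6), c("r", "g", "b"))
  m
}

#' True color-shift matrix of a mixture class
#'
#' Linear mixing: `(1 - fraction) * shift_pure_q + fraction *
#' shift_pure_adulterant`, standing in for VOC blending — fingerprints
#' vary smoothly with the adulterant volume ratio.
#'
#' @param spec a [synthetic_spec()].
#' @param adulterant `"none"`, `"sunflower"` or `"sesame"`.
#' @param fraction adulterant volume fraction in `[0, 1]`.
#' @return A `6 x 3` shift matrix.
#' @export
class_shift <- function(spec, adulterant = c("none", "sunflower", "sesame"),
                        fraction = 0) {
  adulterant <- match.arg(adulterant)
  if (!is.numeric(fraction) || fraction < 0 || fraction > 1)
    stopf("`fraction` must be in [0, 1]")
  pure <- switch(adulterant,
    none = spec$shift_pure_q,
    sunflower = spec$shift_pure_su,
    sesame = spec$shift_pure_se)
  (1 - fraction) * spec$shift_pure_q + fraction * pure
}

# Grid centers of the 2 x 3 layout, reading order (1-based row, col).
grid_centers <- function(spec) {
  h <- spec$image_size[1]; w <- spec$image_size[2]; s <- spec$spacing
  rows <- h / 2 + c(-s / 2, s / 2)
  cols <- w / 2 + c(-s, 0, s)
  cbind(row = rep(rows, each = 3), col = rep(cols, times = 2))
}

# Antialiased coverage of each spot: 1 inside, 0 outside, linear ramp
# across the one-pixel boundary band.
spot_coverage <- function(spec) {
  h <- spec$image_size[1]; w <- spec$image_size[2]
  centers <- grid_centers(spec)
  r <- spec$spot_radius
  ri <- matrix(seq_len(h), h, w)
  ci <- matrix(seq_len(w), h, w, byrow = TRUE)
  cov <- vector("list", 6)
  for (k in 1:6) {
    d <- sqrt((ri - centers[k, 1])^2 + (ci - centers[k, 2])^2)
    cov[[k]] <- pmin(pmax(r + 0.5 - d, 0), 1)
  }
  cov
}

# Ground-truth label map: fully covered pixels of each spot, labeled in
# reading order.
truth_label_map <- function(spec, coverage = spot_coverage(spec)) {
  h <- spec$image_size[1]; w <- spec$image_size[2]
  lab <- matrix(0L, h, w)
  for (k in 1:6) lab[coverage[[k]] >= 1] <- k
  centers <- grid_centers(spec)
  structure(list(labels = lab, centroids = centers, k = 6L),
            class = "spot_label_map")
}

# Composite an array image: background + spots (by coverage), optional
# illumination field, then noise, clipped to [0, 255].
compose_image <- function(spec, spot_colors, illum, noise_sd, coverage) {
  h <- spec$image_size[1]; w <- spec$image_size[2]
  px <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) {
    plane <- matrix(spec$background_color[ch], h, w)
    for (k in 1:6) {
      cv <- coverage[[k]]
      plane <- plane + cv * (spot_colors[k, ch] - spec$background_color[ch])
    }
    plane <- plane * illum
    if (noise_sd > 0) plane <- plane + rnorm(h * w, sd = noise_sd)
    px[, , ch] <- pmin(pmax(plane, 0), 255)
  }
  px
}

# Per-sample linear illumination field, direction and magnitude drawn
# from the current RNG stream.
illumination_field <- function(spec) {
  h <- spec$image_size[1]; w <- spec$image_size[2]
  g <- spec$illumination_gradient
  if (g <= 0) return(matrix(1, h, w))
  theta <- runif(1, 0, 2 * pi)
  amp <- runif(1, 0, g)
  ri <- (matrix(seq_len(h), h, w) - (h + 1) / 2) / h
  ci <- (matrix(seq_len(w), h, w, byrow = TRUE) - (w + 1) / 2) / w
  1 + amp * (cos(theta) * ri + sin(theta) * ci)
}

#' Render a synthetic pre/post image pair with ground truth
#'
#' Draws the array before exposure (base dye colors) and after exposure
#' (base colors plus the class's true shift, clipped to `[0, 255]`),
#' with a shared per-sample illumination field and independent pixel
#' noise per capture. All randomness derives from `sample_seed`.
#'
#' @inheritParams class_shift
#' @param sample_seed integer seed for this sample.
#' @return A list with `pre`, `post` ([sensor_image]s) and `truth`
#'   (list: `labels` ground-truth [label_spots()]-style map of fully
#'   covered pixels, `true_shift`, `class_label`, `adulterant`,
#'   `fraction`).
#' @export
render_pair <- function(spec, adulterant = c("none", "sunflower", "sesame"),
                        fraction = 0, sample_seed = 0) {
  adulterant <- match.arg(adulterant)
  check_geometry(spec)
  shift <- class_shift(spec, adulterant, fraction)
  coverage <- spot_coverage(spec)
  out <- with_seed(sample_seed, {
    illum <- illumination_field(spec)
    pre <- compose_image(spec, spec$base_colors, illum, spec$noise_sd, coverage)
    post <- compose_image(spec, spec$base_colors + shift, illum,
                          spec$noise_sd, coverage)
    list(pre = pre, post = post)
  })
  truth <- list(
    labels = truth_label_map(spec, coverage),
    true_shift = shift,
    class_label = oil_class_label(adulterant, fraction),
    adulterant = adulterant,
    fraction = fraction
  )
  list(pre = sensor_image(out$pre, "pre"),
       post = sensor_image(out$post, "post"),
       truth = truth)
}

check_geometry <- function(spec) {
  h <- spec$image_size[1]; w <- spec$image_size[2]
  centers <- grid_centers(spec)
  r <- spec$spot_radius
  if (any(centers[, 1] - r < 1) || any(centers[, 1] + r > h) ||
      any(centers[, 2] - r < 1) || any(centers[, 2] + r > w))
    stopf("spots exceed the image bounds")
  if (spec$spacing < 2 * r + 2) stopf("spots overlap: spacing %g < 2r + 2",
                                      spec$spacing)
  invisible(TRUE)
}

#' Render a synthetic exposure time-lapse
#'
#' Frame at time `t` carries the class shift scaled by
#' `1 - exp(-t / kinetics_tau_min)` — saturating first-order kinetics —
#' with independent pixel noise per frame and a shared illumination
#' field.
#'
#' @inheritParams render_pair
#' @param times_min strictly increasing, non-negative times in minutes.
#' @return A list of [sensor_image]s (the first frame, `t = 0` or the
#'   earliest time, has phase `"pre"`, later frames `"post"`), plus an
#'   attribute `truth` as in [render_pair()].
#' @export
render_timelapse <- function(spec, adulterant = c("none", "sunflower", "sesame"),
                             fraction = 0, times_min = 0:120,
                             sample_seed = 0) {
  adulterant <- match.arg(adulterant)
  if (length(times_min) == 0) stopf("`times_min` must be non-empty")
  if (any(diff(times_min) <= 0) || any(times_min < 0))
    stopf("`times_min` must be non-negative and strictly increasing")
  check_geometry(spec)
  shift <- class_shift(spec, adulterant, fraction)
  coverage <- spot_coverage(spec)
  frames <- with_seed(sample_seed, {
    illum <- illumination_field(spec)
    lapply(seq_along(times_min), function(i) {
      scale <- 1 - exp(-times_min[i] / spec$kinetics_tau_min)
      compose_image(spec, spec$base_colors + scale * shift, illum,
                    spec$noise_sd, coverage)
    })
  })
  out <- lapply(seq_along(frames), function(i) {
    sensor_image(frames[[i]], if (i == 1) "pre" else "post",
                 time_min = times_min[i])
  })
  attr(out, "truth") <- list(
    labels = truth_label_map(spec, coverage), true_shift = shift,
    class_label = oil_class_label(adulterant, fraction),
    adulterant = adulterant, fraction = fraction,
    tau_min = spec$kinetics_tau_min
  )
  out
}

#' Response profile of a time-lapse frame sequence
#'
#' Extracts the fingerprint of every frame against the first frame
#' (using a fixed label map, segmented from the first frame by default)
#' and returns the Euclidean-norm response over time.
#'
#' @param frames list of [sensor_image]s from [render_timelapse()] or
#'   read from disk, with strictly increasing `time_min`.
#' @param labels optional [label_spots()] map; segmented from the first
#'   frame when omitted.
#' @param ... passed to [segment_array()].
#' @return A [response_profile()].
#' @export
timelapse_profile <- function(frames, labels = NULL, ...) {
  if (length(frames) < 2) stopf("need at least two frames")
  if (is.null(labels)) labels <- segment_array(frames[[1]], ...)
  ref <- frames[[1]]
  ref$phase <- "pre"
  feats <- lapply(frames, function(f) {
    f$phase <- "post"
    dm <- difference_map(ref, f, labels)
    list(time_min = f$time_min,
         features = assemble_feature_vector(spot_mean_rgb(dm)))
  })
  response_profile(feats)
}

#' Generate a labeled synthetic dataset through the full pipeline
#'
#' Renders `n_per_class` image pairs for each of the 13 adulteration
#' classes (pure quince; 10–50% sunflower; pure sunflower; 10–50%
#' sesame; pure sesame), runs every pair through the imaging pipeline
#' (segmentation, difference map, fingerprint), and returns the feature
#' table. The default 8 pairs per class yields the canonical 104-sample
#' design.
#'
#' @param spec a [synthetic_spec()].
#' @param n_per_class samples per class (default 8).
#' @param seed master seed; per-sample seeds are derived
#'   deterministically from it.
#' @param keep_truth attach ground-truth shift matrices as an attribute.
#' @return A data.frame with columns `sample_id`, `label` (factor in
#'   13-class order), `adulterant`, `fraction` and the 18 feature
#'   columns; ground truth in `attr(, "truth")` when requested.
#' @export
make_dataset <- function(spec, n_per_class = 8, seed = 0, keep_truth = FALSE) {
  if (!is_count(n_per_class)) stopf("`n_per_class` must be a positive integer")
  classes <- rbind(
    data.frame(adulterant = "none", fraction = 0),
    data.frame(adulterant = "sunflower", fraction = c(seq(0.1, 0.5, 0.1), 1)),
    data.frame(adulterant = "sesame", fraction = c(seq(0.1, 0.5, 0.1), 1))
  )
  n_total <- nrow(classes) * n_per_class
  seeds <- derive_seeds(seed, n_total)
  rows <- vector("list", n_total)
  truths <- if (keep_truth) vector("list", n_total) else NULL
  i <- 0
  for (c_idx in seq_len(nrow(classes))) {
    for (rep in seq_len(n_per_class)) {
      i <- i + 1
      pair <- render_pair(spec, classes$adulterant[c_idx],
                          classes$fraction[c_idx], sample_seed = seeds[i])
      feats <- tryCatch(
        extract_features(pair$pre, pair$post),
        error = function(e) stopf(
          "segmentation failed for sample_seed %d (%s %g%%): %s",
          seeds[i], classes$adulterant[c_idx],
          100 * classes$fraction[c_idx], conditionMessage(e))
      )
      rows[[i]] <- data.frame(
        sample_id = sprintf("sample_%03d", i),
        label = pair$truth$class_label,
        adulterant = classes$adulterant[c_idx],
        fraction = classes$fraction[c_idx],
        t(feats)
      )
      if (keep_truth) truths[[i]] <- pair$truth$true_shift
    }
  }
  out <- do.call(rbind, rows)
  out$label <- factor(out$label, levels = oil_classes())
  if (keep_truth) attr(out, "truth") <- truths
  out
}
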