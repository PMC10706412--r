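#' Convert an RGB sensor image to luminance
#'
#' Uses the ITU-R BT.601 weights `0.2989 R + 0.5870 G + 0.1140 B`, the
#' conventional luminance transform; Otsu thresholding operates on this
#' scalar raster.
#'
#' @param image a [sensor_image] or `height x width x 3` array on `[0, 255]`.
#' @return A numeric matrix of luminance values in `[0, 255]`.
#' @examples
#' img <- sensor_image(array(200, dim = c(2, 2, 3)), "pre")
#' to_grayscale(img)[1, 1]  # 200
#' @export
to_grayscale <- function(image) {
  px <- if (inherits(image, "sensor_image")) image$pixels else image
  if (length(dim(px)) != 3 || dim(px)[3] != 3)
    stopf("expected an RGB raster")
  0.2989 * px[, , 1] + 0.5870 * px[, , 2] + 0.1140 * px[, , 3]
}

#' Otsu threshold of a grayscale raster
#'
#' Picks the threshold maximizing the between-class variance over the
#' 256-bin intensity histogram (bins are integer gray levels 0..255, a
#' pixel's bin is `floor(value)`). Ties are broken towards the smallest
#' threshold. Pixels whose bin exceeds the threshold form the `TRUE`
#' class of the returned mask.
#'
#' @param gray numeric matrix with values in `[0, 255]` containing at
#'   least two distinct bin values.
#' @return A list with `threshold` (a value in 0..254) and `mask`
#'   (logical matrix, `TRUE` where `floor(gray) > threshold`).
#' @export
otsu_threshold <- function(gray) {
  if (!is.matrix(gray)) stopf("`gray` must be a matrix")
  bins <- pmin(pmax(floor(gray), 0), 255)
  counts <- tabulate(as.integer(bins) + 1L, nbins = 256L)
  if (sum(counts > 0) < 2) stopf("degenerate histogram: raster is constant")
  n <- sum(counts)
  levels <- 0:255
  w0 <- cumsum(counts)                  # pixels with bin <= t
  sum0 <- cumsum(counts * levels)
  total <- sum0[256]
  mu0 <- ifelse(w0 > 0, sum0 / w0, 0)
  w1 <- n - w0
  mu1 <- ifelse(w1 > 0, (total - sum0) / w1, 0)
  between <- (w0 / n) * (w1 / n) * (mu0 - mu1)^2
  between[w0 == 0 | w1 == 0] <- -Inf
  t <- which.max(between) - 1L          # which.max takes the first maximum
  list(threshold = t, mask = bins > t)
}

#' Remove small connected components (area opening)
#'
#' Deletes every 8-connected foreground component whose pixel count is
#' strictly below `min_area`; larger components pass through bit-exact.
#'
#' @param mask logical matrix.
#' @param min_area positive integer; components smaller than this are
#'   removed (default 1000 px, the standard cleanup threshold for this
#'   array geometry).
#' @return A logical matrix of the same shape.
#' @export
area_open <- function(mask, min_area = 1000) {
  if (!is_count(min_area)) stopf("`min_area` must be a positive integer")
  mask <- as_mask(mask)
  lab <- cc_label_8(mask)
  if (max(lab) == 0) return(mask)
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  keep <- which(sizes >= min_area)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

#' Erode a mask and fill small interior holes
#'
#' Applies morphological erosion with a disk structuring element (pixels
#' at Euclidean distance `<= erosion_radius` from the center), then fills
#' every background hole — an 8-connected background component not
#' touching the raster border — whose size is strictly below `max_hole`
#' (area closing).
#'
#' @param mask logical matrix.
#' @param erosion_radius disk radius in pixels (default 3).
#' @param max_hole holes smaller than this many pixels are filled
#'   (default 1000, mirroring the opening threshold).
#' @return A logical matrix of the same shape.
#' @export
refine_mask <- function(mask, erosion_radius = 3, max_hole = 1000) {
  if (!is_count(erosion_radius)) stopf("`erosion_radius` must be a positive integer")
  if (!is_count(max_hole)) stopf("`max_hole` must be a positive integer")
  mask <- as_mask(mask)
  fill_holes(erode_disk(mask, erosion_radius), max_hole)
}

# Erosion by a disk of radius r: out(p) is TRUE iff every offset of the
# disk lands on a TRUE pixel (pixels outside the raster count as FALSE).
erode_disk <- function(mask, r) {
  h <- nrow(mask); w <- ncol(mask)
  off <- expand.grid(di = -r:r, dj = -r:r)
  off <- off[off$di^2 + off$dj^2 <= r^2, ]
  pad <- matrix(FALSE, h + 2 * r, w + 2 * r)
  pad[(1:h) + r, (1:w) + r] <- mask
  out <- matrix(TRUE, h, w)
  for (k in seq_len(nrow(off))) {
    out <- out & pad[(1:h) + r + off$di[k], (1:w) + r + off$dj[k]]
  }
  out
}

# Fill 8-connected background components smaller than max_hole that do
# not touch the raster border.
fill_holes <- function(mask, max_hole) {
  bg <- cc_label_8(!mask)
  if (max(bg) == 0) return(mask)
  border_labels <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  sizes <- tabulate(bg[bg > 0], nbins = max(bg))
  fill <- setdiff(which(sizes < max_hole), border_labels)
  mask[bg %in% fill] <- TRUE
  mask
}

#' Label indicator spots in reading order
#'
#' Labels the 8-connected foreground components 1..K in reading order:
#' components are grouped into rows by their centroid row (a gap larger
#' than half the median component height starts a new row), rows are
#' ordered top to bottom, and labels increase left to right within a row.
#'
#' @param mask logical matrix with exactly `expected_k` components.
#' @param expected_k the number of indicator spots on the array
#'   (default 6 for the standard 2 x 3 layout).
#' @return An object of class `spot_label_map`: a list with `labels`
#'   (integer matrix, 0 = background), `centroids` (`K x 2` matrix of
#'   1-based `(row, col)` means) and `k`.
#' @export
label_spots <- function(mask, expected_k = 6) {
  if (!is_count(expected_k)) stopf("`expected_k` must be a positive integer")
  mask <- as_mask(mask)
  lab <- cc_label_8(mask)
  k <- max(lab)
  if (k == 0) stopf("mask has no foreground component")
  if (k != expected_k)
    stopf("segmentation found %d component(s), expected %d", k, expected_k)
  idx <- which(lab > 0, arr.ind = TRUE)
  comp <- lab[lab > 0]
  cr <- tapply(idx[, 1], comp, mean)
  cc <- tapply(idx[, 2], comp, mean)
  heights <- tapply(idx[, 1], comp, function(r) diff(range(r)) + 1)
  # group into rows: new row when the centroid-row gap exceeds half the
  # median component height
  ord <- order(cr)
  gap <- stats::median(heights) / 2
  band <- integer(k)
  band[ord[1]] <- 1L
  for (i in seq_len(k - 1)) {
    prev <- ord[i]; cur <- ord[i + 1]
    band[cur] <- band[prev] + (cr[cur] - cr[prev] > gap)
  }
  reading <- order(band, cc)
  relabel <- integer(k)
  relabel[reading] <- seq_len(k)
  out <- matrix(0L, nrow(mask), ncol(mask))
  out[lab > 0] <- relabel[comp]
  centroids <- cbind(row = as.numeric(cr[reading]),
                     col = as.numeric(cc[reading]))
  structure(list(labels = out, centroids = centroids, k = k),
            class = "spot_label_map")
}

#' @export
print.spot_label_map <- function(x, ...) {
  cat(sprintf("<spot_label_map> %d spot(s) on a %d x %d raster\n",
              x$k, nrow(x$labels), ncol(x$labels)))
  print(round(x$centroids, 1))
  invisible(x)
}

#' Zero out background pixels of a sensor image
#'
#' Multiplies the image by the spot mask: pixels with label 0 become
#' black, labeled spot pixels pass through unchanged.
#'
#' @param image a [sensor_image].
#' @param labels a [label_spots()] result (or a logical/integer matrix).
#' @return A [sensor_image] with the same phase metadata.
#' @export
apply_mask <- function(image, labels) {
  lab <- label_matrix(labels)
  px <- image$pixels
  if (!identical(dim(px)[1:2], dim(lab)))
    stopf("image and label map shapes differ")
  keep <- lab > 0
  px[, , 1][!keep] <- 0
  px[, , 2][!keep] <- 0
  px[, , 3][!keep] <- 0
  sensor_image(px, image$phase, image$time_min)
}

#' Per-pixel absolute color-difference map
#'
#' Subtracts the pre-exposure image from the post-exposure image inside
#' the labeled spots and takes the absolute value per pixel per channel;
#' background pixels are 0. The resulting raster is the VOC fingerprint
#' of the sample. Correspondence between the two captures is by label
#' index (the array is assumed untouched between captures); if a label
#' map derived from the post image is supplied, paired centroids must
#' agree within `max_shift` pixels.
#'
#' @param pre,post [sensor_image]s with phases `"pre"` and `"post"` and
#'   identical shapes.
#' @param labels [label_spots()] result computed from the pre image.
#' @param post_labels optional label map from the post image, used only
#'   for the registration guard.
#' @param max_shift maximum tolerated centroid displacement in pixels
#'   (default 5).
#' @return An object of class `difference_map`: list with `deltas`
#'   (`height x width x 3`, non-negative) and `labels`.
#' @export
difference_map <- function(pre, post, labels, post_labels = NULL,
                           max_shift = 5) {
  if (!inherits(pre, "sensor_image") || !inherits(post, "sensor_image"))
    stopf("`pre` and `post` must be sensor_image objects")
  if (pre$phase != "pre" || post$phase != "post")
    stopf("phase mismatch: expected pre.phase = 'pre', post.phase = 'post'")
  check_same_shape(pre, post)
  lab <- label_matrix(labels)
  if (!identical(dim(pre$pixels)[1:2], dim(lab)))
    stopf("label map shape does not match the images")
  if (!is.null(post_labels)) {
    a <- labels$centroids
    b <- post_labels$centroids
    if (nrow(a) != nrow(b))
      stopf("pre and post label maps have different spot counts")
    shift <- sqrt(rowSums((a - b)^2))
    if (any(shift > max_shift))
      stopf("array moved between captures: max centroid shift %.1f px > %g",
            max(shift), max_shift)
  }
  keep <- lab > 0
  deltas <- abs(post$pixels - pre$pixels)
  deltas[, , 1][!keep] <- 0
  deltas[, , 2][!keep] <- 0
  deltas[, , 3][!keep] <- 0
  structure(list(deltas = deltas, labels = labels), class = "difference_map")
}

#' @export
print.difference_map <- function(x, ...) {
  d <- dim(x$deltas)
  cat(sprintf("<difference_map> %d x %d px, %d spot(s), max delta %.1f\n",
              d[1], d[2], spot_count(x$labels), max(x$deltas)))
  invisible(x)
}

#' Rescale a difference map for display
#'
#' Maps the informative 6-bit range 3..62 of the color differences onto
#' the full 8-bit range 0..255 for visualization:
#' `round((clip(v, 3, 62) - 3) * 255 / 59)` with half-away-from-zero
#' rounding. Analysis always uses the raw deltas; this transform is for
#' figures only.
#'
#' @param deltas a `difference_map` or a numeric array.
#' @param lo,hi input range endpoints (defaults 3 and 62).
#' @return A [sensor_image] (phase `"post"`) holding the display raster.
#' @export
rescale_for_display <- function(deltas, lo = 3, hi = 62) {
  v <- if (inherits(deltas, "difference_map")) deltas$deltas else deltas
  scaled <- round_half_up((pmin(pmax(v, lo), hi) - lo) * 255 / (hi - lo))
  if (length(dim(scaled)) == 3)
    sensor_image(scaled, "post")
  else scaled
}

#' Segment a sensor-array photograph end to end
#'
#' Runs the full segmentation chain: luminance, Otsu thresholding
#' (foreground polarity chosen as the class whose mean luminance differs
#' more from the border pixels' mean, since the border is reliably plate
#' background), area opening, erosion + hole filling, and reading-order
#' labeling.
#'
#' @param image a [sensor_image].
#' @param min_area area-opening threshold in pixels (default 1000).
#' @param erosion_radius disk radius for [refine_mask()] (default 3).
#' @param max_hole area-closing threshold in pixels (default 1000).
#' @param expected_k expected spot count (default 6).
#' @return A `spot_label_map` (see [label_spots()]).
#' @export
segment_array <- function(image, min_area = 1000, erosion_radius = 3,
                          max_hole = 1000, expected_k = 6) {
  gray <- to_grayscale(image)
  ot <- otsu_threshold(gray)
  mask <- ot$mask
  # polarity: spots are the class farther in mean luminance from the border
  border <- c(gray[1, ], gray[nrow(gray), ], gray[, 1], gray[, ncol(gray)])
  mb <- mean(border)
  if (abs(mean(gray[mask]) - mb) < abs(mean(gray[!mask]) - mb)) mask <- !mask
  mask <- area_open(mask, min_area)
  mask <- refine_mask(mask, erosion_radius, max_hole)
  label_spots(mask, expected_k)
}

#' Write a binary mask or label map as PNG
#'
#' Masks are written as black/white 8-bit PNG. Label maps are written as
#' single-channel 8-bit PNG holding the raw label index (0 = background);
#' the spot count of this array geometry never approaches the 8-bit
#' ceiling.
#'
#' @param x logical matrix, integer matrix, or `spot_label_map`.
#' @param path output `.png` path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(x, path) {
  m <- label_matrix(x)
  png::writePNG(m / 255, path)
  invisible(path)
}

# ---- internal coercions ----

as_mask <- function(mask) {
  if (inherits(mask, "spot_label_map")) return(mask$labels > 0)
  if (is.logical(mask) && is.matrix(mask)) return(mask)
  if (is.numeric(mask) && is.matrix(mask)) return(mask > 0)
  stopf("expected a logical matrix mask")
}

label_matrix <- function(labels) {
  if (inherits(labels, "spot_label_map")) return(labels$labels)
  if (is.logical(labels)) return(matrix(as.integer(labels), nrow(labels)))
  if (is.numeric(labels) && is.matrix(labels)) return(labels)
  stopf("expected a spot_label_map or label matrix")
}

spot_count <- function(labels) {
  if (inherits(labels, "spot_label_map")) labels$k else max(label_matrix(labels))
}
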