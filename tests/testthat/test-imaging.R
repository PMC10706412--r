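test_that("grayscale conversion uses BT.601 luminance weights", {
  # the conventional 4-digit weights sum to 0.9999, so a uniform image
  # comes back uniform to within that truncation
  uni <- sensor_image(array(200, dim = c(3, 3, 3)), "pre")
  expect_equal(to_grayscale(uni), matrix(200 * 0.9999, 3, 3))
  expect_equal(to_grayscale(uni), matrix(200, 3, 3), tolerance = 2e-4)

  red <- array(0, dim = c(2, 2, 3)); red[, , 1] <- 255
  expect_equal(to_grayscale(sensor_image(red, "pre")),
               matrix(0.2989 * 255, 2, 2))

  black <- sensor_image(array(0, dim = c(2, 2, 3)), "pre")
  expect_true(all(to_grayscale(black) == 0))
})

test_that("Otsu threshold separates bimodal rasters and rejects constants", {
  g <- matrix(c(rep(50, 1000), rep(200, 200)), 40, 30)
  ot <- otsu_threshold(g)
  expect_gte(ot$threshold, 50)
  expect_lt(ot$threshold, 200)
  expect_identical(sum(ot$mask), 200L)

  g2 <- matrix(c(0, 255, 255, 0), 2, 2)
  ot2 <- otsu_threshold(g2)
  expect_identical(ot2$mask, g2 == 255)

  expect_error(otsu_threshold(matrix(7, 4, 4)), "degenerate")
})

test_that("Otsu matches the exhaustive brute-force maximizer", {
  set.seed(11)
  for (i in 1:20) {
    g <- matrix(runif(32 * 32, 0, 255), 32, 32)
    expect_identical(as.integer(otsu_threshold(g)$threshold),
                     as.integer(otsu_brute(g)))
  }
})

test_that("area opening removes components strictly below the threshold", {
  m <- matrix(FALSE, 60, 80)
  m[2:34, 2:34] <- TRUE          # 33 x 33 = 1089 px
  m[40:50, 40:50] <- FALSE
  small <- matrix(FALSE, 60, 80)
  small[40:56, 50:60] <- TRUE    # 17 x 11 = 187 px
  m2 <- m | small
  out <- area_open(m2, 1000)
  expect_identical(out, m)

  # boundary of the strict inequality: exactly 1000 px is preserved
  exact <- matrix(FALSE, 50, 50)
  exact[1:40, 1:25] <- TRUE      # 1000 px
  expect_identical(area_open(exact, 1000), exact)
  expect_identical(area_open(exact, 1001), matrix(FALSE, 50, 50))

  empty <- matrix(FALSE, 5, 5)
  expect_identical(area_open(empty, 10), empty)
  expect_error(area_open(empty, 0), "positive")
})

test_that("area opening is idempotent and matches the component oracle", {
  set.seed(21)
  for (i in 1:10) {
    m <- matrix(runif(16 * 16) > 0.55, 16, 16)
    expect_identical(area_open(m, 5), area_open_brute(m, 5))
    expect_identical(area_open(area_open(m, 5), 5), area_open(m, 5))
  }
})

test_that("erosion follows the pixelwise disk definition", {
  sq <- matrix(FALSE, 60, 60)
  sq[6:55, 6:55] <- TRUE
  er <- refine_mask(sq, erosion_radius = 2, max_hole = 1)
  expected <- matrix(FALSE, 60, 60)
  expected[8:53, 8:53] <- TRUE   # 46 x 46, centered
  expect_identical(er, expected)

  set.seed(31)
  for (i in 1:8) {
    m <- matrix(runif(16 * 16) > 0.35, 16, 16)
    expect_identical(refine_mask(m, 2, 1), erode_brute(m, 2))
  }

  # erosion is anti-extensive
  m <- matrix(runif(20 * 20) > 0.3, 20, 20)
  expect_true(all(m[refine_mask(m, 1, 1)]))

  # radius larger than the component empties it
  tiny <- matrix(FALSE, 12, 12)
  tiny[5:7, 5:7] <- TRUE
  expect_false(any(refine_mask(tiny, 4, 1)))
})

test_that("hole filling closes interior holes below the size threshold", {
  d <- disk_mask(40, 40, 20, 20, 12)
  holed <- d
  holed[19:21, 19:21] <- FALSE   # 9 px interior hole
  expect_identical(refine_mask(holed, 1, 100), erode_brute(d, 1))

  # hole at/above max_hole stays open
  big_holed <- d
  big_holed[15:25, 15:25] <- FALSE
  out <- refine_mask(big_holed, 1, 50)
  expect_true(any(!out[16:24, 16:24]))

  expect_error(refine_mask(d, 1, 0), "positive")
})

test_that("spots are labeled in reading order", {
  m <- matrix(FALSE, 80, 130)
  centers <- rbind(c(20, 20), c(20, 60), c(20, 100),
                   c(55, 20), c(55, 60), c(55, 100))
  for (k in 1:6) m <- m | disk_mask(80, 130, centers[k, 1], centers[k, 2], 7)
  lab <- label_spots(m, 6)
  expect_identical(lab$k, 6L)
  expect_equal(lab$centroids, cbind(row = centers[, 1], col = centers[, 2]),
               tolerance = 1e-9)

  single <- disk_mask(30, 30, 15, 15, 6)
  l1 <- label_spots(single, 1)
  expect_identical(l1$k, 1L)
  expect_error(label_spots(m, 5), "found 6")
})

test_that("label order matches a (row band, column) sort oracle", {
  set.seed(41)
  for (rep in 1:5) {
    # random 2 x 3 grid with jitter
    rows <- c(25, 70) + runif(2, -3, 3)
    cols <- c(25, 75, 125) + runif(3, -3, 3)
    centers <- cbind(rep(rows, each = 3) + runif(6, -2, 2),
                     rep(cols, 2) + runif(6, -2, 2))
    m <- matrix(FALSE, 100, 150)
    for (k in 1:6) m <- m | disk_mask(100, 150, centers[k, 1], centers[k, 2], 8)
    lab <- label_spots(m, 6)
    # oracle: sort by (row band, col)
    band <- rep(1:2, each = 3)
    ord <- order(band, centers[, 2])
    expect_equal(lab$centroids[, "col"], centers[ord, 2], tolerance = 0.6)
    expect_equal(lab$centroids[, "row"], centers[ord, 1], tolerance = 0.6)
  }
})

test_that("masking zeroes background and keeps spot pixels", {
  px <- array(runif(6 * 8 * 3, 0, 255), dim = c(6, 8, 3))
  img <- sensor_image(px, "pre")
  all_bg <- matrix(0L, 6, 8)
  expect_true(all(apply_mask(img, all_bg)$pixels == 0))
  all_fg <- matrix(1L, 6, 8)
  expect_equal(apply_mask(img, all_fg)$pixels, px)

  half <- matrix(0L, 6, 8); half[, 1:4] <- 1L
  masked <- apply_mask(img, half)
  for (ch in 1:3)
    expect_equal(sum(masked$pixels[, , ch]), sum(px[, 1:4, ch]))
  expect_error(apply_mask(img, matrix(0L, 3, 3)), "differ")
})

test_that("difference map is the absolute per-pixel change inside spots", {
  set.seed(51)
  h <- 20; w <- 20
  pre_px <- array(runif(h * w * 3, 40, 200), dim = c(h, w, 3))
  post_px <- pmin(pmax(pre_px + array(rnorm(h * w * 3, 0, 30),
                                      dim = c(h, w, 3)), 0), 255)
  lab <- matrix(0L, h, w); lab[3:10, 3:10] <- 1L; lab[12:18, 12:18] <- 2L
  labels <- structure(list(labels = lab,
                           centroids = cbind(row = c(6.5, 15), col = c(6.5, 15)),
                           k = 2L), class = "spot_label_map")
  pre <- sensor_image(pre_px, "pre")
  post <- sensor_image(post_px, "post")
  dm <- difference_map(pre, post, labels)

  # brute-force pixel loop oracle
  expected <- array(0, dim = c(h, w, 3))
  for (i in 1:h) for (j in 1:w) for (ch in 1:3)
    if (lab[i, j] > 0)
      expected[i, j, ch] <- abs(post_px[i, j, ch] - pre_px[i, j, ch])
  expect_equal(dm$deltas, expected)
  expect_true(all(dm$deltas >= 0))
  expect_true(all(dm$deltas[, , 1][lab == 0] == 0))

  # symmetric in the sign of the shift
  pre2 <- sensor_image(post_px, "pre")
  post2 <- sensor_image(pre_px, "post")
  expect_equal(difference_map(pre2, post2, labels)$deltas, dm$deltas)

  # identical captures give a zero map
  same <- difference_map(pre, sensor_image(pre_px, "post"), labels)
  expect_true(all(same$deltas == 0))

  expect_error(difference_map(post, pre, labels), "phase")
})

test_that("difference map guards against array movement between captures", {
  lab_a <- structure(list(labels = matrix(1L, 4, 4),
                          centroids = cbind(row = 2, col = 2), k = 1L),
                     class = "spot_label_map")
  lab_b <- structure(list(labels = matrix(1L, 4, 4),
                          centroids = cbind(row = 2, col = 9), k = 1L),
                     class = "spot_label_map")
  pre <- sensor_image(array(10, dim = c(4, 4, 3)), "pre")
  post <- sensor_image(array(20, dim = c(4, 4, 3)), "post")
  expect_error(difference_map(pre, post, lab_a, post_labels = lab_b), "moved")
  expect_silent(difference_map(pre, post, lab_a, post_labels = lab_a))
})

test_that("display rescaling maps 3..62 onto 0..255 half-away-from-zero", {
  expect_equal(rescale_for_display(matrix(3, 1, 1)), matrix(0, 1, 1))
  expect_equal(rescale_for_display(matrix(62, 1, 1)), matrix(255, 1, 1))
  expect_equal(rescale_for_display(matrix(0, 1, 1)), matrix(0, 1, 1))
  expect_equal(rescale_for_display(matrix(100, 1, 1)), matrix(255, 1, 1))
  # 32.5 -> (29.5 * 255 / 59) = 127.5, rounds half away from zero to 128
  expect_equal(rescale_for_display(matrix(32.5, 1, 1)), matrix(128, 1, 1))

  # monotone nondecreasing and saturating
  v <- seq(-5, 70, by = 0.25)
  out <- rescale_for_display(matrix(v, ncol = 1))
  expect_true(all(diff(out[, 1]) >= 0))
  expect_true(all(out >= 0 & out <= 255))
})

test_that("segmentation recovers the six spots from synthetic images", {
  spec <- small_spec(noise_sd = 5)
  pair <- render_pair(spec, "sunflower", 0.4, sample_seed = 7)
  lab <- segment_array(pair$pre)
  expect_identical(lab$k, 6L)
  err <- sqrt(rowSums((lab$centroids - pair$truth$labels$centroids)^2))
  expect_true(all(err <= 2))
})
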