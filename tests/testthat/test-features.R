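make_dmap <- function(deltas, lab, k = max(lab)) {
  idx <- which(lab > 0, arr.ind = TRUE)
  centroids <- cbind(row = tapply(idx[, 1], lab[lab > 0], mean),
                     col = tapply(idx[, 2], lab[lab > 0], mean))
  labels <- structure(list(labels = lab, centroids = centroids, k = k),
                      class = "spot_label_map")
  structure(list(deltas = deltas, labels = labels), class = "difference_map")
}

test_that("spot means average deltas per label and channel", {
  lab <- matrix(0L, 10, 10)
  lab[2:4, 2:4] <- 1L
  deltas <- array(0, dim = c(10, 10, 3))
  deltas[2:4, 2:4, 1] <- 10; deltas[2:4, 2:4, 2] <- 20; deltas[2:4, 2:4, 3] <- 5
  dm <- make_dmap(deltas, lab)
  expect_equal(unname(spot_mean_rgb(dm)[1, ]), c(10, 20, 5))

  # half zeros, half tens
  deltas2 <- deltas
  deltas2[2:4, 2:4, ] <- 0
  deltas2[2:3, 2:4, ] <- rep(c(15, 15, 15), each = 6)
  dm2 <- make_dmap(deltas2, lab)
  expect_equal(unname(spot_mean_rgb(dm2)[1, ]), c(10, 10, 10))
})

test_that("spot means match the accumulation-loop oracle", {
  set.seed(61)
  lab <- matrix(0L, 15, 15)
  lab[2:6, 2:6] <- 1L; lab[9:13, 3:7] <- 2L; lab[4:8, 9:14] <- 3L
  lab[9:13, 3:7][1, 1] <- 0L  # irregular shape
  deltas <- array(runif(15 * 15 * 3, 0, 60), dim = c(15, 15, 3))
  for (ch in 1:3) deltas[, , ch][lab == 0] <- 0
  dm <- make_dmap(deltas, lab)
  expect_equal(unname(spot_mean_rgb(dm)), spot_mean_brute(deltas, lab),
               tolerance = 1e-9)
})

test_that("feature vector flattening is row-major with 18 entries", {
  m <- matrix(seq_len(18), 6, 3, byrow = TRUE)
  v <- assemble_feature_vector(m)
  expect_length(v, 18)
  expect_identical(names(v), feature_names())
  expect_equal(unname(v), as.numeric(seq_len(18)))

  zero <- assemble_feature_vector(matrix(0, 6, 3))
  expect_true(all(zero == 0))

  # position check: spot k occupies entries 3(k-1)+1 .. 3k
  mk <- matrix(rep(1:6, 3), 6, 3)
  vk <- assemble_feature_vector(mk)
  for (k in 1:6) expect_equal(unname(vk[(3 * (k - 1) + 1):(3 * k)]),
                              rep(k, 3))

  # round-trip back to the table
  expect_equal(matrix(v, 6, 3, byrow = TRUE), unname(m))

  expect_error(assemble_feature_vector(matrix(0, 5, 3)), "6 spots")
})

test_that("Euclidean norm has the standard vector-norm properties", {
  expect_equal(euclidean_norm(rep(0, 18)), 0)
  expect_equal(euclidean_norm(c(3, 4, rep(0, 16))), 5)
  expect_equal(euclidean_norm(rep(1, 18)), sqrt(18))

  set.seed(71)
  for (i in 1:20) {
    v <- rnorm(18); w <- rnorm(18); c0 <- rnorm(1)
    expect_gte(euclidean_norm(v), 0)
    expect_equal(euclidean_norm(c0 * v), abs(c0) * euclidean_norm(v))
    expect_lte(euclidean_norm(v + w),
               euclidean_norm(v) + euclidean_norm(w) + 1e-12)
  }
})

test_that("response profiles preserve order and validate times", {
  f <- function(t, v) list(time_min = t, features = v)
  p <- response_profile(list(f(0, rep(1, 18)), f(1, rep(1, 18))))
  expect_equal(p$norm, rep(sqrt(18), 2))

  growing <- lapply(0:5, function(t) f(t, rep(t, 18)))
  pg <- response_profile(growing)
  expect_true(all(diff(pg$norm) > 0))

  expect_error(response_profile(list(f(1, rep(1, 18)), f(1, rep(1, 18)))),
               "increasing")
  expect_error(response_profile(list(f(0, rep(1, 18)))), "two frames")
})

test_that("steady-state detection finds the earliest stable time", {
  const <- structure(data.frame(time_min = 0:30, norm = rep(5, 31)),
                     class = c("response_profile", "data.frame"))
  expect_equal(steady_state_time(const), 0)

  rising <- structure(data.frame(time_min = 0:30, norm = seq(0, 30)),
                      class = c("response_profile", "data.frame"))
  expect_true(is.na(steady_state_time(rising)))

  zero <- structure(data.frame(time_min = 0:10, norm = rep(0, 11)),
                    class = c("response_profile", "data.frame"))
  expect_error(steady_state_time(zero), "no response")

  # analytic saturation: onset of the windowed criterion is
  # t* = -tau * log(eps / (1 - exp(-window/tau))) for the true curve
  tau <- 20
  t <- seq(0, 120, by = 1)
  prof <- structure(data.frame(time_min = t, norm = 100 * (1 - exp(-t / tau))),
                    class = c("response_profile", "data.frame"))
  detected <- steady_state_time(prof, epsilon = 0.02, window_min = 10)
  tol <- 0.02 * max(prof$norm)
  t_true <- -tau * log(tol / 100 / (1 - exp(-10 / tau)))
  expect_lte(abs(detected - t_true), 1)
})

test_that("optimal exposure picks the maximal final norm with tie-breaks", {
  mk <- function(norms) structure(
    data.frame(time_min = seq_along(norms) - 1, norm = norms),
    class = c("response_profile", "data.frame"))
  expect_equal(optimal_exposure(list(a = mk(c(1, 5)))), "a")
  expect_equal(optimal_exposure(list(a = mk(c(1, 5)), b = mk(c(2, 9)))), "b")
  # tie on final norm: earlier steady state wins
  flat_early <- mk(c(9, rep(9, 20)))
  flat_late <- mk(c(0, seq(0.5, 9, length.out = 20)))
  expect_equal(optimal_exposure(list(late = flat_late, early = flat_early)),
               "early")
  expect_error(optimal_exposure(list()), "no candidate")
})

test_that("extracted features track the folded-normal expectation", {
  # recovery bound: each feature within 4*sd/sqrt(n_px) of E|delta + noise|
  # (noise of a difference of two captures has sd sqrt(2) * noise_sd)
  spec <- small_spec(noise_sd = 2, illumination_gradient = 0)
  n_rep <- 20
  hits <- 0; total <- 0
  for (r in seq_len(n_rep)) {
    pair <- render_pair(spec, "sesame", 0.5, sample_seed = 1000 + r)
    lab <- segment_array(pair$pre)
    v <- extract_features(pair$pre, pair$post, lab)
    n_px <- tabulate(lab$labels[lab$labels > 0], 6)
    truth <- as.numeric(t(pair$truth$true_shift))
    sd_eff <- sqrt(2) * spec$noise_sd
    expected <- folded_mean(abs(truth), sd_eff)
    bound <- 4 * sd_eff / sqrt(rep(n_px, each = 3))
    hits <- hits + sum(abs(v - expected) <= bound)
    total <- total + 18
  }
  expect_gte(hits / total, 0.95)
})

test_that("feature tables round-trip through CSV", {
  spec <- small_spec(noise_sd = 1)
  ds <- make_dataset(spec, n_per_class = 1, seed = 3)
  path <- tempfile(fileext = ".csv")
  write_feature_table(ds, path)
  back <- read_feature_table(path)
  expect_identical(nrow(back), 13L)
  expect_identical(levels(back$label), oil_classes())
  expect_equal(as.matrix(back[, feature_names()]),
               as.matrix(ds[, feature_names()]),
               tolerance = 1e-12, ignore_attr = TRUE)

  prof <- structure(data.frame(time_min = 0:3, norm = c(0, 1, 2, 2.5)),
                    class = c("response_profile", "data.frame"))
  p2 <- tempfile(fileext = ".csv")
  write_response_profile(prof, p2)
  expect_equal(as.data.frame(read_response_profile(p2)), as.data.frame(prof))
})
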