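# Brute-force oracles and small fixtures shared across tests. The
# oracles deliberately use naive per-pixel definitions, independent of
# the package's vectorized/compiled implementations.

# Down-scaled array geometry for fast unit tests; spots (~1257 px) still
# clear the 1000 px area-opening threshold.
small_spec <- function(...) {
  synthetic_spec(image_size = c(240, 320), spot_radius = 20, spacing = 80,
                 ...)
}

# Otsu oracle: exhaustive scan of all 256 candidate thresholds, between-
# class variance computed from the raw binned pixel values per group.
otsu_brute <- function(gray) {
  b <- pmin(pmax(floor(gray), 0), 255)
  n <- length(b)
  best_t <- NA_integer_
  best_v <- -Inf
  for (t in 0:255) {
    g0 <- b[b <= t]
    g1 <- b[b > t]
    if (!length(g0) || !length(g1)) next
    v <- (length(g0) / n) * (length(g1) / n) * (mean(g0) - mean(g1))^2
    if (v > best_v + 1e-12) {
      best_v <- v
      best_t <- t
    }
  }
  best_t
}

# Erosion oracle: direct pixelwise definition with a Euclidean disk.
erode_brute <- function(mask, r) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  for (i in 1:h) for (j in 1:w) {
    ok <- TRUE
    for (di in -r:r) for (dj in -r:r) {
      if (di^2 + dj^2 > r^2) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > h || jj < 1 || jj > w || !mask[ii, jj]) {
        ok <- FALSE
        break
      }
    }
    out[i, j] <- ok
  }
  out
}

# 8-connected component labeling oracle: BFS flood fill.
label_brute <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  k <- 0L
  for (j0 in 1:w) for (i0 in 1:h) {
    if (!mask[i0, j0] || lab[i0, j0] > 0) next
    k <- k + 1L
    queue <- list(c(i0, j0))
    lab[i0, j0] <- k
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        ii <- p[1] + di; jj <- p[2] + dj
        if (ii >= 1 && ii <= h && jj >= 1 && jj <= w &&
            mask[ii, jj] && lab[ii, jj] == 0) {
          lab[ii, jj] <- k
          queue[[length(queue) + 1]] <- c(ii, jj)
        }
      }
    }
  }
  lab
}

# Area-opening oracle built on the labeling oracle.
area_open_brute <- function(mask, min_area) {
  lab <- label_brute(mask)
  if (max(lab) == 0) return(mask)
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  matrix(lab %in% which(sizes >= min_area), nrow(mask), ncol(mask))
}

# Per-spot channel means oracle: explicit accumulation loop.
spot_mean_brute <- function(deltas, labels) {
  k <- max(labels)
  out <- matrix(0, k, 3)
  cnt <- numeric(k)
  for (i in seq_len(nrow(labels))) for (j in seq_len(ncol(labels))) {
    l <- labels[i, j]
    if (l > 0) {
      cnt[l] <- cnt[l] + 1
      for (ch in 1:3) out[l, ch] <- out[l, ch] + deltas[i, j, ch]
    }
  }
  sweep(out, 1, cnt, "/")
}

# Mean of |N(delta, sd^2)| (folded normal), for parameter-recovery checks.
folded_mean <- function(delta, sd) {
  sd * sqrt(2 / pi) * exp(-delta^2 / (2 * sd^2)) +
    delta * (1 - 2 * pnorm(-delta / sd))
}

# Draw a disk mask for morphology fixtures.
disk_mask <- function(h, w, ci, cj, r) {
  ri <- matrix(seq_len(h), h, w)
  cj_ <- matrix(seq_len(w), h, w, byrow = TRUE)
  (ri - ci)^2 + (cj_ - cj)^2 <= r^2
}

# Well-separated 13-class score clouds directly in feature space (no
# imaging), for fast classifier tests.
separable_scores <- function(n_per_class = 6, k = 13, dim = 5, sep = 30,
                             sd = 1, seed = 1) {
  set.seed(seed)
  centers <- matrix(rnorm(k * dim), k, dim)
  centers <- centers / sqrt(rowSums(centers^2)) * sep
  # push classes apart on a simplex-ish layout
  centers <- centers + matrix(seq_len(k) * sep, k, dim)
  x <- do.call(rbind, lapply(seq_len(k), function(i)
    matrix(rnorm(n_per_class * dim, sd = sd), n_per_class, dim) +
      matrix(centers[i, ], n_per_class, dim, byrow = TRUE)))
  list(x = x, y = factor(rep(oil_classes()[seq_len(k)], each = n_per_class),
                         levels = oil_classes()[seq_len(k)]))
}

# Fresh temporary directory, cleaned up when the calling test finishes.
local_tempdir <- function(env = parent.frame()) {
  dir <- tempfile("csanose-test-")
  dir.create(dir)
  withr::defer(unlink(dir, recursive = TRUE), envir = env)
  dir
}

table2_path <- function() {
  system.file("extdata", "table2_confusion.txt", package = "csanose")
}
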