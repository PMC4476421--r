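# Brute-force reference implementations of the detection stages, written
# independently of the package internals (explicit per-pixel loops), plus
# small fixture builders.

# Local maxima: pixel-by-pixel scan. A pixel is a peak when no pixel within
# Euclidean distance `radius` has a greater value and no lexicographically
# smaller (0-based row-major) pixel within that distance has an equal value.
bf_local_maxima <- function(m, radius) {
  nr <- nrow(m); nc <- ncol(m)
  rint <- ceiling(radius)
  out <- NULL
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      ok <- TRUE
      for (a in max(1, i - rint):min(nr, i + rint)) {
        for (b in max(1, j - rint):min(nc, j + rint)) {
          if (a == i && b == j) next
          if ((a - i)^2 + (b - j)^2 > radius^2) next
          if (m[a, b] > m[i, j]) { ok <- FALSE; break }
          if (m[a, b] == m[i, j] &&
              (a < i || (a == i && b < j))) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (ok) out <- rbind(out, c(i - 1L, j - 1L))
    }
  }
  if (is.null(out)) data.frame(row = integer(0), col = integer(0)) else
    data.frame(row = out[, 1L], col = out[, 2L])
}

# Isolation: O(n^2) pairwise scan, keep peaks whose nearest other peak is at
# distance >= radius.
bf_isolated <- function(peaks, radius) {
  n <- nrow(peaks)
  if (n <= 1L) return(peaks)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt((peaks$row[i] - peaks$row[j])^2 +
                (peaks$col[i] - peaks$col[j])^2)
      if (d < radius) keep[i] <- FALSE
    }
  }
  peaks[keep, , drop = FALSE]
}

# ROI: pixel-by-pixel application of the two conditions (inside the
# ceiling(sigma) disk; smoothed value > background, peak always in).
bf_roi <- function(sm, bg_values, peak, sigma) {
  r <- ceiling(sigma)
  out <- NULL
  for (dr in -r:r) {
    for (dc in -r:r) {
      if (dr^2 + dc^2 > r^2) next
      i <- peak[1L] + dr; j <- peak[2L] + dc
      if (i < 0 || j < 0 || i >= nrow(sm) || j >= ncol(sm)) next
      if ((dr == 0 && dc == 0) || sm[i + 1L, j + 1L] > bg_values[i + 1L, j + 1L])
        out <- rbind(out, c(i, j))
    }
  }
  data.frame(row = out[, 1L], col = out[, 2L])
}

# Scores recomputed with explicit sums from a candidate's stored pixels.
bf_scores <- function(cand, config) {
  f <- config$excess_noise_factor
  s <- cand$roi$signal; b <- cand$roi$background
  snr <- sum(s / (f * sqrt(b))) / length(s)
  cnr <- sum(s) / (f * sqrt(sum(cand$disk_background)))
  list(snr_eff = snr, cnr_eff = cnr, q = min(snr, cnr))
}

# Probability that a photon from a Gaussian PSF centered at (x0, y0) lands in
# the pixel with center (x, y) (0-based, centers at integers).
pixel_mass <- function(x, y, x0, y0, sigma) {
  (pnorm(x + 0.5, x0, sigma) - pnorm(x - 0.5, x0, sigma)) *
    (pnorm(y + 0.5, y0, sigma) - pnorm(y - 0.5, y0, sigma))
}

# A pixel-sampled Gaussian spot (values at pixel centers) on a flat offset.
gauss_spot <- function(n, x0, y0, sigma_x, sigma_y = sigma_x,
                       amplitude = 100, offset = 0) {
  x <- matrix(rep(0:(n - 1), each = n), n)   # col coordinate
  y <- matrix(rep(0:(n - 1), times = n), n)  # row coordinate
  offset + amplitude * exp(-((x - x0)^2 / (2 * sigma_x^2) +
                             (y - y0)^2 / (2 * sigma_y^2)))
}

# Flat background map without running the estimator.
flat_background <- function(n, level, floor = 1e-3) {
  structure(list(values = matrix(pmax(level, floor), n, n), floor = floor),
            class = "background_map")
}

# Tiny camera with unit gain / zero bias / F = 1 for exact-value tests.
unit_camera <- function(...) {
  camera_config(bias_offset = 0, effective_gain = 1, excess_noise_factor = 1,
                ...)
}

# One simulated isolated spot: Poisson(photons) photons placed by the PSF
# around a known sub-pixel center on a Poisson background, via the package's
# own generator restricted to one emitter (frames with != 1 emitter are
# regenerated by drawing again).
single_spot_frames <- function(n_spots, frame_size = 32, mean_photons = 500,
                               background = 10, seed = 1) {
  cfg <- sim_config(frame_size = frame_size, n_frames = 1L,
                    emitters_per_frame_mean = 1, mean_photons = mean_photons,
                    uniform_background = background, seed = seed)
  set.seed(seed)
  out <- vector("list", n_spots)
  k <- 0L
  while (k < n_spots) {
    fr <- simulate_frame(cfg, frame_index = k)
    if (nrow(fr$truth) != 1L) next
    k <- k + 1L
    out[[k]] <- fr
  }
  out
}
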