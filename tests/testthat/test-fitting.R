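cam <- camera_config()
sigma <- psf_sigma_px(cam)

make_candidate <- function(frame_mat, peak, bg_level) {
  bg <- flat_background(nrow(frame_mat), bg_level)
  cand <- select_roi(frame_mat, bg, peak, sigma)
  cand <- score_candidate(cand, cam)
  cand$status <- "accepted"
  cand
}

as_frame <- function(m, idx = 0L) {
  structure(list(pixels = m, frame_index = as.integer(idx)),
            class = "photon_frame")
}

test_that("initial estimates recover centroid, amplitude and offset", {
  n <- 21
  spot <- gauss_spot(n, 10.2, 9.8, sigma, amplitude = 80, offset = 5)
  cand <- make_candidate(spot, c(10, 10), 5)
  init <- initial_estimate(cand, as_frame(spot))
  expect_lt(abs(init$x0 - 10.2), 0.05)
  expect_lt(abs(init$y0 - 9.8), 0.05)
  expect_equal(init$offset, 5)

  # single-pixel ROI: centroid is the peak itself
  spike <- matrix(5, n, n); spike[11, 11] <- 30
  cand2 <- make_candidate(spike, c(10, 10), 5)
  init2 <- initial_estimate(cand2, as_frame(spike))
  expect_equal(c(init2$x0, init2$y0), c(10, 10))

  # uniform 3x3 block: centroid at its geometric center
  block <- matrix(5, n, n)
  block[10:12, 10:12] <- 7  # 0-based rows/cols 9..11, center (10, 10)
  cand3 <- make_candidate(block, c(10, 10), 5)
  init3 <- initial_estimate(cand3, as_frame(block))
  expect_equal(c(init3$x0, init3$y0), c(10, 10))
})

test_that("noiseless Gaussians are recovered to high accuracy (all models)", {
  n <- 25
  truth <- list(x = 12.70, y = 10.30, sx = 1.46, sy = 1.46, A = 100, off = 10)
  spot <- gauss_spot(n, truth$x, truth$y, truth$sx, truth$sy,
                     amplitude = truth$A, offset = truth$off)
  cand <- make_candidate(spot, c(10, 13), 10)
  for (model in 2:3) {
    spec <- gaussian_model_spec(model, 3, theoretical_sigma_px = sigma)
    loc <- fit_gaussian(cand, as_frame(spot), spec, cam)
    expect_equal(loc$status, "fitted")
    expect_equal(loc$x_px, truth$x, tolerance = 1e-4)
    expect_equal(loc$y_px, truth$y, tolerance = 1e-4)
    expect_equal(loc$sigma_x_px, truth$sx, tolerance = 1e-4)
    expect_equal(loc$amplitude, truth$A, tolerance = 1e-3)
    expect_equal(loc$offset, truth$off, tolerance = 1e-3)
    # photon count consistency with the fitted parameters
    expect_equal(loc$photons,
                 2 * pi * loc$amplitude * loc$sigma_x_px * loc$sigma_y_px,
                 tolerance = 1e-6)
    # nm coordinates are px times the sample-plane pixel size
    expect_equal(loc$x_nm, loc$x_px * cam$sample_pixel_nm)
  }
  # dense grid-search cross-check of the position (model 2 objective)
  grid <- expand.grid(x = seq(12.60, 12.80, by = 0.01),
                      y = seq(10.20, 10.40, by = 0.01))
  sse <- vapply(seq_len(nrow(grid)), function(i) {
    sum((spot - gauss_spot(n, grid$x[i], grid$y[i], truth$sx,
                           amplitude = truth$A, offset = truth$off))^2)
  }, numeric(1))
  best <- grid[which.min(sse), ]
  expect_equal(best$x, 12.70, tolerance = 1e-8)
  expect_equal(best$y, 10.30, tolerance = 1e-8)
})

test_that("model 2 is symmetric by construction", {
  n <- 25
  set.seed(31)
  spot <- gauss_spot(n, 12.3, 11.6, sigma, amplitude = 60, offset = 8) +
    matrix(rnorm(n * n, 0, 0.5), n)
  cand <- make_candidate(spot, c(12, 12), 8)
  spec <- gaussian_model_spec(2, 3, theoretical_sigma_px = sigma)
  loc <- fit_gaussian(cand, as_frame(spot), spec, cam)
  expect_identical(loc$sigma_x_px, loc$sigma_y_px)
})

test_that("fit is invariant under integer translation of spot and window", {
  n <- 31
  spot1 <- gauss_spot(n, 12.35, 11.72, sigma, amplitude = 70, offset = 6)
  spot2 <- gauss_spot(n, 12.35 + 5, 11.72 + 5, sigma, amplitude = 70,
                      offset = 6)
  cand1 <- make_candidate(spot1, c(12, 12), 6)
  cand2 <- make_candidate(spot2, c(17, 17), 6)
  spec <- gaussian_model_spec(3, 3, theoretical_sigma_px = sigma)
  loc1 <- fit_gaussian(cand1, as_frame(spot1), spec, cam)
  loc2 <- fit_gaussian(cand2, as_frame(spot2), spec, cam)
  expect_equal(loc2$x_px - loc1$x_px, 5, tolerance = 1e-8)
  expect_equal(loc2$y_px - loc1$y_px, 5, tolerance = 1e-8)
  expect_equal(loc2$sigma_x_px, loc1$sigma_x_px, tolerance = 1e-8)
})

test_that("localization error on noisy spots is small and model 1 is robust", {
  spots <- single_spot_frames(150, seed = 32)
  errs <- matrix(NA_real_, length(spots), 2)
  for (i in seq_along(spots)) {
    fr <- to_photoelectrons(spots[[i]]$raw, cam)
    tr <- spots[[i]]$truth
    for (model in c(1, 3)) {
      spec <- gaussian_model_spec(model, 3, theoretical_sigma_px = sigma)
      det <- detect_emitters(fr, cam, q_threshold = 2)
      locs <- localize_candidates(det$candidates, fr, spec, cam)
      tab <- localization_table(locs)
      if (!nrow(tab)) next
      d <- sqrt((tab$x_px - tr$x_px)^2 + (tab$y_px - tr$y_px)^2)
      errs[i, if (model == 1) 1 else 2] <- min(d)
    }
  }
  expect_gt(mean(!is.na(errs[, 1])), 0.9)  # nearly all spots recovered
  expect_lt(sqrt(mean(errs[, 1]^2, na.rm = TRUE)), 0.2)  # RMS error, px
  # fixed width never worse than elliptical on in-focus data
  both <- stats::complete.cases(errs)
  expect_lte(median(errs[both, 1]), median(errs[both, 2]) + 0.02)
})

test_that("width filter enforces the PWT band and spares model 1", {
  spec2 <- gaussian_model_spec(2, 3, theoretical_sigma_px = sigma)
  mk <- function(sx, sy, model) {
    structure(list(frame_index = 0L, x_px = 1, y_px = 1, x_nm = 64, y_nm = 64,
                   amplitude = 10, sigma_x_px = sx, sigma_y_px = sy,
                   offset = 0, photons = 100, pearson_r = 0.9,
                   precision_nm = 10, q = 4, model = model, status = "fitted",
                   fit_data = NULL, fit_model = NULL),
              class = "localization")
  }
  expect_equal(width_filter(mk(0.3, 1.4, 2), spec2)$status, "rejected_width")
  expect_equal(width_filter(mk(2.9 * sigma, 2.9 * sigma, 2), spec2)$status,
               "fitted")
  expect_equal(width_filter(mk(3.5 * sigma, 1.4, 2), spec2)$status,
               "rejected_width")
  spec1 <- gaussian_model_spec(1, 3, theoretical_sigma_px = sigma)
  expect_equal(width_filter(mk(sigma, sigma, 1), spec1)$status, "fitted")
  # widening PWT never shrinks the pass band
  tight <- gaussian_model_spec(2, 1.5, theoretical_sigma_px = sigma)
  wide <- gaussian_model_spec(2, 3, theoretical_sigma_px = sigma)
  sx <- seq(0.3, 5, by = 0.1)
  pass <- function(spec) vapply(sx, function(s)
    width_filter(mk(s, s, 2), spec)$status == "fitted", logical(1))
  expect_true(all(pass(wide) | !pass(tight)))
})

test_that("Pearson goodness-of-fit filter behaves at both extremes", {
  n <- 25
  spot <- gauss_spot(n, 12, 12, sigma, amplitude = 80, offset = 10)
  cand <- make_candidate(spot, c(12, 12), 10)
  spec <- gaussian_model_spec(1, 3, theoretical_sigma_px = sigma)
  loc <- fit_gaussian(cand, as_frame(spot), spec, cam)
  expect_equal(loc$pearson_r, 1, tolerance = 1e-6)
  expect_equal(fit_quality_filter(loc)$status, "accepted")
  # correlation equals the textbook covariance formula on the same pairs
  r_ref <- sum((loc$fit_data - mean(loc$fit_data)) *
               (loc$fit_model - mean(loc$fit_model))) /
    sqrt(sum((loc$fit_data - mean(loc$fit_data))^2) *
         sum((loc$fit_model - mean(loc$fit_model))^2))
  expect_equal(loc$pearson_r, r_ref)

  # pure noise windows almost never correlate with the model
  set.seed(33)
  rejected <- 0L
  for (i in 1:50) {
    noise <- matrix(rpois(n * n, 20), n)
    candn <- make_candidate(noise, c(12, 12), 20)
    locn <- fit_gaussian(candn, as_frame(noise), spec, cam)
    if (locn$status != "fitted" ||
        fit_quality_filter(locn)$status == "rejected_fit_quality")
      rejected <- rejected + 1L
  }
  expect_gt(rejected, 45L)

  # zero-variance window is rejected, not an error
  flat <- matrix(10, n, n)
  candf <- make_candidate(flat, c(12, 12), 10)
  candf$status <- "accepted"
  locf <- fit_gaussian(candf, as_frame(flat), spec, cam)
  if (locf$status == "fitted")
    expect_equal(fit_quality_filter(locf)$status, "rejected_fit_quality")
})
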