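cam <- camera_config()
r_airy <- airy_radius_px(cam)
sigma <- psf_sigma_px(cam)

test_that("local maxima: isolated peaks and plateaus behave as specified", {
  m <- matrix(0, 20, 20)
  m[10, 10] <- 5
  p <- find_local_maxima(m + 1, r_airy)
  # the bright pixel, plus far-field plateau pixels of the flat region
  expect_true(any(p$row == 9 & p$col == 9))

  m2 <- matrix(0, 30, 30)
  m2[5, 5] <- 7
  m2[25, 25] <- 7   # separated by far more than 2 r_airy
  p2 <- find_local_maxima(m2, r_airy)
  bright <- p2[p2$row %in% c(4, 24), ]
  expect_equal(nrow(bright), 2L)
})

test_that("local maxima match the brute-force neighborhood scan", {
  set.seed(21)
  for (i in 1:5) {
    m <- matrix(rpois(16 * 16, 8), 16)
    expect_equal(find_local_maxima(m, 2.5), bf_local_maxima(m, 2.5),
                 ignore_attr = TRUE)
  }
})

test_that("isolation filter removes both members of close pairs", {
  close_pair <- data.frame(row = c(10, 11), col = c(10, 11))  # d ~ 1.41
  expect_equal(nrow(reject_nonisolated(close_pair, r_airy)), 0L)

  far_pair <- data.frame(row = c(10, 10), col = c(10, 10 + ceiling(1.5 * r_airy)))
  expect_equal(nrow(reject_nonisolated(far_pair, r_airy)), 2L)

  set.seed(22)
  pk <- data.frame(row = sample(0:40, 12), col = sample(0:40, 12))
  expect_equal(reject_nonisolated(pk, r_airy), bf_isolated(pk, r_airy),
               ignore_attr = TRUE)
})

test_that("ROI selection applies the disk and signal conditions", {
  n <- 21
  bg <- flat_background(n, 5)
  spot <- gauss_spot(n, 10, 10, sigma, amplitude = 50, offset = 5)
  cand <- select_roi(spot, bg, c(10, 10), sigma)
  oracle <- bf_roi(spot, bg$values, c(10, 10), sigma)
  expect_equal(data.frame(row = cand$roi$row, col = cand$roi$col)[
    order(cand$roi$row, cand$roi$col), ],
    oracle[order(oracle$row, oracle$col), ], ignore_attr = TRUE)
  # noiseless Gaussian exceeds the background on the whole disk
  expect_equal(length(cand$roi$row), length(cand$disk_background))

  # background-only region: ROI degenerates to the peak pixel
  flat <- matrix(5, n, n)
  cand2 <- select_roi(flat, bg, c(10, 10), sigma)
  expect_equal(cbind(cand2$roi$row, cand2$roi$col), cbind(10, 10),
               ignore_attr = TRUE)
  expect_equal(cand2$roi$signal, 0)

  # peaks too close to the border are rejected
  cand3 <- select_roi(spot, bg, c(1, 10), sigma)
  expect_equal(cand3$status, "rejected_edge")
})

test_that("scoring separates needles, single emitters and broad blobs", {
  n <- 15
  bg <- flat_background(n, 50)

  spike <- matrix(50, n, n); spike[8, 8] <- 150  # S = 100 at one pixel
  cand <- score_candidate(select_roi(spike, bg, c(7, 7), sigma), cam)
  expect_equal(cand$snr_eff, 10)
  expect_equal(cand$cnr_eff, 100 / sqrt(2 * 650), tolerance = 1e-12)
  expect_equal(cand$q, cand$cnr_eff)
  expect_lt(cand$q, 3)  # needle penalized

  broad <- matrix(58, n, n)  # S = 8 everywhere, 13-pixel disk ROI
  cand2 <- score_candidate(select_roi(broad, bg, c(7, 7), sigma), cam)
  expect_equal(cand2$snr_eff, 0.8)
  expect_equal(cand2$cnr_eff, 104 / sqrt(2 * 650), tolerance = 1e-12)
  expect_equal(cand2$q, 0.8)  # broad signal penalized

  none <- matrix(50, n, n)
  cand3 <- score_candidate(select_roi(none, bg, c(7, 7), sigma), cam)
  expect_equal(c(cand3$snr_eff, cand3$cnr_eff, cand3$q), c(0, 0, 0))
})

test_that("scores agree with independent explicit-sum recomputation", {
  set.seed(23)
  n <- 21
  for (i in 1:10) {
    m <- matrix(rpois(n * n, 20), n) +
      gauss_spot(n, 10 + runif(1, -1, 1), 10 + runif(1, -1, 1), sigma,
                 amplitude = runif(1, 5, 60))
    bg <- flat_background(n, 20)
    cand <- score_candidate(select_roi(m, bg, c(10, 10), sigma), cam)
    ref <- bf_scores(cand, cam)
    expect_equal(cand$snr_eff, ref$snr_eff)
    expect_equal(cand$cnr_eff, ref$cnr_eff)
    expect_equal(cand$q, ref$q)
  }
})

test_that("Rose criterion and Q threshold drive acceptance statuses", {
  mk <- function(snr, cnr) {
    structure(list(frame_index = 0L, peak = c(5L, 5L),
                   roi = list(row = 5L, col = 5L, signal = 1, background = 1),
                   disk_background = 1, snr_eff = snr, cnr_eff = cnr,
                   q = min(snr, cnr), status = "candidate"),
              class = "candidate")
  }
  out <- filter_candidates(list(mk(10, 2.9), mk(3.5, 5), mk(10, 3)), 4)
  expect_equal(vapply(out, `[[`, "", "status"),
               c("rejected_rose", "rejected_q", "rejected_rose"))

  out2 <- filter_candidates(list(mk(10, 2.9), mk(5, 5), mk(0.5, 4)), 0)
  expect_equal(vapply(out2, `[[`, "", "status"),
               c("rejected_rose", "accepted", "accepted"))
  expect_error(filter_candidates(list(mk(1, 1)), -1), "non-negative")
})

test_that("accepted sets shrink monotonically as the Q threshold rises", {
  set.seed(24)
  cfg <- sim_regime("low_snr", n_frames = 1, frame_size = 128, seed = 24)
  st <- simulate_stack(cfg)
  fr <- to_photoelectrons(st$frames[[1]], cam)
  det <- detect_emitters(fr, cam, q_threshold = 0)
  scored <- Filter(function(x) !is.na(x$cnr_eff), det$candidates)
  key <- function(cands) {
    acc <- Filter(function(x) x$status == "accepted", cands)
    sort(vapply(acc, function(x) paste(x$peak, collapse = ","), ""))
  }
  prev <- NULL
  for (thr in c(0, 1, 2, 4, 8)) {
    cur <- key(filter_candidates(
      lapply(scored, function(x) { x$status <- "candidate"; x }), thr))
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("frame relabeling never changes per-frame results", {
  cfg <- sim_regime("high_snr", n_frames = 1, frame_size = 128, seed = 25)
  st <- simulate_stack(cfg)
  fr_a <- to_photoelectrons(st$frames[[1]], cam, frame_index = 0L)
  fr_b <- to_photoelectrons(st$frames[[1]], cam, frame_index = 17L)
  ta <- candidate_table(detect_emitters(fr_a, cam, 2)$candidates)
  tb <- candidate_table(detect_emitters(fr_b, cam, 2)$candidates)
  expect_equal(unique(tb$frame), 17L)
  tb$frame <- 0L
  expect_equal(ta, tb)
})
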