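#' Simulation configuration
#'
#' Defines a synthetic SMLM acquisition. The defaults reproduce the three
#' benchmark regimes used throughout the package's own validation: emitters
#' with on average 500 signal photons each on a uniform background of 10
#' (high SNR) or 50 (low SNR) photons per pixel, optionally with a broad
#' Gaussian-profile background superimposed (peak 50 photons, FWHM = half
#' the frame) mimicking uneven wide-field/TIRF illumination; optics 64 nm
#' pixels, 665 nm emission, NA 1.49; ~40 emitters per frame.
#'
#' @param frame_size Pixels per side (>= 32; default 256).
#' @param n_frames Number of frames.
#' @param emitters_per_frame_mean Poisson mean of the per-frame emitter
#'   count (default 40).
#' @param mean_photons Poisson mean of the per-emitter signal photon count
#'   (default 500).
#' @param uniform_background Uniform background, photons/pixel (10 or 50 in
#'   the standard regimes).
#' @param gaussian_bg_peak Peak of the optional Gaussian-profile background,
#'   photons (0 disables it).
#' @param gaussian_bg_fwhm_frac FWHM of that profile as a fraction of the
#'   frame size (default 0.5).
#' @param camera A \code{\link{camera_config}}; its optics set the PSF width
#'   and its bias/gain produce the raw intensity image.
#' @param seed Integer seed; fully determines the output.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(frame_size = 256L, n_frames = 10L,
                       emitters_per_frame_mean = 40,
                       mean_photons = 500,
                       uniform_background = 10,
                       gaussian_bg_peak = 0,
                       gaussian_bg_fwhm_frac = 0.5,
                       camera = camera_config(),
                       seed = 1L) {
  stopifnot(frame_size >= 32, n_frames >= 0, emitters_per_frame_mean >= 0,
            mean_photons >= 0, uniform_background >= 0, gaussian_bg_peak >= 0,
            gaussian_bg_fwhm_frac > 0, inherits(camera, "camera_config"))
  structure(list(frame_size = as.integer(frame_size),
                 n_frames = as.integer(n_frames),
                 emitters_per_frame_mean = emitters_per_frame_mean,
                 mean_photons = mean_photons,
                 uniform_background = uniform_background,
                 gaussian_bg_peak = gaussian_bg_peak,
                 gaussian_bg_fwhm_frac = gaussian_bg_fwhm_frac,
                 camera = camera, seed = as.integer(seed)),
            class = "sim_config")
}

#' Standard benchmark regimes
#'
#' @param regime One of \code{"high_snr"} (background 10),
#'   \code{"low_snr"} (background 50), \code{"low_snr_gb"} (background 50
#'   plus a Gaussian-profile background peaking at 50 photons).
#' @param ... Overrides passed to \code{\link{sim_config}}.
#' @return A \code{sim_config}.
#' @export
sim_regime <- function(regime = c("high_snr", "low_snr", "low_snr_gb"), ...) {
  regime <- match.arg(regime)
  base <- switch(regime,
    high_snr = list(uniform_background = 10, gaussian_bg_peak = 0),
    low_snr = list(uniform_background = 50, gaussian_bg_peak = 0),
    low_snr_gb = list(uniform_background = 50, gaussian_bg_peak = 50))
  do.call(sim_config, utils::modifyList(base, list(...)))
}

#' Expected background surface of a simulation, photoelectrons/pixel
#'
#' Uniform level plus, if enabled, the centered Gaussian profile
#' (sigma = FWHM / 2.355; FWHM = \code{gaussian_bg_fwhm_frac * frame_size}).
#'
#' @param cfg A \code{sim_config}.
#' @return Matrix of expected background values.
#' @export
sim_background_expectation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$frame_size
  bg <- matrix(cfg$uniform_background, n, n)
  if (cfg$gaussian_bg_peak > 0) {
    s <- cfg$gaussian_bg_fwhm_frac * n / (2 * sqrt(2 * log(2)))
    ctr <- (n - 1) / 2
    d2 <- outer((0:(n - 1) - ctr)^2, (0:(n - 1) - ctr)^2, "+")
    bg <- bg + cfg$gaussian_bg_peak * exp(-d2 / (2 * s^2))
  }
  bg
}

#' Simulate one raw camera frame with ground truth
#'
#' For each frame: the emitter count is Poisson-drawn, positions are uniform
#' inside a margin of 3 PSF sigmas from the border (overlaps allowed); each
#' emitter's photon count is Poisson(\code{mean_photons}) and every photon
#' lands at a position drawn from the 2D Gaussian PSF around the true
#' center, accumulating into pixels -- the Poisson photon count plus the
#' random placement IS the signal's shot noise, realized photon by photon.
#' The background (uniform + optional Gaussian profile) is added as a
#' Poisson draw on its expectation, and the camera model (gain, then bias
#' offset) turns photoelectrons into the 16-bit-range intensity image.
#'
#' Coordinates are 0-based with pixel centers at integers; x = column.
#'
#' @param cfg A \code{sim_config}.
#' @param frame_index 0-based frame index recorded in the truth table.
#' @return List: \code{raw} (intensity matrix), \code{truth} (data.frame:
#'   frame, x_px, y_px, x_nm, y_nm, photons).
#' @export
simulate_frame <- function(cfg, frame_index = 0L) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$frame_size
  cam <- cfg$camera
  sigma <- psf_sigma_px(cam)
  margin <- 3 * sigma
  n_em <- stats::rpois(1L, cfg$emitters_per_frame_mean)
  expected <- sim_background_expectation(cfg)
  counts <- matrix(0, n, n)
  if (n_em > 0L) {
    x <- stats::runif(n_em, margin, n - 1 - margin)
    y <- stats::runif(n_em, margin, n - 1 - margin)
    photons <- stats::rpois(n_em, cfg$mean_photons)
    tot <- sum(photons)
    if (tot > 0L) {
      cx <- rep(x, photons) + stats::rnorm(tot, 0, sigma)
      cy <- rep(y, photons) + stats::rnorm(tot, 0, sigma)
      px <- floor(cx + 0.5); py <- floor(cy + 0.5)
      ok <- px >= 0 & px < n & py >= 0 & py < n
      if (any(ok)) {
        idx <- py[ok] + 1L + px[ok] * n  # row py+1, col px+1 in column-major
        acc <- tabulate(idx, nbins = n * n)
        counts <- counts + matrix(acc, n, n)
      }
    }
  } else {
    x <- numeric(0); y <- numeric(0); photons <- integer(0)
  }
  electrons <- counts + matrix(stats::rpois(n * n, as.vector(expected)), n, n)
  raw <- electrons * cam$effective_gain + cam$bias_offset
  truth <- data.frame(frame = rep(as.integer(frame_index), length(x)),
                      x_px = x, y_px = y,
                      x_nm = x * cam$sample_pixel_nm,
                      y_nm = y * cam$sample_pixel_nm,
                      photons = photons)
  list(raw = raw, truth = truth)
}

#' Simulate a stack of frames in memory
#'
#' Seeds the generator from \code{cfg$seed}, so the output is fully
#' reproducible.
#'
#' @param cfg A \code{sim_config}.
#' @return List: \code{frames} (list of raw intensity matrices),
#'   \code{truth} (combined ground-truth data.frame), \code{cfg}.
#' @export
simulate_stack <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  frames <- vector("list", cfg$n_frames)
  truths <- vector("list", cfg$n_frames)
  for (i in seq_len(cfg$n_frames)) {
    fr <- simulate_frame(cfg, frame_index = i - 1L)
    frames[[i]] <- fr$raw
    truths[[i]] <- fr$truth
  }
  truth <- if (cfg$n_frames > 0L) do.call(rbind, truths) else
    data.frame(frame = integer(0), x_px = numeric(0), y_px = numeric(0),
               x_nm = numeric(0), y_nm = numeric(0), photons = integer(0))
  list(frames = frames, truth = truth, cfg = cfg)
}

#' Simulate a dataset to disk (TIFF stack + ground-truth CSV + manifest)
#'
#' @param cfg A \code{sim_config}.
#' @param out_dir Output directory (created if needed).
#' @param name Basename for the three files.
#' @return Invisibly, the paths (\code{tiff}, \code{truth}, \code{manifest}).
#' @export
simulate_dataset <- function(cfg, out_dir, name = "simulation") {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_stack(cfg)
  tiff_path <- file.path(out_dir, paste0(name, ".tif"))
  truth_path <- file.path(out_dir, paste0(name, "_truth.csv"))
  manifest_path <- file.path(out_dir, paste0(name, "_manifest.yaml"))
  if (length(sim$frames)) {
    top <- max(vapply(sim$frames, max, numeric(1)))
    if (top > 65535)
      stop("simulated intensities exceed the 16-bit range; lower the gain")
    tiff::writeTIFF(lapply(sim$frames, function(f) f / 65535), tiff_path,
                    bits.per.sample = 16L)
  } else {
    file.create(tiff_path)
  }
  utils::write.csv(sim$truth, truth_path, row.names = FALSE)
  man <- list(
    frame_size = cfg$frame_size, n_frames = cfg$n_frames,
    emitters_per_frame_mean = cfg$emitters_per_frame_mean,
    mean_photons = cfg$mean_photons,
    uniform_background = cfg$uniform_background,
    gaussian_bg_peak = cfg$gaussian_bg_peak,
    gaussian_bg_fwhm_frac = cfg$gaussian_bg_fwhm_frac,
    seed = cfg$seed,
    camera = unclass(cfg$camera),
    software = paste("snsmlm", as.character(utils::packageVersion("snsmlm"))))
  yaml::write_yaml(man, manifest_path)
  invisible(list(tiff = tiff_path, truth = truth_path,
                 manifest = manifest_path))
}
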