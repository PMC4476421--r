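#' Camera and optics configuration
#'
#' Bundles the instrument constants every stage of the pipeline needs: the
#' camera's bias offset and effective electronic gain (to convert intensity
#' readings to photoelectrons), the EMCCD excess-noise factor, and the optics
#' (pixel size, magnification, numerical aperture, emission wavelength) from
#' which the Airy radius and theoretical PSF width are derived.
#'
#' @param bias_offset Camera bias offset, in intensity counts.
#' @param effective_gain Effective electronic gain, counts per photoelectron.
#'   Must be strictly positive.
#' @param excess_noise_factor Multiplicative noise inflation of the
#'   electron-multiplying register; sqrt(2) for an EMCCD at high gain, 1 for a
#'   hypothetical noiseless amplifier. Must be >= 1.
#' @param pixel_size_nm Physical pixel size of the camera sensor, nm.
#' @param magnification Total optical magnification (>= 1). The sample-plane
#'   pixel size is \code{pixel_size_nm / magnification}.
#' @param numerical_aperture Numerical aperture of the objective, in (0, 1.7].
#' @param emission_wavelength_nm Wavelength of maximum fluorescence emission,
#'   nm, in [300, 1000].
#'
#' @return An object of class \code{camera_config} (a validated list) with the
#'   supplied fields plus \code{sample_pixel_nm}, the sample-plane pixel size.
#' @examples
#' cfg <- camera_config(bias_offset = 100, effective_gain = 30,
#'                      pixel_size_nm = 64, magnification = 1,
#'                      numerical_aperture = 1.49,
#'                      emission_wavelength_nm = 665)
#' airy_radius_px(cfg)
#' psf_sigma_px(cfg)
#' @export
camera_config <- function(bias_offset = 100,
                          effective_gain = 30,
                          excess_noise_factor = sqrt(2),
                          pixel_size_nm = 64,
                          magnification = 1,
                          numerical_aperture = 1.49,
                          emission_wavelength_nm = 665) {
  stopifnot(
    "effective_gain must be > 0" = is.numeric(effective_gain) && effective_gain > 0,
    "pixel_size_nm must be > 0" = is.numeric(pixel_size_nm) && pixel_size_nm > 0,
    "magnification must be >= 1" = is.numeric(magnification) && magnification >= 1,
    "numerical_aperture must be in (0, 1.7]" =
      is.numeric(numerical_aperture) && numerical_aperture > 0 && numerical_aperture <= 1.7,
    "emission_wavelength_nm must be in [300, 1000]" =
      is.numeric(emission_wavelength_nm) &&
      emission_wavelength_nm >= 300 && emission_wavelength_nm <= 1000,
    "excess_noise_factor must be >= 1" =
      is.numeric(excess_noise_factor) && excess_noise_factor >= 1,
    "bias_offset must be finite" = is.numeric(bias_offset) && is.finite(bias_offset)
  )
  cfg <- list(
    bias_offset = as.numeric(bias_offset),
    effective_gain = as.numeric(effective_gain),
    excess_noise_factor = as.numeric(excess_noise_factor),
    pixel_size_nm = as.numeric(pixel_size_nm),
    magnification = as.numeric(magnification),
    numerical_aperture = as.numeric(numerical_aperture),
    emission_wavelength_nm = as.numeric(emission_wavelength_nm),
    sample_pixel_nm = as.numeric(pixel_size_nm) / as.numeric(magnification)
  )
  stopifnot("sample-plane pixel size must be > 0" = cfg$sample_pixel_nm > 0)
  class(cfg) <- "camera_config"
  cfg
}

#' @export
print.camera_config <- function(x, ...) {
  cat("camera_config:\n")
  cat(sprintf("  bias offset        %g counts\n", x$bias_offset))
  cat(sprintf("  effective gain     %g counts/e-\n", x$effective_gain))
  cat(sprintf("  excess noise F     %.4g\n", x$excess_noise_factor))
  cat(sprintf("  pixel size         %g nm (sample plane %g nm)\n",
              x$pixel_size_nm, x$sample_pixel_nm))
  cat(sprintf("  NA %.3g, lambda %g nm\n", x$numerical_aperture,
              x$emission_wavelength_nm))
  cat(sprintf("  Airy radius        %.3f px, PSF sigma %.3f px\n",
              airy_radius_px(x), psf_sigma_px(x)))
  invisible(x)
}

#' Convert raw camera intensities to photoelectrons
#'
#' Applies \code{(I - bias_offset) / effective_gain} pixelwise. Values that
#' would come out negative (readings below the bias, possible through readout
#' noise) are clamped to zero: photoelectron counts cannot be negative and a
#' negative value would invalidate the Poisson noise model downstream.
#'
#' @param raw_frame Numeric matrix of raw intensity readings.
#' @param config A \code{\link{camera_config}}.
#' @param frame_index 0-based index of the frame within its stack.
#' @return A \code{photon_frame}: a list with \code{pixels} (numeric matrix of
#'   photoelectron counts, same shape as the input) and \code{frame_index}.
#' @export
to_photoelectrons <- function(raw_frame, config, frame_index = 0L) {
  stopifnot(inherits(config, "camera_config"), is.matrix(raw_frame))
  bad <- which(!is.finite(raw_frame))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(raw_frame))
    stop(sprintf("non-finite intensity at pixel (row %d, col %d) of frame %d",
                 rc[1L], rc[2L], frame_index))
  }
  px <- (raw_frame - config$bias_offset) / config$effective_gain
  px[px < 0] <- 0
  structure(list(pixels = px, frame_index = as.integer(frame_index)),
            class = "photon_frame")
}

#' Shot-noise standard deviation of a background level
#'
#' The noise in a pixel with \code{n_bg} expected background photoelectrons on
#' an EMCCD is \code{F * sqrt(n_bg)}, where F is the excess-noise factor.
#'
#' @param background_electrons Non-negative background level(s), e-.
#' @param config A \code{\link{camera_config}}.
#' @return Noise standard deviation(s), e-.
#' @export
noise_sigma <- function(background_electrons, config) {
  stopifnot(inherits(config, "camera_config"))
  if (any(background_electrons < 0))
    stop("background_electrons must be >= 0")
  config$excess_noise_factor * sqrt(background_electrons)
}

#' Per-pixel signal-to-noise ratio
#'
#' SNR of a pixel carrying \code{signal_electrons} above a local background of
#' \code{background_electrons}: \code{S / (F * sqrt(n_bg))}.
#'
#' @param signal_electrons Signal photoelectrons (background-subtracted).
#' @param background_electrons Background photoelectrons; must be > 0 (use the
#'   background map's floor, never a raw zero).
#' @param config A \code{\link{camera_config}}.
#' @return SNR value(s).
#' @export
pixel_snr <- function(signal_electrons, background_electrons, config) {
  stopifnot(inherits(config, "camera_config"))
  if (any(background_electrons <= 0))
    stop("background_electrons must be > 0 (apply the background floor first)")
  signal_electrons / (config$excess_noise_factor * sqrt(background_electrons))
}

#' Airy (Rayleigh) radius in camera pixels
#'
#' Distance from the center of a point emitter's image to its first
#' diffraction minimum, 0.61 * lambda / NA in the sample plane, expressed in
#' pixels: \code{0.61 * lambda * M / (NA * mu)}.
#'
#' @param config A \code{\link{camera_config}}.
#' @return Radius in pixels.
#' @export
airy_radius_px <- function(config) {
  stopifnot(inherits(config, "camera_config"))
  0.61 * config$emission_wavelength_nm * config$magnification /
    (config$numerical_aperture * config$pixel_size_nm)
}

#' Theoretical Gaussian PSF width in camera pixels
#'
#' Standard deviation of the 2D Gaussian approximating the diffraction-limited
#' PSF, 0.21 * lambda / NA in the sample plane, expressed in pixels.
#'
#' @param config A \code{\link{camera_config}}.
#' @return Sigma in pixels.
#' @export
psf_sigma_px <- function(config) {
  stopifnot(inherits(config, "camera_config"))
  0.21 * config$emission_wavelength_nm * config$magnification /
    (config$numerical_aperture * config$pixel_size_nm)
}
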