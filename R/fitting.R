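#' Gaussian fit model specification
#'
#' Three 2D Gaussian PSF model variants for sub-pixel localization:
#' \describe{
#'   \item{model 1}{fixed width: sigma in x and y pinned to the theoretical
#'     PSF sigma; only position, amplitude and offset are fitted. Recommended
#'     when emitters are in focus (e.g. TIRF illumination) and under poor
#'     imaging conditions.}
#'   \item{model 2}{symmetric variable width: one fitted sigma shared by x
#'     and y.}
#'   \item{model 3}{elliptical: sigma_x and sigma_y fitted independently.}
#' }
#' Models 2 and 3 take a PSF-width tolerance \code{pwt} bounding the fitted
#' width at \code{pwt * theoretical_sigma_px} from above.
#'
#' @param model 1, 2 or 3.
#' @param pwt PSF-width tolerance (>= 1; ignored by model 1).
#' @param theoretical_sigma_px Theoretical PSF sigma in pixels (from
#'   \code{\link{psf_sigma_px}}).
#' @param sigma_min_px Lower width bound in pixels (default 0.5, set by the
#'   pixel size: anything narrower is a spike, not a PSF).
#' @return A \code{gaussian_model_spec} list.
#' @export
gaussian_model_spec <- function(model = 1L, pwt = 3,
                                theoretical_sigma_px, sigma_min_px = 0.5) {
  stopifnot(model %in% 1:3, theoretical_sigma_px > 0, sigma_min_px > 0)
  if (model != 1L && (!is.numeric(pwt) || pwt < 1))
    stop("models 2 and 3 require pwt >= 1")
  structure(list(model = as.integer(model), pwt = as.numeric(pwt),
                 theoretical_sigma_px = as.numeric(theoretical_sigma_px),
                 sigma_min_px = as.numeric(sigma_min_px)),
            class = "gaussian_model_spec")
}

#' Initial parameter estimates for the Gaussian fit
#'
#' Position starts at the intensity-weighted centroid of the
#' background-subtracted signal over the fit window (a square of half-size
#' \code{ceiling(2 * PSF sigma)} around the peak, wide enough that disk
#' truncation barely biases the centroid); the amplitude at (peak value -
#' local background); the offset at the local background under the peak;
#' widths at the theoretical PSF sigma.
#'
#' @param candidate An accepted \code{candidate}.
#' @param frame A \code{photon_frame} (raw photoelectrons; the fit does not
#'   use the smoothed frame).
#' @return Named list: \code{x0}, \code{y0} (0-based px, x = column),
#'   \code{amplitude}, \code{offset}, \code{sigma}; or NULL when the window
#'   carries no signal.
#' @export
initial_estimate <- function(candidate, frame) {
  stopifnot(inherits(candidate, "candidate"))
  roi <- candidate$roi
  m <- .frame_pixels(frame)
  pk <- candidate$peak
  bg_pk <- roi$background[roi$row == pk[1L] & roi$col == pk[2L]][1L]
  h <- as.integer(ceiling(2 * candidate$psf_sigma_px))
  rows <- max(0L, pk[1L] - h):min(nrow(m) - 1L, pk[1L] + h)
  cols <- max(0L, pk[2L] - h):min(ncol(m) - 1L, pk[2L] + h)
  w <- pmax(m[rows + 1L, cols + 1L, drop = FALSE] - mean(roi$background), 0)
  tot <- sum(w)
  if (!is.finite(tot) || tot <= 0) return(NULL)
  x0 <- sum(rep(cols, each = length(rows)) * w) / tot
  y0 <- sum(rep(rows, times = length(cols)) * w) / tot
  list(x0 = x0, y0 = y0,
       amplitude = max(m[pk[1L] + 1L, pk[2L] + 1L] - bg_pk, 1e-3),
       offset = bg_pk, sigma = NA_real_)
}

# Gaussian surface over window coordinates; p holds the full parameter set.
.gauss2d <- function(p, x, y) {
  p[["offset"]] + p[["amplitude"]] *
    exp(-((x - p[["x0"]])^2 / (2 * p[["sx"]]^2) +
          (y - p[["y0"]])^2 / (2 * p[["sy"]]^2)))
}

#' Fit a 2D Gaussian to a candidate by Levenberg-Marquardt
#'
#' Unweighted least squares over a square window of half-size
#' \code{ceiling(2 * theoretical sigma)} centered on the peak, on the raw
#' photoelectron frame. Convergence: relative parameter change below 1e-6,
#' capped at 200 iterations; non-convergence and singular Jacobians yield
#' status \code{rejected_nonconverged}.
#'
#' @param candidate An accepted \code{candidate}.
#' @param frame The \code{photon_frame} the candidate came from.
#' @param spec A \code{\link{gaussian_model_spec}}.
#' @param config A \code{\link{camera_config}} (pixel size for nm
#'   coordinates; background noise for the precision estimate).
#' @return A \code{localization} object: frame_index, x/y in px (0-based,
#'   pixel centers at integers) and nm, amplitude, sigma_x/sigma_y (px),
#'   offset, photons (\code{2*pi*A*sx*sy}), pearson_r, precision_nm
#'   (Thompson-style estimate), q (inherited), status.
#' @export
fit_gaussian <- function(candidate, frame, spec, config) {
  stopifnot(inherits(spec, "gaussian_model_spec"),
            inherits(config, "camera_config"))
  m <- .frame_pixels(frame)
  sig0 <- spec$theoretical_sigma_px
  h <- as.integer(ceiling(2 * sig0))
  pk <- candidate$peak
  loc <- structure(
    list(frame_index = candidate$frame_index, x_px = NA_real_, y_px = NA_real_,
         x_nm = NA_real_, y_nm = NA_real_, amplitude = NA_real_,
         sigma_x_px = NA_real_, sigma_y_px = NA_real_, offset = NA_real_,
         photons = NA_real_, pearson_r = NA_real_, precision_nm = NA_real_,
         q = candidate$q, model = spec$model, status = "fitted",
         fit_data = NULL, fit_model = NULL),
    class = "localization")
  if (pk[1L] - h < 0L || pk[2L] - h < 0L ||
      pk[1L] + h > nrow(m) - 1L || pk[2L] + h > ncol(m) - 1L) {
    loc$status <- "rejected_edge"
    return(loc)
  }
  init <- initial_estimate(candidate, frame)
  if (is.null(init)) {
    loc$status <- "rejected_nonconverged"
    return(loc)
  }
  rows <- (pk[1L] - h):(pk[1L] + h)
  cols <- (pk[2L] - h):(pk[2L] + h)
  win <- m[rows + 1L, cols + 1L]
  gx <- matrix(rep(cols, each = length(rows)), nrow = length(rows))
  gy <- matrix(rep(rows, times = length(cols)), nrow = length(rows))

  par0 <- switch(spec$model,
    c(x0 = init$x0, y0 = init$y0, amplitude = init$amplitude,
      offset = init$offset),
    c(x0 = init$x0, y0 = init$y0, amplitude = init$amplitude,
      offset = init$offset, sigma = sig0),
    c(x0 = init$x0, y0 = init$y0, amplitude = init$amplitude,
      offset = init$offset, sx = sig0, sy = sig0))
  expand <- function(p) {
    full <- as.list(p)
    if (spec$model == 1L) { full$sx <- sig0; full$sy <- sig0 }
    if (spec$model == 2L) { full$sx <- p[["sigma"]]; full$sy <- p[["sigma"]] }
    full
  }
  resid_fn <- function(p) as.vector(win - .gauss2d(expand(p), gx, gy))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = par0, fn = resid_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 200, ptol = 1e-6, ftol = 1e-15)),
    error = function(e) NULL)
  if (is.null(fit) || !(fit$info %in% 1:4)) {
    loc$status <- "rejected_nonconverged"
    return(loc)
  }
  p <- expand(stats::coef(fit))
  p$sx <- abs(p$sx); p$sy <- abs(p$sy)
  model_vals <- .gauss2d(p, gx, gy)
  loc$x_px <- p$x0; loc$y_px <- p$y0
  loc$x_nm <- p$x0 * config$sample_pixel_nm
  loc$y_nm <- p$y0 * config$sample_pixel_nm
  loc$amplitude <- p$amplitude
  loc$sigma_x_px <- p$sx; loc$sigma_y_px <- p$sy
  loc$offset <- p$offset
  loc$photons <- 2 * pi * p$amplitude * p$sx * p$sy
  loc$fit_data <- as.vector(win)
  loc$fit_model <- as.vector(model_vals)
  if (stats::var(loc$fit_data) > 0 && stats::var(loc$fit_model) > 0)
    loc$pearson_r <- stats::cor(loc$fit_model, loc$fit_data)
  # Thompson-style localization precision (nm): shot-noise + pixelation +
  # background terms, using the fitted photon count and local background.
  a <- config$sample_pixel_nm
  s_nm <- mean(c(p$sx, p$sy)) * a
  n_ph <- max(loc$photons, 1)
  b2 <- config$excess_noise_factor^2 * max(p$offset, 0)
  loc$precision_nm <- sqrt((s_nm^2 + a^2 / 12) / n_ph +
                           8 * pi * s_nm^4 * b2 / (a^2 * n_ph^2))
  loc
}

#' PSF-width filter
#'
#' For models 2 and 3 every fitted sigma must lie in
#' \code{[sigma_min_px, pwt * theoretical_sigma_px]}; widths outside the band
#' are spikes (too narrow) or out-of-focus/multi-emitter blobs (too wide) and
#' are discarded. Model 1 always passes (its width is not fitted).
#'
#' @param loc A \code{localization}.
#' @param spec The \code{\link{gaussian_model_spec}} used for the fit.
#' @return The localization, possibly with status \code{rejected_width}.
#' @export
width_filter <- function(loc, spec) {
  stopifnot(inherits(loc, "localization"), inherits(spec, "gaussian_model_spec"))
  if (loc$status != "fitted" || spec$model == 1L) return(loc)
  lo <- spec$sigma_min_px
  hi <- spec$pwt * spec$theoretical_sigma_px
  ok <- loc$sigma_x_px >= lo && loc$sigma_x_px <= hi &&
        loc$sigma_y_px >= lo && loc$sigma_y_px <= hi
  if (!ok) loc$status <- "rejected_width"
  loc
}

#' Goodness-of-fit filter (Pearson correlation)
#'
#' Pearson correlation between the fitted model surface and the data over
#' the fit window; localizations with \code{r < r_min} (or a zero-variance
#' window, where r is undefined) are discarded.
#'
#' @param loc A \code{localization} carrying its fit window.
#' @param r_min Minimum correlation (default 0.5).
#' @return The localization with status \code{accepted} or
#'   \code{rejected_fit_quality}.
#' @export
fit_quality_filter <- function(loc, r_min = 0.5) {
  stopifnot(inherits(loc, "localization"))
  if (loc$status != "fitted") return(loc)
  if (is.na(loc$pearson_r) || loc$pearson_r < r_min) {
    loc$status <- "rejected_fit_quality"
  } else {
    loc$status <- "accepted"
  }
  loc
}

#' Localization table
#'
#' @param locs List of \code{localization} objects.
#' @param include_rejected Keep rejected rows (default FALSE).
#' @return data.frame with the fixed column set: frame, x_nm, y_nm, x_px,
#'   y_px, sigma_x_px, sigma_y_px, amplitude_e, offset_e, photons_e,
#'   pearson_r, precision_nm, q, status. This is the primary output of the
#'   pipeline.
#' @export
localization_table <- function(locs, include_rejected = FALSE) {
  empty <- data.frame(frame = integer(0), x_nm = numeric(0), y_nm = numeric(0),
                      x_px = numeric(0), y_px = numeric(0),
                      sigma_x_px = numeric(0), sigma_y_px = numeric(0),
                      amplitude_e = numeric(0), offset_e = numeric(0),
                      photons_e = numeric(0), pearson_r = numeric(0),
                      precision_nm = numeric(0), q = numeric(0),
                      status = character(0))
  if (!length(locs)) return(empty)
  num <- function(field) vapply(locs, `[[`, numeric(1), field)
  tab <- data.frame(
    frame = vapply(locs, `[[`, integer(1), "frame_index"),
    x_nm = num("x_nm"), y_nm = num("y_nm"),
    x_px = num("x_px"), y_px = num("y_px"),
    sigma_x_px = num("sigma_x_px"), sigma_y_px = num("sigma_y_px"),
    amplitude_e = num("amplitude"), offset_e = num("offset"),
    photons_e = num("photons"), pearson_r = num("pearson_r"),
    precision_nm = num("precision_nm"), q = num("q"),
    status = vapply(locs, `[[`, character(1), "status"))
  if (!include_rejected) tab <- tab[tab$status == "accepted", , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Fit all accepted candidates of a frame
#'
#' @param candidates Candidate list (only those with status \code{accepted}
#'   are fitted).
#' @param frame The source \code{photon_frame}.
#' @param spec A \code{\link{gaussian_model_spec}}.
#' @param config A \code{\link{camera_config}}.
#' @param r_min Pearson goodness-of-fit threshold (default 0.5).
#' @return List of \code{localization} objects (all fitted candidates, with
#'   statuses from the width and quality filters applied).
#' @export
localize_candidates <- function(candidates, frame, spec, config, r_min = 0.5) {
  acc <- Filter(function(cand) cand$status == "accepted", candidates)
  lapply(acc, function(cand) {
    loc <- fit_gaussian(cand, frame, spec, config)
    loc <- width_filter(loc, spec)
    fit_quality_filter(loc, r_min)
  })
}
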