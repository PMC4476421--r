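#' Read a multi-page TIFF stack
#'
#' @param path Path to an 8/16-bit grayscale multi-page TIFF.
#' @return List of numeric matrices, one per frame, in native integer
#'   intensity units.
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) stop("cannot read TIFF ", path, ": ",
                                             conditionMessage(e)))
  if (is.matrix(pages)) pages <- list(pages)
  dims <- vapply(pages, function(p) {
    if (length(dim(p)) != 2L)
      stop("page is not single-channel grayscale")
    dim(p)
  }, integer(2))
  if (length(pages) > 1L && any(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])) {
    bad <- which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])[1L]
    stop(sprintf("ragged stack: page %d has different dimensions", bad))
  }
  lapply(pages, function(p) {
    storage.mode(p) <- "double"
    p
  })
}

#' Pipeline configuration
#'
#' Bundles every parameter of the identification + localization pipeline.
#' \code{q_threshold} is the only parameter without a physically dictated
#' default: it is the user's choice and trades false positives against
#' false negatives.
#'
#' @param camera A \code{\link{camera_config}}.
#' @param q_threshold Quality threshold (the one mandatory user parameter).
#' @param model Gaussian fit model, 1 (fixed width), 2 (symmetric) or 3
#'   (elliptical).
#' @param pwt PSF-width tolerance for models 2-3 (default 3).
#' @param smooth_sigma_px Noise-reduction sigma, px (default 1).
#' @param rose_cnr_min Rose criterion bound (default 3; exposed for
#'   diagnostics, not meant to be changed).
#' @param r_min Pearson goodness-of-fit threshold (default 0.5).
#' @param background_window_factor Median-window radius as a multiple of the
#'   Airy radius (default 1).
#' @param background_floor Background map floor, e- (default 1e-3).
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(camera = camera_config(), q_threshold = 2,
                            model = 1L, pwt = 3, smooth_sigma_px = 1,
                            rose_cnr_min = 3, r_min = 0.5,
                            background_window_factor = 1,
                            background_floor = 1e-3) {
  stopifnot(inherits(camera, "camera_config"), q_threshold >= 0,
            model %in% 1:3, smooth_sigma_px > 0)
  structure(list(camera = camera, q_threshold = q_threshold,
                 model = as.integer(model), pwt = pwt,
                 smooth_sigma_px = smooth_sigma_px,
                 rose_cnr_min = rose_cnr_min, r_min = r_min,
                 background_window_factor = background_window_factor,
                 background_floor = background_floor),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Top-level keys: \code{bias_offset}, \code{effective_gain},
#' \code{excess_noise_factor}, \code{pixel_size_nm}, \code{magnification},
#' \code{numerical_aperture}, \code{emission_wavelength_nm} (camera), and
#' any \code{\link{pipeline_config}} argument. \code{overrides} (a named
#' list, e.g. from CLI flags) wins over the file.
#'
#' @param path YAML file path, or NULL for pure-override configuration.
#' @param overrides Named list of overriding values.
#' @return A \code{pipeline_config}.
#' @export
load_pipeline_config <- function(path = NULL, overrides = list()) {
  vals <- if (!is.null(path)) yaml::read_yaml(path) else list()
  vals[names(overrides)] <- overrides
  cam_keys <- c("bias_offset", "effective_gain", "excess_noise_factor",
                "pixel_size_nm", "magnification", "numerical_aperture",
                "emission_wavelength_nm")
  cam <- do.call(camera_config, vals[intersect(names(vals), cam_keys)])
  pipe_keys <- setdiff(names(formals(pipeline_config)), "camera")
  do.call(pipeline_config,
          c(list(camera = cam), vals[intersect(names(vals), pipe_keys)]))
}

#' Run the full localization pipeline over a stack
#'
#' Per frame: intensity-to-photoelectron conversion, Gaussian smoothing,
#' local-maxima search within the Airy radius, isolation filtering, ROI
#' selection, SNR/CNR/Q scoring, Rose + Q thresholding, Levenberg-Marquardt
#' Gaussian fitting, and the width and goodness-of-fit filters. Frames are
#' processed independently, so results do not depend on frame order.
#'
#' @param stack List of raw intensity matrices (e.g. from
#'   \code{\link{read_stack}} or \code{\link{simulate_stack}}) or a TIFF
#'   path.
#' @param config A \code{\link{pipeline_config}}.
#' @param keep_rejected Include rejected localizations in the table
#'   (default FALSE).
#' @return List: \code{localizations} (the localization table),
#'   \code{candidates} (per-candidate diagnostic table across all frames),
#'   \code{manifest} (run metadata: configuration, per-status counts,
#'   wall time).
#' @export
localize_stack <- function(stack, config, keep_rejected = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(stack)) stack <- read_stack(stack)
  t0 <- Sys.time()
  cam <- config$camera
  spec <- gaussian_model_spec(config$model, config$pwt,
                              theoretical_sigma_px = psf_sigma_px(cam))
  loc_tabs <- vector("list", length(stack))
  cand_tabs <- vector("list", length(stack))
  for (i in seq_along(stack)) {
    fr <- to_photoelectrons(stack[[i]], cam, frame_index = i - 1L)
    bg <- estimate_background(fr, cam,
                              window_factor = config$background_window_factor,
                              floor = config$background_floor)
    det <- detect_emitters(fr, cam, config$q_threshold,
                           smooth_sigma_px = config$smooth_sigma_px,
                           rose_cnr_min = config$rose_cnr_min,
                           background = bg)
    locs <- localize_candidates(det$candidates, fr, spec, cam,
                                r_min = config$r_min)
    loc_tabs[[i]] <- localization_table(locs, include_rejected = keep_rejected)
    cand_tabs[[i]] <- candidate_table(det$candidates)
  }
  loc_tab <- if (length(stack)) do.call(rbind, loc_tabs) else
    localization_table(list())
  cand_tab <- if (length(stack)) do.call(rbind, cand_tabs) else
    candidate_table(list())
  rownames(loc_tab) <- rownames(cand_tab) <- NULL
  manifest <- list(
    software = paste("snsmlm", as.character(utils::packageVersion("snsmlm"))),
    n_frames = length(stack),
    q_threshold = config$q_threshold,
    model = config$model, pwt = config$pwt,
    rose_cnr_min = config$rose_cnr_min, r_min = config$r_min,
    smooth_sigma_px = config$smooth_sigma_px,
    camera = unclass(config$camera),
    candidate_status_counts = as.list(table(cand_tab$status)),
    localization_count = sum(loc_tab$status == "accepted"),
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  list(localizations = loc_tab, candidates = cand_tab, manifest = manifest)
}

#' Write pipeline results to a directory
#'
#' Writes \code{localizations.csv} (the primary output),
#' \code{candidates.csv} (diagnostics, for Q-histogram analysis) and
#' \code{manifest.yaml}.
#'
#' @param result Return value of \code{\link{localize_stack}}.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  loc_path <- file.path(out_dir, "localizations.csv")
  cand_path <- file.path(out_dir, "candidates.csv")
  man_path <- file.path(out_dir, "manifest.yaml")
  utils::write.csv(result$localizations, loc_path, row.names = FALSE)
  utils::write.csv(result$candidates, cand_path, row.names = FALSE)
  yaml::write_yaml(result$manifest, man_path)
  invisible(list(localizations = loc_path, candidates = cand_path,
                 manifest = man_path))
}
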