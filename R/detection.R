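#' Find local intensity maxima
#'
#' A pixel is reported as a peak when no pixel within Euclidean distance
#' \code{radius_px} of it has a strictly greater value, and no
#' lexicographically smaller pixel (row-major order) within that distance has
#' an equal value. The second clause resolves flat plateaus deterministically
#' by keeping only the smallest coordinate.
#'
#' @param smoothed_frame Numeric matrix (normally the lightly smoothed
#'   photoelectron frame).
#' @param radius_px Neighborhood radius in pixels (>= 1); the Airy radius in
#'   the standard pipeline.
#' @return A data.frame with 0-based \code{row}, \code{col} peak coordinates.
#' @export
find_local_maxima <- function(smoothed_frame, radius_px) {
  stopifnot(is.matrix(smoothed_frame), radius_px >= 1)
  m <- smoothed_frame
  offs <- .disk_offsets(radius_px, include_center = FALSE)
  neighmax <- matrix(-Inf, nrow(m), ncol(m))
  eq_lexneg <- matrix(FALSE, nrow(m), ncol(m))
  for (i in seq_along(offs$drow)) {
    dr <- offs$drow[i]; dc <- offs$dcol[i]
    sh <- .shift_matrix(m, -dr, -dc)  # value of the neighbor at (+dr, +dc)
    neighmax <- pmax(neighmax, sh)
    if (dr < 0 || (dr == 0 && dc < 0))  # lexicographically smaller side
      eq_lexneg <- eq_lexneg | (sh == m)
  }
  is_peak <- (m >= neighmax) & !eq_lexneg
  idx <- which(is_peak, arr.ind = TRUE)
  out <- data.frame(row = idx[, 1L] - 1L, col = idx[, 2L] - 1L)
  out[order(out$row, out$col), , drop = FALSE]
}

#' Discard non-isolated peaks
#'
#' Removes every peak that has another peak closer than \code{radius_px}
#' (both members of a close pair are dropped): overlapping PSFs cannot be
#' analyzed as single emitters and multi-emitter deconvolution is out of
#' scope.
#'
#' @param peaks data.frame of 0-based \code{row}, \code{col} coordinates.
#' @param radius_px Minimum allowed pairwise distance (the Airy radius).
#' @return The subset of \code{peaks} with all pairwise distances
#'   >= \code{radius_px}.
#' @export
reject_nonisolated <- function(peaks, radius_px) {
  n <- nrow(peaks)
  if (n <= 1L) return(peaks)
  d <- as.matrix(stats::dist(cbind(peaks$row, peaks$col)))
  diag(d) <- Inf
  keep <- apply(d, 1L, min) >= radius_px
  peaks[keep, , drop = FALSE]
}

#' Select the region of interest around a candidate peak
#'
#' The ROI contains the pixels within Euclidean distance
#' \code{ceiling(psf_sigma_px)} of the peak whose (smoothed) value exceeds
#' the local background -- i.e. only pixels actually carrying signal enter
#' the SNR analysis. The peak pixel itself is always included. The candidate
#' also records the background over the full theoretical PSF disk (the same
#' radius, no signal condition), which the contrast-to-noise denominator
#' needs.
#'
#' Peaks closer than \code{ceiling(psf_sigma_px) + 1} pixels to a frame
#' border are rejected outright (neither the ROI nor the fit window fits).
#'
#' @param smoothed_frame Numeric matrix the scores are computed on.
#' @param background A \code{background_map} from
#'   \code{\link{estimate_background}}.
#' @param peak Length-2 vector, 0-based (row, col).
#' @param psf_sigma_px Theoretical PSF sigma in pixels.
#' @param frame_index 0-based frame index carried into the candidate.
#' @return A \code{candidate} object (list) with fields \code{frame_index},
#'   \code{peak}, \code{roi} (list of parallel vectors: row, col, signal,
#'   background), \code{disk_background} (background over the full disk),
#'   \code{snr_eff}, \code{cnr_eff}, \code{q} (NA until scored) and
#'   \code{status}.
#' @export
select_roi <- function(smoothed_frame, background, peak, psf_sigma_px,
                       frame_index = 0L) {
  stopifnot(inherits(background, "background_map"), length(peak) == 2L)
  r <- as.integer(ceiling(psf_sigma_px))
  nr <- nrow(smoothed_frame); nc <- ncol(smoothed_frame)
  cand <- structure(
    list(frame_index = as.integer(frame_index),
         peak = as.integer(peak), psf_sigma_px = as.numeric(psf_sigma_px),
         roi = NULL, disk_background = numeric(0),
         snr_eff = NA_real_, cnr_eff = NA_real_, q = NA_real_,
         status = "candidate"),
    class = "candidate")
  margin <- r + 1L
  if (peak[1L] < margin || peak[2L] < margin ||
      peak[1L] > nr - 1L - margin || peak[2L] > nc - 1L - margin) {
    cand$status <- "rejected_edge"
    return(cand)
  }
  offs <- .disk_offsets(r, include_center = TRUE)
  rows <- peak[1L] + offs$drow
  cols <- peak[2L] + offs$dcol
  vals <- smoothed_frame[cbind(rows + 1L, cols + 1L)]
  bg <- background$values[cbind(rows + 1L, cols + 1L)]
  cand$disk_background <- bg
  in_roi <- vals > bg | (offs$drow == 0L & offs$dcol == 0L)
  cand$roi <- list(row = rows[in_roi], col = cols[in_roi],
                   signal = pmax(vals[in_roi] - bg[in_roi], 0),
                   background = bg[in_roi])
  cand
}

#' Score a candidate with SNR_eff, CNR_eff and the quality metric Q
#'
#' Three shot-noise statistics over the candidate's ROI:
#' \itemize{
#'   \item \code{snr_eff}: mean over ROI pixels of the per-pixel SNR
#'     \code{S / (F * sqrt(n_bg))};
#'   \item \code{cnr_eff}: aggregate contrast over aggregate noise,
#'     \code{sum(S) / (F * sqrt(sum of background over the full PSF disk))}
#'     -- the denominator uses the whole theoretical disk, not just the ROI;
#'   \item \code{q = min(snr_eff, cnr_eff)}.
#' }
#' A needle-like single-pixel spike scores a high SNR_eff but a low CNR_eff;
#' a broad, over-wide blob scores the reverse. Neither looks like a single
#' emitter, and taking the minimum penalizes both.
#'
#' @param candidate A \code{candidate} from \code{\link{select_roi}}.
#' @param config A \code{\link{camera_config}}.
#' @return The candidate with \code{snr_eff}, \code{cnr_eff}, \code{q}
#'   filled (zeros, and status \code{rejected_empty_roi}, when the ROI holds
#'   no signal).
#' @export
score_candidate <- function(candidate, config) {
  stopifnot(inherits(candidate, "candidate"), inherits(config, "camera_config"))
  if (candidate$status != "candidate") return(candidate)
  roi <- candidate$roi
  if (is.null(roi) || length(roi$row) == 0L || sum(roi$signal) == 0) {
    candidate$snr_eff <- candidate$cnr_eff <- candidate$q <- 0
    if (is.null(roi) || length(roi$row) == 0L)
      candidate$status <- "rejected_empty_roi"
    return(candidate)
  }
  f <- config$excess_noise_factor
  candidate$snr_eff <- mean(roi$signal / (f * sqrt(roi$background)))
  candidate$cnr_eff <- sum(roi$signal) / (f * sqrt(sum(candidate$disk_background)))
  candidate$q <- min(candidate$snr_eff, candidate$cnr_eff)
  candidate
}

#' Apply the Rose criterion and the user's quality threshold
#'
#' A candidate is accepted iff \code{cnr_eff > rose_cnr_min} (the Rose
#' criterion, strict, not user-configurable in the standard pipeline) and
#' \code{q >= q_threshold} (the single user-chosen parameter). Rejected
#' candidates keep a status recording which constraint failed; statuses only
#' ever move from \code{candidate} to a terminal value.
#'
#' @param candidates List of scored \code{candidate} objects.
#' @param q_threshold Quality threshold (>= 0).
#' @param rose_cnr_min Rose-criterion bound (default 3).
#' @return The list with statuses set to \code{accepted},
#'   \code{rejected_rose} or \code{rejected_q}.
#' @export
filter_candidates <- function(candidates, q_threshold, rose_cnr_min = 3) {
  if (!is.numeric(q_threshold) || q_threshold < 0)
    stop("q_threshold must be a non-negative number")
  lapply(candidates, function(cand) {
    if (cand$status != "candidate") return(cand)
    if (is.na(cand$cnr_eff)) stop("candidate not scored")
    if (!(cand$cnr_eff > rose_cnr_min)) {
      cand$status <- "rejected_rose"
    } else if (cand$q < q_threshold) {
      cand$status <- "rejected_q"
    } else {
      cand$status <- "accepted"
    }
    cand
  })
}

#' Per-candidate diagnostic table
#'
#' @param candidates List of \code{candidate} objects.
#' @return data.frame: frame, row, col, snr_eff, cnr_eff, q, status. This is
#'   the table behind quality-histogram diagnostics of a measurement.
#' @export
candidate_table <- function(candidates) {
  if (!length(candidates)) {
    return(data.frame(frame = integer(0), row = integer(0), col = integer(0),
                      snr_eff = numeric(0), cnr_eff = numeric(0),
                      q = numeric(0), status = character(0)))
  }
  data.frame(
    frame = vapply(candidates, `[[`, integer(1), "frame_index"),
    row = vapply(candidates, function(cand) cand$peak[1L], integer(1)),
    col = vapply(candidates, function(cand) cand$peak[2L], integer(1)),
    snr_eff = vapply(candidates, `[[`, numeric(1), "snr_eff"),
    cnr_eff = vapply(candidates, `[[`, numeric(1), "cnr_eff"),
    q = vapply(candidates, `[[`, numeric(1), "q"),
    status = vapply(candidates, `[[`, character(1), "status"))
}

#' Detect emitter candidates in one photoelectron frame
#'
#' Runs the per-frame identification chain: light Gaussian smoothing, local
#' background estimation, local-maxima search within the Airy radius,
#' isolation filtering, ROI selection, shot-noise scoring, and the
#' Rose + quality threshold filter.
#'
#' @param frame A \code{photon_frame} (see \code{\link{to_photoelectrons}}).
#' @param config A \code{\link{camera_config}}.
#' @param q_threshold User quality threshold.
#' @param smooth_sigma_px Noise-reduction kernel sigma (default 1 px, below
#'   the PSF sigma so the spot shape survives).
#' @param rose_cnr_min Rose-criterion bound (default 3).
#' @param background Optionally a precomputed \code{background_map}.
#' @return List with \code{candidates} (all, with statuses),
#'   \code{smoothed} and \code{background} for downstream reuse.
#' @export
detect_emitters <- function(frame, config, q_threshold,
                            smooth_sigma_px = 1, rose_cnr_min = 3,
                            background = NULL) {
  stopifnot(inherits(frame, "photon_frame"))
  sm <- smooth_frame(frame, smooth_sigma_px)
  if (is.null(background)) background <- estimate_background(frame, config)
  r_airy <- airy_radius_px(config)
  sigma <- psf_sigma_px(config)
  peaks <- find_local_maxima(sm, r_airy)
  peaks <- reject_nonisolated(peaks, r_airy)
  cands <- lapply(seq_len(nrow(peaks)), function(i) {
    cand <- select_roi(sm, background, c(peaks$row[i], peaks$col[i]), sigma,
                       frame_index = frame$frame_index)
    score_candidate(cand, config)
  })
  cands <- filter_candidates(cands, q_threshold, rose_cnr_min)
  list(candidates = cands, smoothed = sm, background = background)
}
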