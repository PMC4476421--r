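#' Render a super-resolution image from a localization table
#'
#' Histogram mode bins localizations into \code{bin_size_nm} pixels; Gaussian
#' mode splats each localization as a unit-integral Gaussian of
#' \code{gaussian_sigma_nm} (truncated at 4 sigma; the discrete kernel is
#' renormalized and mass falling off the canvas is reflected back, so total
#' rendered mass equals the localization count).
#'
#' @param locs data.frame with \code{x_nm}, \code{y_nm} columns (accepted
#'   localizations).
#' @param bin_size_nm Super-resolution pixel size, nm (default 10).
#' @param mode \code{"histogram"} or \code{"gaussian"}.
#' @param gaussian_sigma_nm Splat sigma for gaussian mode, nm (default 20).
#' @param field_nm Length-2 vector (width, height) of the field of view in
#'   nm; defaults to the localization extent.
#' @return Numeric matrix (row = y bin, col = x bin) of rendered mass.
#' @export
render_image <- function(locs, bin_size_nm = 10,
                         mode = c("histogram", "gaussian"),
                         gaussian_sigma_nm = 20, field_nm = NULL) {
  mode <- match.arg(mode)
  stopifnot(bin_size_nm > 0)
  if (is.null(field_nm)) {
    field_nm <- if (nrow(locs)) c(max(locs$x_nm), max(locs$y_nm)) else
      c(bin_size_nm, bin_size_nm)
  }
  nx <- max(1L, as.integer(ceiling((field_nm[1L] + bin_size_nm / 2) / bin_size_nm)))
  ny <- max(1L, as.integer(ceiling((field_nm[2L] + bin_size_nm / 2) / bin_size_nm)))
  img <- matrix(0, ny, nx)
  if (!nrow(locs)) {
    warning("empty localization table; rendering an all-zero image")
    return(img)
  }
  ix <- pmin(pmax(floor(locs$x_nm / bin_size_nm) + 1L, 1L), nx)
  iy <- pmin(pmax(floor(locs$y_nm / bin_size_nm) + 1L, 1L), ny)
  if (mode == "histogram") {
    acc <- tabulate(iy + (ix - 1L) * ny, nbins = nx * ny)
    return(img + matrix(acc, ny, nx))
  }
  s_bin <- gaussian_sigma_nm / bin_size_nm
  r <- max(1L, as.integer(ceiling(4 * s_bin)))
  k1 <- stats::dnorm(-r:r, sd = s_bin)
  kern <- outer(k1, k1)
  kern <- kern / sum(kern)
  for (i in seq_along(ix)) {
    rows <- (iy[i] - r):(iy[i] + r)
    cols <- (ix[i] - r):(ix[i] + r)
    rr <- ifelse(rows < 1L, 2L - rows, ifelse(rows > ny, 2L * ny - rows, rows))
    cc <- ifelse(cols < 1L, 2L - cols, ifelse(cols > nx, 2L * nx - cols, cols))
    rr <- pmin(pmax(rr, 1L), ny); cc <- pmin(pmax(cc, 1L), nx)
    for (a in seq_along(rr))
      for (b in seq_along(cc))
        img[rr[a], cc[b]] <- img[rr[a], cc[b]] + kern[a, b]
  }
  img
}

#' Write a rendered image as TIFF
#'
#' @param image Matrix from \code{\link{render_image}}.
#' @param path Output path.
#' @param bit_depth 8, 16, or \code{"float"} (32-bit float sample).
#' @return Invisibly, \code{path}.
#' @export
write_rendered <- function(image, path, bit_depth = 16) {
  top <- max(image)
  scaled <- if (top > 0) image / top else image
  if (identical(bit_depth, "float")) {
    tiff::writeTIFF(image / max(top, 1), path, bits.per.sample = 32L)
  } else {
    tiff::writeTIFF(scaled, path, bits.per.sample = as.integer(bit_depth))
  }
  invisible(path)
}

#' Intensity profile across a line segment
#'
#' Projects all localizations within \code{width_nm / 2} of the segment onto
#' the axis perpendicular to it, bins the signed perpendicular distances and
#' normalizes the profile to its maximum -- the standard way to measure the
#' apparent width of a filamentous structure in a reconstruction.
#'
#' @param locs data.frame with \code{x_nm}, \code{y_nm}.
#' @param p0,p1 Segment endpoints, length-2 (x, y) in nm.
#' @param width_nm Total width of the collection band: localizations within
#'   \code{width_nm / 2} of the segment line (and between its endpoints) are
#'   kept; the profile axis spans the same band.
#' @param bin_nm Profile bin width, nm (default 10).
#' @return data.frame: \code{position_nm} (bin centers, 0 on the segment),
#'   \code{count}, \code{intensity} (count / max count).
#' @export
line_profile <- function(locs, p0, p1, width_nm, bin_nm = 10) {
  stopifnot(length(p0) == 2L, length(p1) == 2L, width_nm > 0, bin_nm > 0)
  v <- c(p1[1L] - p0[1L], p1[2L] - p0[2L])
  len <- sqrt(sum(v^2))
  stopifnot(len > 0)
  u <- v / len                      # along the segment
  w <- c(-u[2L], u[1L])             # perpendicular
  dx <- locs$x_nm - p0[1L]
  dy <- locs$y_nm - p0[2L]
  along <- dx * u[1L] + dy * u[2L]
  perp <- dx * w[1L] + dy * w[2L]
  half <- width_nm / 2
  perp <- perp[along >= 0 & along <= len & abs(perp) <= half]
  nb <- max(1L, as.integer(ceiling(2 * half / bin_nm)))
  breaks <- seq(-half, half, length.out = nb + 1L)
  bin_nm <- breaks[2L] - breaks[1L]
  centers <- breaks[-1L] - bin_nm / 2
  counts <- if (length(perp)) {
    graphics::hist(perp, breaks = breaks, plot = FALSE)$counts
  } else {
    warning("no localizations in the profile band")
    rep(0L, length(centers))
  }
  top <- max(counts)
  data.frame(position_nm = centers, count = counts,
             intensity = if (top > 0) counts / top else counts * 0)
}
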