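# Internal numerics shared by the background and detection stages.

# cache for 1D smoothing operators, keyed by "n|sigma"
.op_cache <- new.env(parent = emptyenv())

# 1D Gaussian convolution operator (n x n) with reflective boundaries.
# Row i holds the kernel weights for output sample i; out-of-range taps are
# folded back by mirror reflection about the edge samples, so a normalized
# kernel keeps column sums (hence the frame total) at 1.
.gauss_operator <- function(n, sigma) {
  key <- paste(n, signif(sigma, 12), sep = "|")
  hit <- .op_cache[[key]]
  if (!is.null(hit)) return(hit)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  op <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- (i - r):(i + r)
    # reflect: 0 -> 2, -1 -> 3, n+1 -> n-1, ... (edge sample not repeated)
    idx <- ifelse(idx < 1L, 2L - idx, idx)
    idx <- ifelse(idx > n, 2L * n - idx, idx)
    idx <- pmin(pmax(idx, 1L), n)
    for (j in seq_along(idx)) op[i, idx[j]] <- op[i, idx[j]] + k[j]
  }
  .op_cache[[key]] <- op
  op
}

# Integer pixel offsets (drow, dcol) within Euclidean distance `radius` of the
# origin; optionally excluding the origin itself. Cached: this runs once per
# candidate in the hot path.
.disk_cache <- new.env(parent = emptyenv())
.disk_offsets <- function(radius, include_center = TRUE) {
  key <- paste(signif(radius, 12), include_center, sep = "|")
  hit <- .disk_cache[[key]]
  if (!is.null(hit)) return(hit)
  r <- as.integer(ceiling(radius))
  g <- expand.grid(drow = -r:r, dcol = -r:r)
  keep <- g$drow^2 + g$dcol^2 <= radius^2
  g <- g[keep, , drop = FALSE]
  if (!include_center) g <- g[!(g$drow == 0 & g$dcol == 0), , drop = FALSE]
  g <- list(drow = as.integer(g$drow), dcol = as.integer(g$dcol))
  .disk_cache[[key]] <- g
  g
}

# Shift a matrix by (drow, dcol), padding with `fill`.
.shift_matrix <- function(m, drow, dcol, fill = -Inf) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1L, 1L + drow):min(nr, nr + drow)
  cs <- max(1L, 1L + dcol):min(nc, nc + dcol)
  out[rs, cs] <- m[rs - drow, cs - dcol, drop = FALSE]
  out
}

# Pixel-integrated mass of a unit 2D Gaussian centered at (x0, y0) (0-based,
# pixel centers at integers) over the pixel whose center is (x, y).
.pixel_gauss_mass <- function(x, y, x0, y0, sigma) {
  (stats::pnorm(x + 0.5, x0, sigma) - stats::pnorm(x - 0.5, x0, sigma)) *
    (stats::pnorm(y + 0.5, y0, sigma) - stats::pnorm(y - 0.5, y0, sigma))
}

.frame_pixels <- function(frame) {
  if (inherits(frame, "photon_frame")) frame$pixels else frame
}
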