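# Weighted back-projection reconstruction and missing-wedge bookkeeping.

#' Reconstruction parameters
#'
#' @param output_shape Integer triple `(nx, ny, nz)`; `NULL` derives
#'   `(nx, ny, nx)` from the projection size.
#' @param weighting `"ramp"` (|k| filter with raised-cosine rolloff) or
#'   `"none"`.
#' @param rolloff_fraction Fraction of the top frequencies apodized by the
#'   raised cosine, in `(0, 1]`.
#' @return Object of class `recon_params`.
#' @export
recon_params <- function(output_shape = NULL, weighting = c("ramp", "none"),
                         rolloff_fraction = 0.05) {
  weighting <- match.arg(weighting)
  stopifnot(rolloff_fraction > 0, rolloff_fraction <= 1)
  structure(list(output_shape = output_shape, weighting = weighting,
                 rolloff_fraction = rolloff_fraction),
            class = "recon_params")
}

ramp_weights <- function(nx, rolloff_fraction) {
  k <- abs(fft_freq(nx))
  kmax <- max(k)
  w <- k / kmax
  k0 <- (1 - rolloff_fraction) * kmax
  hi <- k > k0
  w[hi] <- w[hi] * 0.5 * (1 + cos(pi * (k[hi] - k0) / (kmax - k0)))
  w
}

#' Ramp-weight the projections of a tilt series
#'
#' Filters each image along x (the axis perpendicular to the tilt axis)
#' with `|k|` apodized by a raised cosine over the top `rolloff_fraction`
#' of frequencies.  The weights are even in k, so real images stay real,
#' and the DC component is removed.  `weighting = "none"` returns the
#' input unchanged.
#'
#' @param stack A [tilt_series()].
#' @param params A [recon_params()].
#' @return A weighted [tilt_series()].
#' @export
weight_projections <- function(stack, params = recon_params()) {
  stopifnot(inherits(stack, "tilt_series"), inherits(params, "recon_params"))
  if (length(stack$angles) == 0) stop_septomo("empty tilt series")
  if (params$weighting == "none") return(stack)
  d <- dim(stack$images)
  w <- ramp_weights(d[1], params$rolloff_fraction)
  out <- stack
  for (i in seq_len(d[3])) {
    img <- stack$images[, , i]
    out$images[, , i] <- Re(mvfft(mvfft(img) * w, inverse = TRUE)) / d[1]
  }
  out
}

#' Weighted back-projection reconstruction
#'
#' Sums, over tilt angles, the ramp-weighted projections smeared back
#' along their beam directions into the output grid (voxel-driven
#' gathering with linear interpolation in the plane perpendicular to the
#' tilt axis; the exact adjoint of [project()]).  Linear in the input
#' stack.  The result lives in the acquisition frame; use
#' [unorient_volume()] to return to the phantom frame.
#'
#' @param stack A [tilt_series()].
#' @param params A [recon_params()].
#' @return A `density_volume`.
#' @export
wbp <- function(stack, params = recon_params()) {
  stopifnot(inherits(stack, "tilt_series"))
  d <- dim(stack$images)
  shape <- params$output_shape %||% c(d[1], d[2], d[1])
  if (shape[1] != d[1] || shape[2] != d[2]) {
    stop_septomo("output_shape (", paste(shape, collapse = "x"),
                 ") incompatible with projection size ", d[1], "x", d[2])
  }
  weighted <- weight_projections(stack, params)
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  acc <- matrix(0, nx * nz, ny)
  for (i in seq_along(stack$angles)) {
    A <- proj_matrix(nx, nz, stack$angles[i])
    acc <- acc + as.matrix(Matrix::crossprod(A, weighted$images[, , i]))
  }
  scale <- pi / (2 * length(stack$angles)) / stack$pixel_size
  vol <- aperm(array(acc * scale, c(nx, nz, ny)), c(1L, 3L, 2L))
  density_volume(vol, stack$pixel_size)
}

#' Fourier-plane occupancy of a single-axis tilt range
#'
#' Fraction of the kx-kz plane sampled by tilting to `+/- tilt_range`
#' degrees: `tilt_range / 90`.  The remainder is the missing wedge.
#'
#' @param tilt_range Half-angle in degrees, in `(0, 90]`.
#' @return Fraction in `[0, 1]`.
#' @export
missing_wedge_occupancy <- function(tilt_range) {
  if (!is.numeric(tilt_range) || tilt_range <= 0 || tilt_range > 90) {
    stop_septomo("tilt_range must be in (0, 90] degrees")
  }
  tilt_range / 90
}

#' Power inside the missing wedge
#'
#' Ratio of Fourier power inside the missing wedge (directions within
#' `90 - tilt_range` degrees of the kz axis in the kx-kz plane) to power
#' in the sampled region, DC excluded.  Near zero for a noise-free
#' wedge-limited reconstruction.
#'
#' @param volume A `density_volume` in the acquisition frame.
#' @param tilt_range Half-angle of the tilt range, degrees.
#' @return Non-negative ratio.
#' @export
wedge_power_ratio <- function(volume, tilt_range) {
  stopifnot(inherits(volume, "density_volume"))
  d <- dim(volume$values)
  kx <- fft_freq(d[1]); kz <- fft_freq(d[3])
  psi <- atan2(abs(rep(kz, each = d[1])), abs(rep(kx, times = d[3]))) * 180 / pi
  missing_xz <- matrix(psi > tilt_range, d[1], d[3])
  P <- Mod(fft(volume$values))^2
  P[1, 1, 1] <- 0
  in_wedge <- sampled <- 0
  for (iy in seq_len(d[2])) {
    pl <- P[, iy, ]
    in_wedge <- in_wedge + sum(pl[missing_xz])
    sampled <- sampled + sum(pl[!missing_xz])
  }
  in_wedge / sampled
}
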