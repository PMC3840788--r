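# Single-axis tilt-series simulation: specimen orientation, projection by
# linear splatting on the plane perpendicular to the tilt axis, CTF in
# Fourier space, additive Gaussian noise.
#
# Conventions: the beam runs along z at zero tilt; the tilt axis is y.
# Projections are (x, y) images; x is the in-image axis perpendicular to
# the tilt axis.

#' Tilt scheme
#'
#' @param min_angle,max_angle Tilt range in degrees (the standard scheme is
#'   -60 to +60).
#' @param step Increment in degrees.
#' @return Object of class `tilt_scheme` with the ordered angle list.
#' @export
tilt_scheme <- function(min_angle = -60, max_angle = 60, step = 2) {
  stopifnot(step > 0, max_angle > min_angle)
  angles <- seq(min_angle, max_angle, by = step)
  structure(list(angles = angles, increment = step,
                 tilt_axis = c(0, 1, 0)), class = "tilt_scheme")
}

#' Microscope optics
#'
#' @param voltage Acceleration voltage, kV.
#' @param defocus_um Underfocus, micrometres (positive).
#' @param cs_mm Spherical aberration, mm (default 2.0, typical for the
#'   instrument class).
#' @param amplitude_contrast Amplitude-contrast fraction in `[0, 1]`
#'   (default 0.07).
#' @return Object of class `optics_params`.
#' @export
optics_params <- function(voltage = 200, defocus_um = 4, cs_mm = 2.0,
                          amplitude_contrast = 0.07) {
  stopifnot(voltage > 0, defocus_um >= 0, cs_mm >= 0,
            amplitude_contrast >= 0, amplitude_contrast <= 1)
  structure(list(voltage = voltage, defocus_um = defocus_um, cs_mm = cs_mm,
                 amplitude_contrast = amplitude_contrast),
            class = "optics_params")
}

#' Relativistic electron wavelength
#'
#' `lambda = 12.2639 / sqrt(V + 0.97845e-6 V^2)` Angstrom with V in volts;
#' 0.02508 A at 200 kV.
#'
#' @param voltage Acceleration voltage, kV (> 0).
#' @return Wavelength in Angstrom.
#' @export
electron_wavelength <- function(voltage) {
  if (!is.numeric(voltage) || any(voltage <= 0)) {
    stop_septomo("voltage must be positive")
  }
  v <- voltage * 1000
  12.2639 / sqrt(v + 0.97845e-6 * v^2)
}

#' Contrast transfer function
#'
#' `CTF(k) = -(sqrt(1 - A^2) sin(gamma) + A cos(gamma))` with
#' `gamma(k) = pi lambda dz k^2 - (pi/2) Cs lambda^3 k^4`; underfocus is
#' positive and contrast is negative at low frequency (protein appears
#' dark).  Applied multiplicatively in Fourier space.
#'
#' @param k Spatial frequency (1/Angstrom), any shape.
#' @param optics An [optics_params()].
#' @return Transfer values, same shape as `k`.
#' @export
ctf <- function(k, optics) {
  stopifnot(inherits(optics, "optics_params"))
  lambda <- electron_wavelength(optics$voltage)
  dz <- optics$defocus_um * 1e4      # um -> A
  cs <- optics$cs_mm * 1e7           # mm -> A
  a <- optics$amplitude_contrast
  gamma <- pi * lambda * dz * k^2 - (pi / 2) * cs * lambda^3 * k^4
  -(sqrt(1 - a^2) * sin(gamma) + a * cos(gamma))
}

apply_ctf <- function(image, optics, pixel_size) {
  k <- freq_grid(dim(image), pixel_size)
  h <- ctf(k, optics)
  apply_fourier_filter(image, h)
}

#' Geometry modes
#'
#' How the specimen's long (filament) axis is oriented relative to the
#' beam (z) and tilt axis (y) at zero tilt.
#'
#' @return Character vector of valid mode names.
#' @export
geometry_modes <- function() {
  c("long_axis_parallel_to_beam", "parallel_to_tilt_axis",
    "perpendicular_to_tilt_axis")
}

#' Orient a volume for a given acquisition geometry
#'
#' Phantoms are built with the filament axis along y (the tilt axis);
#' `orient_volume` permutes axes so that the axis lies along the beam (z),
#' along the tilt axis (identity), or perpendicular to it (x).
#' `unorient_volume` applies the inverse permutation (all three modes are
#' involutions).
#'
#' @param volume A `density_volume`.
#' @param geometry One of [geometry_modes()].
#' @return A `density_volume` in the acquisition frame.
#' @export
orient_volume <- function(volume, geometry) {
  geometry <- match.arg(geometry, geometry_modes())
  perm <- switch(geometry,
    parallel_to_tilt_axis = c(1L, 2L, 3L),
    long_axis_parallel_to_beam = c(1L, 3L, 2L),
    perpendicular_to_tilt_axis = c(2L, 1L, 3L))
  out <- volume
  out$values <- aperm(volume$values, perm)
  out
}

#' @rdname orient_volume
#' @export
unorient_volume <- function(volume, geometry) orient_volume(volume, geometry)

# Sparse projection operator for one tilt angle on the (x, z) plane:
# rows are output x bins, columns are (x, z) voxels in column-major order.
# Linear splatting; the transpose is exactly linear-interpolating
# back-projection, so forward and adjoint are consistent.
proj_matrix <- function(nx, nz, angle_deg) {
  th <- angle_deg * pi / 180
  cx <- (nx + 1) / 2; cz <- (nz + 1) / 2
  ix <- rep(seq_len(nx), times = nz)
  iz <- rep(seq_len(nz), each = nx)
  xp <- cx + cos(th) * (ix - cx) + sin(th) * (iz - cz)
  i0 <- floor(xp)
  w1 <- 1 - (xp - i0)
  cols <- c(seq_along(ix), seq_along(ix))
  rows <- c(i0, i0 + 1)
  wts <- c(w1, 1 - w1)
  ok <- rows >= 1 & rows <= nx
  Matrix::sparseMatrix(i = rows[ok], j = cols[ok], x = wts[ok],
                       dims = c(nx, nx * nz))
}

#' Project a volume at a tilt angle
#'
#' Line integral along the beam after rotating the volume about the tilt
#' axis (y).  The rotation/integration is performed by linear splatting in
#' the (x, z) plane (y is invariant), so mass is conserved exactly at 0
#' degrees and projection is linear in the volume.
#'
#' @param volume A `density_volume` already in the acquisition frame (see
#'   [orient_volume()]), or combined with `geometry` to orient first.
#' @param angle Tilt angle in degrees, |angle| <= 90.
#' @param geometry Optional [geometry_modes()] value applied before
#'   projecting.
#' @return Numeric `(nx, ny)` matrix with `pixel_size` attribute; values
#'   are line integrals (density times length).
#' @export
project <- function(volume, angle, geometry = NULL) {
  stopifnot(inherits(volume, "density_volume"))
  if (abs(angle) > 90) stop_septomo("|angle| must be <= 90 degrees")
  if (!is.null(geometry)) volume <- orient_volume(volume, geometry)
  d <- dim(volume$values)
  A <- proj_matrix(d[1], d[3], angle)
  vxz_y <- matrix(aperm(volume$values, c(1L, 3L, 2L)), d[1] * d[3], d[2])
  img <- as.matrix(A %*% vxz_y) * volume$voxel_size
  attr(img, "pixel_size") <- volume$voxel_size
  img
}

#' Add Gaussian noise at a target SNR
#'
#' Zero-mean additive Gaussian noise with variance equal to the image's
#' sample variance divided by `snr`.
#'
#' @param image Numeric matrix.
#' @param snr Signal-to-noise ratio (> 0; `Inf` returns the input).
#' @param seed Integer seed.
#' @return Noisy matrix, same attributes.
#' @export
add_noise <- function(image, snr, seed = 1L) {
  if (!is.numeric(snr) || length(snr) != 1L || !(snr > 0)) {
    stop_septomo("snr must be positive (or Inf)")
  }
  if (!is.finite(snr)) return(image)
  nsd <- sqrt(stats::var(as.vector(image)) / snr)
  out <- image + with_seed(seed, matrix(rnorm(length(image), sd = nsd),
                                        nrow(image), ncol(image)))
  attributes(out) <- attributes(image)
  out
}

#' Tilt series container
#'
#' @param images Array `[x, y, angle]` of projections.
#' @param angles Tilt angles, degrees.
#' @param geometry One of [geometry_modes()].
#' @param optics [optics_params()] used, or `NULL` if no CTF was applied.
#' @param snr Noise level used (`Inf` = none).
#' @param seed Seed used for the noise.
#' @param pixel_size Pixel size, Angstrom.
#' @return Object of class `tilt_series`.
#' @export
tilt_series <- function(images, angles, geometry, optics = NULL, snr = Inf,
                        seed = NA_integer_, pixel_size = 7.3) {
  stopifnot(is.array(images), length(dim(images)) == 3L,
            dim(images)[3] == length(angles))
  structure(list(images = images, angles = angles, geometry = geometry,
                 optics = optics, snr = snr, seed = seed,
                 pixel_size = pixel_size), class = "tilt_series")
}

#' @export
print.tilt_series <- function(x, ...) {
  cat(sprintf("<tilt_series> %d projections (%d x %d px @ %.2f A), %g..%g deg, %s\n",
              length(x$angles), dim(x$images)[1], dim(x$images)[2],
              x$pixel_size, min(x$angles), max(x$angles), x$geometry))
  invisible(x)
}

#' @export
length.tilt_series <- function(x) length(x$angles)

#' Simulate a tilt series
#'
#' One projection per scheme angle: the volume is oriented for the
#' requested geometry, projected, optionally multiplied by the CTF in
#' Fourier space, and optionally degraded with additive Gaussian noise.
#' The full parameter set is embedded as metadata, and the same arguments
#' always reproduce the same stack.
#'
#' @param volume A `density_volume` in the phantom frame (filament axis
#'   along y).
#' @param scheme A [tilt_scheme()].
#' @param geometry One of [geometry_modes()].
#' @param optics An [optics_params()], or `NULL` to skip the CTF.
#' @param snr Per-image SNR for additive noise (`Inf` = noise free).
#' @param seed Integer seed for the noise.
#' @return A [tilt_series()].
#' @export
simulate_tilt_series <- function(volume, scheme = tilt_scheme(),
                                 geometry = "long_axis_parallel_to_beam",
                                 optics = NULL, snr = Inf, seed = 1L) {
  stopifnot(inherits(volume, "density_volume"), inherits(scheme, "tilt_scheme"))
  geometry <- match.arg(geometry, geometry_modes())
  vol <- orient_volume(volume, geometry)
  d <- dim(vol$values)
  n <- length(scheme$angles)
  images <- array(0, c(d[1], d[2], n))
  with_seed(seed, {
    for (i in seq_len(n)) {
      img <- project(vol, scheme$angles[i])
      if (!is.null(optics)) img <- apply_ctf(img, optics, vol$voxel_size)
      if (is.finite(snr)) {
        nsd <- sqrt(stats::var(as.vector(img)) / snr)
        img <- img + matrix(rnorm(length(img), sd = nsd), d[1], d[2])
      }
      images[, , i] <- img
    }
  })
  tilt_series(images, scheme$angles, geometry, optics, snr,
              as.integer(seed), vol$voxel_size)
}
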