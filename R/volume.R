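#' Grid parameters for a density volume
#'
#' @param shape Integer triple `(nx, ny, nz)` in voxels (each >= 8).
#' @param voxel_size Voxel edge length in Angstrom (> 0).  The default
#'   7.3 A matches 4x4-binned tomographic pixels.
#' @param origin Physical coordinate of the grid center, Angstrom.
#' @return Object of class `grid_params`.
#' @export
grid_params <- function(shape = c(128L, 128L, 128L), voxel_size = 7.3,
                        origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 8L), voxel_size > 0,
            length(origin) == 3L)
  structure(list(shape = shape, voxel_size = voxel_size, origin = origin),
            class = "grid_params")
}

#' 3D density volume
#'
#' A scalar field on a regular grid with physical voxel size.  The array is
#' indexed `[x, y, z]`.
#'
#' @param values 3D numeric array.
#' @param voxel_size Voxel edge length, Angstrom.
#' @param origin Physical coordinate of the grid center, Angstrom.
#' @return Object of class `density_volume`.
#' @export
density_volume <- function(values, voxel_size = 7.3, origin = c(0, 0, 0)) {
  stopifnot(is.array(values), length(dim(values)) == 3L, voxel_size > 0)
  if (!all(is.finite(values))) stop_septomo("volume values must be finite")
  structure(list(values = values, voxel_size = voxel_size, origin = origin),
            class = "density_volume")
}

#' @export
print.density_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<density_volume> %d x %d x %d voxels @ %.3f A (%.1f nm box)\n",
              d[1], d[2], d[3], x$voxel_size, d[1] * x$voxel_size / 10))
  invisible(x)
}

#' @export
dim.density_volume <- function(x) dim(x$values)

same_grid <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$voxel_size, b$voxel_size))
}

# Radial frequency magnitude grid (cycles/Angstrom) for an array of the
# given dimensions, in fft layout.
freq_grid <- function(dims, voxel_size) {
  ks <- lapply(dims, fft_freq, d = voxel_size)
  if (length(dims) == 2L) {
    sqrt(outer(ks[[1]]^2, ks[[2]]^2, `+`))
  } else {
    k2 <- outer(ks[[1]]^2, ks[[2]]^2, `+`)
    k <- array(0, dims)
    for (iz in seq_len(dims[3])) k[, , iz] <- k2 + ks[[3]][iz]^2
    sqrt(k)
  }
}

apply_fourier_filter <- function(values, filter) {
  n <- length(values)
  Re(fft(fft(values) * filter, inverse = TRUE)) / n
}

#' Gaussian low-pass filter
#'
#' Attenuates Fourier amplitudes with a Gaussian reaching half amplitude at
#' the cutoff frequency `1/resolution`; the mean (DC) value is preserved.
#' Works on a `density_volume` or on a 2D image matrix (pass `pixel_size`
#' for matrices).
#'
#' @param x A `density_volume` or numeric matrix.
#' @param resolution Target resolution in Angstrom; must exceed twice the
#'   voxel/pixel size (Nyquist).
#' @param pixel_size Pixel size in Angstrom for matrix input.
#' @return Same type as `x`.
#' @export
low_pass <- function(x, resolution, pixel_size = NULL) {
  if (inherits(x, "density_volume")) {
    check_nyquist(resolution, x$voxel_size)
    k <- freq_grid(dim(x$values), x$voxel_size)
    h <- exp(-log(2) * (k * resolution)^2)
    out <- x
    out$values <- apply_fourier_filter(x$values, h)
    out
  } else if (is.matrix(x)) {
    ps <- pixel_size %||% attr(x, "pixel_size")
    if (is.null(ps)) stop_septomo("pixel_size required for matrix input")
    check_nyquist(resolution, ps)
    k <- freq_grid(dim(x), ps)
    h <- exp(-log(2) * (k * resolution)^2)
    out <- apply_fourier_filter(x, h)
    attributes(out) <- attributes(x)
    out
  } else {
    stop_septomo("low_pass expects a density_volume or a matrix")
  }
}

check_nyquist <- function(resolution, voxel_size) {
  if (!is.numeric(resolution) || resolution <= 2 * voxel_size) {
    stop_septomo("resolution must exceed twice the voxel size (",
                 2 * voxel_size, " A)")
  }
}

#' Bin an image by block averaging
#'
#' Non-overlapping `factor x factor` block means, as applied to raw
#' micrographs (e.g. 4x4 binning of 1.825 A pixels gives 7.3 A pixels).
#' Dimensions must be divisible by the factor; the global mean is preserved
#' exactly.
#'
#' @param image Numeric matrix, optionally with a `pixel_size` attribute.
#' @param factor Integer >= 1 dividing both dimensions.
#' @return Binned matrix; `pixel_size` attribute multiplied by `factor`.
#' @export
bin_image <- function(image, factor) {
  stopifnot(is.matrix(image))
  factor <- as.integer(factor)
  if (factor < 1) stop_septomo("factor must be >= 1")
  d <- dim(image)
  if (any(d %% factor != 0)) {
    stop_septomo("image dimensions (", d[1], " x ", d[2],
                 ") are not divisible by factor ", factor)
  }
  if (factor == 1L) return(image)
  ps <- attr(image, "pixel_size")
  nx <- d[1] %/% factor; ny <- d[2] %/% factor
  dim(image) <- c(factor, nx, factor, ny)
  out <- apply(image, c(2, 4), mean)
  if (!is.null(ps)) attr(out, "pixel_size") <- ps * factor
  out
}
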