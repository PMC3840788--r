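# File I/O: MRC volumes/stacks, IMOD-style .tlt angle files, lattice
# tables, and YAML parameter blocks.
#
# The MRC reader/writer below covers the subset of the MRC2014 standard
# this package produces: mode 2 (float32) volumes and image stacks,
# little-endian, no extended header.

#' Write a volume or image stack as an MRC file
#'
#' @param x A `density_volume`, a 3D array (image stack: `[x, y, image]`)
#'   or a 2D matrix.
#' @param path Output path.
#' @param voxel_size Voxel/pixel size in Angstrom (taken from a
#'   `density_volume` automatically).
#' @param is_stack Mark the file as an image stack (ispg = 0) rather than a
#'   volume (ispg = 1).
#' @return `path`, invisibly.
#' @export
write_mrc <- function(x, path, voxel_size = NULL, is_stack = FALSE) {
  if (inherits(x, "density_volume")) {
    voxel_size <- voxel_size %||% x$voxel_size
    values <- x$values
  } else {
    values <- x
  }
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  stopifnot(is.array(values), length(dim(values)) == 3L)
  if (is.null(voxel_size)) voxel_size <- 1
  d <- dim(values)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(v) writeBin(as.integer(v), con, size = 4L, endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4L, endian = "little")
  wi(d)                       # nx ny nz
  wi(2L)                      # mode 2 = float32
  wi(c(0L, 0L, 0L))           # nxstart
  wi(d)                       # mx my mz
  wf(d * voxel_size)          # cella
  wf(c(90, 90, 90))           # cellb
  wi(c(1L, 2L, 3L))           # mapc mapr maps
  wf(c(min(values), max(values), mean(values)))
  wi(if (is_stack) 0L else 1L)  # ispg
  wi(0L)                      # nsymbt
  wi(integer(25L))            # extra
  wf(c(0, 0, 0))              # origin
  writeChar("MAP ", con, nchars = 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(sd(values))              # rms
  wi(1L)                      # nlabl
  lab <- formatC("Created by septomo", width = -80)
  writeChar(lab, con, nchars = 80L, eos = NULL)
  writeBin(raw(800L - 80L), con)
  writeBin(as.numeric(values), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read an MRC file
#'
#' Supports modes 0 (int8), 1 (int16) and 2 (float32), little-endian.
#'
#' @param path Input path.
#' @return A `density_volume`; for stacks the third array dimension indexes
#'   images and attribute `is_stack` is `TRUE`.
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n = n, size = 4L, endian = "little")
  rf <- function(n) readBin(con, "numeric", n = n, size = 4L, endian = "little")
  d <- ri(3)
  mode <- ri(1)
  ri(3)                       # nxstart
  m <- ri(3)
  cella <- rf(3)
  rf(3)                       # cellb
  ri(3)                       # mapc mapr maps
  rf(3)                       # dmin dmax dmean
  ispg <- ri(1)
  nsymbt <- ri(1)
  seek(con, 1024 + nsymbt)
  n <- prod(d)
  values <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = n, size = 1L, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n = n, size = 2L,
                             endian = "little")),
    "2" = readBin(con, "numeric", n = n, size = 4L, endian = "little"),
    stop_septomo("unsupported MRC mode: ", mode))
  voxel <- if (m[1] > 0 && cella[1] > 0) cella[1] / m[1] else 1
  vol <- density_volume(array(values, d), voxel_size = voxel)
  attr(vol, "is_stack") <- identical(ispg, 0L)
  vol
}

#' Write / read a plain-text tilt angle file (one angle per line)
#'
#' @param angles Numeric vector of tilt angles in degrees.
#' @param path File path.
#' @return `path` (write) or numeric vector (read).
#' @export
write_tlt <- function(angles, path) {
  writeLines(formatC(angles, format = "f", digits = 2), path)
  invisible(path)
}

#' @rdname write_tlt
#' @export
read_tlt <- function(path) as.numeric(readLines(path))

#' Serialize a lattice to a tab-separated table
#'
#' One subunit per row: filament, axial index, kind, x/y/z in nm, and the
#' bridge-bound flag.
#'
#' @param lattice A `septin_lattice`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lattice_table <- function(lattice, path) {
  stopifnot(inherits(lattice, "septin_lattice"))
  write.table(lattice$subunits, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_lattice_table
#' @export
read_lattice_table <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write / read a lattice specification as YAML
#'
#' @param spec A [lattice_spec()].
#' @param path File path.
#' @return `path` (write) or a `lattice_spec` (read).
#' @export
write_lattice_spec <- function(spec, path) {
  stopifnot(inherits(spec, "lattice_spec"))
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_lattice_spec
#' @export
read_lattice_spec <- function(path) {
  vals <- yaml::read_yaml(path)
  vals$bridge_period <- vals$bridge_period %||% NA
  vals$bridge_span <- vals$bridge_span %||% NA
  vals$bridge_mass_scale <- vals$bridge_mass_scale %||% NA
  do.call(lattice_spec, vals)
}

#' Write a tilt series: MRC stack, .tlt angle file, YAML metadata
#'
#' @param ts A `tilt_series`.
#' @param basename Path prefix; writes `<basename>.mrc`, `<basename>.tlt`
#'   and `<basename>.yaml`.
#' @return `basename`, invisibly.
#' @export
write_tilt_series <- function(ts, basename) {
  stopifnot(inherits(ts, "tilt_series"))
  write_mrc(ts$images, paste0(basename, ".mrc"),
            voxel_size = ts$pixel_size, is_stack = TRUE)
  write_tlt(ts$angles, paste0(basename, ".tlt"))
  meta <- list(geometry = ts$geometry, snr = ts$snr, seed = ts$seed,
               pixel_size = ts$pixel_size,
               optics = if (is.null(ts$optics)) NULL else unclass(ts$optics))
  yaml::write_yaml(meta, paste0(basename, ".yaml"))
  invisible(basename)
}

#' @rdname write_tilt_series
#' @export
read_tilt_series <- function(basename) {
  vol <- read_mrc(paste0(basename, ".mrc"))
  angles <- read_tlt(paste0(basename, ".tlt"))
  meta <- yaml::read_yaml(paste0(basename, ".yaml"))
  optics <- if (!is.null(meta$optics)) do.call(optics_params, meta$optics)
  tilt_series(images = vol$values, angles = angles,
              geometry = meta$geometry, optics = optics,
              snr = meta$snr %||% Inf, seed = meta$seed,
              pixel_size = meta$pixel_size %||% vol$voxel_size)
}
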