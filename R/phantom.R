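# Phantom rendering: septin lattices -> Gaussian-blob density volumes and
# projections, plus labelled 2D particle mixtures.  Blobs stand in for
# fitted crystal structures; everything downstream is filtered to >= 45 A,
# where the difference is immaterial.

# Integrated mass of one cross-bridge in septin-subunit units, before the
# variant mass scale: a bridge contains up to 12 Gic1 dimers and a 49 kDa
# Gic1 dimer weighs about as much as one septin subunit.
BRIDGE_BASE_MASS <- 12

default_subunit_sigma <- function(subunit_diameter_nm) {
  # FWHM of the blob ~ subunit diameter
  subunit_diameter_nm * 10 / (2 * sqrt(2 * log(2)))
}

# Per-source Gaussian splat onto the grid using separable 1d profiles on a
# +/- 5 sigma support box.  `values` are densities (mass / A^3), so
# sum(values) * voxel^3 equals the total mass.
splat_gauss3 <- function(vol, center, sigma, mass, voxel, axes_coords) {
  idx <- vector("list", 3L)
  prof <- vector("list", 3L)
  for (a in 1:3) {
    co <- axes_coords[[a]]
    lo <- center[a] - 5 * sigma[a]; hi <- center[a] + 5 * sigma[a]
    sel <- which(co >= lo & co <= hi)
    if (length(sel) == 0) return(vol)
    idx[[a]] <- sel
    prof[[a]] <- exp(-((co[sel] - center[a])^2) / (2 * sigma[a]^2)) /
      (sigma[a] * sqrt(2 * pi))
  }
  add <- mass * outer(outer(prof[[1]], prof[[2]]), prof[[3]])
  vol[idx[[1]], idx[[2]], idx[[3]]] <-
    vol[idx[[1]], idx[[2]], idx[[3]]] + add
  vol
}

# Gaussian sources (center A, sigma A per axis, mass) for a lattice.
# Subunits get isotropic unit-mass blobs; each bridge contributes one
# anisotropic blob per adjacent filament pair, its axial (y) width set by
# the bridge span, its x width filling the surface-to-surface gap between
# filaments, and its z width given by bridge_sigma.
lattice_sources <- function(lattice, subunit_sigma, bridge_sigma) {
  spec <- lattice$spec
  if (is.null(subunit_sigma)) {
    subunit_sigma <- default_subunit_sigma(spec$subunit_diameter)
  }
  s <- lattice$subunits
  src_c <- cbind(s$x, s$y, s$z) * 10          # nm -> A
  src_sig <- matrix(subunit_sigma, nrow(s), 3)
  src_m <- rep(1, nrow(s))
  fwhm <- 2 * sqrt(2 * log(2))
  for (b in lattice$bridges) {
    fils <- sort(unique(lattice$subunits$filament[b$contacts]))
    if (length(fils) < 2) next
    npairs <- length(fils) - 1
    sig_y <- b$span * spec$subunit_diameter * 10 / fwhm
    gap_x <- (spec$inter_filament_spacing - spec$subunit_diameter) * 10
    sig_x <- max(gap_x / fwhm, subunit_sigma)
    sig_z <- if (is.null(bridge_sigma)) 60 else bridge_sigma
    for (p in seq_len(npairs)) {
      f1 <- fils[p]; f2 <- fils[p + 1]
      x1 <- s$x[match(f1, s$filament)]; x2 <- s$x[match(f2, s$filament)]
      z1 <- mean(s$z[s$filament == f1 & abs(s$y - b$y) < 2 * spec$subunit_diameter])
      if (!is.finite(z1)) z1 <- 0
      src_c <- rbind(src_c, c((x1 + x2) / 2 * 10, b$y * 10, z1 * 10))
      src_sig <- rbind(src_sig, c(sig_x, sig_y, sig_z))
      src_m <- c(src_m, BRIDGE_BASE_MASS * b$mass_scale / npairs)
    }
  }
  list(centers = src_c, sigmas = src_sig, masses = src_m)
}

grid_axis_coords <- function(grid) {
  lapply(1:3, function(a) {
    n <- grid$shape[a]
    (seq_len(n) - (n + 1) / 2) * grid$voxel_size + grid$origin[a]
  })
}

#' Render a lattice into a 3D density volume
#'
#' Each subunit contributes an isotropic Gaussian of unit integrated mass;
#' each cross-bridge contributes anisotropic Gaussians of total mass
#' `12 * mass_scale` subunit-equivalents (up to 12 Gic1 dimers of ~49 kDa
#' each, about one septin subunit apiece).  The volume integral
#' (`sum * voxel^3`) equals the summed source masses.
#'
#' @param lattice A [build_lattice()] result.
#' @param grid A [grid_params()].
#' @param subunit_sigma Subunit blob sigma in Angstrom; default gives a
#'   full width at half maximum equal to the subunit diameter.
#' @param bridge_sigma Bridge blob sigma along the beam-free (z) axis,
#'   Angstrom; default 60 A (FWHM ~ 14 nm, the size of the chaperonin
#'   complex used as the bridge stand-in).
#' @return A [density_volume()].
#' @export
render_volume <- function(lattice, grid, subunit_sigma = NULL,
                          bridge_sigma = NULL) {
  stopifnot(inherits(lattice, "septin_lattice"), inherits(grid, "grid_params"))
  vol <- array(0, grid$shape)
  if (nrow(lattice$subunits) == 0) {
    return(density_volume(vol, grid$voxel_size, grid$origin))
  }
  src <- lattice_sources(lattice, subunit_sigma, bridge_sigma)
  co <- grid_axis_coords(grid)
  half <- grid$shape * grid$voxel_size / 2
  ext <- apply(abs(sweep(src$centers, 2, grid$origin)), 2, max)
  if (any(ext > half)) {
    stop_septomo("lattice extent (", paste(round(ext), collapse = ", "),
                 " A) exceeds grid half-extent (",
                 paste(round(half), collapse = ", "), " A)")
  }
  for (i in seq_len(nrow(src$centers))) {
    vol <- splat_gauss3(vol, src$centers[i, ], src$sigmas[i, ],
                        src$masses[i], grid$voxel_size, co)
  }
  density_volume(vol, grid$voxel_size, grid$origin)
}

#' Render a noise-free 2D projection of a lattice
#'
#' Closed-form line-integral projection of the Gaussian-blob model: `side`
#' integrates along z and shows the railroad pattern in the (x, y) plane;
#' `top` integrates along the filament axis (y) and shows filament
#' cross-sections in the (x, z) plane.  `sum(image) * pixel^2` equals the
#' total source mass, matching the 3D render.
#'
#' @inheritParams render_volume
#' @param view `"side"` or `"top"`.
#' @return Numeric matrix with a `pixel_size` attribute (Angstrom).
#' @export
render_projection <- function(lattice, grid, view = c("side", "top"),
                              subunit_sigma = NULL, bridge_sigma = NULL) {
  view <- match.arg(view)
  stopifnot(inherits(lattice, "septin_lattice"), inherits(grid, "grid_params"))
  axes <- if (view == "side") c(1L, 2L) else c(1L, 3L)
  co <- grid_axis_coords(grid)
  img <- matrix(0, grid$shape[axes[1]], grid$shape[axes[2]])
  if (nrow(lattice$subunits) > 0) {
    src <- lattice_sources(lattice, subunit_sigma, bridge_sigma)
    for (i in seq_len(nrow(src$centers))) {
      g1 <- exp(-((co[[axes[1]]] - src$centers[i, axes[1]])^2) /
                  (2 * src$sigmas[i, axes[1]]^2)) /
        (src$sigmas[i, axes[1]] * sqrt(2 * pi))
      g2 <- exp(-((co[[axes[2]]] - src$centers[i, axes[2]])^2) /
                  (2 * src$sigmas[i, axes[2]]^2)) /
        (src$sigmas[i, axes[2]] * sqrt(2 * pi))
      img <- img + src$masses[i] * outer(g1, g2)
    }
  }
  attr(img, "pixel_size") <- grid$voxel_size
  img
}

#' Generate a labelled 2D particle mixture
#'
#' Draws `n` independent particles emulating the products of Cdc42-GDP
#' driven filament dissociation: Cdc10-capped octamer rods carrying a
#' terminal Cdc42-GDP blob at both ends, or Cdc10-less hexamer rods
#' without extra density.  Each rod is rotated in-plane by a uniform random
#' angle and additive Gaussian noise is applied at the requested SNR
#' (signal variance / noise variance).  Labels are the generation-time
#' ground truth.
#'
#' @param n Number of particles (>= 1).
#' @param fraction_octamer Bernoulli probability of the capped-octamer
#'   class, in `[0, 1]`.
#' @param snr Signal-to-noise ratio (`Inf` = noise free).
#' @param seed Integer seed; the same arguments always reproduce the set.
#' @param image_size Image side length, pixels.
#' @param pixel_size Pixel size, Angstrom.
#' @param subunit_diameter Axial subunit spacing, nm.
#' @return Object of class `particle_set`: `images` (array
#'   `[x, y, particle]`), `labels` (`"octamer_capped"` / `"hexamer"`),
#'   `pixel_size`, `snr`, `seed`.
#' @export
generate_particle_mixture <- function(n, fraction_octamer, snr = Inf,
                                      seed = 1L, image_size = 64L,
                                      pixel_size = 7.3,
                                      subunit_diameter = 4) {
  if (n < 1) stop_septomo("n must be >= 1")
  if (!is.numeric(fraction_octamer) || fraction_octamer < 0 ||
      fraction_octamer > 1) {
    stop_septomo("fraction_octamer must be in [0, 1]")
  }
  if (!(snr > 0)) stop_septomo("snr must be positive (or Inf)")
  d <- subunit_diameter * 10                      # A
  sig <- default_subunit_sigma(subunit_diameter)
  cap_sig <- 0.8 * sig
  cap_mass <- 0.5                                 # Cdc42 ~ half a septin
  nx <- as.integer(image_size)
  co <- (seq_len(nx) - (nx + 1) / 2) * pixel_size
  oct_len <- length(protomer_order("CDC42GDP_OCTAMER"))
  hex_len <- length(protomer_order("HEXAMER_NO_CDC10"))

  with_seed(seed, {
    labels <- ifelse(runif(n) < fraction_octamer, "octamer_capped", "hexamer")
    images <- array(0, c(nx, nx, n))
    for (p in seq_len(n)) {
      if (labels[p] == "octamer_capped") {
        pos <- (seq_len(oct_len) - (oct_len + 1) / 2) * d
        masses <- rep(1, oct_len)
        sigs <- rep(sig, oct_len)
        cap_at <- (oct_len / 2 + 0.5) * d
        pos <- c(pos, -cap_at, cap_at)
        masses <- c(masses, cap_mass, cap_mass)
        sigs <- c(sigs, cap_sig, cap_sig)
      } else {
        pos <- (seq_len(hex_len) - (hex_len + 1) / 2) * d
        masses <- rep(1, hex_len)
        sigs <- rep(sig, hex_len)
      }
      phi <- runif(1, 0, pi)
      cx <- pos * cos(phi); cy <- pos * sin(phi)
      img <- matrix(0, nx, nx)
      for (b in seq_along(pos)) {
        g1 <- exp(-((co - cx[b])^2) / (2 * sigs[b]^2))
        g2 <- exp(-((co - cy[b])^2) / (2 * sigs[b]^2))
        img <- img + masses[b] / (2 * pi * sigs[b]^2) * outer(g1, g2)
      }
      if (is.finite(snr)) {
        nsd <- sqrt(stats::var(as.vector(img)) / snr)
        img <- img + matrix(rnorm(nx * nx, sd = nsd), nx, nx)
      }
      images[, , p] <- img
    }
    structure(list(images = images, labels = labels, pixel_size = pixel_size,
                   snr = snr, seed = as.integer(seed)),
              class = "particle_set")
  })
}

#' @export
print.particle_set <- function(x, ...) {
  cat(sprintf("<particle_set> %d particles (%d x %d px @ %.2f A), %.1f%% capped octamers\n",
              dim(x$images)[3], dim(x$images)[1], dim(x$images)[2],
              x$pixel_size, 100 * mean(x$labels == "octamer_capped")))
  invisible(x)
}
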