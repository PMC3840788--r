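# Quantification suite: volume similarity, missing-wedge elongation,
# lattice measurements, particle classification, mask-based extraction.

#' Pearson cross-correlation of two volumes
#'
#' @param a,b `density_volume`s on identical grids.
#' @param mask Optional `segmentation_mask`; correlation is computed over
#'   mask voxels only.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
cross_correlation <- function(a, b, mask = NULL) {
  stopifnot(inherits(a, "density_volume"), inherits(b, "density_volume"))
  if (!same_grid(a, b)) stop_septomo("volumes are on different grids")
  va <- as.vector(a$values); vb <- as.vector(b$values)
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "segmentation_mask"))
    if (!identical(dim(mask$values), dim(a$values))) {
      stop_septomo("mask grid does not match volumes")
    }
    keep <- as.vector(mask$values) > 0
    if (!any(keep)) stop_septomo("mask is empty (all zero)")
    va <- va[keep]; vb <- vb[keep]
  }
  stats::cor(va, vb)
}

# Linear-interpolated extent of the contiguous above-threshold run of a 1d
# profile containing index `center`.
threshold_extent <- function(p, center, thr) {
  n <- length(p)
  if (p[center] < thr) {
    # walk to the nearest above-threshold sample (profile max may sit a
    # voxel away from the nominal center)
    near <- which(p >= thr)
    if (length(near) == 0) stop_septomo("empty component at threshold")
    center <- near[which.min(abs(near - center))]
  }
  lo <- center
  while (lo > 1 && p[lo - 1] >= thr) lo <- lo - 1
  hi <- center
  while (hi < n && p[hi + 1] >= thr) hi <- hi + 1
  left <- if (lo > 1) (lo - 1) + (thr - p[lo - 1]) / (p[lo] - p[lo - 1]) else 1
  right <- if (hi < n) hi + (p[hi] - thr) / (p[hi] - p[hi + 1]) else n
  right - left
}

#' Elongation along the beam axis
#'
#' Measures the z extent ("diameter along z") of a density component at
#' `threshold_frac` of its local maximum in both the reconstruction and
#' the model, on the z profile through `component_center` (averaged over a
#' small transverse window), and returns the percent increase.  Both
#' volumes must be in the acquisition frame (z = beam).
#'
#' @param recon,model `density_volume`s on the same grid.
#' @param component_center Integer voxel triple `(ix, iy, iz)` inside the
#'   component (e.g. a cross-bridge center).
#' @param threshold_frac Fraction of the component maximum defining the
#'   extent, in `(0, 1)`; 0.5 gives a FWHM-like diameter.
#' @param window Transverse half-width (voxels) of the profile average.
#' @return Percent increase `100 * (extent_recon / extent_model - 1)`.
#' @export
z_elongation <- function(recon, model, component_center,
                         threshold_frac = 0.5, window = 2L) {
  stopifnot(inherits(recon, "density_volume"), inherits(model, "density_volume"))
  if (!same_grid(recon, model)) stop_septomo("volumes are on different grids")
  if (threshold_frac <= 0 || threshold_frac >= 1) {
    stop_septomo("threshold_frac must be in (0, 1)")
  }
  d <- dim(model$values)
  cc <- as.integer(round(component_center))
  if (any(cc < 1) || any(cc > d)) stop_septomo("component_center outside grid")
  zprof <- function(v) {
    xs <- max(1, cc[1] - window):min(d[1], cc[1] + window)
    ys <- max(1, cc[2] - window):min(d[2], cc[2] + window)
    apply(v$values[xs, ys, , drop = FALSE], 3, mean)
  }
  extent_at <- function(p) {
    # local maximum of the component: highest profile value within a
    # quarter-box of the center (avoids picking up neighbouring features)
    zwin <- max(1, cc[3] - d[3] %/% 8):min(d[3], cc[3] + d[3] %/% 8)
    pk <- max(p[zwin])
    if (pk <= 0) stop_septomo("empty component at threshold")
    threshold_extent(p, cc[3], threshold_frac * pk)
  }
  e_model <- extent_at(zprof(model))
  e_recon <- extent_at(zprof(recon))
  100 * (e_recon / e_model - 1)
}

#' Inter-filament spacing from a density map
#'
#' Averages the density along the filament axis (and, for volumes, along
#' the beam axis) to a 1d transverse profile, locates filament peaks with
#' parabolic sub-pixel interpolation, and returns the mean center-to-center
#' distance of adjacent peaks in nanometres.
#'
#' @param density A `density_volume` or a 2D matrix with `pixel_size`.
#' @param filament_axis Axis index the filaments run along (default 2 = y
#'   in the phantom frame; use 3 for beam-parallel reconstructions).
#' @param min_frac Peaks below `min_frac * max(profile)` are ignored.
#' @return Spacing in nm.
#' @export
interfilament_spacing <- function(density, filament_axis = 2L,
                                  min_frac = 0.5) {
  if (inherits(density, "density_volume")) {
    d <- dim(density$values)
    trans <- setdiff(1:3, filament_axis)[1]   # filaments separate along x
    prof <- apply(density$values, trans, mean)
    step <- density$voxel_size
  } else if (is.matrix(density)) {
    prof <- rowMeans(density)
    step <- attr(density, "pixel_size") %||% 1
  } else {
    stop_septomo("density must be a density_volume or a matrix")
  }
  pk <- find_peaks_1d(prof, min_frac = min_frac, min_separation = 2)
  if (nrow(pk) < 2) stop_septomo("fewer than 2 filament peaks detected")
  mean(diff(pk$pos)) * step / 10
}

#' Count free subunits between cross-bridges in a side view
#'
#' Detects cross-bridges on the mid-line between filaments (bridges span
#' the inter-filament gap; subunits do not), excises each bridge's axial
#' full width at half maximum, and counts subunit peaks on the filament
#' profiles strictly between consecutive bridges.  Returns the modal count
#' over all filament/interval combinations.
#'
#' @param side_view 2D matrix (x = transverse, y = filament axis) with a
#'   `pixel_size` attribute, e.g. from [render_projection()].
#' @param subunit_spacing_px Axial subunit spacing in pixels.
#' @return Integer modal gap count.
#' @export
count_gap_subunits <- function(side_view, subunit_spacing_px) {
  stopifnot(is.matrix(side_view), subunit_spacing_px > 0)
  trans <- rowMeans(side_view)
  fil <- find_peaks_1d(trans, min_frac = 0.5, min_separation = 2)
  if (nrow(fil) < 2) stop_septomo("fewer than 2 filaments detected")
  band <- function(x0, hw) {
    rows <- max(1, round(x0 - hw)):min(nrow(side_view), round(x0 + hw))
    colMeans(side_view[rows, , drop = FALSE])
  }
  # bridge profile: mid-lines between adjacent filaments, averaged
  mids <- (head(fil$pos, -1) + tail(fil$pos, -1)) / 2
  bprof <- Reduce(`+`, lapply(mids, band, hw = 1)) / length(mids)
  bpk <- find_peaks_1d(bprof, min_frac = 0.5,
                       min_separation = 2 * subunit_spacing_px)
  if (nrow(bpk) < 2) stop_septomo("no cross-bridges detected")
  # per-bridge FWHM on the mid-line profile -> exclusion half-width
  half_widths <- vapply(seq_len(nrow(bpk)), function(i) {
    threshold_extent(bprof, round(bpk$pos[i]), 0.5 * bpk$value[i]) / 2
  }, numeric(1))
  counts <- integer(0)
  for (f in seq_len(nrow(fil))) {
    fprof <- band(fil$pos[f], hw = 1)
    # remove the broad bridge-dome baseline so subunit bumps riding its
    # slopes remain local maxima
    kw <- max(3L, round(2 * subunit_spacing_px))
    base <- stats::filter(fprof, rep(1 / kw, kw), sides = 2)
    base[is.na(base)] <- fprof[is.na(base)]
    det <- fprof - as.numeric(base)
    det <- det - min(det)
    spk <- find_peaks_1d(det, min_frac = 0.1,
                         min_separation = 0.5 * subunit_spacing_px)
    for (i in seq_len(nrow(bpk) - 1)) {
      lo <- bpk$pos[i] + half_widths[i]
      hi <- bpk$pos[i + 1] - half_widths[i + 1]
      counts <- c(counts, sum(spk$pos > lo & spk$pos < hi))
    }
  }
  counts <- counts[counts > 0]
  if (length(counts) == 0) stop_septomo("no subunit peaks between bridges")
  as.integer(names(sort(table(counts), decreasing = TRUE))[1])
}

# Axial intensity profile of one particle image after principal-axis
# alignment.  The image is smoothed to ~30 A, a robust noise floor
# (median + 2 MAD) is subtracted, and intensity is accumulated along the
# principal axis within a 60 A transverse band.  Returns bin centers (A)
# and summed intensity per bin.
axial_profile <- function(img, pixel_size, band_halfwidth = 60) {
  res <- max(30, 3 * pixel_size)
  sm <- low_pass(img, resolution = res, pixel_size = pixel_size)
  floor_lvl <- stats::median(sm) + 2 * stats::mad(sm)
  w <- pmax(sm - floor_lvl, 0)
  n <- nrow(img)
  co <- (seq_len(n) - (n + 1) / 2) * pixel_size
  X <- matrix(co, n, n); Y <- matrix(co, n, n, byrow = TRUE)
  tot <- sum(w)
  if (tot <= 0) return(list(s = 0, p = 0))
  cx <- sum(w * X) / tot; cy <- sum(w * Y) / tot
  xc <- X - cx; yc <- Y - cy
  sxx <- sum(w * xc^2); syy <- sum(w * yc^2); sxy <- sum(w * xc * yc)
  phi <- 0.5 * atan2(2 * sxy, sxx - syy)
  s <- xc * cos(phi) + yc * sin(phi)
  t_ <- -xc * sin(phi) + yc * cos(phi)
  keep <- abs(t_) <= band_halfwidth
  bins <- round(s[keep] / pixel_size)
  prof <- tapply(w[keep], bins, sum)
  list(s = as.numeric(names(prof)) * pixel_size, p = as.numeric(prof))
}

particle_features <- function(img, pixel_size, hex_half = 120) {
  ap <- axial_profile(img, pixel_size)
  tot <- sum(ap$p)
  if (tot <= 0) return(c(length_A = 0, end_score = 0))
  # robust rod length: span of the central 90% of axial mass
  cum <- cumsum(ap$p) / tot
  q05 <- ap$s[which(cum >= 0.05)[1]]
  q95 <- ap$s[which(cum >= 0.95)[1]]
  length_A <- q95 - q05
  endmass <- sum(ap$p[abs(ap$s) > hex_half]) / tot
  c(length_A = length_A, end_score = endmass)
}

#' Classify a particle mixture into capped octamers and hexamers
#'
#' Aligns each particle to its principal axis, measures the rod length and
#' the fraction of axial density beyond the hexamer half-length (the
#' terminal Cdc42-GDP density), and classifies a particle as a capped
#' octamer when both features exceed thresholds.  Thresholds are the
#' midpoints between class means on a small labelled calibration set
#' generated at run time at the same SNR (no stored weights).
#'
#' @param particles A [generate_particle_mixture()] result.
#' @param calibration_n Particles per class in the calibration set.
#' @return List with `labels`, `octamer_fraction`, `features` (matrix) and
#'   `thresholds`.
#' @export
classify_particles <- function(particles, calibration_n = 40L) {
  stopifnot(inherits(particles, "particle_set"))
  n <- dim(particles$images)[3]
  if (n < 1) stop_septomo("empty particle set")
  ps <- particles$pixel_size
  hex_half <- 120   # hexamer half-length, A (6 subunits x 40 A / 2)

  cal_seed <- (particles$seed %||% 0L) + 7919L
  cal_feats <- function(frac, seed_off) {
    set <- generate_particle_mixture(calibration_n, frac, snr = particles$snr,
                                     seed = cal_seed + seed_off,
                                     image_size = dim(particles$images)[1],
                                     pixel_size = ps)
    t(vapply(seq_len(calibration_n), function(i) {
      particle_features(set$images[, , i], ps, hex_half)
    }, numeric(2)))
  }
  f_oct <- cal_feats(1, 0L)
  f_hex <- cal_feats(0, 1L)
  thresholds <- (colMeans(f_oct) + colMeans(f_hex)) / 2

  feats <- t(vapply(seq_len(n), function(i) {
    particle_features(particles$images[, , i], ps, hex_half)
  }, numeric(2)))
  is_oct <- feats[, "length_A"] > thresholds["length_A"] &
    feats[, "end_score"] > thresholds["end_score"]
  labels <- ifelse(is_oct, "octamer_capped", "hexamer")
  list(labels = labels, octamer_fraction = mean(is_oct),
       features = feats, thresholds = thresholds)
}

#' Segmentation mask
#'
#' `make_segmentation_mask` produces a binary mask algorithmically by
#' thresholding a low-pass filtered copy of the volume (replacing manual
#' slice-by-slice tracing).
#'
#' @param volume A `density_volume`.
#' @param resolution Low-pass resolution before thresholding, Angstrom.
#' @param threshold_frac Binarization threshold as a fraction of the
#'   filtered maximum.
#' @return Object of class `segmentation_mask` (0/1 array + grid info).
#' @export
make_segmentation_mask <- function(volume, resolution = 60,
                                   threshold_frac = 0.2) {
  stopifnot(inherits(volume, "density_volume"))
  sm <- low_pass(volume, resolution)
  vals <- (sm$values >= threshold_frac * max(sm$values)) * 1
  structure(list(values = vals, voxel_size = volume$voxel_size),
            class = "segmentation_mask")
}

#' @rdname make_segmentation_mask
#' @param values 0/1 array.
#' @param voxel_size Voxel size, Angstrom.
#' @export
segmentation_mask <- function(values, voxel_size) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  structure(list(values = (values > 0) * 1, voxel_size = voxel_size),
            class = "segmentation_mask")
}

dilate_mask_values <- function(m, n_voxels) {
  if (n_voxels < 1) return(m)
  d <- dim(m)
  shift <- function(a, axis, by) {
    idx <- lapply(d, seq_len)
    src <- pmin(pmax(idx[[axis]] - by, 1L), d[axis])
    args <- idx; args[[axis]] <- src
    do.call(`[`, c(list(a), args))
  }
  for (i in seq_len(n_voxels)) {
    out <- m
    for (axis in 1:3) {
      out <- pmax(out, shift(m, axis, 1L), shift(m, axis, -1L))
    }
    m <- out
  }
  m
}

#' Mask-based density extraction
#'
#' The subtomogram processing step: the binary segment is dilated by
#' `expand_voxels`, softened with a Gaussian edge, multiplied into the raw
#' volume, and the extracted density is low-pass filtered (40 A in the
#' original procedure).  Voxels outside the dilated mask are zero.
#'
#' @param raw A `density_volume`.
#' @param seg A `segmentation_mask` on the same grid.
#' @param expand_voxels Dilation radius in voxels (>= 0).
#' @param filter_resolution Final low-pass resolution, Angstrom.
#' @param soften_sigma Gaussian edge width in voxels.
#' @return A `density_volume`.
#' @export
mask_extract <- function(raw, seg, expand_voxels = 2L,
                         filter_resolution = 40, soften_sigma = 1.5) {
  stopifnot(inherits(raw, "density_volume"),
            inherits(seg, "segmentation_mask"), expand_voxels >= 0)
  if (!identical(dim(seg$values), dim(raw$values))) {
    stop_septomo("mask grid does not match volume")
  }
  dil <- dilate_mask_values(seg$values, as.integer(expand_voxels))
  # Gaussian softening of the mask edge (real-space sigma in voxels)
  k <- freq_grid(dim(dil), 1)
  soft <- apply_fourier_filter(dil, exp(-2 * pi^2 * soften_sigma^2 * k^2))
  soft <- pmin(pmax(soft, 0), 1)
  extracted <- raw
  extracted$values <- raw$values * soft
  extracted <- low_pass(extracted, filter_resolution)
  extracted$values[dil == 0] <- 0
  extracted
}

#' Assemble a quantification report
#'
#' Bundle of the pipeline metrics; only the analyses that ran are present.
#'
#' @param cc Cross-correlation coefficient.
#' @param z_elongation_pct Beam-axis elongation, percent.
#' @param spacing_nm Inter-filament spacing, nm.
#' @param gap_count Subunits between bridges.
#' @param octamer_fraction Recovered capped-octamer fraction.
#' @return Object of class `quant_report`.
#' @export
quant_report <- function(cc = NULL, z_elongation_pct = NULL,
                         spacing_nm = NULL, gap_count = NULL,
                         octamer_fraction = NULL) {
  out <- list(cc = cc, z_elongation_pct = z_elongation_pct,
              spacing_nm = spacing_nm, gap_count = gap_count,
              octamer_fraction = octamer_fraction)
  structure(out[!vapply(out, is.null, logical(1))], class = "quant_report")
}

#' @export
print.quant_report <- function(x, ...) {
  cat("<quant_report>\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' @rdname quant_report
#' @param report A `quant_report`.
#' @param path Output JSON path.
#' @export
write_quant_report <- function(report, path) {
  stopifnot(inherits(report, "quant_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
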