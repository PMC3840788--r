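# End-to-end convenience pipeline: default cable phantom -> tilt simulation
# -> weighted back-projection -> metrics.  This is the workflow used to
# validate the lattice model against wedge-limited tomography.

#' Default SNR for the "close to reality" CTF + noise simulation
#'
#' The original simulation states only that noise was added, not its
#' level.  This default was calibrated once so that the full replica
#' pipeline reproduces the published model-to-tomogram cross-correlation
#' (see the methods vignette) and is documented rather than tuned per run.
#'
#' @export
DEFAULT_SIM_SNR <- 3

#' Build the default railroad cable phantom
#'
#' Constructs a bridged filament-cable lattice sized to the grid (filament
#' axis along y) and renders it as a Gaussian-blob volume.
#'
#' @param variant A bridged, polymerizing variant (default the
#'   Gic1-Cdc42-GppNHp cable with 1.5x bridge mass).
#' @param grid A [grid_params()].
#' @param n_filaments Number of filaments.
#' @param seed Lattice seed.
#' @param ... Further arguments to [lattice_spec()].
#' @return List with `lattice`, `volume`, and `grid`.
#' @export
cable_phantom <- function(variant = "WT_GIC1_CDC42GTP",
                          grid = grid_params(), n_filaments = 2L,
                          seed = 1L, ...) {
  L <- length(protomer_order(variant))
  args <- list(...)
  d <- args$subunit_diameter %||% 4
  grid_len_nm <- grid$shape[2] * grid$voxel_size / 10
  n_rep <- args$n_repeats %||% max(1L, floor((grid_len_nm / d + 1) / L))
  args$n_repeats <- n_rep
  args$n_filaments <- n_filaments
  spec <- do.call(lattice_spec, args)
  lattice <- build_lattice(spec, variant, seed = seed)
  volume <- render_volume(lattice, grid)
  list(lattice = lattice, volume = volume, grid = grid)
}

#' Voxel index of a cross-bridge center in the acquisition frame
#'
#' @param lattice The phantom lattice.
#' @param grid The rendering grid.
#' @param geometry Acquisition geometry used.
#' @param which `"central"` picks the bridge nearest the lattice midpoint.
#' @return Integer voxel triple `(ix, iy, iz)`.
#' @export
bridge_center_voxel <- function(lattice, grid, geometry =
                                  "long_axis_parallel_to_beam",
                                which = "central") {
  if (length(lattice$bridges) == 0) stop_septomo("lattice has no bridges")
  yb <- vapply(lattice$bridges, function(b) b$y, numeric(1))
  y <- yb[which.min(abs(yb))] * 10                    # nm -> A
  n <- grid$shape
  vox_spec <- c((n[1] + 1) / 2,                       # x: between filaments
                y / grid$voxel_size + (n[2] + 1) / 2, # y: bridge position
                (n[3] + 1) / 2)                       # z: filament plane
  perm <- switch(match.arg(geometry, geometry_modes()),
    parallel_to_tilt_axis = c(1L, 2L, 3L),
    long_axis_parallel_to_beam = c(1L, 3L, 2L),
    perpendicular_to_tilt_axis = c(2L, 1L, 3L))
  as.integer(round(vox_spec[perm]))
}

#' Run the wedge-limited tomography simulation
#'
#' The validation computation: low-pass the phantom to the working
#' resolution (the "simulated EM density map"), simulate a single-axis
#' tilt series in the requested geometry (optionally with CTF and noise),
#' reconstruct by weighted back-projection, and compare to the model.
#' When a CTF is applied the reconstruction is contrast-inverted back to
#' the density-positive convention and low-pass filtered to the working
#' resolution before comparison.
#'
#' @param volume Phantom `density_volume` (filament axis along y).
#' @param tilt_range Half-angle, degrees (`+/- tilt_range`).
#' @param tilt_step Increment, degrees.
#' @param geometry One of [geometry_modes()].
#' @param optics [optics_params()] or `NULL` for a CTF-free simulation.
#' @param snr Additive noise level (`Inf` = none).
#' @param seed Noise seed.
#' @param resolution Working resolution, Angstrom (45 A default).
#' @param weighting Back-projection weighting, `"ramp"` or `"none"`.
#' @return List: `model` (filtered phantom, acquisition frame), `recon`,
#'   `tilt_series`, `cc` (whole-volume Pearson correlation), `cc_masked`
#'   (Pearson within the model-support segmentation mask, the
#'   structure-region comparison mode), `mask`, `geometry`.
#' @export
wedge_simulation <- function(volume, tilt_range = 60, tilt_step = 2,
                             geometry = "long_axis_parallel_to_beam",
                             optics = NULL, snr = Inf, seed = 1L,
                             resolution = 45, weighting = "ramp") {
  geometry <- match.arg(geometry, geometry_modes())
  model <- low_pass(volume, resolution)
  scheme <- tilt_scheme(-tilt_range, tilt_range, tilt_step)
  ts <- simulate_tilt_series(model, scheme, geometry, optics = optics,
                             snr = snr, seed = seed)
  rec <- wbp(ts, recon_params(weighting = weighting))
  if (!is.null(optics)) {
    rec$values <- -rec$values          # undo the CTF contrast inversion
    rec <- low_pass(rec, resolution)
  }
  model_acq <- orient_volume(model, geometry)
  mask <- make_segmentation_mask(model_acq)
  list(model = model_acq, recon = rec, tilt_series = ts,
       cc = cross_correlation(rec, model_acq),
       cc_masked = cross_correlation(rec, model_acq, mask),
       mask = mask, geometry = geometry)
}
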