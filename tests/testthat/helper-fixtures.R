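# Shared fixtures, built in code.  Sizes are kept small (64^3) except where
# an acceptance criterion states the working scale.

small_grid <- function(n = 64L) grid_params(c(n, n, n), 7.3)

# Default two-filament Gic1-Cdc42-GppNHp cable at a given grid size.
small_cable <- function(n = 64L, variant = "WT_GIC1_CDC42GTP", ...) {
  cable_phantom(variant, grid = small_grid(n), ...)
}

# Centered isotropic 3D Gaussian volume (no lattice machinery).
gaussian_volume <- function(n = 48L, sigma = 30, voxel = 7.3) {
  co <- (seq_len(n) - (n + 1) / 2) * voxel
  g1 <- exp(-co^2 / (2 * sigma^2))
  density_volume(outer(outer(g1, g1), g1), voxel)
}

# Inscribed-cylinder mask of the (x, z) tilt plane: the region fully
# covered by back-projection at every angle.
cylinder_mask <- function(vol, margin = 1) {
  d <- dim(vol$values)
  cx <- (d[1] + 1) / 2; cz <- (d[3] + 1) / 2
  r2 <- outer((seq_len(d[1]) - cx)^2, (seq_len(d[3]) - cz)^2, `+`)
  disc <- r2 <= (d[1] / 2 - margin)^2
  cyl <- aperm(array(rep(disc, d[2]), c(d[1], d[3], d[2])), c(1, 3, 2))
  segmentation_mask(cyl * 1, vol$voxel_size)
}

expect_same_volume <- function(a, b, tol = 1e-10) {
  expect_equal(a$values, b$values, tolerance = tol)
}
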