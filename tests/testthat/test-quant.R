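test_that("cross_correlation limits, masking, and noise attenuation", {
  v <- gaussian_volume(32)
  expect_equal(cross_correlation(v, v), 1)
  neg <- density_volume(-v$values, v$voxel_size)
  expect_equal(cross_correlation(v, neg), -1)
  other <- gaussian_volume(24)
  expect_error(cross_correlation(v, other), "different grids")
  expect_error(cross_correlation(v, v,
                                 segmentation_mask(array(0, dim(v$values)),
                                                   v$voxel_size)),
               "empty")
  # analytic attenuation: cor(x, x + noise) = 1/sqrt(1 + 1/SNR)
  set.seed(2)
  x <- array(rnorm(32^3), c(32, 32, 32))
  for (snr in c(4, 1)) {
    noisy <- density_volume(x + array(rnorm(32^3, sd = sqrt(1 / snr)),
                                      dim(x)), 7.3)
    expect_equal(cross_correlation(density_volume(x, 7.3), noisy),
                 1 / sqrt(1 + 1 / snr), tolerance = 0.02)
  }
})

test_that("z_elongation is zero for identical volumes and checks inputs", {
  ph <- small_cable(64)
  sim <- wedge_simulation(ph$volume, 60, 2, "long_axis_parallel_to_beam",
                          resolution = 45)
  cv <- bridge_center_voxel(ph$lattice, ph$grid)
  expect_equal(z_elongation(sim$model, sim$model, cv), 0)
  expect_error(z_elongation(sim$model, sim$model, cv, threshold_frac = 1.2),
               "\\(0, 1\\)")
  expect_error(z_elongation(sim$model, sim$model, c(999, 1, 1)),
               "outside grid")
})

test_that("interfilament spacing recovers construction and resists resampling", {
  # construction recovery at several spacings, half-voxel tolerance
  for (s in c(16, 24)) {
    lat <- build_lattice(lattice_spec(n_filaments = 2,
                                      inter_filament_spacing = s), "WT_GIC1")
    top <- render_projection(lat, grid_params(c(96, 96, 48), 7.3), "top")
    expect_equal(interfilament_spacing(top), s, tolerance = 0.37 / s)
  }
  # voxel-size invariance for the same physical phantom
  lat <- build_lattice(lattice_spec(n_filaments = 2), "WT_GIC1")
  sp1 <- interfilament_spacing(render_projection(lat, grid_params(c(96, 96, 48), 7.3), "top"))
  sp2 <- interfilament_spacing(render_projection(lat, grid_params(c(128, 128, 64), 5.0), "top"))
  expect_equal(sp1, sp2, tolerance = 0.02)
  flat <- matrix(1, 32, 32)
  attr(flat, "pixel_size") <- 7.3
  expect_error(interfilament_spacing(flat), "fewer than 2")
})

test_that("gap counts from side views match the analytic model", {
  g <- grid_params(c(128, 192, 64), 7.3)
  px <- 40 / 7.3
  for (v in c("WT_GIC1", "CDC11_DELTA_GIC1", "WT_GIC1_CDC42GTP")) {
    L <- length(protomer_order(v))
    lat <- build_lattice(lattice_spec(n_filaments = 2,
                                      n_repeats = ceiling(32 / L)), v)
    side <- render_projection(lat, g, "side")
    expect_equal(count_gap_subunits(side, px), expected_gap(v), info = v)
  }
  # unbridged filaments: no cross-bridges to count
  lat_wt <- build_lattice(lattice_spec(n_filaments = 2, n_repeats = 4), "WT")
  expect_error(count_gap_subunits(render_projection(lat_wt, g, "side"), px),
               "no cross-bridges|no subunit peaks")
})

test_that("classifier separates the classes and recovers the mixture", {
  pure <- generate_particle_mixture(30, 1.0, snr = Inf, seed = 2)
  res <- classify_particles(pure)
  expect_equal(res$octamer_fraction, 1.0)
  expect_true(all(res$labels == pure$labels))

  mix <- generate_particle_mixture(300, 0.9, snr = 1, seed = 8)
  res2 <- classify_particles(mix)
  se3 <- 3 * sqrt(0.9 * 0.1 / 300)
  expect_lt(abs(res2$octamer_fraction - 0.9), se3)

  # in-plane rotation invariance (exact 90-degree rotations)
  rot <- mix
  for (i in seq_len(dim(rot$images)[3])) {
    rot$images[, , i] <- t(rot$images[, , i])[, dim(rot$images)[1]:1]
  }
  expect_equal(classify_particles(rot)$labels, res2$labels)
})

test_that("classifier calibration holds across seeds", {
  fr <- vapply(c(21, 22, 23), function(s) {
    classify_particles(generate_particle_mixture(200, 0.9, snr = 1,
                                                 seed = s))$octamer_fraction
  }, numeric(1))
  se3 <- 3 * sqrt(0.9 * 0.1 / 200)
  expect_true(all(abs(fr - 0.9) < se3))
})

test_that("mask_extract identities and monotonicity", {
  v <- gaussian_volume(32)
  ones <- segmentation_mask(array(1, dim(v$values)), v$voxel_size)
  expect_same_volume(mask_extract(v, ones, expand_voxels = 0,
                                  filter_resolution = 40),
                     low_pass(v, 40), tol = 1e-8)
  zeros <- segmentation_mask(array(0, dim(v$values)), v$voxel_size)
  expect_true(all(mask_extract(v, zeros, 2, 40)$values == 0))

  seg <- make_segmentation_mask(v, resolution = 60, threshold_frac = 0.5)
  retained <- vapply(0:3, function(e) {
    sum(mask_extract(v, seg, e, 40)$values)
  }, numeric(1))
  expect_true(all(diff(retained) >= 0))
  bad <- segmentation_mask(array(1, c(16, 16, 16)), v$voxel_size)
  expect_error(mask_extract(v, bad, 1, 40), "match")
})

test_that("quant_report keeps only the analyses that ran and writes JSON", {
  r <- quant_report(cc = 0.95, gap_count = 6L)
  expect_named(r, c("cc", "gap_count"))
  path <- withr::local_tempfile(fileext = ".json")
  write_quant_report(r, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$cc, 0.95)
  expect_equal(back$gap_count, 6L)
})
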