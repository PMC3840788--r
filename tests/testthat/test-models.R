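test_that("protomer orders match the known subunit sequences", {
  expect_equal(protomer_order("WT"),
               c("Cdc11", "Cdc12", "Cdc3", "Cdc10",
                 "Cdc10", "Cdc3", "Cdc12", "Cdc11"))
  # Cdc11 deletion: remove Cdc11 from the WT order, preserving order
  expect_equal(protomer_order("CDC11_DELTA"),
               protomer_order("WT")[protomer_order("WT") != "Cdc11"])
  # Cdc42-GDP octamer is the inverted rod with Cdc10 caps at both ends
  oct_gdp <- protomer_order("CDC42GDP_OCTAMER")
  expect_equal(oct_gdp,
               c("Cdc10", "Cdc3", "Cdc12", "Cdc11",
                 "Cdc11", "Cdc12", "Cdc3", "Cdc10"))
  expect_equal(oct_gdp[c(1, 8)], c("Cdc10", "Cdc10"))
  # Cdc3 sits at the ends of the Cdc10-less hexamer
  expect_equal(protomer_order("HEXAMER_NO_CDC10")[c(1, 6)],
               c("Cdc3", "Cdc3"))
  expect_error(protomer_order("NOPE"), "NOPE")
})

test_that("every protomer order is a palindrome (two-fold symmetry)", {
  for (v in complex_variants()) {
    ord <- protomer_order(v)
    expect_equal(ord, rev(ord), info = v)
  }
})

test_that("ligand binding sites follow the Cdc10 rules", {
  wt <- protomer_order("WT")
  g <- ligand_binding_sites(wt, "Gic1", "WT_GIC1")
  expect_equal(nrow(g), 1L)
  expect_equal(c(g$i, g$j), c(4L, 5L))   # the adjacent Cdc10 pair (1-based)
  expect_false(g$bind_only)
  # no Cdc10, no site
  expect_equal(nrow(ligand_binding_sites(protomer_order("CDC10_DELTA"),
                                         "Gic1", "CDC10_DELTA")), 0L)
  # N-terminally truncated Cdc10: Gic1 binds without cross-linking,
  # Cdc42-GDP does not bind at all
  tr_g <- ligand_binding_sites(wt, "Gic1", "CDC10_TRUNC_GIC1")
  expect_true(all(tr_g$bind_only))
  expect_equal(nrow(ligand_binding_sites(wt, "Cdc42_GDP",
                                         "CDC10_TRUNC_GIC1")), 0L)
  # Cdc42-GppNHp binds Gic1, not the septins
  expect_equal(nrow(ligand_binding_sites(wt, "Cdc42_GppNHp", "WT")), 0L)
})

test_that("build_lattice is deterministic and respects the binding rules", {
  spec <- lattice_spec(n_filaments = 2, randomize_starts = TRUE,
                       max_start_offset = 8)
  a <- build_lattice(spec, "WT_GIC1", seed = 42)
  b <- build_lattice(spec, "WT_GIC1", seed = 42)
  expect_identical(a, b)
  c <- build_lattice(spec, "WT_GIC1", seed = 43)
  expect_false(identical(a$subunits$y, c$subunits$y))

  # bridge contacts are exclusively Cdc10, for every bridged variant
  for (v in c("WT_GIC1", "WT_GIC1_CDC42GTP", "CDC11_DELTA_GIC1")) {
    lat <- build_lattice(lattice_spec(n_filaments = 3), v)
    expect_gt(length(lat$bridges), 0)
    ct <- unlist(lapply(lat$bridges, `[[`, "contacts"))
    expect_true(all(lat$subunits$kind[ct] == "Cdc10"), info = v)
  }

  expect_error(build_lattice(lattice_spec(n_filaments = 2), "CDC11_DELTA"),
               "does not polymerize")
})

test_that("a six-filament cable engages 12 Cdc10 subunits per bridge", {
  lat <- build_lattice(lattice_spec(n_filaments = 6), "WT_GIC1")
  expect_equal(length(lat$bridges[[1]]$contacts), 12L)
  expect_equal(cdc10_per_bridge(6), 12L)
  expect_equal(cdc10_per_bridge(1), 2L)
  # 3-filament oracle: enumerate contacts on a built lattice
  lat3 <- build_lattice(lattice_spec(n_filaments = 3), "WT_GIC1")
  expect_equal(length(lat3$bridges[[1]]$contacts), cdc10_per_bridge(3))
  expect_error(cdc10_per_bridge(0), ">= 1")
})

test_that("analytic gaps match the published counts and the built lattice", {
  expect_equal(expected_gap("WT_GIC1"), 6L)
  expect_equal(expected_gap("CDC11_DELTA_GIC1"), 4L)
  expect_equal(expected_gap("WT_GIC1_CDC42GTP"), 4L)
  expect_error(expected_gap("WT"), "bridged")
  # constructive agreement for all bridged variants
  for (v in c("WT_GIC1", "WT_GIC1_CDC42GTP", "CDC11_DELTA_GIC1")) {
    lat <- build_lattice(lattice_spec(n_filaments = 2, n_repeats = 5), v)
    expect_equal(measured_gap(lat), expected_gap(v), info = v)
  }
})

test_that("oligomer_state rounds the mass ratio", {
  expect_equal(oligomer_state(49, 23.38), 2L)    # the Gic1 dimer
  expect_equal(oligomer_state(23.38, 23.38), 1L)
  expect_equal(oligomer_state(100, 24), 4L)      # round(4.17)
  expect_error(oligomer_state(-1, 24), "positive")
  expect_error(oligomer_state(49, 0), "positive")
})

test_that("lattice_spec validates its geometry", {
  expect_error(lattice_spec(n_filaments = 2, inter_filament_spacing = 3,
                            subunit_diameter = 4), "exceed")
  expect_error(build_lattice(lattice_spec(n_filaments = 2, bridge_span = 10),
                             "WT_GIC1"), "span")
  expect_error(build_lattice(lattice_spec(n_filaments = 2, bridge_period = 2,
                                          bridge_span = 4),
                             "WT_GIC1_CDC42GTP"), "period")
})
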