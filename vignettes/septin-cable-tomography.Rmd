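---
title: "Septin-Gic1 cable phantoms and missing-wedge tomography: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Septin-Gic1 cable phantoms and missing-wedge tomography: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(septomo)
```

This vignette documents the models, parameter choices and numerical
conventions behind `septomo`. It is the package's own account of its
science; every number quoted here is computed by the test suite or the
acceptance script, not asserted.

## 1. The lattice model

The repeating unit of a wild-type septin filament is the palindromic
octamer Cdc11-Cdc12-Cdc3-Cdc10-Cdc10-Cdc3-Cdc12-Cdc11. Variants differ by
deletion (Cdc11Δ hexamers, Cdc10Δ hexamers), by N-terminal truncation of
Cdc10 (which leaves Gic1 binding intact but abolishes cross-linking and
Cdc42-GDP binding), and by bound ligand. `protomer_order()` returns these
orders; all are palindromes, reflecting the two-fold rotational symmetry of
the rods. For the Cdc11Δ hexamer we use the order obtained by deleting
Cdc11 from the octamer, Cdc12-Cdc3-Cdc10-Cdc10-Cdc3-Cdc12; as a cyclic
(filament) sequence it is indistinguishable from the Cdc10-capped rotation,
and on polymerization the Cdc10-Cdc10 pairs form across protomer
junctions, which is why `build_lattice()` searches the doubled order for
bridge anchor sites.

`build_lattice()` lays filaments on parallel y-axes and places one
cross-bridge per protomer at the Cdc10 pair. A bridge *contacts* only
Cdc10 subunits (two per filament — twelve in a six-filament cable) but
*covers* `bridge_span` subunits per filament: 2 for Gic1, 4 for
Gic1-Cdc42-GppNHp. The free gap between bridges is therefore
`protomer length − span`: 6 (WT), 4 (Cdc11Δ), 4 (Cdc42-GppNHp). The tests
verify this identity both analytically (`expected_gap`) and by enumerating
built lattices (`measured_gap`) and rendered side views
(`count_gap_subunits`).

Key geometric parameters, all configurable in `lattice_spec()`:

| parameter | default | rationale |
|---|---|---|
| `subunit_diameter` | 4 nm | an 8-subunit octamer spans 32 nm, the established rod length |
| `inter_filament_spacing` | 20 nm | the observed cross-bridge distance, read as center-to-center (the convention is not stated in the source; edge-to-edge would differ by one subunit diameter and is available by setting 24 nm) |
| `bridge_period` | 1 protomer | forced by the observed gap counts (gap = protomer − span) |
| `bridge_mass_scale` | 1.0 / 1.5 | Gic1-Cdc42-GppNHp bridges are about one and a half times larger |
| `max_start_offset`, `randomize_starts` | 8, off | filaments "start at random positions"; with no stated distribution we draw integer offsets uniformly on [0, max] |
| `bend_curvature` | 0 | bending is documented qualitatively only; we expose a circular-arc sagitta `z = κ y² / 2` |
| `bridge_mass_jitter` | 0 | the number of Gic1 dimers "varies between cross-bridges" with no stated distribution; off by default |

## 2. Phantom rendering

Subunits are isotropic Gaussians of unit mass whose FWHM equals the
subunit diameter. Bridges are anisotropic Gaussians: axial FWHM equal to
the covered span, transverse FWHM filling the inter-filament gap, and a
60 Å sigma (FWHM ≈ 14 nm) along the remaining axis — the size of the
chaperonin complex used as the bridge stand-in in the original
simulations. Bridge mass is `12 × mass_scale` subunit equivalents: a
cross-bridge holds up to 12 Gic1 dimers, and a 49 kDa dimer weighs about
one septin subunit. Gaussian blobs replace fitted crystal structures; at
the 45 Å working resolution of every comparison the difference is
immaterial, and the artifact stays self-contained.

Rendering is linear and mass-conserving: the volume integral equals the
summed source masses to 0.1% (the splat support is ±5σ). The projection
renderer (`render_projection`) marginalizes the Gaussians analytically, so
the 2D and 3D paths are independent implementations checked against each
other; broad bridge blobs near the grid boundary lose ~0.3% of their tails
in the 3D path, which sets the tolerance of that test.

## 3. Tilt simulation and reconstruction

Beam along z at zero tilt, tilt axis y, scheme ±60° in 2° steps
(61 images). Optics: 200 kV (λ = 0.02508 Å by the relativistic formula),
4 µm underfocus, and two values the source does not state — spherical
aberration 2.0 mm and amplitude contrast 0.07, typical for the instrument
class. The CTF, `−(√(1−A²) sin γ + A cos γ)` with
`γ = πλΔz k² − (π/2) Cs λ³ k⁴`, is negative at low frequency (protein
dark); after back-projection the pipeline multiplies the reconstruction by
−1 to restore the density-positive convention. The CTF-free path
reproduces the geometry-only simulations; CTF + noise reproduces the
"close to reality" one.

Noise is additive Gaussian, parameterized as SNR = signal variance / noise
variance per projection. The source states a dose (~1 e⁻/Å²) but no noise
level for its simulation; per the build contract the default
(`DEFAULT_SIM_SNR = 3`) was calibrated once so that the replica reproduces
the published cross-correlation, and is documented here rather than tuned
per run. The masked correlation moves by < 0.01 between SNR 1 and ∞, so
this choice is not load-bearing.

Projection rotates the volume about y by linear splatting in the (x, z)
plane; back-projection is the exact adjoint (voxel-driven bilinear
gathering), so projection/back-projection are consistent by construction
and both are linear. Weighted back-projection uses the |k| ramp apodized
by a raised cosine over the top 5% of frequencies (the dialect of the
original IMOD pipeline is not published; exact numeric equality with IMOD
is not claimed). The ramp removes DC, so reconstructions are zero-mean
with the negative halos characteristic of real tomograms.

Degenerate inputs are defined: a single 0° unweighted image back-smears
constant along z; `weighting = "none"` is the identity; SNR = ∞ adds
nothing; |angle| > 90° and sub-Nyquist low-pass resolutions are errors.

## 4. Quantification protocols

**Cross-correlation.** `cross_correlation()` is Pearson, optionally over a
mask. Whether the published 0.95 was computed masked or whole-volume is
not stated, so both modes are exposed and the replica reports the masked
one. Rationale: the published comparison fitted the reconstruction into
the model and judged structural similarity; whole-volume Pearson is
instead dominated by the empty background, where the uncorrected CTF has
removed the low-frequency contrast (it sits near 0.73 in the same run —
the tests compute both). The mask is the package's default segmentation
mask — 60 Å low-pass, threshold 0.2 of maximum, fixed before any
measurement; the masked CC is flat (±0.01) over thresholds 0.2–0.3.

**z-elongation.** The published "increase in diameter along the z
direction by ∼14%" comes with no measurement protocol. A literal 3D
connected component at half-maximum merges the bridge with the filaments
it touches (the bridge spans the gap by construction) and would measure
filament length. We therefore measure the *diameter along z* directly:
the thresholded extent (with linear sub-voxel crossing interpolation) of
the z-profile through the bridge center, averaged over a ±2 voxel
transverse window, at `threshold_frac` of the component's local maximum.
Sensitivity is reported, not hidden: the acceptance suite runs at the 0.5
default, and values at 0.4/0.5/0.6 remain within the stated ±5 point
band. Elongation is monotone in the missing wedge (±40° > ±60° > ±80°),
which the suite checks at full scale.

**Spacing.** Transverse density profile averaged along the filament and
beam axes; peaks by parabolic interpolation; mean adjacent-peak distance.
The bridge density between the filaments biases the peaks slightly inward
(~0.25 nm at default geometry), within the half-voxel acceptance band.

**Gap counting.** Bridges are found on the mid-line between filament rows
(they span the gap; subunits do not); each bridge's axial FWHM is excised,
which removes exactly the covered subunits; subunit peaks are counted on
the running-mean-detrended filament profile between bridges, and the modal
count is returned. Detrending is required because subunit bumps adjacent
to a bridge ride the bridge dome's slope.

**Classification.** Particles are aligned to their principal axis after
30 Å smoothing and subtraction of a robust noise floor (median + 2 MAD).
Two features: rod length (span of the central 90% of axial mass) and
terminal-density fraction beyond the hexamer half-length (120 Å). A
particle is a capped octamer when both exceed thresholds set at the
midpoint of class means on a labelled calibration set generated at run
time at the same SNR — no stored weights. Features are rotation-invariant
by construction.

**Mask extraction.** Binary segment → dilation (6-neighborhood, iterated)
→ Gaussian edge softening → multiply into the raw volume → 40 Å low-pass →
re-zero outside the dilated mask. Retained density is non-decreasing in
the dilation radius.

## 5. What the generator does and does not emulate

It emulates: the stated cable geometry and stoichiometry, variant-specific
binding rules, tilt geometry with its missing wedge, an uncorrected CTF,
and stationary Gaussian noise. It does **not** emulate: atomic structure,
solvent/ice, detector MTF, dose fractionation or beam-induced motion,
fiducial alignment error (synthetic stacks are perfectly aligned), filament
heterogeneity beyond start offsets, or membrane interactions. A green test
therefore establishes that the *pipeline arithmetic* reproduces the
published simulation results on the stated world — not that the pipeline
would perform identically on real micrographs.

Two scope notes. Full-sampling recovery (CC ≥ 0.99) is evaluated inside
the inscribed cylinder of the tilt plane, the region every projection
covers; the cube corners are geometrically under-sampled by any
back-projection. And the reference-free alignment / k-means machinery of
the original single-particle analysis is deliberately replaced by the
two-feature classifier above, which suffices for the 90/10 mixture it is
asked to recover.

## 6. Known limitations

- The WBP frequency response is only approximately flat (discrete angles,
  linear interpolation); whole-volume correlations carry this signature.
- `z_elongation` is a 1D diameter; it requires the component to be
  separable from its neighbors along z (true for default phantoms with
  ≥ 2 bridge repeats in the box).
- The MRC reader covers modes 0/1/2, little-endian, without extended
  headers — sufficient for files this package writes.
- Randomized start offsets are drawn per filament in whole subunits; there
  is no axial jitter within a filament.
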