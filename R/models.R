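#' Septin subunit and ligand kinds
#'
#' The four essential budding-yeast septins and the ligands that decorate
#' them in the complexes modelled here.
#'
#' @return Character vector of valid kind names.
#' @export
subunit_kinds <- function() c("Cdc3", "Cdc10", "Cdc11", "Cdc12")

#' @rdname subunit_kinds
#' @export
ligand_kinds <- function() c("Gic1", "Cdc42_GDP", "Cdc42_GppNHp")

# One row per complex variant: the repeating protomer (or particle) order,
# whether the variant polymerizes into filaments, which ligand (if any)
# forms inter-filament cross-bridges, how many subunits per filament a
# bridge spans, the relative bridge mass, and whether Cdc10 carries the
# N-terminal truncation that abolishes Cdc42-GDP binding and cross-linking.
.variant_table <- local({
  oct_wt  <- c("Cdc11", "Cdc12", "Cdc3", "Cdc10", "Cdc10", "Cdc3", "Cdc12", "Cdc11")
  hex_c11 <- c("Cdc12", "Cdc3", "Cdc10", "Cdc10", "Cdc3", "Cdc12")
  hex_c10 <- c("Cdc11", "Cdc12", "Cdc3", "Cdc3", "Cdc12", "Cdc11")
  oct_gdp <- c("Cdc10", "Cdc3", "Cdc12", "Cdc11", "Cdc11", "Cdc12", "Cdc3", "Cdc10")
  hex_no10 <- c("Cdc3", "Cdc12", "Cdc11", "Cdc11", "Cdc12", "Cdc3")
  list(
    WT                 = list(order = oct_wt,  polymerizes = TRUE,  bridge_ligand = NA,
                              bridge_span = NA, mass_scale = NA, cdc10_truncated = FALSE),
    WT_GIC1            = list(order = oct_wt,  polymerizes = TRUE,  bridge_ligand = "Gic1",
                              bridge_span = 2L, mass_scale = 1.0, cdc10_truncated = FALSE),
    WT_GIC1_CDC42GTP   = list(order = oct_wt,  polymerizes = TRUE,  bridge_ligand = "Cdc42_GppNHp",
                              bridge_span = 4L, mass_scale = 1.5, cdc10_truncated = FALSE),
    WT_CDC42GDP        = list(order = oct_wt,  polymerizes = FALSE, bridge_ligand = NA,
                              bridge_span = NA, mass_scale = NA, cdc10_truncated = FALSE),
    CDC11_DELTA        = list(order = hex_c11, polymerizes = FALSE, bridge_ligand = NA,
                              bridge_span = NA, mass_scale = NA, cdc10_truncated = FALSE),
    CDC11_DELTA_GIC1   = list(order = hex_c11, polymerizes = TRUE,  bridge_ligand = "Gic1",
                              bridge_span = 2L, mass_scale = 1.0, cdc10_truncated = FALSE),
    CDC10_DELTA        = list(order = hex_c10, polymerizes = TRUE,  bridge_ligand = NA,
                              bridge_span = NA, mass_scale = NA, cdc10_truncated = FALSE),
    CDC10_TRUNC_GIC1   = list(order = oct_wt,  polymerizes = FALSE, bridge_ligand = NA,
                              bridge_span = NA, mass_scale = NA, cdc10_truncated = TRUE),
    HIGH_SALT_OCTAMER  = list(order = oct_wt,  polymerizes = FALSE, bridge_ligand = NA,
                              bridge_span = NA, mass_scale = NA, cdc10_truncated = FALSE),
    CDC42GDP_OCTAMER   = list(order = oct_gdp, polymerizes = FALSE, bridge_ligand = NA,
                              bridge_span = NA, mass_scale = NA, cdc10_truncated = FALSE),
    HEXAMER_NO_CDC10   = list(order = hex_no10, polymerizes = FALSE, bridge_ligand = NA,
                              bridge_span = NA, mass_scale = NA, cdc10_truncated = FALSE)
  )
})

#' Complex variants
#'
#' All recognized septin complex variants: the wild-type octamer with and
#' without Gic1 or Cdc42 ligands, the deletion and truncation mutants, the
#' high-salt octamer, and the products of Cdc42-GDP driven filament
#' dissociation (Cdc10-capped octamers and Cdc10-less hexamers).
#'
#' @return Character vector of variant names.
#' @export
complex_variants <- function() names(.variant_table)

variant_info <- function(variant) {
  stopifnot(is.character(variant), length(variant) == 1L)
  info <- .variant_table[[variant]]
  if (is.null(info)) {
    stop_septomo("unknown complex variant: '", variant, "'")
  }
  info
}

#' Protomer subunit order of a complex variant
#'
#' Returns the ordered subunit kinds of the repeating protomer (for
#' filament-forming variants) or of the free particle (for non-polymerizing
#' variants).  Octamer and hexamer rods have two-fold rotational symmetry,
#' so every order is a palindrome: the wild-type octamer runs
#' Cdc11-Cdc12-Cdc3-Cdc10-Cdc10-Cdc3-Cdc12-Cdc11, while the octamer
#' produced by Cdc42-GDP driven dissociation is inverted, with Cdc10
#' capping both ends.
#'
#' @param variant One of [complex_variants()].
#' @return Character vector of subunit kinds.
#' @export
#' @examples
#' protomer_order("WT")
#' protomer_order("CDC11_DELTA")
protomer_order <- function(variant) {
  variant_info(variant)$order
}

#' Ligand binding sites on a subunit order
#'
#' Both Gic1 and Cdc42-GDP engage the adjacent Cdc10 pair; Cdc42-GppNHp
#' binds Gic1 rather than the septins and therefore has no direct site.
#' For complexes whose Cdc10 lacks its N-terminal region, Gic1 still binds
#' but can no longer cross-link filaments (sites flagged `bind_only`),
#' whereas Cdc42-GDP does not bind at all.
#'
#' @param order Character vector of subunit kinds (see [protomer_order()]).
#' @param ligand One of [ligand_kinds()].
#' @param variant Variant context, used for the Cdc10 truncation rule.
#' @return Data frame with 1-based columns `i`, `j` (adjacent Cdc10 pair)
#'   and logical `bind_only`.  Zero rows when the ligand has no site.
#' @export
ligand_binding_sites <- function(order, ligand, variant = "WT") {
  stopifnot(length(order) >= 1L, all(order %in% subunit_kinds()))
  ligand <- match.arg(ligand, ligand_kinds())
  info <- variant_info(variant)
  none <- data.frame(i = integer(0), j = integer(0), bind_only = logical(0))
  if (ligand == "Cdc42_GppNHp") return(none)          # binds Gic1, not septin
  if (ligand == "Cdc42_GDP" && info$cdc10_truncated) return(none)
  n <- length(order)
  i <- which(order[-n] == "Cdc10" & order[-1] == "Cdc10")
  if (length(i) == 0) return(none)
  data.frame(i = i, j = i + 1L,
             bind_only = rep(ligand == "Gic1" && info$cdc10_truncated, length(i)))
}

#' Lattice geometry specification
#'
#' Parameters of a filament-cable lattice.  All lengths are in nanometres.
#' Filaments run along the y axis and are offset from one another along x;
#' cross-bridges connect adjacent filaments at the Cdc10 pair.
#'
#' @param n_filaments Number of parallel filaments (>= 0).
#' @param n_repeats Protomer repeats per filament.
#' @param subunit_diameter Axial subunit spacing, nm.  Default 4 nm so that
#'   an octamer rod spans 32 nm.
#' @param inter_filament_spacing Center-to-center distance between adjacent
#'   filaments, nm.  Default 20 nm.
#' @param bridge_period Subunits between consecutive bridge centers along a
#'   filament.  `NA` means one bridge per protomer (the default; the
#'   observed gap counts force this).
#' @param bridge_span Subunits per filament covered by one bridge.  `NA`
#'   means the variant default (2 for Gic1, 4 for Gic1-Cdc42-GppNHp).
#' @param randomize_starts Draw per-filament start offsets from the seed.
#' @param max_start_offset Maximum start offset in subunits.
#' @param bend_curvature Circular-arc curvature of the filament axes, 1/nm
#'   (0 = straight).
#' @param bridge_mass_scale Relative integrated bridge mass; `NA` means the
#'   variant default (1.0 for Gic1, 1.5 for Gic1-Cdc42-GppNHp).
#' @param bridge_mass_jitter Fractional uniform jitter on per-bridge mass
#'   (0 = identical bridges; the observed bridge-to-bridge variability has
#'   no stated distribution, so this is off by default).
#' @return Object of class `lattice_spec`.
#' @export
lattice_spec <- function(n_filaments = 2L, n_repeats = 4L,
                         subunit_diameter = 4, inter_filament_spacing = 20,
                         bridge_period = NA, bridge_span = NA,
                         randomize_starts = FALSE, max_start_offset = 8L,
                         bend_curvature = 0, bridge_mass_scale = NA,
                         bridge_mass_jitter = 0) {
  stopifnot(n_filaments >= 0, n_repeats >= 1, subunit_diameter > 0,
            bend_curvature >= 0, max_start_offset >= 0,
            bridge_mass_jitter >= 0, bridge_mass_jitter < 1)
  if (n_filaments >= 2 && inter_filament_spacing <= subunit_diameter) {
    stop_septomo("inter_filament_spacing must exceed subunit_diameter")
  }
  structure(list(
    n_filaments = as.integer(n_filaments), n_repeats = as.integer(n_repeats),
    subunit_diameter = subunit_diameter,
    inter_filament_spacing = inter_filament_spacing,
    bridge_period = bridge_period, bridge_span = bridge_span,
    randomize_starts = isTRUE(randomize_starts),
    max_start_offset = as.integer(max_start_offset),
    bend_curvature = bend_curvature, bridge_mass_scale = bridge_mass_scale,
    bridge_mass_jitter = bridge_mass_jitter
  ), class = "lattice_spec")
}

# Resolve NA bridge fields against the variant defaults.
resolve_bridge_params <- function(spec, info, order) {
  span <- spec$bridge_span
  if (is.na(span)) span <- info$bridge_span
  period <- spec$bridge_period
  if (is.na(period)) period <- length(order)
  mass <- spec$bridge_mass_scale
  if (is.na(mass)) mass <- info$mass_scale
  list(span = span, period = period, mass = mass)
}

#' Build a filament-cable lattice
#'
#' Lays `n_filaments` parallel filaments of repeating protomers along the
#' y axis, separated along x by the inter-filament spacing, and places
#' cross-bridges at the Cdc10 pair positions every `bridge_period` subunits
#' for bridged variants.  A bridge geometrically covers `bridge_span`
#' subunits per filament (its Cdc10 contacts are recorded separately).
#' The same `(spec, variant, seed)` always yields the identical lattice.
#'
#' @param spec A [lattice_spec()].
#' @param variant One of [complex_variants()]; must polymerize (or
#'   `n_filaments = 0` for particle-only use).
#' @param seed Integer seed for randomized start offsets and mass jitter.
#' @return Object of class `septin_lattice`: list with `subunits` (data
#'   frame: filament, axial_index, kind, x, y, z in nm, bridge_bound),
#'   `bridges` (list of records with y position, contact row indices,
#'   ligand, mass_scale), plus the resolved spec and variant.
#' @export
build_lattice <- function(spec, variant, seed = 1L) {
  stopifnot(inherits(spec, "lattice_spec"))
  info <- variant_info(variant)
  order <- info$order
  L <- length(order)
  if (spec$n_filaments >= 1 && !info$polymerizes) {
    stop_septomo("variant does not polymerize: '", variant, "'")
  }
  bp <- resolve_bridge_params(spec, info, order)
  bridged <- !is.na(info$bridge_ligand)
  if (bridged) {
    if (bp$span > L) stop_septomo("bridge_span exceeds protomer length")
    if (bp$period < bp$span) stop_septomo("bridge_period must be >= bridge_span")
  }
  d <- spec$subunit_diameter
  nf <- spec$n_filaments
  nsub <- spec$n_repeats * L

  draws <- with_seed(seed, {
    offs <- if (spec$randomize_starts && nf > 0) {
      sample.int(spec$max_start_offset + 1L, nf, replace = TRUE) - 1L
    } else rep(0L, max(nf, 0L))
    jit <- runif(64L, -spec$bridge_mass_jitter, spec$bridge_mass_jitter)
    list(offs = offs, jit = jit)
  })

  y0 <- -(nsub - 1) * d / 2     # center the unshifted filament at y = 0
  subunits <- do.call(rbind, lapply(seq_len(nf), function(f) {
    j <- seq_len(nsub)
    y <- (draws$offs[f] + j - 1) * d + y0
    x <- (f - (nf + 1) / 2) * spec$inter_filament_spacing
    z <- spec$bend_curvature * y^2 / 2   # circular-arc sagitta, small angle
    data.frame(filament = f, axial_index = j,
               kind = order[((j - 1) %% L) + 1L],
               x = x, y = y, z = z, bridge_bound = FALSE)
  }))
  if (is.null(subunits)) {
    subunits <- data.frame(filament = integer(0), axial_index = integer(0),
                           kind = character(0), x = numeric(0), y = numeric(0),
                           z = numeric(0), bridge_bound = logical(0))
  }

  bridges <- list()
  if (bridged && nf >= 2) {
    # Cdc10 pairs can straddle the protomer junction (Cdc11-less hexamers
    # polymerize Cdc10-to-Cdc10), so search the doubled order.
    ord2 <- rep(order, 2L)
    pair_i <- which(ord2[-length(ord2)] == "Cdc10" & ord2[-1] == "Cdc10")
    if (length(pair_i) > 0) {
      pair_center0 <- (pair_i[1] + pair_i[1] + 1 - 2) / 2  # 0-based midpoint
      y_lo <- min(subunits$y); y_hi <- max(subunits$y)
      k <- seq(floor((y_lo - y0) / (bp$period * d)) - 1,
               ceiling((y_hi - y0) / (bp$period * d)) + 1)
      y_bridges <- y0 + (pair_center0 + k * bp$period) * d
      y_bridges <- y_bridges[y_bridges >= y_lo - d & y_bridges <= y_hi + d]
      bi <- 0L
      for (yb in y_bridges) {
        contacts <- integer(0)
        participating <- 0L
        for (f in seq_len(nf)) {
          rows <- which(subunits$filament == f & subunits$kind == "Cdc10" &
                          abs(subunits$y - yb) <= d * 1.01)
          if (length(rows) >= 2) {
            contacts <- c(contacts, rows)
            participating <- participating + 1L
          }
        }
        if (participating >= 2) {
          bi <- bi + 1L
          jit <- draws$jit[((bi - 1L) %% length(draws$jit)) + 1L]
          covered <- which(abs(subunits$y - yb) <= bp$span * d / 2 + d * 0.01)
          subunits$bridge_bound[covered] <- TRUE
          bridges[[bi]] <- list(
            y = yb, contacts = contacts, ligand = info$bridge_ligand,
            mass_scale = bp$mass * (1 + jit), span = bp$span
          )
        }
      }
    }
  }

  structure(list(subunits = subunits, bridges = bridges, spec = spec,
                 variant = variant, seed = as.integer(seed),
                 protomer_length = L),
            class = "septin_lattice")
}

#' @export
print.septin_lattice <- function(x, ...) {
  cat(sprintf("<septin_lattice> %s: %d filaments, %d subunits, %d bridges\n",
              x$variant, x$spec$n_filaments, nrow(x$subunits),
              length(x$bridges)))
  invisible(x)
}

#' Analytic gap between cross-bridges
#'
#' Number of subunits per filament left uncontacted between consecutive
#' cross-bridges: protomer length minus bridge span.  Six for the
#' wild-type/Gic1 cable (octamer protomer, span 2), four for the Cdc11
#' deletion (hexamer protomer, span 2) and four for Gic1-Cdc42-GppNHp
#' (octamer protomer, span 4).
#'
#' @param variant A bridged variant.
#' @return Integer subunit count.
#' @export
expected_gap <- function(variant) {
  info <- variant_info(variant)
  if (is.na(info$bridge_ligand)) {
    stop_septomo("variant '", variant, "' does not form bridged filaments")
  }
  as.integer(length(info$order) - info$bridge_span)
}

#' Gap measured by enumerating a built lattice
#'
#' Constructive counterpart of [expected_gap()]: counts, per filament, the
#' unbound subunits lying strictly between consecutive bridge centers and
#' returns the modal count.
#'
#' @param lattice A [build_lattice()] result with >= 2 bridges.
#' @return Integer subunit count.
#' @export
measured_gap <- function(lattice) {
  stopifnot(inherits(lattice, "septin_lattice"))
  if (length(lattice$bridges) < 2) stop_septomo("need >= 2 bridges to measure a gap")
  yb <- sort(vapply(lattice$bridges, function(b) b$y, numeric(1)))
  counts <- integer(0)
  for (f in unique(lattice$subunits$filament)) {
    s <- lattice$subunits[lattice$subunits$filament == f, ]
    for (i in seq_len(length(yb) - 1)) {
      counts <- c(counts, sum(!s$bridge_bound & s$y > yb[i] & s$y < yb[i + 1]))
    }
  }
  counts <- counts[counts > 0]
  as.integer(names(sort(table(counts), decreasing = TRUE))[1])
}

#' Cdc10 contacts per cross-bridge
#'
#' Each cross-bridge engages the Cdc10 pair of every filament it touches,
#' i.e. two Cdc10 subunits per filament (12 for a six-filament cable).
#'
#' @param n_filaments Number of filaments (>= 1).
#' @return Integer, `2 * n_filaments`.
#' @export
cdc10_per_bridge <- function(n_filaments) {
  if (!is.numeric(n_filaments) || length(n_filaments) != 1L || n_filaments < 1) {
    stop_septomo("n_filaments must be >= 1")
  }
  2L * as.integer(n_filaments)
}

#' Oligomeric state from an apparent molecular weight
#'
#' Nearest integer ratio of an observed (e.g. gel-filtration) mass to the
#' monomer mass, with a minimum of one.  Gic1(104-314) elutes at 49 kDa
#' against a calculated 23.38 kDa, i.e. a dimer.
#'
#' @param observed_kda Observed mass, kDa (> 0).
#' @param monomer_kda Monomer mass, kDa (> 0).
#' @return Integer oligomer count.
#' @export
oligomer_state <- function(observed_kda, monomer_kda) {
  if (!is.numeric(observed_kda) || !is.numeric(monomer_kda) ||
      observed_kda <= 0 || monomer_kda <= 0) {
    stop_septomo("masses must be positive")
  }
  max(1L, as.integer(round(observed_kda / monomer_kda)))
}
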