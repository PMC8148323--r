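# Reduced-order airway transport: 1-D advection-dispersion of vapor through
# a segmented conduit from the mouth to a distal boundary at bronchial
# generation 4, with wall uptake per segment from the layered tissue model.
#
# The geometry is a single symmetric path (generation lumping): each
# bronchial generation's tubes are pooled into one segment whose
# cross-section and perimeter are the generation totals. Turbulent and
# secondary-flow mixing is folded into an axial dispersion coefficient
# proportional to local velocity times hydraulic diameter.

AIRWAY_SEGMENT_NAMES <- c("oral_cavity", "oropharynx", "larynx", "trachea",
                          "bronchi_G1", "bronchi_G2", "bronchi_G3",
                          "bronchi_G4")

#' Construct an airway segment
#'
#' @param name Segment name (mouth-to-distal path order).
#' @param length Axial length, m.
#' @param cross_section Total lumen cross-section, m^2 (generation total for
#'   pooled bronchi).
#' @param perimeter Total wetted perimeter, m. Defaults to the circular
#'   equivalent of `cross_section`.
#' @param n_tubes Number of pooled parallel tubes (bronchial generations).
#' @param tissue_stack_ref Label of the wall stack parameterization.
#' @return An `airway_segment`.
#' @export
airway_segment <- function(name, length, cross_section, perimeter = NULL,
                           n_tubes = 1L, tissue_stack_ref = "airway_wall") {
  check_positive(length, "length")
  check_positive(cross_section, "cross_section")
  if (is.null(perimeter)) {
    perimeter <- n_tubes * pi * sqrt(4 * (cross_section / n_tubes) / pi)
  }
  check_positive(perimeter, "perimeter")
  structure(
    list(name = as.character(name), length = length,
         cross_section = cross_section, perimeter = perimeter,
         n_tubes = as.integer(n_tubes),
         hydraulic_diameter = 4 * cross_section / perimeter,
         tissue_stack_ref = tissue_stack_ref),
    class = "airway_segment"
  )
}

#' Build the default segmented airway tree
#'
#' Symmetric-generation conduit: oral cavity, oropharynx, larynx, trachea
#' and pooled bronchial generations 1-4 (the distal boundary sits past
#' generation 4). Dimensions follow published symmetric-airway morphometry
#' (generation diameters/lengths) plus literature oral-cavity and
#' pharynx/larynx volumes; every entry is overridable through the
#' `airway.segments` config key.
#'
#' @param config Optional named list overriding segments: each element
#'   `list(length=, cross_section=, perimeter=, n_tubes=)` keyed by segment
#'   name.
#' @return An `airway_tree`: ordered list of [airway_segment]s with a
#'   `dead_space_volume` attribute (m^3).
#' @export
#' @examples
#' tree <- build_airway_tree()
#' attr(tree, "dead_space_volume") # ~9.5e-5 m^3
build_airway_tree <- function(config = NULL) {
  defaults <- list(
    # upper airway as flattened channels (mouth drawn during puffing):
    # explicit perimeters exceed the circular equivalent
    oral_cavity = list(length = 0.080, cross_section = 3.0e-4,
                       perimeter = 0.112, n_tubes = 1L),
    oropharynx  = list(length = 0.060, cross_section = 2.2e-4,
                       perimeter = 0.080, n_tubes = 1L),
    larynx      = list(length = 0.040, cross_section = 1.8e-4,
                       perimeter = 0.050, n_tubes = 1L),
    trachea     = list(length = 0.120, cross_section = 2.54e-4, n_tubes = 1L),
    bronchi_G1  = list(length = 0.0476, cross_section = 2.34e-4, n_tubes = 2L),
    bronchi_G2  = list(length = 0.0190, cross_section = 2.16e-4, n_tubes = 4L),
    bronchi_G3  = list(length = 0.0076, cross_section = 1.97e-4, n_tubes = 8L),
    bronchi_G4  = list(length = 0.0127, cross_section = 2.54e-4, n_tubes = 16L)
  )
  if (!is.null(config)) {
    bad <- setdiff(names(config), AIRWAY_SEGMENT_NAMES)
    if (length(bad)) stop_config("unknown airway segment(s): ", paste(bad, collapse = ", "))
    for (nm in names(config)) {
      defaults[[nm]] <- utils::modifyList(defaults[[nm]], config[[nm]])
    }
  }
  segs <- lapply(AIRWAY_SEGMENT_NAMES, function(nm) {
    d <- defaults[[nm]]
    airway_segment(nm, d$length, d$cross_section,
                   perimeter = d$perimeter, n_tubes = d$n_tubes)
  })
  dead_space <- sum(vapply(segs, function(s) s$length * s$cross_section, 0))
  structure(segs, class = "airway_tree", dead_space_volume = dead_space)
}

#' @export
print.airway_tree <- function(x, ...) {
  cat("<airway_tree>", length(x), "segments, dead space",
      format(attr(x, "dead_space_volume") * 1e6, digits = 4), "mL\n")
  for (s in x) {
    cat(sprintf("  %-12s L=%6.1f mm  A=%6.2f cm^2  d_h=%5.1f mm\n",
                s$name, s$length * 1e3, s$cross_section * 1e4,
                s$hydraulic_diameter * 1e3))
  }
  invisible(x)
}

#' Serialize / restore an airway tree (exact numeric round trip)
#' @param tree An `airway_tree`.
#' @param path Optional file; when `NULL` the JSON string is returned.
#' @export
airway_tree_to_json <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "airway_tree"))
  x <- lapply(tree, unclass)
  names(x) <- vapply(tree, `[[`, "", "name")
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = I(17))
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' @rdname airway_tree_to_json
#' @param json JSON string or path from [airway_tree_to_json()].
#' @export
airway_tree_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  segs <- lapply(x, function(d) {
    airway_segment(d$name, as.numeric(d$length), as.numeric(d$cross_section),
                   perimeter = as.numeric(d$perimeter),
                   n_tubes = as.integer(d$n_tubes),
                   tissue_stack_ref = d$tissue_stack_ref)
  })
  dead_space <- sum(vapply(segs, function(s) s$length * s$cross_section, 0))
  structure(unname(segs), class = "airway_tree",
            dead_space_volume = dead_space)
}

# Gas-side film coefficient for a segment: Sherwood correlation on the
# hydraulic diameter (Sh = 3.66, fully developed laminar, by default).
segment_film_coeff <- function(segment, species, sherwood = 3.66) {
  if (!is.null(species$gas_film_coeff)) return(species$gas_film_coeff)
  sherwood * species$D_air / segment$hydraulic_diameter
}

#' Simulate one puff (inhalation + exhalation) through the airway tree
#'
#' Operator-split integration: flux-limited upwind advection plus axial
#' dispersion of the lumen concentration, then wall uptake per segment via
#' the implicit layered tissue solver forced by the segment-mean
#' concentration. During inhalation the mouth boundary carries `C_inlet`;
#' mass crossing the distal boundary accumulates in a well-mixed distal
#' reservoir. During exhalation the distal boundary returns the reservoir
#' contents and the mouth outflow is tallied as exhaled mass. Sub-stepping
#' keeps the advection CFL number below 0.9.
#'
#' @param tree An `airway_tree`.
#' @param species A [chemical_species].
#' @param puff_in Inhalation [flow_waveform] (non-negative flow).
#' @param exhale Exhalation [flow_waveform] (non-positive flow), appended
#'   after the inhalation.
#' @param C_inlet Inhaled vapor concentration, kg/m^3.
#' @param dt Outer (uptake-coupling) time step, s.
#' @param cells_per_segment Lumen cells per segment.
#' @param grid_points_per_layer Tissue cells per wall layer.
#' @param dispersion_alpha Axial dispersion coefficient multiplier:
#'   `D_disp = alpha * |u| * d_h` (Taylor-style velocity scaling).
#' @param distal_reservoir_volume Volume of the well-mixed region past the
#'   distal boundary, m^3.
#' @param desorption When `FALSE` (default) wall flux is clamped
#'   non-negative: no re-entrainment of absorbed mass during exhalation.
#' @return An `airway_result` with mass ledger entries (kg): `inhaled_mass`,
#'   `absorbed_mass` (+ `wall_uptake_per_segment`), `exhaled_mass`,
#'   `distal_outflow_mass`, `resident_mass`, plus `times`,
#'   `segment_concentrations` (matrix, segments x saved steps) and
#'   `mouth_outflow_rate` (kg/s, for the room-coupling emission series).
#' @export
simulate_puff <- function(tree, species, puff_in, exhale, C_inlet,
                          dt = 0.005, cells_per_segment = 10L,
                          grid_points_per_layer = 6L,
                          dispersion_alpha = 2.0,
                          distal_reservoir_volume = 3e-4,
                          desorption = FALSE) {
  stopifnot(inherits(tree, "airway_tree"),
            inherits(puff_in, "flow_waveform"),
            inherits(exhale, "flow_waveform"))
  check_nonneg(C_inlet, "C_inlet")
  if (any(puff_in$flow < 0) || any(exhale$flow > 0)) {
    stop_invalid("puff_in must be non-negative and exhale non-positive")
  }
  combined <- concat_waveforms(puff_in, exhale)
  t_end <- max(combined$times)
  Qfun <- function(t) approx(combined$times, combined$flow, xout = t, rule = 2)$y

  nseg <- length(tree)
  ncell <- nseg * cells_per_segment
  seg_idx <- rep(seq_len(nseg), each = cells_per_segment)
  dx <- rep(vapply(tree, function(s) s$length / cells_per_segment, 0),
            each = cells_per_segment)
  A <- rep(vapply(tree, `[[`, 0, "cross_section"), each = cells_per_segment)
  vol <- A * dx
  dh <- rep(vapply(tree, `[[`, 0, "hydraulic_diameter"), each = cells_per_segment)
  wall_area_seg <- vapply(tree, function(s) s$perimeter * s$length, 0)

  # per-segment tissue columns (skipped entirely for an insoluble tracer)
  soluble <- species$K_mucus_air > 0
  if (soluble) {
    steppers <- vector("list", nseg)
    phis <- vector("list", nseg)
    kg_seg <- numeric(nseg)
    for (s in seq_len(nseg)) {
      stk <- airway_wall_stack(species, grid_points_per_layer)
      kg_seg[s] <- segment_film_coeff(tree[[s]], species)
      g <- tissue_grid(stk, kg_seg[s])
      steppers[[s]] <- tissue_make_stepper(g, dt)
      phis[[s]] <- numeric(g$n)
    }
  }

  nt <- as.integer(ceiling(t_end / dt - 1e-9))
  C <- numeric(ncell)               # lumen concentrations
  m_res <- 0                        # distal reservoir mass, kg
  inhaled <- exhaled <- 0
  absorbed_seg <- numeric(nseg)
  A_face <- (A[-ncell] + A[-1]) / 2
  dx_face <- (dx[-ncell] + dx[-1]) / 2

  save_times <- numeric(nt + 1L)
  conc_hist <- matrix(0, nrow = nseg, ncol = nt + 1L)
  mouth_rate <- numeric(nt + 1L)

  for (k in seq_len(nt)) {
    t0 <- (k - 1L) * dt
    t1 <- k * dt
    Q <- Qfun((t0 + t1) / 2)
    u <- Q / A
    Ddisp <- dispersion_alpha * abs(u) * dh
    # CFL-limited sub-stepping for the explicit advection-dispersion update
    rate <- max(abs(u) / dx + 2 * Ddisp / dx^2)
    nsub <- max(1L, as.integer(ceiling(rate * dt / 0.9)))
    dts <- dt / nsub
    for (ss in seq_len(nsub)) {
      # upwind advective face fluxes (kg/s), faces 0..ncell
      if (Q >= 0) {
        Fin <- Q * C_inlet                       # mouth face, inflow
        Fint <- Q * C[-ncell]                    # internal faces, upwind = left
        Fout <- Q * C[ncell]                     # distal face, outflow
      } else {
        Fin <- Q * C[1]                          # mouth face, outflow (Q<0)
        Fint <- Q * C[-1]                        # internal faces, upwind = right
        Fout <- Q * (m_res / distal_reservoir_volume)  # reservoir returns
      }
      Fdisp <- -Ddisp_face(Ddisp) * A_face * diff(C) / dx_face
      Ftot_int <- Fint + Fdisp
      dm <- (c(Fin, Ftot_int) - c(Ftot_int, Fout)) * dts
      C <- C + dm / vol
      if (Q >= 0) {
        inhaled <- inhaled + Fin * dts
        m_res <- m_res + Fout * dts
      } else {
        exhaled <- exhaled - Fin * dts           # Fin < 0: out of the mouth
        m_res <- m_res + Fout * dts              # Fout < 0: reservoir drains
      }
    }
    # wall uptake, one implicit tissue step per segment on mean concentration
    if (soluble) {
      for (s in seq_len(nseg)) {
        cells <- which(seg_idx == s)
        Cm <- sum(C[cells] * vol[cells]) / sum(vol[cells])
        st <- steppers[[s]](phis[[s]], Cm)
        fl <- st$flux_in
        if (!desorption && fl < 0) {
          fl <- 0                       # no re-entrainment from tissue
        } else {
          phis[[s]] <- st$phi
        }
        dm_up <- fl * wall_area_seg[s] * dt
        avail <- sum(C[cells] * vol[cells])
        if (dm_up > 0 && avail > 0) {
          if (dm_up > avail) dm_up <- avail
          C[cells] <- C[cells] * (1 - dm_up / avail)
          absorbed_seg[s] <- absorbed_seg[s] + dm_up
        }
      }
    }
    save_times[k + 1L] <- t1
    conc_hist[, k + 1L] <- vapply(seq_len(nseg), function(s) {
      cells <- which(seg_idx == s)
      sum(C[cells] * vol[cells]) / sum(vol[cells])
    }, 0)
    mouth_rate[k + 1L] <- if (Q < 0) -Q * C[1] else 0
  }

  structure(
    list(times = save_times,
         segment_names = vapply(tree, `[[`, "", "name"),
         segment_concentrations = conc_hist,
         mouth_outflow_rate = mouth_rate,
         inhaled_mass = inhaled,
         absorbed_mass = sum(absorbed_seg),
         wall_uptake_per_segment = stats::setNames(
           absorbed_seg, vapply(tree, `[[`, "", "name")),
         exhaled_mass = exhaled,
         distal_outflow_mass = m_res,
         resident_mass = sum(C * vol)),
    class = "airway_result"
  )
}

# dispersion coefficient at internal faces (mean of adjacent cells)
Ddisp_face <- function(Ddisp) {
  n <- length(Ddisp)
  (Ddisp[-n] + Ddisp[-1]) / 2
}

#' Construct an exposure budget
#'
#' Four-way mass ledger of one puff, as percentages of the inhaled mass.
#' Validates that the fractions close to 100 within 0.1 percentage points.
#'
#' @param absorbed_frac,exhaled_frac,remaining_frac,to_lung_frac Percent of
#'   inhaled mass.
#' @param inhaled_mass Inhaled mass, kg (may be `NA` for literature
#'   fixtures).
#' @return An `exposure_budget`.
#' @export
exposure_budget <- function(absorbed_frac, exhaled_frac, remaining_frac,
                            to_lung_frac, inhaled_mass = NA_real_) {
  f <- c(absorbed_frac, exhaled_frac, remaining_frac, to_lung_frac)
  if (any(f < 0) || any(f > 100)) {
    stop_invalid("budget fractions must lie in [0, 100]")
  }
  if (abs(sum(f) - 100) > 0.1) {
    stop_invalid("budget fractions must sum to 100 within 0.1 pp, got ",
                 format(sum(f), digits = 6))
  }
  structure(list(absorbed_frac = absorbed_frac, exhaled_frac = exhaled_frac,
                 remaining_frac = remaining_frac, to_lung_frac = to_lung_frac,
                 inhaled_mass = inhaled_mass),
            class = "exposure_budget")
}

#' @export
print.exposure_budget <- function(x, ...) {
  cat("<exposure_budget> (% of inhaled)\n")
  cat(sprintf("  absorbed %5.1f | exhaled %5.1f | remaining %5.1f | to lung %5.1f\n",
              x$absorbed_frac, x$exhaled_frac, x$remaining_frac, x$to_lung_frac))
  invisible(x)
}

#' Budget fractions of a simulated puff
#'
#' @param result An `airway_result` from [simulate_puff()].
#' @return An [exposure_budget()].
#' @export
budget <- function(result) {
  stopifnot(inherits(result, "airway_result"))
  if (result$inhaled_mass <= 0) {
    stop_invalid("undefined budget: inhaled mass is zero")
  }
  f <- 100 / result$inhaled_mass
  exposure_budget(result$absorbed_mass * f, result$exhaled_mass * f,
                  result$resident_mass * f, result$distal_outflow_mass * f,
                  inhaled_mass = result$inhaled_mass)
}

#' Published reference budgets for the three puff profiles
#'
#' Absorbed / exhaled / remaining-in-tract / to-lung fractions (% of the
#' inhaled mass) reported by a published CFD study of e-cigarette cannabis
#' vaping on a CT-derived respiratory tract, bundled as fixtures for the
#' dose-chain accounting (they embed 3-D geometry effects a reduced-order
#' model does not reproduce). Nicotine rows carry the printed
#' remaining-in-tract fractions only; unprinted entries are `NA`.
#'
#' @param species `"thc"` or `"nicotine"`.
#' @return Data frame with columns `puff`, `absorbed`, `exhaled`,
#'   `remaining`, `to_lung` (percent).
#' @export
#' @examples
#' reference_budgets()          # THC: short/long/post puff rows
reference_budgets <- function(species = c("thc", "nicotine")) {
  species <- match.arg(species)
  if (species == "thc") {
    data.frame(
      puff = c("short_puff", "long_puff", "post_puff"),
      absorbed = c(84.1, 85.0, 64.4),
      exhaled = c(6.6, 6.6, 3.2),
      remaining = c(9.3, 8.4, 0.0),
      to_lung = c(0.0, 0.0, 32.4)
    )
  } else {
    data.frame(
      puff = c("short_puff", "long_puff"),
      absorbed = NA_real_,
      exhaled = NA_real_,
      remaining = c(1.6, 1.4),
      to_lung = NA_real_
    )
  }
}
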