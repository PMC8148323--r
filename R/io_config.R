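# Scenario configuration parsing, validation, pipeline orchestration and
# the run manifest.

# Allowed keys per config section; unknown keys are rejected rather than
# silently absorbed (typo protection).
CONFIG_SCHEMA <- list(
  seed = NULL,
  window_s = NULL,
  species = c("name", "molar_mass", "D_air", "D_layer", "K_mucus_air",
              "K_skin_air", "gas_film_coeff"),
  puff = c("kind", "duration_s", "volume_m3", "shape", "dt_s"),
  exhalation = c("duration_s", "volume_m3"),
  airway = c("C_inlet", "dispersion_alpha", "cells_per_segment",
             "distal_reservoir_volume", "segments"),
  tissue = c("grid_points_per_layer"),
  room = c("volume", "ventilation_flow", "supply_velocity", "supply_temp",
           "occupant_separation", "near_field_volume", "interzonal_flow",
           "direct_transfer_fraction", "declared_ach"),
  breathing = c("minute_volume_m3", "period_s"),
  skin = c("exposed_area_m2", "deposition_velocity_m_s"),
  dose_chain = c("oil_mass_g", "thc_mass_fraction", "puffs_per_fill",
                 "puffs_per_session")
)

#' Default scenario configuration
#'
#' The post-puff worst-case scenario: THC defaults, 1.34 s triangular post
#' puff with a 2.5 s forceful exhalation, the 27 m^3 displacement-ventilated
#' room with the calibrated near-field, nasal breathing at 6 L/min with a
#' 4 s period, face-only skin exposure, and the 0.5 g / 80% / 100-puff
#' e-liquid dose assumptions.
#'
#' @return Named scenario list.
#' @export
default_scenario <- function() {
  sp <- thc_defaults()
  list(
    seed = 1L,
    window_s = 12,
    species = list(name = sp$name, molar_mass = sp$molar_mass,
                   D_air = sp$D_air, D_layer = sp$D_layer,
                   K_mucus_air = sp$K_mucus_air, K_skin_air = sp$K_skin_air,
                   gas_film_coeff = NULL),
    puff = list(kind = "post_puff", duration_s = 1.34, volume_m3 = 55e-6,
                shape = "triangular", dt_s = 0.005),
    exhalation = list(duration_s = 2.5, volume_m3 = NULL),
    airway = list(C_inlet = 1.0, dispersion_alpha = 2.0,
                  cells_per_segment = 10L, distal_reservoir_volume = 3e-4,
                  segments = NULL),
    tissue = list(grid_points_per_layer = 6L),
    room = list(volume = 27, ventilation_flow = 0.018, supply_velocity = 0.2,
                supply_temp = 22, occupant_separation = 1.0,
                near_field_volume = 0.005, interzonal_flow = 0.001,
                direct_transfer_fraction = CALIBRATED_DIRECT_TRANSFER,
                declared_ach = NULL),
    breathing = list(minute_volume_m3 = 6e-3, period_s = 4),
    skin = list(exposed_area_m2 = 0.025,
                deposition_velocity_m_s = CALIBRATED_DEPOSITION_VELOCITY),
    dose_chain = list(oil_mass_g = 0.5, thc_mass_fraction = 0.80,
                      puffs_per_fill = 100, puffs_per_session = 20)
  )
}

validate_config_keys <- function(config) {
  bad <- setdiff(names(config), names(CONFIG_SCHEMA))
  if (length(bad)) stop_config("unknown config key(s): ", paste(bad, collapse = ", "))
  for (sec in names(config)) {
    allowed <- CONFIG_SCHEMA[[sec]]
    if (is.null(allowed)) next
    if (!is.null(config[[sec]]) && !is.list(config[[sec]])) {
      stop_config("config section `", sec, "` must be a mapping")
    }
    bad <- setdiff(names(config[[sec]]), allowed)
    if (length(bad)) {
      stop_config("unknown key(s) in `", sec, "`: ", paste(bad, collapse = ", "))
    }
  }
  invisible(config)
}

merge_defaults <- function(defaults, config) {
  for (sec in names(config)) {
    if (is.list(config[[sec]]) && is.list(defaults[[sec]])) {
      for (k in names(config[[sec]])) defaults[[sec]][[k]] <- config[[sec]][[k]]
    } else {
      defaults[[sec]] <- config[[sec]]
    }
  }
  defaults
}

#' Load and validate a scenario configuration
#'
#' Reads a YAML scenario file (or takes an already-parsed list), rejects
#' unknown keys, fills defaults from [default_scenario()], and runs every
#' type constructor once so each invariant is checked at load time with an
#' error naming the offending field.
#'
#' @param path YAML file path, or a named list.
#' @return The resolved, validated scenario list (class
#'   `vapedose_scenario`).
#' @export
load_config <- function(path) {
  config <- if (is.character(path)) {
    if (!file.exists(path)) stop_config("config file not found: ", path)
    yaml::read_yaml(path)
  } else if (is.list(path)) path
  else stop_config("`path` must be a file path or a named list")
  if (is.null(config)) config <- list()
  validate_config_keys(config)
  resolved <- merge_defaults(default_scenario(), config)
  # touch every constructor so invariants fail loudly here
  sp <- resolved_species(resolved)
  build_airway_tree(resolved$airway$segments)
  do.call(room_scenario, resolved_room_args(resolved))
  skin_stack(sp, exposed_area = resolved$skin$exposed_area_m2,
             deposition_velocity = resolved$skin$deposition_velocity_m_s,
             grid_points_per_layer = resolved$tissue$grid_points_per_layer)
  build_nasal_cycle(resolved$breathing$minute_volume_m3,
                    resolved$breathing$period_s)
  structure(drop_nulls(resolved), class = c("vapedose_scenario", "list"))
}

# canonical form: absent and NULL optional keys are equivalent
drop_nulls <- function(x) {
  if (!is.list(x)) return(x)
  x <- x[!vapply(x, is.null, TRUE)]
  lapply(x, drop_nulls)
}

resolved_species <- function(config) {
  s <- config$species
  chemical_species(s$name, s$molar_mass, s$D_air, s$D_layer,
                   s$K_mucus_air, s$K_skin_air,
                   gas_film_coeff = s$gas_film_coeff)
}

resolved_room_args <- function(config) {
  r <- config$room
  list(volume = r$volume, ventilation_flow = r$ventilation_flow,
       supply_velocity = r$supply_velocity, supply_temp = r$supply_temp,
       occupant_separation = r$occupant_separation,
       near_field_volume = r$near_field_volume,
       interzonal_flow = r$interzonal_flow,
       direct_transfer_fraction = r$direct_transfer_fraction,
       declared_ach = r$declared_ach)
}

#' Write a resolved scenario back to YAML
#'
#' A dumped config reloads to an identical resolved scenario.
#'
#' @param config A resolved scenario from [load_config()].
#' @param path Output path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 17L)
  invisible(path)
}

config_hash <- function(config) {
  # content hash over the canonical serialization (no external digest dep)
  raw <- serialize(unclass(config), NULL, version = 3)
  sprintf("%08x-%d", sum(as.integer(raw) * seq_along(raw)) %% .Machine$integer.max,
          length(raw))
}

#' Run the full first-to-secondhand pipeline
#'
#' Stage order: puff and exhalation waveforms, airway transport with wall
#' uptake, exposure budget; the airway stage's mouth-outflow series scaled
#' to the dose-chain exhaled mass becomes the room stage's emission (the
#' quasi-coupling), then two-zone room dispersion, bystander nasal
#' inhalation, dermal uptake, and the dose-chain report using the
#' simulated budget and secondhand fractions.
#'
#' @param config A scenario list or path accepted by [load_config()].
#' @param out_dir Optional directory; when given, CSV series and JSON
#'   reports are written and listed in the manifest.
#' @return A `run_manifest`: `config_hash`, `package_version`, `seed`,
#'   `warnings`, `outputs` plus the stage results (`airway`, `budget`,
#'   `room`, `dermal`, `dose_report`, `secondhand`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (!inherits(config, "vapedose_scenario")) config <- load_config(config)
  warnings <- character(0)
  species <- resolved_species(config)
  dt <- config$puff$dt_s

  puff <- build_puff(config$puff$kind, config$puff$duration_s,
                     config$puff$volume_m3, config$puff$shape, dt = dt)
  exh_vol <- config$exhalation$volume_m3
  if (is.null(exh_vol)) exh_vol <- config$puff$volume_m3
  exhale <- build_exhalation(exh_vol, config$exhalation$duration_s, dt = dt)

  tree <- build_airway_tree(config$airway$segments)
  airway <- simulate_puff(tree, species, puff, exhale,
                          C_inlet = config$airway$C_inlet, dt = dt,
                          cells_per_segment = config$airway$cells_per_segment,
                          grid_points_per_layer = config$tissue$grid_points_per_layer,
                          dispersion_alpha = config$airway$dispersion_alpha,
                          distal_reservoir_volume = config$airway$distal_reservoir_volume)
  bdg <- budget(airway)

  room <- do.call(room_scenario, resolved_room_args(config))
  ach <- withCallingHandlers(
    nominal_ach(room),
    warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })

  cycle <- build_nasal_cycle(config$breathing$minute_volume_m3,
                             config$breathing$period_s)
  emission <- list(times = airway$times, rate = airway$mouth_outflow_rate)
  series <- simulate_room(room, emission, cycle,
                          window = config$window_s, dt = dt)
  ledger <- room_mass_ledger(series)
  emitted <- ledger$emitted

  skin <- skin_stack(species, exposed_area = config$skin$exposed_area_m2,
                     deposition_velocity = config$skin$deposition_velocity_m_s,
                     grid_points_per_layer = config$tissue$grid_points_per_layer)
  dermal <- simulate_dermal(skin, species,
                            list(times = series$times, conc = series$C_near),
                            window = config$window_s, dt = dt)
  dermal_mass <- dermal$absorbed_mass[length(dermal$absorbed_mass)]

  sh_inhaled_pct <- if (emitted > 0) 100 * ledger$inhaled / emitted else 0
  sh_dermal_pct <- if (emitted > 0) 100 * dermal_mass / emitted else 0

  dc <- config$dose_chain
  report <- dose_chain(dose_chain_inputs(
    oil_mass = dc$oil_mass_g, thc_mass_fraction = dc$thc_mass_fraction,
    puffs_per_fill = dc$puffs_per_fill,
    puffs_per_session = dc$puffs_per_session,
    budget = bdg,
    secondhand_inhaled_frac_of_exhaled = min(sh_inhaled_pct, 100),
    secondhand_dermal_frac_of_exhaled = min(sh_dermal_pct, 100)),
    rounding = "full_precision")

  outputs <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    f1 <- file.path(out_dir, "exposure_series.csv")
    write_exposure_csv(series, f1)
    f2 <- file.path(out_dir, "dose_report.json")
    dose_report_to_json(report, f2)
    f3 <- file.path(out_dir, "airway_segments.csv")
    seg <- data.frame(time_s = airway$times,
                      t(airway$segment_concentrations))
    names(seg) <- c("time_s", airway$segment_names)
    utils::write.csv(seg, f3, row.names = FALSE, quote = FALSE)
    outputs <- c(f1, f2, f3)
  }

  structure(
    list(config_hash = config_hash(config),
         package_version = as.character(utils::packageVersion("vapedose")),
         seed = config$seed,
         warnings = warnings,
         nominal_ach = ach,
         outputs = outputs,
         airway = airway, budget = bdg, room_series = series,
         room_ledger = ledger, dermal = dermal,
         secondhand = list(inhaled_pct_of_exhaled = sh_inhaled_pct,
                           dermal_pct_of_exhaled = sh_dermal_pct),
         dose_report = report),
    class = "run_manifest"
  )
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest>", x$config_hash, "vapedose", x$package_version, "\n")
  cat("  budget:"); print(x$budget)
  cat(sprintf("  secondhand: inhaled %.2f%%, dermal %.2f%% of exhaled\n",
              x$secondhand$inhaled_pct_of_exhaled,
              x$secondhand$dermal_pct_of_exhaled))
  if (length(x$warnings)) cat("  warnings:", x$warnings, sep = "\n    ")
  invisible(x)
}
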