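# Transdermal uptake of vapor-phase THC at the bystander's exposed skin:
# gas-side deposition film in series with 1-D diffusion through skin
# layers, reusing the layered tissue solver with a skin parameterization.

#' Construct a skin stack
#'
#' Surface lipid / stratum corneum / viable epidermis by default, with the
#' species' skin:air partition coefficient on the first layer, an exposed
#' area (face-only default for the short-range plume scenario) and a
#' gas-side deposition velocity. The default deposition velocity is the
#' calibrated value produced by [calibrate_near_field()].
#'
#' @param species A [chemical_species] supplying skin-layer diffusivities
#'   and `K_skin_air`.
#' @param exposed_area Exposed skin area, m^2 (default 0.025: face).
#' @param deposition_velocity Gas-side mass-transfer coefficient, m/s.
#' @param grid_points_per_layer Cells per layer for the solver.
#' @return A `skin_stack`.
#' @export
skin_stack <- function(species = thc_defaults(),
                       exposed_area = 0.025,
                       deposition_velocity = CALIBRATED_DEPOSITION_VELOCITY,
                       grid_points_per_layer = 6L) {
  check_positive(exposed_area, "exposed_area")
  check_positive(deposition_velocity, "deposition_velocity")
  stack <- tissue_stack(
    list(
      tissue_layer("surface_lipid", 1e-6, species$D_layer$surface_lipid,
                   partition_vs_previous = species$K_skin_air),
      tissue_layer("stratum_corneum", 15e-6, species$D_layer$stratum_corneum),
      tissue_layer("viable_epidermis", 50e-6, species$D_layer$viable_epidermis)
    ),
    grid_points_per_layer = grid_points_per_layer
  )
  structure(list(stack = stack, exposed_area = exposed_area,
                 deposition_velocity = deposition_velocity),
            class = "skin_stack")
}

#' Simulate transdermal uptake under a time-varying air concentration
#'
#' Runs the layered diffusion solver with the skin parameterization and the
#' deposition velocity as the gas-side film coefficient. Absorbed mass is
#' `exposed_area` times the cumulative flux; it never exceeds the delivery
#' bound `exposed_area * deposition_velocity * integral(C dt)`.
#'
#' @param skin A [skin_stack].
#' @param species A [chemical_species].
#' @param C_air_series Constant concentration (kg/m^3) or a list with
#'   `times` and `conc`/`flow`.
#' @param window Exposure window, s.
#' @param dt Time step, s.
#' @return List with `times`, `flux` (kg/m^2/s), `absorbed_mass`
#'   (cumulative, kg) and the underlying `wall_flux_result`.
#' @export
simulate_dermal <- function(skin, species, C_air_series, window, dt = 0.01) {
  stopifnot(inherits(skin, "skin_stack"))
  res <- solve_tissue_diffusion(skin$stack, species, C_air_series,
                                t_end = window, dt = dt,
                                gas_film_coeff = skin$deposition_velocity)
  list(times = res$times,
       flux = res$flux,
       absorbed_mass = res$cumulative_uptake * skin$exposed_area,
       wall_flux = res)
}

#' Steady-state dermal flux (series-resistance closed form)
#'
#' Gas-side deposition film plus per-layer resistances against the
#' perfect-sink base: `flux = C_air / (1/v_d + sum L_i/(D_i K_cum_i))`.
#'
#' @param skin A [skin_stack].
#' @param C_air Air concentration, kg/m^3.
#' @return Flux, kg/m^2/s.
#' @export
steady_dermal_flux <- function(skin, C_air) {
  stopifnot(inherits(skin, "skin_stack"))
  steady_stack_flux(skin$stack, C_air,
                    gas_film_coeff = skin$deposition_velocity)
}
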