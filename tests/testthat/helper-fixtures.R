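# Shared fixtures: built in code at test time, no stored data.

thc <- thc_defaults()
nicotine <- nicotine_defaults()

default_tree <- build_airway_tree()

# One puff through the default tree at the default resolution.
run_default_puff <- function(kind, species = thc, C_inlet = 1, ...) {
  dur <- switch(kind, short_puff = 2.43, long_puff = 5.0, post_puff = 1.34)
  exd <- if (kind == "post_puff") 2.5 else 1.8
  puff <- build_puff(kind, dur, 55e-6)
  exhale <- build_exhalation(55e-6, exd)
  simulate_puff(default_tree, species, puff, exhale, C_inlet = C_inlet, ...)
}

# Airway run for a synthetic scenario config (as from random_scenario()).
run_scenario_puff <- function(sc) {
  sp <- chemical_species(sc$species$name, sc$species$molar_mass,
                         sc$species$D_air, sc$species$D_layer,
                         sc$species$K_mucus_air, sc$species$K_skin_air)
  puff <- build_puff(sc$puff$kind, sc$puff$duration_s, sc$puff$volume_m3,
                     sc$puff$shape)
  exhale <- build_exhalation(sc$puff$volume_m3, sc$exhalation$duration_s)
  simulate_puff(default_tree, sp, puff, exhale,
                C_inlet = sc$airway$C_inlet,
                dispersion_alpha = sc$airway$dispersion_alpha)
}

mass_closure_error <- function(r) {
  abs(r$inhaled_mass - r$absorbed_mass - r$exhaled_mass -
        r$resident_mass - r$distal_outflow_mass) / r$inhaled_mass
}

# trapezoid over the inhalation (positive) part of a waveform
trapz_pos <- function(w) {
  f <- pmax(w$flow, 0)
  n <- length(w$times)
  sum(diff(w$times) * (f[-1] + f[-n]) / 2)
}

# multiplicative gaussian noise with a private RNG stream
with_noise <- function(x, sd, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  x * (1 + stats::rnorm(length(x), 0, sd))
}

# recovery harness fixture: liquid-side-controlled uptake so K is identifiable
recovery_stack <- tissue_stack(
  list(tissue_layer("mucus", 5e-5, 4e-10, 1000)),
  grid_points_per_layer = 8L)
recovery_species <- thc_defaults()

recover_from <- function(K_true, noise_sd = 0, seed = 1) {
  st <- recovery_stack
  st$layers[[1]]$partition_vs_previous <- K_true
  fl <- solve_tissue_diffusion(st, recovery_species, 1e-4, t_end = 2,
                               dt = 0.02, gas_film_coeff = 0.05)$flux
  if (noise_sd > 0) fl <- with_noise(fl, noise_sd, seed)
  recover_partition_coefficient(fl, recovery_stack, recovery_species,
                                C_air = 1e-4, t_end = 2, dt = 0.02,
                                gas_film_coeff = 0.05)
}
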