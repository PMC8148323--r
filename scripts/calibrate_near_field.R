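#!/usr/bin/env Rscript
# Calibrates the two near-field parameters of the secondhand-exposure model
# (direct_transfer_fraction of the exhaled jet into the breathing zone, and
# the skin deposition velocity) so that the default post-puff scenario
# reproduces the reference secondhand fractions: the bystander inhales 5.9%
# and dermally absorbs 2.6% of the exhaled mass over the 12 s window.
# The resulting values are frozen in R/calibration_defaults.R.

library(vapedose)

cfg <- default_scenario()
species <- thc_defaults()
dt <- cfg$puff$dt_s

puff <- build_puff(cfg$puff$kind, cfg$puff$duration_s, cfg$puff$volume_m3,
                   cfg$puff$shape, dt = dt)
exhale <- build_exhalation(cfg$puff$volume_m3, cfg$exhalation$duration_s,
                           dt = dt)
tree <- build_airway_tree()
airway <- simulate_puff(tree, species, puff, exhale,
                        C_inlet = cfg$airway$C_inlet, dt = dt)
emission <- list(times = airway$times, rate = airway$mouth_outflow_rate)

scenario <- room_scenario()                 # defaults except the fraction
cycle <- build_nasal_cycle(cfg$breathing$minute_volume_m3,
                           cfg$breathing$period_s)
skin <- skin_stack(species, exposed_area = cfg$skin$exposed_area_m2)

cal <- calibrate_near_field(scenario, emission, cycle, skin, species,
                            window = cfg$window_s, dt = dt,
                            target_inhaled_pct = 5.9,
                            target_dermal_pct = 2.6)

cat(sprintf("direct_transfer_fraction : %.10f\n", cal$direct_transfer_fraction))
cat(sprintf("deposition_velocity      : %.10e m/s\n", cal$deposition_velocity))
cat(sprintf("achieved inhaled         : %.4f %% of exhaled\n",
            cal$achieved_inhaled_pct))
cat(sprintf("achieved dermal          : %.4f %% of exhaled\n",
            cal$achieved_dermal_pct))
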