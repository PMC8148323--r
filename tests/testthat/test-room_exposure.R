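test_that("nominal ACH follows Q*3600/V and flags inconsistent declarations", {
  expect_equal(nominal_ach(room_scenario()), 2.4, tolerance = 1e-12)
  expect_identical(nominal_ach(room_scenario(ventilation_flow = 0)), 0)
  # the flow consistent with a declared 0.6 1/h in 27 m^3
  expect_equal(nominal_ach(room_scenario(ventilation_flow = 0.0045)), 0.6,
               tolerance = 1e-12)
  expect_warning(nominal_ach(room_scenario(declared_ach = 0.6)), "declares")
  expect_silent(nominal_ach(room_scenario(ventilation_flow = 0.0045,
                                          declared_ach = 0.6)))
})

test_that("well-mixed pulse decays as exp(-Q t / V)", {
  sc <- room_scenario()
  tau <- sc$volume / sc$ventilation_flow        # 1500 s
  ser <- simulate_room(sc, emission = 1e-6, cycle = NULL, window = tau,
                       dt = 0.25, mode = "well_mixed")
  n <- length(ser$times)
  inv <- ser$C_far[n] * sc$volume
  expect_equal(inv, 1e-6 / exp(1), tolerance = 1e-3)
  # decay rate by log-linear regression on the tail
  keep <- ser$times > 0
  fit <- stats::lm(log(ser$C_far[keep]) ~ ser$times[keep])
  expect_equal(-unname(stats::coef(fit)[2]), sc$ventilation_flow / sc$volume,
               tolerance = 1e-3)
})

test_that("two-zone model conserves mass with emission and breathing", {
  sc <- room_scenario(direct_transfer_fraction = 0.9)
  cyc <- build_nasal_cycle()
  em <- build_puff("custom", 2.5, 1)      # unit-mass pulse over 2.5 s
  ser <- simulate_room(sc, list(times = em$times, rate = em$flow), cyc,
                       window = 12, dt = 0.01)
  led <- room_mass_ledger(ser)
  resid <- led$emitted - led$near_inventory - led$far_inventory -
    led$exhausted - led$inhaled
  expect_lt(abs(resid) / led$emitted, 1e-6)
  expect_true(all(diff(ser$exhausted_cumulative) >= 0))
  expect_true(all(ser$C_near >= 0) && all(ser$C_far >= 0))

  # zero emission -> identically zero series
  ser0 <- simulate_room(sc, 0, cyc, window = 5, dt = 0.01)
  expect_identical(max(ser0$C_near), 0)
  expect_identical(max(ser0$inhaled_cumulative), 0)
})

test_that("soft exhalation never reaches the bystander's breathing zone", {
  sc <- room_scenario(direct_transfer_fraction = 0)
  cyc <- build_nasal_cycle()
  em <- build_puff("custom", 1.8, 1)
  ser <- simulate_room(sc, list(times = em$times, rate = em$flow), cyc,
                       window = 12, dt = 0.01)
  expect_identical(max(ser$C_near), 0)
  expect_identical(ser$inhaled_cumulative[length(ser$times)], 0)
})

test_that("inhaled mass does not increase with ventilation", {
  cyc <- build_nasal_cycle()
  em <- build_puff("custom", 2.5, 1)
  doses <- vapply(c(0.005, 0.018, 0.05), function(Q) {
    sc <- room_scenario(ventilation_flow = Q, direct_transfer_fraction = 0.9)
    ser <- simulate_room(sc, list(times = em$times, rate = em$flow), cyc,
                         window = 12, dt = 0.01)
    ser$inhaled_cumulative[length(ser$times)]
  }, 0)
  expect_true(all(diff(doses) <= 1e-12))
  # in a well-mixed room the dependence is strict
  doses_wm <- vapply(c(0.005, 0.05), function(Q) {
    sc <- room_scenario(ventilation_flow = Q)
    ser <- simulate_room(sc, list(times = em$times, rate = em$flow), cyc,
                         window = 600, dt = 0.05, mode = "well_mixed")
    ser$inhaled_cumulative[length(ser$times)]
  }, 0)
  expect_lt(doses_wm[2], doses_wm[1])
})

test_that("bystander inhaled mass integrates concentration times inflow", {
  cyc <- build_nasal_cycle(minute_volume = 6e-3, period = 4)
  # constant concentration: dose = C * inhaled air volume
  sc <- room_scenario()
  ser <- simulate_room(sc, 0, cyc, window = 12, dt = 0.01)
  C0 <- 2e-6
  ser$C_near <- rep(C0, length(ser$times))
  v_air <- 3 * (6e-3 / 60) * 4     # 3 breaths x tidal volume (MV/60 * period)
  got <- bystander_inhaled_mass(ser, cyc, window = 12)
  expect_equal(got, C0 * v_air, tolerance = 0.01)
  # zero concentration -> zero dose
  ser$C_near <- numeric(length(ser$times))
  expect_identical(bystander_inhaled_mass(ser, cyc, window = 12), 0)
  expect_error(bystander_inhaled_mass(ser, cyc, window = 99),
               class = "vapedose_invalid_argument")
})

test_that("calibrated near-field reproduces the reference secondhand fractions", {
  cfg <- default_scenario()
  m <- run_pipeline(cfg)
  expect_equal(m$secondhand$inhaled_pct_of_exhaled, 5.9, tolerance = 0.5 / 5.9)
  expect_equal(m$secondhand$dermal_pct_of_exhaled, 2.6, tolerance = 0.3 / 2.6)
})
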