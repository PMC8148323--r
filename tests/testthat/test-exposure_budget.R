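post_budget <- exposure_budget(64.4, 3.2, 0, 32.4)
post_inputs <- dose_chain_inputs(
  oil_mass = 0.5, thc_mass_fraction = 0.80, puffs_per_fill = 100,
  puffs_per_session = 20, budget = post_budget,
  secondhand_inhaled_frac_of_exhaled = 5.9,
  secondhand_dermal_frac_of_exhaled = 2.6
)

test_that("per-puff dose arithmetic", {
  expect_equal(per_puff_dose(0.5, 0.80, 100), 4, tolerance = 1e-12)
  expect_equal(per_puff_dose(1, 1.0, 1), 1000, tolerance = 1e-12)
  expect_equal(per_puff_dose(0.5, 0.80, 200), 2, tolerance = 1e-12)
  expect_error(per_puff_dose(0.5, 0.80, 0), class = "vapedose_invalid_argument")
})

test_that("session emission is the plain product", {
  expect_equal(session_emission(0.1, 20), 2, tolerance = 1e-12)
  expect_identical(session_emission(0.37, 0), 0)
  expect_equal(session_emission(0.128, 20), 2.56, tolerance = 1e-12)
})

test_that("printed-precision dose chain reproduces the reference numbers", {
  rep <- dose_chain(post_inputs, rounding = "paper_sigfigs")
  expect_equal(rep$per_puff_dose, 4, tolerance = 1e-12)
  expect_equal(rep$absorbed_per_puff, 2.6, tolerance = 1e-12)
  expect_equal(rep$lung_or_remaining_per_puff, 1.3, tolerance = 1e-12)
  expect_equal(rep$exhaled_per_puff, 0.1, tolerance = 1e-12)
  expect_equal(rep$session_emission, 2, tolerance = 1e-12)
  expect_equal(rep$overall_inhaled_frac, 0.19, tolerance = 1e-12)
  expect_equal(rep$overall_dermal_frac, 0.08, tolerance = 1e-12)
  expect_equal(rep$bystander_inhaled_per_puff, 7.6, tolerance = 1e-12)
  expect_equal(rep$bystander_dermal_per_puff, 3.2, tolerance = 1e-12)
})

test_that("full-precision chain is the exact arithmetic", {
  rep <- dose_chain(post_inputs, rounding = "full_precision")
  expect_equal(rep$exhaled_per_puff, 4 * 0.032, tolerance = 1e-12)
  expect_equal(rep$bystander_inhaled_per_puff, 4000 * 0.032 * 0.059,
               tolerance = 1e-12)
  expect_equal(rep$bystander_dermal_per_puff, 4000 * 0.032 * 0.026,
               tolerance = 1e-12)
  expect_equal(rep$session_emission, 2.56, tolerance = 1e-12)
  expect_equal(rep$absorbed_per_puff + rep$exhaled_per_puff +
                 rep$lung_or_remaining_per_puff, 4, tolerance = 1e-12)

  # printed mode equals full precision after rounding to printed figures
  pp <- dose_chain(post_inputs, rounding = "paper_sigfigs")
  expect_identical(signif(rep$absorbed_per_puff, 2), pp$absorbed_per_puff)
  expect_identical(signif(rep$lung_or_remaining_per_puff, 2),
                   pp$lung_or_remaining_per_puff)
  expect_identical(signif(rep$exhaled_per_puff, 1), pp$exhaled_per_puff)
  expect_identical(round(rep$overall_inhaled_frac, 2), pp$overall_inhaled_frac)
  expect_identical(round(rep$overall_dermal_frac, 2), pp$overall_dermal_frac)
})

test_that("zero fractions zero every downstream dose", {
  b <- exposure_budget(100, 0, 0, 0)
  inp <- dose_chain_inputs(budget = b)
  rep <- dose_chain(inp, rounding = "full_precision")
  expect_identical(rep$exhaled_per_puff, 0)
  expect_identical(rep$bystander_inhaled_per_puff, 0)
  expect_identical(rep$bystander_dermal_per_puff, 0)
  expect_identical(rep$session_emission, 0)
})

test_that("dose chain is homogeneous of degree 1 in the per-puff dose", {
  double_oil <- post_inputs
  double_oil$oil_mass <- 1.0
  r1 <- dose_chain(post_inputs, rounding = "full_precision")
  r2 <- dose_chain(double_oil, rounding = "full_precision")
  for (f in c("per_puff_dose", "absorbed_per_puff", "exhaled_per_puff",
              "lung_or_remaining_per_puff", "session_emission",
              "bystander_inhaled_per_puff", "bystander_dermal_per_puff")) {
    expect_equal(r2[[f]], 2 * r1[[f]], tolerance = 1e-12)
  }
  # fractions of the inhaled dose are scale-free
  expect_equal(r2$overall_inhaled_frac, r1$overall_inhaled_frac,
               tolerance = 1e-12)
})
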