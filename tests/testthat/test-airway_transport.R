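test_that("default tree reaches bronchial generation 4 and validates geometry", {
  expect_identical(default_tree[[length(default_tree)]]$name, "bronchi_G4")
  expect_gt(attr(default_tree, "dead_space_volume"), 0)
  expect_error(airway_segment("trachea", 0, 2.5e-4),
               class = "vapedose_invalid_argument")
  back <- airway_tree_from_json(airway_tree_to_json(default_tree))
  for (i in seq_along(default_tree)) {
    expect_identical(back[[i]]$length, default_tree[[i]]$length)
    expect_identical(back[[i]]$cross_section, default_tree[[i]]$cross_section)
    expect_identical(back[[i]]$perimeter, default_tree[[i]]$perimeter)
  }
})

test_that("insoluble tracer is never absorbed and the budget still closes", {
  sp0 <- thc
  sp0$K_mucus_air <- 0
  r <- run_default_puff("short_puff", species = sp0)
  expect_identical(r$absorbed_mass, 0)
  b <- budget(r)
  expect_identical(b$absorbed_frac, 0)
  expect_equal(b$exhaled_frac + b$remaining_frac + b$to_lung_frac, 100,
               tolerance = 1e-3)
})

test_that("zero inlet concentration produces zero masses and no budget", {
  r <- run_default_puff("short_puff", C_inlet = 0)
  expect_identical(r$inhaled_mass, 0)
  expect_identical(r$absorbed_mass, 0)
  expect_identical(r$exhaled_mass, 0)
  expect_error(budget(r), class = "vapedose_invalid_argument")
})

test_that("transport-uptake system is linear in the inlet concentration", {
  r1 <- run_default_puff("short_puff", C_inlet = 1)
  r2 <- run_default_puff("short_puff", C_inlet = 2)
  for (f in c("inhaled_mass", "absorbed_mass", "exhaled_mass",
              "resident_mass", "distal_outflow_mass")) {
    expect_equal(r2[[f]], 2 * r1[[f]], tolerance = 1e-10)
  }
})

test_that("puff-profile orderings match the expected transport physics", {
  bs <- budget(run_default_puff("short_puff"))
  bl <- budget(run_default_puff("long_puff"))
  bp <- budget(run_default_puff("post_puff"))
  # longer draw at fixed volume -> more wall residence -> more absorbed
  expect_gte(bl$absorbed_frac, bs$absorbed_frac)
  # high-flow post puff drives vapor deeper and leaves less time to absorb
  expect_gt(bp$to_lung_frac, bs$to_lung_frac)
  expect_lt(bp$absorbed_frac, bs$absorbed_frac)
})

test_that("mass ledger closes for the three default scenarios", {
  for (kind in c("short_puff", "long_puff", "post_puff")) {
    r <- run_default_puff(kind)
    expect_lt(mass_closure_error(r), 0.005)
    b <- budget(r)
    expect_equal(b$absorbed_frac + b$exhaled_frac + b$remaining_frac +
                   b$to_lung_frac, 100, tolerance = 0.1)
  }
})

test_that("budget fractions pass through reference masses unchanged", {
  # a result carrying the published short-puff masses on 100 units inhaled
  r <- structure(list(inhaled_mass = 100, absorbed_mass = 84.1,
                      exhaled_mass = 6.6, resident_mass = 9.3,
                      distal_outflow_mass = 0), class = "airway_result")
  b <- budget(r)
  expect_equal(b$absorbed_frac, 84.1, tolerance = 1e-12)
  expect_equal(b$exhaled_frac, 6.6, tolerance = 1e-12)
  expect_equal(b$remaining_frac, 9.3, tolerance = 1e-12)
  expect_identical(b$to_lung_frac, 0)

  # everything exhaled
  r2 <- structure(list(inhaled_mass = 1, absorbed_mass = 0, exhaled_mass = 1,
                       resident_mass = 0, distal_outflow_mass = 0),
                  class = "airway_result")
  b2 <- budget(r2)
  expect_identical(b2$exhaled_frac, 100)

  expect_error(exposure_budget(60, 60, 0, 0), "100")
  expect_error(exposure_budget(-1, 71, 30, 0), class = "vapedose_invalid_argument")
})

test_that("budget fractions are stable under grid and step refinement", {
  b1 <- budget(run_default_puff("post_puff"))
  b2 <- budget(run_default_puff("post_puff", dt = 0.0025,
                                cells_per_segment = 20L))
  for (f in c("absorbed_frac", "exhaled_frac", "remaining_frac",
              "to_lung_frac")) {
    expect_lt(abs(b1[[f]] - b2[[f]]), 0.5)
  }
})

test_that("reference budget fixtures close to 100 percent", {
  rb <- reference_budgets("thc")
  sums <- rowSums(rb[, c("absorbed", "exhaled", "remaining", "to_lung")])
  expect_true(all(abs(sums - 100) <= 0.1))
  rn <- reference_budgets("nicotine")
  expect_equal(rn$remaining, c(1.6, 1.4))
})
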