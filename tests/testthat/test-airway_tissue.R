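test_that("double-film interface balances the two resistances", {
  # zero bulk air, fresh tissue: everything zero
  iv0 <- interface_values(0, 1e-3, 1e-3, 100)
  expect_identical(c(iv0$C_air_wall, iv0$C_mucus_surface, iv0$flux), c(0, 0, 0))

  # gas-side resistance vanishes -> wall approaches bulk
  iv <- interface_values(1, 1e3, 1e-3, 100)
  expect_equal(iv$C_air_wall, 1, tolerance = 1e-3)

  # equal films, K = 1, fresh tissue: the hand-solved two-resistance balance
  iv <- interface_values(1, 2e-3, 2e-3, 1)
  expect_equal(iv$C_air_wall, 0.5, tolerance = 1e-12)

  # flux conservation and interface equilibrium, property-checked
  set.seed(42)
  for (i in 1:50) {
    kg <- 10^runif(1, -4, -1); kl <- 10^runif(1, -4, -1)
    K <- 10^runif(1, 0, 5); Cb <- runif(1); Cl <- runif(1) * K * Cb
    iv <- interface_values(Cb, kg, kl, K, C_liquid_bulk = Cl)
    gas_flux <- kg * (Cb - iv$C_air_wall)
    liq_flux <- kl * (iv$C_mucus_surface - Cl)
    # absolute comparison on the natural flux scale (the two expressions
    # cancel almost completely near interface equilibrium)
    expect_lt(abs(gas_flux - liq_flux), 1e-10 * kg * max(Cb, 1e-12))
    expect_equal(iv$C_mucus_surface, K * iv$C_air_wall, tolerance = 1e-12)
  }

  # insoluble limit is not an error
  iv <- interface_values(1, 1e-3, 1e-3, 0)
  expect_identical(iv$flux, 0)
  expect_identical(iv$C_air_wall, 1)
})

test_that("transient solver matches the semi-infinite early-time flux", {
  st <- tissue_stack(list(tissue_layer("mucus", 1e-3, 4e-10, 1)),
                     grid_points_per_layer = 300L)
  r <- solve_tissue_diffusion(st, thc, 1.0, t_end = 5, dt = 0.005)
  for (tt in c(1, 2, 5)) {
    i <- which.min(abs(r$times - tt))
    expect_equal(r$flux[i], sqrt(4e-10 / (pi * tt)), tolerance = 0.02)
  }
})

test_that("finite multilayer stack reaches the series-resistance steady flux", {
  st <- airway_wall_stack(thc, grid_points_per_layer = 20L)
  r <- solve_tissue_diffusion(st, thc, 1.0, t_end = 2000, dt = 0.5,
                              gas_film_coeff = 2e-3)
  expect_equal(r$flux[length(r$flux)],
               steady_stack_flux(st, 1.0, gas_film_coeff = 2e-3),
               tolerance = 0.005)
})

test_that("solver conserves mass and behaves for degenerate forcing", {
  st <- airway_wall_stack(thc, grid_points_per_layer = 8L)
  # zero forcing -> identically zero
  r0 <- solve_tissue_diffusion(st, thc, 0, t_end = 1, dt = 0.01)
  expect_identical(max(abs(r0$flux)), 0)
  expect_identical(r0$cumulative_uptake[length(r0$cumulative_uptake)], 0)

  # transient forcing: uptake = flux integral = inventory + sink outflow
  forcing <- build_puff("custom", 2, 55e-6)  # reuse a pulse shape as conc
  series <- list(times = forcing$times, conc = forcing$flow * 1e3)
  r <- solve_tissue_diffusion(st, thc, series, t_end = 4, dt = 0.01,
                              gas_film_coeff = 1e-3)
  n <- length(r$times)
  expect_equal(r$cumulative_uptake[n], sum(r$flux[-1] * diff(r$times)),
               tolerance = 1e-6)
  expect_equal(r$cumulative_uptake[n], r$tissue_inventory + r$sink_outflow[n],
               tolerance = 1e-4)
  # under constant (never-decreasing) forcing the uptake is monotone
  rc <- solve_tissue_diffusion(st, thc, 1e-3, t_end = 4, dt = 0.01,
                               gas_film_coeff = 1e-3)
  expect_true(all(diff(rc$cumulative_uptake) >= 0))

  expect_error(tissue_stack(list(tissue_layer("mucus", 1e-5, 1e-10)),
                            grid_points_per_layer = 2L),
               class = "vapedose_config_error")
})

test_that("refining time step and grid changes cumulative uptake by < 1%", {
  mk <- function(npl) airway_wall_stack(thc, grid_points_per_layer = npl)
  run <- function(npl, dt) {
    r <- solve_tissue_diffusion(mk(npl), thc, 1.0, t_end = 4, dt = dt,
                                gas_film_coeff = 1e-3)
    r$cumulative_uptake[length(r$cumulative_uptake)]
  }
  base <- run(8L, 0.02)
  fine <- run(16L, 0.01)
  expect_equal(base, fine, tolerance = 0.01)
})

test_that("uptake is monotone in partition coefficient and diffusivity", {
  uptake_for <- function(K, Dmult = 1) {
    sp <- thc
    sp$K_mucus_air <- K
    sp$D_layer <- lapply(sp$D_layer, function(d) d * Dmult)
    st <- airway_wall_stack(sp, grid_points_per_layer = 6L)
    r <- solve_tissue_diffusion(st, sp, 1.0, t_end = 2, dt = 0.02,
                                gas_film_coeff = 2e-3)
    r$cumulative_uptake[length(r$cumulative_uptake)]
  }
  uK <- vapply(c(1e3, 1e4, 1e5), uptake_for, 0)
  expect_true(all(diff(uK) >= 0))
  uD <- vapply(c(0.25, 1, 4), function(m) uptake_for(5e4, m), 0)
  expect_true(all(diff(uD) >= 0))
})

test_that("with the sink disabled uptake never exceeds equilibrium capacity", {
  sp <- thc
  sp$K_mucus_air <- 500   # modest K so the bound is approachable in-window
  st <- tissue_stack(
    list(tissue_layer("mucus", 5e-6, sp$D_layer$mucus, sp$K_mucus_air)),
    base_condition = "impermeable", grid_points_per_layer = 10L)
  r <- solve_tissue_diffusion(st, sp, 1e-3, t_end = 60, dt = 0.05,
                              gas_film_coeff = 1e-2)
  cap <- equilibrium_capacity(st, 1e-3)
  expect_true(all(r$cumulative_uptake <= cap * (1 + 1e-8)))
  expect_gt(r$cumulative_uptake[length(r$cumulative_uptake)], 0.5 * cap)
})

test_that("equilibrium capacity is the direct layer sum and scales with K", {
  st1 <- tissue_stack(list(tissue_layer("mucus", 1e-5, 1e-10, 2)))
  expect_identical(equilibrium_capacity(st1, 0), 0)
  expect_equal(equilibrium_capacity(st1, 1), 2e-5, tolerance = 1e-12)
  st2 <- tissue_stack(list(tissue_layer("mucus", 1e-5, 1e-10, 4)))
  expect_equal(equilibrium_capacity(st2, 1), 2 * equilibrium_capacity(st1, 1),
               tolerance = 1e-12)
})
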