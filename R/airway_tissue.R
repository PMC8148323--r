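# Layered air-mucus-tissue-blood (AMTB) wall-uptake model.
#
# One-dimensional transient diffusion through an ordered stack of tissue
# layers (mucus -> epithelium -> sub-epithelium) with a perfect blood sink
# at the base, forced by a time-varying near-wall air concentration through
# a double-film partition boundary condition at the air-mucus interface.
#
# Numerics: the concentration is transformed to the partition-normalized
# potential phi = C / K_cum (K_cum = cumulative partition coefficient
# relative to air), which is continuous across layer interfaces and equals
# the local-equilibrium air concentration. In phi the system is a
# heat-equation analogue with capacity K_cum and conductivity D * K_cum,
# discretized by finite volumes with harmonic-mean interface conductances
# and integrated by backward Euler (unconditionally stable). The discrete
# ledger (surface influx = tissue inventory + sink outflow) closes to
# machine precision by construction.

#' Construct a tissue layer
#'
#' @param name Layer name (`mucus`, `epithelium`, `subepithelium`, or a
#'   skin-layer name).
#' @param thickness Layer thickness, m.
#' @param diffusivity Diffusivity of the species in the layer, m^2/s.
#' @param partition_vs_previous Equilibrium concentration ratio to the
#'   adjacent outer phase (for the first layer: versus air, i.e. the
#'   mucus:air or skin:air partition coefficient).
#' @return A `tissue_layer`.
#' @export
tissue_layer <- function(name, thickness, diffusivity,
                         partition_vs_previous = 1) {
  check_positive(thickness, "thickness")
  check_positive(diffusivity, "diffusivity")
  check_positive(partition_vs_previous, "partition_vs_previous")
  structure(list(name = as.character(name), thickness = thickness,
                 diffusivity = diffusivity,
                 partition_vs_previous = partition_vs_previous),
            class = "tissue_layer")
}

#' Construct a tissue stack
#'
#' @param layers List of [tissue_layer]s, ordered from the air interface
#'   inward. For airway walls the first layer is mucus.
#' @param base_condition `perfect_sink` (blood compartment at zero
#'   concentration) or `impermeable` (closed base, used for
#'   equilibrium-capacity checks).
#' @param grid_points_per_layer Finite-volume cells per layer (>= 3).
#' @return A `tissue_stack`.
#' @export
tissue_stack <- function(layers, base_condition = "perfect_sink",
                         grid_points_per_layer = 12L) {
  if (!length(layers)) stop_invalid("a tissue stack needs at least one layer")
  for (l in layers) stopifnot(inherits(l, "tissue_layer"))
  base_condition <- match.arg(base_condition, c("perfect_sink", "impermeable"))
  if (grid_points_per_layer < 3L) {
    stop_config("grid too coarse: need >= 3 points per layer to resolve the thinnest layer")
  }
  structure(list(layers = layers, base_condition = base_condition,
                 grid_points_per_layer = as.integer(grid_points_per_layer)),
            class = "tissue_stack")
}

#' Default airway-wall stack
#'
#' Mucus / epithelium / sub-epithelium with order-of-magnitude thicknesses
#' of 10, 50 and 100 micrometres and a perfect blood sink at the base. The
#' first-layer partition coefficient is taken from the species record at
#' solve time.
#'
#' @param species A [chemical_species] providing per-layer diffusivities.
#' @param grid_points_per_layer Cells per layer.
#' @return A [tissue_stack].
#' @export
airway_wall_stack <- function(species = thc_defaults(),
                              grid_points_per_layer = 12L) {
  tissue_stack(
    list(
      tissue_layer("mucus", 10e-6, species$D_layer$mucus,
                   partition_vs_previous = species$K_mucus_air),
      tissue_layer("epithelium", 50e-6, species$D_layer$epithelium),
      tissue_layer("subepithelium", 100e-6, species$D_layer$subepithelium)
    ),
    grid_points_per_layer = grid_points_per_layer
  )
}

#' Double-film interface values at the air-mucus boundary
#'
#' Two mass-transfer films in series meet at the interface: a gas-side film
#' with coefficient `gas_film_coeff` and a liquid-side film with
#' `liquid_film_coeff`, with partition equilibrium
#' `C_mucus_surface = K * C_air_wall` holding exactly at the interface and
#' flux conserved across it. `C_liquid_bulk` is the mucus concentration
#' beyond the liquid film (0 for fresh tissue).
#'
#' @param C_air_bulk Bulk air concentration, kg/m^3.
#' @param gas_film_coeff Gas-side coefficient, m/s.
#' @param liquid_film_coeff Liquid-side coefficient, m/s.
#' @param K Partition coefficient (mucus:air). `K = 0` is the insoluble
#'   limit: zero flux, `C_air_wall = C_air_bulk`.
#' @param C_liquid_bulk Mucus-side bulk concentration, kg/m^3.
#' @return List with `C_air_wall`, `C_mucus_surface`, `flux` (kg/m^2/s,
#'   positive into tissue).
#' @export
#' @examples
#' # equal film coefficients, K = 1, fresh tissue: wall sits at C_bulk / 2
#' interface_values(1, 1e-3, 1e-3, 1)$C_air_wall
interface_values <- function(C_air_bulk, gas_film_coeff, liquid_film_coeff,
                             K, C_liquid_bulk = 0) {
  check_nonneg(C_air_bulk, "C_air_bulk")
  check_positive(gas_film_coeff, "gas_film_coeff")
  check_positive(liquid_film_coeff, "liquid_film_coeff")
  check_nonneg(K, "K")
  check_nonneg(C_liquid_bulk, "C_liquid_bulk")
  if (K == 0) {
    return(list(C_air_wall = C_air_bulk, C_mucus_surface = 0, flux = 0))
  }
  # k_g (C_b - C_w) = k_l (K C_w - C_l)
  C_w <- (gas_film_coeff * C_air_bulk + liquid_film_coeff * C_liquid_bulk) /
    (gas_film_coeff + liquid_film_coeff * K)
  list(C_air_wall = C_w,
       C_mucus_surface = K * C_w,
       flux = gas_film_coeff * (C_air_bulk - C_w))
}

# ---- internal grid + stepping machinery -----------------------------------

# Build the finite-volume grid for a stack/species pair. `k_gas` is the
# gas-side film coefficient (Inf = no gas-side resistance). Returns an
# environment-free list usable by tissue_make_stepper().
tissue_grid <- function(stack, k_gas = Inf) {
  nl <- length(stack$layers)
  npl <- stack$grid_points_per_layer
  Kcum <- numeric(nl)
  k_prev <- 1
  for (i in seq_len(nl)) {
    Kcum[i] <- k_prev * stack$layers[[i]]$partition_vs_previous
    k_prev <- Kcum[i]
  }
  h <- cap <- kond <- numeric(0)   # cell width, capacity Kc*h, conductivity D*Kc
  layer_of <- integer(0)
  for (i in seq_len(nl)) {
    li <- stack$layers[[i]]
    hi <- rep(li$thickness / npl, npl)
    h <- c(h, hi)
    cap <- c(cap, Kcum[i] * hi)
    kond <- c(kond, rep(li$diffusivity * Kcum[i], npl))
    layer_of <- c(layer_of, rep(i, npl))
  }
  n <- length(h)
  # face conductances between cell centers (n-1 internal faces)
  G_int <- 1 / (h[-n] / (2 * kond[-n]) + h[-1] / (2 * kond[-1]))
  # top face: gas film in series with the first half-cell
  G_top <- if (is.finite(k_gas)) 1 / (1 / k_gas + h[1] / (2 * kond[1]))
           else 2 * kond[1] / h[1]
  # bottom face: half-cell to a zero-potential sink, or closed
  G_bot <- if (stack$base_condition == "perfect_sink") 2 * kond[n] / h[n] else 0
  list(n = n, h = h, cap = cap, kond = kond, layer_of = layer_of,
       Kcum = Kcum, G_int = G_int, G_top = G_top, G_bot = G_bot,
       x = cumsum(h) - h / 2)
}

# Precompute the backward-Euler factorization for a fixed dt, returning a
# stepper closure: step(phi, C_air, dt) -> list(phi, flux_in, sink_out_rate).
tissue_make_stepper <- function(grid, dt) {
  n <- grid$n
  lower <- -grid$G_int
  upper <- -grid$G_int
  diag <- grid$cap / dt +
    c(grid$G_top, numeric(n - 1)) +
    c(grid$G_int, 0) + c(0, grid$G_int) +
    c(numeric(n - 1), grid$G_bot)
  fac <- tridiag_factor(lower, diag, upper)
  cap_dt <- grid$cap / dt
  function(phi, C_air) {
    d <- cap_dt * phi
    d[1] <- d[1] + grid$G_top * C_air
    phi_new <- tridiag_solve(fac, d)
    list(phi = phi_new,
         flux_in = grid$G_top * (C_air - phi_new[1]),
         sink_rate = grid$G_bot * phi_new[n])
  }
}

#' Solve transient diffusion through a tissue stack
#'
#' Integrates the layered diffusion system under a prescribed bulk-air
#' concentration series with the double-film boundary at the air interface
#' and the stack's base condition at the bottom.
#'
#' @param stack A [tissue_stack].
#' @param species A [chemical_species]; the first-layer partition
#'   coefficient is `partition_vs_previous` of the first layer (for stacks
#'   built by [airway_wall_stack()] this is the species' `K_mucus_air`).
#' @param C_air_series Either a single non-negative number (constant
#'   forcing) or a list/`flow_waveform`-like object with `times` and
#'   concentration values in its second field (`flow` or `conc`), kg/m^3.
#' @param t_end End time, s (required for constant forcing; defaults to the
#'   series support otherwise).
#' @param dt Time step, s.
#' @param gas_film_coeff Gas-side film coefficient, m/s. Defaults to the
#'   species override, else `Inf` (no gas-side resistance).
#' @return A `wall_flux_result`: `times`, `flux` (kg/m^2/s into tissue),
#'   `cumulative_uptake` (kg/m^2), `sink_outflow` (kg/m^2),
#'   `tissue_inventory` (kg/m^2), and the final `phi` profile with the grid.
#' @export
solve_tissue_diffusion <- function(stack, species, C_air_series,
                                   t_end = NULL, dt = 0.01,
                                   gas_film_coeff = NULL) {
  stopifnot(inherits(stack, "tissue_stack"))
  check_positive(dt, "dt")
  k_gas <- gas_film_coeff
  if (is.null(k_gas)) {
    k_gas <- if (!is.null(species$gas_film_coeff)) species$gas_film_coeff else Inf
  }
  if (is.numeric(C_air_series) && length(C_air_series) == 1L) {
    check_nonneg(C_air_series, "C_air_series")
    if (is.null(t_end)) stop_invalid("`t_end` required for constant forcing")
    conc_fun <- function(t) rep(C_air_series, length(t))
  } else {
    ts <- C_air_series$times
    cs <- if (!is.null(C_air_series$conc)) C_air_series$conc else C_air_series$flow
    check_nonneg(cs, "C_air_series values")
    if (is.null(t_end)) t_end <- max(ts)
    conc_fun <- function(t) approx(ts, cs, xout = t, rule = 2)$y
  }
  grid <- tissue_grid(stack, k_gas)
  stepper <- tissue_make_stepper(grid, dt)
  nt <- max(1L, as.integer(ceiling(t_end / dt - 1e-9)))
  times <- numeric(nt + 1L)
  flux <- numeric(nt + 1L)
  cum <- numeric(nt + 1L)
  sink <- numeric(nt + 1L)
  phi <- numeric(grid$n)
  # forcing evaluated at the end of each step (implicit-consistent)
  for (k in seq_len(nt)) {
    t_new <- k * dt
    st <- stepper(phi, conc_fun(t_new))
    phi <- st$phi
    times[k + 1L] <- t_new
    flux[k + 1L] <- st$flux_in
    cum[k + 1L] <- cum[k] + st$flux_in * dt
    sink[k + 1L] <- sink[k] + st$sink_rate * dt
  }
  structure(
    list(times = times, flux = flux, cumulative_uptake = cum,
         sink_outflow = sink,
         tissue_inventory = sum(grid$cap * phi),
         phi = phi, grid = grid),
    class = "wall_flux_result"
  )
}

#' Equilibrium tissue loading at a given air concentration
#'
#' Upper bound for uptake with the sink disabled: the mass per unit area
#' held by the stack when every layer equilibrates with the air phase,
#' `sum_i thickness_i * K_cum_i * C_air`.
#'
#' @param stack A [tissue_stack].
#' @param C_air Air concentration, kg/m^3.
#' @return Areal capacity, kg/m^2.
#' @export
equilibrium_capacity <- function(stack, C_air) {
  stopifnot(inherits(stack, "tissue_stack"))
  check_nonneg(C_air, "C_air")
  Kc <- 1
  total <- 0
  for (l in stack$layers) {
    Kc <- Kc * l$partition_vs_previous
    total <- total + l$thickness * Kc * C_air
  }
  total
}

#' Steady-state series-resistance flux through a stack
#'
#' Closed-form resistor network: gas film plus one resistance
#' `L_i / (D_i * K_cum_i)` per layer, driving potential `C_air` against the
#' zero-concentration sink.
#'
#' @param stack A [tissue_stack] with `perfect_sink` base.
#' @param C_air Air concentration, kg/m^3.
#' @param gas_film_coeff Gas-side film coefficient, m/s (`Inf` = none).
#' @return Flux, kg/m^2/s.
#' @export
steady_stack_flux <- function(stack, C_air, gas_film_coeff = Inf) {
  stopifnot(inherits(stack, "tissue_stack"))
  check_nonneg(C_air, "C_air")
  R <- if (is.finite(gas_film_coeff)) 1 / gas_film_coeff else 0
  Kc <- 1
  for (l in stack$layers) {
    Kc <- Kc * l$partition_vs_previous
    R <- R + l$thickness / (l$diffusivity * Kc)
  }
  C_air / R
}

#' Export a wall-flux result as CSV
#'
#' Columns `time_s,flux_kg_m2_s,cumulative_kg_m2`.
#'
#' @param result A `wall_flux_result`.
#' @param path Output file path.
#' @export
write_wall_flux_csv <- function(result, path) {
  stopifnot(inherits(result, "wall_flux_result"))
  df <- data.frame(time_s = result$times,
                   flux_kg_m2_s = result$flux,
                   cumulative_kg_m2 = result$cumulative_uptake)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
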