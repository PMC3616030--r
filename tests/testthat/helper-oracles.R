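# Shared fixtures and independent iteration oracles.

medes_mullet <- function(price = 0.01) medes_species(price)$red_mullet
medes_seabass <- function() medes_species()$european_seabass

# Single-patch delay-difference iteration with recruitment held at R0 and
# survival at s_nat: the long-run limit is the unfished equilibrium. Written
# directly from the recursion, independent of the closed form.
iterate_unfished <- function(params, years = 600, B_start = 1) {
  s <- params$s_nat
  B <- B_prev <- B_start
  for (t in seq_len(years)) {
    B_new <- (1 + params$rho) * s * B - params$rho * s * s * B_prev -
      params$rho * s * params$w_km1 * params$R0 + params$w_k * params$R0
    B_prev <- B
    B <- max(0, B_new)
  }
  B
}

# Single-patch iteration under a constant harvest rate with Beverton-Holt
# recruitment anchored at the unfished settlement E0 = B0 (identity
# kernels). Eggs are the start-of-year biomass, taken before catch.
iterate_fished <- function(params, u, years = 1500) {
  s_nat <- params$s_nat
  B0 <- iterate_unfished(params)
  s <- s_nat * (1 - u)
  B <- B_prev <- B0
  R <- R_next <- params$R0
  for (t in seq_len(years)) {
    R_next <- 4 * params$h * params$R0 * B /
      ((1 - params$h) * B0 + (5 * params$h - 1) * B)
    B_new <- (1 + params$rho) * s * B - params$rho * s * s * B_prev -
      params$rho * s * params$w_km1 * R + params$w_k * R_next
    B_prev <- B
    R <- R_next
    B <- max(0, B_new)
  }
  B
}

# random valid species draw for property loops
random_species <- function(role = "fished") {
  w_k <- runif(1, 20, 500)
  species_params(
    name = "draw", s_nat = runif(1, 0.3, 0.95), w_k = w_k,
    w_km1 = if (runif(1) < 0.5) 0 else runif(1, 0, 0.3 * w_k),
    rho = runif(1, 0.3, 0.9), R0 = 10^runif(1, 3, 5),
    sigma_L = runif(1, 0.3, 5), sigma_A = runif(1, 0.05, 2),
    h = runif(1, 0.3, 0.95), price = 0.01, role = role)
}

random_tourism <- function() {
  tourism_params(alpha = runif(1, 1, 50), beta = -10^runif(1, -5, -2),
                 gamma = 10^runif(1, -9, -6), fixed_fee = runif(1, 0, 5))
}

# tiny two-species scenario used across scenario tests (fast: 40 + 30 yr)
small_medes <- function(burn_in_years = 40, post_years = 30, ...) {
  medes_scenario(burn_in_years = burn_in_years, post_years = post_years, ...)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
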