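# Random-but-valid scenario generation for property-based testing.

#' Generate a random valid scenario configuration
#'
#' Draws a complete scenario — coastline, zoning, one fished and one
#' tourism species, harvest rates, costs and calibrated dive demand —
#' uniformly within the type invariants. Used for property-based testing;
#' deterministic per seed, and the caller's random-number state is left
#' untouched.
#'
#' @param seed Integer seed.
#' @param burn_in_years,post_years Timeline lengths (kept short by default
#'   so property suites stay fast).
#' @return A [scenario_config()].
#' @examples
#' cfg <- generate_synthetic_scenario(42)
#' identical(cfg, generate_synthetic_scenario(42))
#' @export
generate_synthetic_scenario <- function(seed, burn_in_years = 30,
                                        post_years = 30) {
  check_number(seed, "seed")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(),
                      inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))

  n_patches <- sample(20:60, 1)
  f_nt <- stats::runif(1, 0.05, 0.2)  # >= 1 no-take patch at n >= 20
  f_pa <- stats::runif(1, 0.05, 0.3)
  coast <- build_zones(n_patches, c(f_nt, f_pa, 1 - f_nt - f_pa))

  draw_species <- function(name, role) {
    w_k <- stats::runif(1, 20, 500)
    species_params(
      name = name,
      s_nat = stats::runif(1, 0.4, 0.95),
      w_k = w_k,
      w_km1 = if (stats::runif(1) < 0.5) 0 else stats::runif(1, 0, 0.3 * w_k),
      rho = stats::runif(1, 0.4, 0.9),
      R0 = 10^stats::runif(1, 3, 5),
      sigma_L = stats::runif(1, 0.5, 5),
      sigma_A = stats::runif(1, 0.05, 2),
      h = stats::runif(1, 0.3, 0.95),
      price = 10^stats::runif(1, -3, -1),
      role = role)
  }
  species <- list(draw_species("synthetic_fished", "fished"),
                  draw_species("synthetic_tourism", "tourism"))
  u_pre <- c(synthetic_fished = stats::runif(1, 0.05, 0.6),
             synthetic_tourism = stats::runif(1, 0, 0.3))

  n_nt <- sum(coast$zone == "no_take")
  B_ref <- n_nt * unfished_equilibrium(species[[2]])
  fee <- stats::runif(1, 1, 10)
  tourism <- calibrate_demand(
    target_dives = stats::runif(1, 1e3, 1e5),
    fee = fee, B_ref = B_ref,
    choke_multiple = stats::runif(1, 1.5, 4),
    biomass_share = stats::runif(1, 0, 0.9),
    fee_policy = sample(c("fixed", "optimal"), 1),
    fixed_fee = fee)

  events <- if (stats::runif(1) < 0.3) {
    list(list(type = "cap_dives",
              year = sample(seq_len(max(1, post_years - 2)), 1), fee = fee))
  } else {
    list()
  }

  scenario_config(
    coast = coast, species = species, u_pre = u_pre,
    econ = econ_params(cost = stats::runif(1, 0, 1e4)),
    tourism = tourism,
    burn_in_years = burn_in_years, post_years = post_years,
    partial_reduction = stats::runif(1, 0.2, 0.8),
    events = events,
    name = sprintf("synthetic-%d", as.integer(seed)),
    seed = as.integer(seed))
}
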