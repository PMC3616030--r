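# Delay-difference (Deriso-Schnute) biomass dynamics per patch.
#
# The recursion tracks biomass after adult movement with a one-year lag and
# approximates age structure with two classes (recruits and adults):
#   B[t+1] = (1+rho) s[t] B[t] - rho s[t] s[t-1] B[t-1]
#            - rho s[t] w_km1 R[t] + w_k R[t+1]

#' Annual survival under harvest
#'
#' Total annual survival is the product of natural survival and survival
#' from fishing, where a harvest rate `u` removes a fraction `u` of the
#' post-movement biomass.
#'
#' @param s_nat Natural survival fraction in `[0, 1]` (scalar).
#' @param u Harvest rate(s) in `[0, 1]`; vectorised over patches.
#' @return Realised survival fraction(s), `s_nat * (1 - u)`.
#' @examples
#' annual_survival(0.66, c(0, 0.5, 1))
#' @export
annual_survival <- function(s_nat, u) {
  check_number(s_nat, "s_nat", 0, 1)
  check_vector(u, "u", lower = 0, upper = 1)
  s_nat * (1 - u)
}

#' Per-patch population state of the delay-difference model
#'
#' Holds the current and lagged post-movement biomass, current and incoming
#' recruitment, and the survival realised in the previous year — everything
#' the recursion needs for one step.
#'
#' @param B Per-patch biomass after adult movement, current year (grams).
#' @param B_prev Per-patch biomass after adult movement, previous year.
#' @param R Per-patch recruitment entering the current year (individuals).
#' @param R_next Per-patch recruitment entering next year (individuals).
#' @param s_prev Per-patch survival realised in the previous year.
#' @return An object of class `pop_state`.
#' @export
pop_state <- function(B, B_prev = B, R, R_next = R, s_prev) {
  n <- length(B)
  check_vector(B, "B", lower = 0)
  check_vector(B_prev, "B_prev", len = n, lower = 0)
  check_vector(R, "R", len = n, lower = 0)
  check_vector(R_next, "R_next", len = n, lower = 0)
  if (length(s_prev) == 1L) s_prev <- rep(s_prev, n)
  check_vector(s_prev, "s_prev", len = n, lower = 0, upper = 1)
  structure(list(B = B, B_prev = B_prev, R = R, R_next = R_next,
                 s_prev = s_prev),
            class = "pop_state")
}

#' One year of delay-difference biomass dynamics
#'
#' Advances the Deriso-Schnute recursion one year in every patch. Negative
#' intermediate biomass (possible for extreme parameter combinations through
#' the lag term) is clamped to zero; the amount clamped is returned in the
#' `"clamped"` attribute so callers can log it. The caller is responsible for
#' rotating the lags afterwards (`B_prev <- B`, `R <- R_next`,
#' `s_prev <- s_now`).
#'
#' @param state A [pop_state()].
#' @param params A [species_params()].
#' @param s_now Per-patch survival fractions for the current year.
#' @return Per-patch biomass at the start of next year (grams), before adult
#'   movement; attribute `"clamped"` holds the total biomass (grams) clamped
#'   to zero.
#' @examples
#' mullet <- species_params("m", s_nat = 0.66, w_k = 53.93, rho = 0.77,
#'                          R0 = 52000, sigma_L = 2, sigma_A = 1, h = 0.75)
#' B0 <- unfished_equilibrium(mullet)
#' st <- pop_state(B = B0, R = mullet$R0, s_prev = mullet$s_nat)
#' step_biomass(st, mullet, s_now = mullet$s_nat)  # stays at B0
#' @export
step_biomass <- function(state, params, s_now) {
  stopifnot(inherits(state, "pop_state"), inherits(params, "species_params"))
  n <- length(state$B)
  if (length(s_now) == 1L) s_now <- rep(s_now, n)
  check_vector(s_now, "s_now", len = n, lower = 0, upper = 1)
  B_new <- (1 + params$rho) * s_now * state$B -
    params$rho * s_now * state$s_prev * state$B_prev -
    params$rho * s_now * params$w_km1 * state$R +
    params$w_k * state$R_next
  neg <- B_new < 0
  clamped <- -sum(B_new[neg])
  if (clamped > 0) B_new[neg] <- 0
  attr(B_new, "clamped") <- clamped
  B_new
}

#' Unfished equilibrium biomass per patch
#'
#' Stationary solution of the delay-difference recursion with recruitment
#' held at `R0` and survival at `s_nat`:
#' `B0 = R0 (w_k - rho s w_km1) / ((1 - s)(1 - rho s))`.
#'
#' @param params A [species_params()].
#' @return Equilibrium biomass per patch (grams, scalar).
#' @export
unfished_equilibrium <- function(params) {
  stopifnot(inherits(params, "species_params"))
  s <- params$s_nat
  denom <- (1 - s) * (1 - params$rho * s)
  if (denom <= 0) {
    stop("unfished equilibrium is undefined: (1 - s_nat)(1 - rho*s_nat) <= 0",
         call. = FALSE)
  }
  params$R0 * (params$w_k - params$rho * s * params$w_km1) / denom
}

#' Long-run equilibrium biomass under a constant harvest rate
#'
#' Closed-form fixed point of the non-spatial (single patch, or equivalently
#' uniform coastline with identity movement) dynamics under constant harvest
#' `u`, with Beverton-Holt recruitment anchored at the unfished equilibrium.
#' Solving the stationarity condition with `R = 4 h R0 B / ((1-h) B0 +
#' (5h-1) B)` gives
#' `B(u) = (4 h R0 W / D - (1-h) B0) / (5h - 1)` where
#' `W = w_k - rho s w_km1`, `D = (1-s)(1 - rho s)` and `s = s_nat (1 - u)`;
#' floored at zero (the stock collapses when harvest outruns productivity).
#'
#' @param params A [species_params()].
#' @param u Harvest rate(s) in `[0, 1]`; vectorised.
#' @return Equilibrium biomass (grams) for each `u`.
#' @examples
#' m <- species_params("m", s_nat = 0.66, w_k = 53.93, rho = 0.77,
#'                     R0 = 52000, sigma_L = 2, sigma_A = 1, h = 0.75)
#' equilibrium_biomass(m, c(0, 0.2, 0.4))
#' @export
equilibrium_biomass <- function(params, u) {
  stopifnot(inherits(params, "species_params"))
  check_vector(u, "u", lower = 0, upper = 1)
  B0 <- unfished_equilibrium(params)
  s <- params$s_nat * (1 - u)
  D <- (1 - s) * (1 - params$rho * s)
  W <- params$w_k - params$rho * s * params$w_km1
  h <- params$h
  pmax(0, (4 * h * params$R0 * W / D - (1 - h) * B0) / (5 * h - 1))
}

#' Locate the maximum-sustainable-yield harvest rate
#'
#' Maximises long-run equilibrium yield `u * B(u)` (see
#' [equilibrium_biomass()]) over `u` in `[0, 1]` with [stats::optimize()].
#'
#' @param params A [species_params()].
#' @param tol Convergence tolerance passed to [stats::optimize()].
#' @return A list with `u_msy` (harvest rate) and `yield` (grams/year/patch).
#' @export
find_msy <- function(params, tol = 1e-8) {
  stopifnot(inherits(params, "species_params"))
  opt <- stats::optimize(function(u) u * equilibrium_biomass(params, u),
                         interval = c(0, 1), maximum = TRUE, tol = tol)
  list(u_msy = opt$maximum, yield = opt$objective)
}
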