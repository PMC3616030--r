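# Fishery profit and dive-tourism economics: linear inverse demand,
# revenue-maximising pricing, consumer surplus, and demand calibration.

#' Tourism demand parameters and fee policy
#'
#' The marginal value of a dive is linear in the number of dives and in the
#' reserve biomass of the species divers come to see:
#' `MV(q, B) = alpha + beta q + gamma B` with `beta < 0` (additional dives
#' are increasingly less valuable) and `gamma >= 0` (more fish make a dive
#' more valuable).
#'
#' @param alpha Demand intercept (currency per dive).
#' @param beta Slope in dives (currency per dive^2, `< 0`).
#' @param gamma Biomass sensitivity (currency per dive per gram, `>= 0`).
#' @param fee_policy `"fixed"` (charge `fixed_fee`), `"optimal"`
#'   (revenue-maximising fee each year) or `"capped"` (fixed fee with a
#'   ceiling on annual dives).
#' @param fixed_fee Fee per dive used by the fixed and capped policies.
#' @param cap Maximum dives per year (capped policy; may be `NA` until a cap
#'   event fires).
#' @return An object of class `tourism_params`.
#' @export
tourism_params <- function(alpha, beta, gamma = 0,
                           fee_policy = c("fixed", "optimal", "capped"),
                           fixed_fee = 0, cap = NA_real_) {
  fee_policy <- match.arg(fee_policy)
  check_number(alpha, "alpha")
  check_number(beta, "beta", upper = -.Machine$double.xmin)
  check_number(gamma, "gamma", lower = 0)
  check_number(fixed_fee, "fixed_fee", lower = 0)
  if (!is.na(cap)) check_number(cap, "cap", lower = 0)
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 fee_policy = fee_policy, fixed_fee = fixed_fee, cap = cap),
            class = "tourism_params")
}

#' @export
print.tourism_params <- function(x, ...) {
  cat(sprintf("<tourism_params> alpha=%.4g  beta=%.4g  gamma=%.4g\n",
              x$alpha, x$beta, x$gamma))
  cat(sprintf("  policy=%s  fixed_fee=%.3g  cap=%s\n", x$fee_policy,
              x$fixed_fee, ifelse(is.na(x$cap), "unset", format(x$cap))))
  invisible(x)
}

#' Per-patch fishing cost parameters
#'
#' @param cost Cost per unit effort per patch (currency); scalar (recycled)
#'   or one value per patch. One unit of effort is the effort that produces
#'   one unit of harvest rate, so the annual cost in patch i is
#'   `cost_i * u_i`.
#' @return An object of class `econ_params`.
#' @export
econ_params <- function(cost = 0) {
  check_vector(cost, "cost", lower = 0)
  structure(list(cost = cost), class = "econ_params")
}

#' Annual catch per patch
#'
#' Catch is the harvest rate applied to the post-movement biomass:
#' `C_i = u_i * B_i`.
#'
#' @param u Per-patch harvest rates in `[0, 1]`.
#' @param B_moved Per-patch biomass after adult movement (grams).
#' @return Per-patch catch (grams).
#' @export
catch_biomass <- function(u, B_moved) {
  check_vector(u, "u", lower = 0, upper = 1)
  check_vector(B_moved, "B_moved", len = length(u), lower = 0)
  u * B_moved
}

#' Annual fishery profit
#'
#' `FV = sum_i (price * C_i - cost_i * u_i)`; may be negative when costs
#' exceed landed value.
#'
#' @param C Per-patch catch (grams).
#' @param u Per-patch harvest rates.
#' @param price Value per gram of catch.
#' @param econ An [econ_params()] (per-patch costs).
#' @return Annual profit (currency, scalar).
#' @export
fishery_profit <- function(C, u, price, econ) {
  stopifnot(inherits(econ, "econ_params"))
  check_vector(C, "C", lower = 0)
  check_vector(u, "u", len = length(C), lower = 0, upper = 1)
  check_number(price, "price", lower = 0)
  cost <- econ$cost
  if (length(cost) == 1L) cost <- rep(cost, length(C))
  check_vector(cost, "cost", len = length(C), lower = 0)
  sum(price * C - cost * u)
}

#' Marginal value of an additional dive
#'
#' The linear inverse demand line `MV = alpha + beta q + gamma B`.
#'
#' @param q Number of dives (`>= 0`).
#' @param B Reserve biomass of the tourism species (grams).
#' @param t A [tourism_params()].
#' @return Currency per dive.
#' @export
marginal_dive_value <- function(q, B, t) {
  stopifnot(inherits(t, "tourism_params"))
  t$alpha + t$beta * q + t$gamma * B
}

#' Dives demanded at a given fee
#'
#' Inverts the demand line: `q = (fee - alpha - gamma B) / beta`, truncated
#' at zero once the fee exceeds the choke price `alpha + gamma B`.
#'
#' @param fee Fee per dive (currency).
#' @param B Reserve biomass (grams).
#' @param t A [tourism_params()].
#' @return Number of dives (`>= 0`).
#' @export
dives_demanded <- function(fee, B, t) {
  stopifnot(inherits(t, "tourism_params"))
  if (t$beta >= 0) stop("`beta` must be negative", call. = FALSE)
  pmax(0, (fee - t$alpha - t$gamma * B) / t$beta)
}

#' Revenue-maximising number of dives
#'
#' Setting the derivative of `fee(q) * q` to zero gives
#' `q* = -(alpha + gamma B) / (2 beta)`, floored at zero.
#'
#' @inheritParams dives_demanded
#' @return Number of dives.
#' @export
optimal_dives <- function(B, t) {
  stopifnot(inherits(t, "tourism_params"))
  if (t$beta >= 0) stop("`beta` must be negative", call. = FALSE)
  pmax(0, -(t$alpha + t$gamma * B) / (2 * t$beta))
}

#' Revenue-maximising fee per dive
#'
#' With linear demand the revenue-maximising fee is half the choke price:
#' `P* = (alpha + gamma B) / 2`. At this fee exactly [optimal_dives()] dives
#' are demanded.
#'
#' @inheritParams dives_demanded
#' @return Fee per dive (currency, floored at zero).
#' @export
optimal_fee <- function(B, t) {
  stopifnot(inherits(t, "tourism_params"))
  pmax(0, (t$alpha + t$gamma * B) / 2)
}

#' Annual tourism revenue
#'
#' @param fee Fee per dive.
#' @param q Number of dives.
#' @return `fee * q` (currency).
#' @export
tourism_revenue <- function(fee, q) {
  fee * q
}

#' Consumer surplus of divers
#'
#' The area under the inverse demand line above the fee, up to `q` dives:
#' `CS = (alpha + gamma B - fee) q + beta q^2 / 2`. Under a binding dive cap
#' this is the surplus of the capped dives at the fixed fee.
#'
#' @param fee Fee per dive.
#' @param q Number of dives actually taken (must not exceed demand at the
#'   fee, up to rounding).
#' @param B Reserve biomass (grams).
#' @param t A [tourism_params()].
#' @return Consumer surplus (currency).
#' @export
consumer_surplus <- function(fee, q, B, t) {
  stopifnot(inherits(t, "tourism_params"))
  if (t$beta >= 0) stop("`beta` must be negative", call. = FALSE)
  check_vector(q, "q", lower = 0)
  q_max <- dives_demanded(fee, B, t)
  if (any(q > q_max * (1 + 1e-9) + 1e-9)) {
    stop("`q` exceeds the dives demanded at this fee", call. = FALSE)
  }
  (t$alpha + t$gamma * B - fee) * q + t$beta * q^2 / 2
}

#' Calibrate linear dive demand to a known operating point
#'
#' The three demand parameters are rarely observable directly; what a site
#' knows is how many dives it sells at the going fee. This routine
#' constructs `(alpha, beta, gamma)` so that exactly `target_dives` dives
#' are demanded at `fee` when the reserve holds `B_ref` grams of the
#' tourism species, with the choke price at `B_ref` equal to
#' `choke_multiple * fee` and a fraction `biomass_share` of that choke price
#' attributed to the biomass term `gamma * B_ref`.
#'
#' @param target_dives Observed/targeted annual dives (`> 0`).
#' @param fee Fee per dive at the operating point (`> 0`).
#' @param B_ref Reference reserve biomass (grams; `> 0` unless
#'   `biomass_share = 0`).
#' @param choke_multiple Choke price as a multiple of the fee (`> 1`).
#' @param biomass_share Fraction of the choke price carried by the biomass
#'   term, in `[0, 1)` (default 0.5).
#' @param fee_policy,fixed_fee,cap Passed through to [tourism_params()];
#'   `fixed_fee` defaults to the calibration fee.
#' @return A [tourism_params()] reproducing the operating point.
#' @examples
#' t <- calibrate_demand(63000, fee = 3.5, B_ref = 1e8)
#' dives_demanded(3.5, 1e8, t)  # 63000
#' @export
calibrate_demand <- function(target_dives, fee, B_ref,
                             choke_multiple = 2, biomass_share = 0.5,
                             fee_policy = "fixed", fixed_fee = fee,
                             cap = NA_real_) {
  check_number(target_dives, "target_dives", lower = .Machine$double.xmin)
  check_number(fee, "fee", lower = .Machine$double.xmin)
  check_number(choke_multiple, "choke_multiple", lower = 1 + 1e-12)
  check_number(biomass_share, "biomass_share", lower = 0, upper = 1 - 1e-12)
  choke <- choke_multiple * fee
  if (biomass_share > 0) {
    check_number(B_ref, "B_ref", lower = .Machine$double.xmin)
    gamma <- biomass_share * choke / B_ref
  } else {
    gamma <- 0
  }
  alpha <- (1 - biomass_share) * choke
  beta <- (fee - choke) / target_dives
  tourism_params(alpha = alpha, beta = beta, gamma = gamma,
                 fee_policy = fee_policy, fixed_fee = fixed_fee, cap = cap)
}
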