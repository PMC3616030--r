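#' Biological and economic parameters for a single species
#'
#' Bundles the per-species constants of the delay-difference model with the
#' dispersal ranges, Beverton-Holt steepness, ex-vessel price and the role
#' the species plays in the economic layer.
#'
#' @param name Species label.
#' @param s_nat Annual natural survival fraction in `[0, 1]`.
#' @param w_k Average weight (grams) of an animal of reproductive age `k` and
#'   older.
#' @param w_km1 Average weight (grams) of a recruit (age `k - 1`).
#' @param rho Brody growth coefficient in `[0, 1)`; controls how fast an
#'   individual's weight approaches its asymptote.
#' @param R0 Unfished recruitment per patch (individuals per year).
#' @param sigma_L Larval dispersal range (patch-length units, `> 0`).
#' @param sigma_A Adult movement range (patch-length units, `> 0`).
#' @param h Beverton-Holt steepness in `(0.2, 1]`: the fraction of unfished
#'   recruitment produced when spawning output falls to 20% of its unfished
#'   level.
#' @param price Value per gram of catch (currency/g).
#' @param role `"fished"` (catch is valued in fishery profit) or `"tourism"`
#'   (biomass drives dive demand; any bycatch is unvalued).
#'
#' @return An object of class `species_params` (a named list).
#' @examples
#' mullet <- species_params("red_mullet", s_nat = 0.66, w_k = 53.93,
#'                          w_km1 = 0, rho = 0.77, R0 = 52000, sigma_L = 2,
#'                          sigma_A = 1, h = 0.75, price = 0.01,
#'                          role = "fished")
#' unfished_equilibrium(mullet)
#' @export
species_params <- function(name, s_nat, w_k, w_km1 = 0, rho, R0,
                           sigma_L, sigma_A, h, price = 0,
                           role = c("fished", "tourism")) {
  role <- match.arg(role)
  check_number(s_nat, "s_nat", 0, 1)
  check_number(w_k, "w_k", lower = .Machine$double.eps)
  check_number(w_km1, "w_km1", 0)
  check_number(rho, "rho", 0, 1 - 1e-12)
  check_number(R0, "R0", 0)
  check_number(sigma_L, "sigma_L", lower = .Machine$double.xmin)
  check_number(sigma_A, "sigma_A", lower = .Machine$double.xmin)
  check_number(h, "h", lower = 0.2 + 1e-12, upper = 1)
  check_number(price, "price", 0)
  structure(
    list(name = as.character(name), s_nat = s_nat, w_k = w_k, w_km1 = w_km1,
         rho = rho, R0 = R0, sigma_L = sigma_L, sigma_A = sigma_A, h = h,
         price = price, role = role),
    class = "species_params"
  )
}

#' @export
print.species_params <- function(x, ...) {
  cat(sprintf("<species_params> %s (%s)\n", x$name, x$role))
  cat(sprintf("  s_nat=%.3g  w_k=%.4g g  w_km1=%.4g g  rho=%.3g\n",
              x$s_nat, x$w_k, x$w_km1, x$rho))
  cat(sprintf("  R0=%.4g  sigma_L=%.3g  sigma_A=%.3g  h=%.3g  price=%.3g\n",
              x$R0, x$sigma_L, x$sigma_A, x$h, x$price))
  invisible(x)
}
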