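#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the annual series of a simulation
#'
#' @param x A [run_scenario()] result.
#' @param series `"annual"` (default), `"patches"` or `"audit"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.reserve_sim <- function(x, series = c("annual", "patches", "audit"),
                             ...) {
  series <- match.arg(series)
  x[[series]]
}

#' One-row summary of a simulation
#'
#' Reports the pre-reserve baseline (mean total value over the final 10
#' burn-in years), final-year values, the payback year and the dive series
#' endpoints.
#'
#' @param x A [run_scenario()] result.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.reserve_sim <- function(x, ...) {
  ann <- x$annual
  pre <- ann[ann$year < 0 & ann$year >= -10, ]
  fin <- ann[nrow(ann), ]
  tibble::tibble(
    baseline_TV = mean(pre$TV),
    baseline_FV = mean(pre$FV),
    final_TV = fin$TV,
    final_FV = fin$FV,
    final_dives = fin$dives,
    final_fee = fin$fee,
    final_TR = fin$TR,
    final_CS = fin$CS,
    payback_year = payback_year(x),
    n_years = nrow(ann),
    n_events = length(x$events_log),
    clamped_total = sum(ann$clamped))
}
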