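# ggplot2 views of simulation results.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Annual value series of a simulation
#'
#' Fishery profit, tourism value (revenue + consumer surplus) and total
#' value against simulation year, with the reserve implementation marked at
#' year zero.
#'
#' @param object A [run_scenario()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.reserve_sim <- function(object, ...) {
  dat <- object$annual |>
    dplyr::mutate(`tourism value` = .data$TR + .data$CS,
                  `fishery profit` = .data$FV,
                  `total value` = .data$TV) |>
    tidyr::pivot_longer(c("fishery profit", "tourism value", "total value"),
                        names_to = "component", values_to = "value")
  ggplot2::ggplot(dat, ggplot2::aes(.data$year, .data$value,
                                    colour = .data$component)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "year (0 = reserve implementation)",
                  y = "annual value (currency)", colour = NULL,
                  title = object$config$name) +
    ggplot2::theme_minimal()
}

#' Alongshore biomass profile in a chosen year
#'
#' Post-movement biomass per patch for each species, with the no-take and
#' partially protected zones shaded.
#'
#' @param result A [run_scenario()] result.
#' @param year Simulation year to show (default: final year).
#' @return A ggplot.
#' @export
plot_biomass_profile <- function(result, year = NULL) {
  stopifnot(inherits(result, "reserve_sim"))
  year <- year %||% max(result$patches$year)
  dat <- dplyr::filter(result$patches, .data$year == !!year)
  zones <- dat |>
    dplyr::distinct(.data$patch, .data$zone) |>
    dplyr::filter(.data$zone != "open")
  ggplot2::ggplot(dat, ggplot2::aes(.data$patch, .data$biomass)) +
    ggplot2::geom_rect(data = zones,
                       ggplot2::aes(xmin = .data$patch - 0.5,
                                    xmax = .data$patch + 0.5,
                                    fill = .data$zone),
                       ymin = -Inf, ymax = Inf, alpha = 0.25,
                       inherit.aes = FALSE) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::labs(x = "patch", y = "biomass after movement (g)",
                  fill = "zone",
                  title = sprintf("year %d", as.integer(year))) +
    ggplot2::theme_minimal()
}

#' Dive demand, revenue and consumer surplus at a biomass level
#'
#' Draws the inverse demand line at reserve biomass `B`, the fee, and the
#' revenue and consumer-surplus areas it implies.
#'
#' @param t A [tourism_params()].
#' @param B Reserve biomass (grams).
#' @param fee Fee per dive; defaults to the revenue-maximising fee.
#' @return A ggplot.
#' @export
plot_demand <- function(t, B, fee = NULL) {
  stopifnot(inherits(t, "tourism_params"))
  fee <- fee %||% optimal_fee(B, t)
  q_choke <- dives_demanded(0, B, t)
  q_fee <- dives_demanded(fee, B, t)
  line <- tibble::tibble(q = seq(0, q_choke, length.out = 200)) |>
    dplyr::mutate(mv = marginal_dive_value(.data$q, B, t))
  cs_poly <- dplyr::filter(line, .data$q <= q_fee)
  ggplot2::ggplot(line, ggplot2::aes(.data$q, .data$mv)) +
    ggplot2::geom_ribbon(data = cs_poly,
                         ggplot2::aes(ymin = fee, ymax = .data$mv),
                         fill = "steelblue", alpha = 0.35) +
    ggplot2::annotate("rect", xmin = 0, xmax = q_fee, ymin = 0, ymax = fee,
                      fill = "darkgreen", alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = fee, linetype = "dotted") +
    ggplot2::labs(x = "dives per year", y = "marginal dive value",
                  title = "linear inverse dive demand",
                  subtitle = "shaded: consumer surplus (blue), revenue (green)") +
    ggplot2::theme_minimal()
}
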