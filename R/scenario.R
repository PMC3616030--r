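# Scenario engine: zoning, reserve harvest rules, the annual simulation
# loop, management events and the payback summary.

#' Partition a coastline into no-take, partial and open zones
#'
#' Patch counts come from the fractions by largest-remainder rounding (ties
#' broken in the order no-take, partial, open). The no-take block is centred
#' on the coastline midpoint, the partial zone flanks it symmetrically (an
#' odd patch goes to the right flank), and the remainder is open. Centring
#' keeps the reserve away from the domain ends, so reserve effects are not
#' confounded with boundary renormalisation of the kernels.
#'
#' @param n_patches Number of patches.
#' @param fractions Numeric length-3 vector `(no_take, partial, open)`;
#'   non-negative, summing to 1.
#' @param patch_length Patch length (distance units).
#' @return A [coastline()] with zone labels.
#' @examples
#' build_zones(100, c(0.01, 0.12, 0.87))
#' @export
build_zones <- function(n_patches, fractions, patch_length = 1) {
  check_vector(fractions, "fractions", len = 3, lower = 0)
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("`fractions` must sum to 1", call. = FALSE)
  }
  n_patches <- as.integer(n_patches)
  exact <- n_patches * fractions
  counts <- floor(exact)
  rem <- exact - counts
  short <- n_patches - sum(counts)
  if (short > 0) {
    take <- order(rem, -seq_along(rem), decreasing = TRUE)[seq_len(short)]
    counts[take] <- counts[take] + 1
  }
  n_nt <- counts[1]; n_pa <- counts[2]
  zone <- rep("open", n_patches)
  nt_start <- floor((n_patches - n_nt) / 2) + 1
  if (n_nt > 0) zone[seq(nt_start, length.out = n_nt)] <- "no_take"
  left <- floor(n_pa / 2)
  right <- n_pa - left
  if (left > 0) zone[seq(nt_start - left, length.out = left)] <- "partial"
  if (right > 0) {
    zone[seq(nt_start + n_nt, length.out = right)] <- "partial"
  }
  coastline(n_patches, patch_length, zone)
}

#' Zoned harvest rates after reserve implementation
#'
#' Fishing stops in the no-take zone, is reduced by `partial_reduction` in
#' the partially protected zone, and continues unchanged outside.
#'
#' @param u_pre Pre-reserve harvest rate for the species.
#' @param coast A [coastline()] with zone labels.
#' @param partial_reduction Fraction by which harvest is reduced in the
#'   partial zone (default 0.5, i.e. halved).
#' @return Per-patch harvest rates.
#' @export
apply_reserve <- function(u_pre, coast, partial_reduction = 0.5) {
  stopifnot(inherits(coast, "coastline"))
  check_number(u_pre, "u_pre", 0, 1)
  check_number(partial_reduction, "partial_reduction", 0, 1)
  u <- rep(u_pre, coast$n_patches)
  u[coast$zone == "no_take"] <- 0
  u[coast$zone == "partial"] <- u_pre * (1 - partial_reduction)
  u
}

#' Assemble a reserve-implementation scenario
#'
#' Bundles the coastline, species list (each with its pre-reserve harvest
#' rate), economic and tourism parameters, timeline and management events
#' into a validated configuration the simulator consumes.
#'
#' @param coast A [coastline()] (typically from [build_zones()]).
#' @param species List of [species_params()].
#' @param u_pre Named (by species) or positional numeric vector of
#'   pre-reserve harvest rates in `[0, 1]`.
#' @param econ An [econ_params()].
#' @param tourism A [tourism_params()], e.g. from [calibrate_demand()].
#' @param burn_in_years Pre-reserve years simulated (default 100).
#' @param post_years Post-reserve years simulated (default 100).
#' @param partial_reduction Harvest reduction in the partial zone.
#' @param events List of management events; currently
#'   `list(type = "cap_dives", year = <post-reserve year>, fee = <fee>)`,
#'   which freezes the fee and caps annual dives at the demand realised in
#'   the event year.
#' @param include_partial_in_reserve Should the partial zone's biomass count
#'   toward the dive-demand biomass? Default `FALSE` (divers visit the
#'   no-take core).
#' @param name Scenario label.
#' @param seed Integer recorded in the manifest; the simulator itself is
#'   deterministic and uses no randomness.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(coast, species, u_pre, econ, tourism,
                            burn_in_years = 100, post_years = 100,
                            partial_reduction = 0.5, events = list(),
                            include_partial_in_reserve = FALSE,
                            name = "scenario", seed = 1L) {
  stopifnot(inherits(coast, "coastline"), inherits(econ, "econ_params"),
            inherits(tourism, "tourism_params"))
  if (!length(species) || !all(vapply(species, inherits, TRUE,
                                      "species_params"))) {
    stop("`species` must be a non-empty list of species_params",
         call. = FALSE)
  }
  nm <- vapply(species, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("species names must be unique", call. = FALSE)
  check_vector(u_pre, "u_pre", len = length(species), lower = 0, upper = 1)
  if (!is.null(names(u_pre))) {
    if (!setequal(names(u_pre), nm)) {
      stop("names of `u_pre` must match species names", call. = FALSE)
    }
    u_pre <- u_pre[nm]
  } else {
    names(u_pre) <- nm
  }
  check_number(burn_in_years, "burn_in_years", lower = 1)
  check_number(post_years, "post_years", lower = 1)
  check_number(partial_reduction, "partial_reduction", 0, 1)
  cost <- econ$cost
  if (length(cost) != 1L && length(cost) != coast$n_patches) {
    stop("`econ$cost` must be scalar or one value per patch", call. = FALSE)
  }
  for (ev in events) {
    if (!is.list(ev) || is.null(ev$type)) {
      stop("each event must be a list with a `type`", call. = FALSE)
    }
    if (!identical(ev$type, "cap_dives")) {
      stop("unknown event type: ", ev$type, call. = FALSE)
    }
    check_number(ev$year, "events$year", lower = 0)
    check_number(ev$fee %||% tourism$fixed_fee, "events$fee", lower = 0)
  }
  structure(
    list(name = name, coast = coast, species = species, u_pre = u_pre,
         econ = econ, tourism = tourism,
         burn_in_years = as.integer(burn_in_years),
         post_years = as.integer(post_years),
         partial_reduction = partial_reduction, events = events,
         include_partial_in_reserve = include_partial_in_reserve,
         seed = as.integer(seed)),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config> '%s': %d species, %d patches, %d + %d years\n",
              x$name, length(x$species), x$coast$n_patches,
              x$burn_in_years, x$post_years))
  for (i in seq_along(x$species)) {
    sp <- x$species[[i]]
    cat(sprintf("  %s (%s): u_pre = %.4g\n", sp$name, sp$role, x$u_pre[i]))
  }
  if (length(x$events)) {
    cat(sprintf("  events: %s\n",
                paste(vapply(x$events, function(e)
                  sprintf("%s@yr%g", e$type, e$year), ""), collapse = ", ")))
  }
  invisible(x)
}

# biomass of the tourism-role species inside the reserve, given post-movement
# biomass matrices (patches x species)
reserve_biomass <- function(B_tilde, config) {
  zones <- c("no_take", if (config$include_partial_in_reserve) "partial")
  in_res <- config$coast$zone %in% zones
  idx <- which(vapply(config$species, `[[`, "", "role") == "tourism")
  if (!length(idx) || !any(in_res)) return(0)
  sum(vapply(idx, function(j) sum(B_tilde[in_res, j]), 0))
}

#' Run a reserve-implementation simulation
#'
#' Simulates every species independently on the shared coastline through the
#' burn-in (years `-burn_in_years` to `-1`, fished at `u_pre` everywhere)
#' and the post-reserve period (years `0` to `post_years - 1`, zoned harvest
#' from [apply_reserve()]). Each species starts at its unfished equilibrium.
#'
#' Within a year, for each species: (1) adults move; (2) catch and survival
#' are taken from the post-movement biomass; (3) eggs equal the start-of-year
#' (post-movement, pre-catch) spawning biomass and are dispersed and settled;
#' (4) Beverton-Holt recruitment converts settlement to next year's recruits;
#' (5) the delay-difference update produces next year's biomass. Economics
#' then values the year: fishery profit from fished-role species, dive demand
#' from the tourism-role biomass in the reserve under the active fee policy,
#' tourism revenue and consumer surplus. A `cap_dives` event freezes the fee
#' and caps dives at the demand realised in its year.
#'
#' @param config A [scenario_config()].
#' @return An object of class `reserve_sim`: list with tibbles `annual`
#'   (year, FV, reserve biomass, dives, fee, TR, CS, TV, policy), `patches`
#'   (year, species, patch, zone, biomass, catch), `audit` (per-year term
#'   sums of the biomass update for mass-balance reconstruction), the
#'   `config`, and `events_log`.
#' @examples
#' cfg <- medes_scenario(burn_in_years = 50, post_years = 30)
#' sim <- run_scenario(cfg)
#' glance(sim)
#' @export
run_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  coast <- config$coast
  n <- coast$n_patches
  n_sp <- length(config$species)
  years <- seq(-config$burn_in_years, config$post_years - 1L)
  n_yr <- length(years)

  # per-species static pieces
  KA <- lapply(config$species, function(sp)
    dispersal_matrix(coast, sp$sigma_A)$matrix)
  KL <- lapply(config$species, function(sp)
    dispersal_matrix(coast, sp$sigma_L)$matrix)
  B0 <- vapply(config$species, unfished_equilibrium, 0)
  E0 <- lapply(seq_len(n_sp), function(j)
    settle_larvae(rep(B0[j], n), KL[[j]]))
  u_post <- lapply(seq_len(n_sp), function(j)
    apply_reserve(config$u_pre[j], coast, config$partial_reduction))

  # state: start-of-year (pre-movement) biomass + delay-difference lags
  B_raw <- lapply(seq_len(n_sp), function(j) rep(B0[j], n))
  B_tilde_prev <- lapply(seq_len(n_sp), function(j)
    move_adults(B_raw[[j]], KA[[j]]))
  R_cur <- lapply(seq_len(n_sp), function(j)
    rep(config$species[[j]]$R0, n))
  s_prev <- lapply(seq_len(n_sp), function(j)
    rep(config$species[[j]]$s_nat, n))

  tour <- config$tourism
  cap_ev <- NULL
  for (ev in config$events) if (ev$type == "cap_dives") cap_ev <- ev
  events_log <- list()

  annual <- vector("list", n_yr)
  audit <- vector("list", n_yr)
  Bt_rec <- array(NA_real_, c(n_yr, n, n_sp))
  C_rec <- array(NA_real_, c(n_yr, n, n_sp))

  for (k in seq_len(n_yr)) {
    yr <- years[k]
    B_tilde_now <- vector("list", n_sp)
    total_clamped <- 0
    for (j in seq_len(n_sp)) {
      sp <- config$species[[j]]
      u <- if (yr < 0) rep(config$u_pre[j], n) else u_post[[j]]
      B_tilde <- move_adults(B_raw[[j]], KA[[j]])
      if (any(!is.finite(B_tilde))) {
        stop(sprintf("non-finite biomass for %s in year %d (patch %d)",
                     sp$name, yr, which(!is.finite(B_tilde))[1]),
             call. = FALSE)
      }
      C <- catch_biomass(u, B_tilde)
      s_now <- annual_survival(sp$s_nat, u)
      E <- settle_larvae(B_tilde, KL[[j]])
      R_next <- beverton_holt(E, sp$h, sp$R0, E0[[j]])
      st <- pop_state(B = B_tilde, B_prev = B_tilde_prev[[j]],
                      R = R_cur[[j]], R_next = R_next,
                      s_prev = s_prev[[j]])
      B_new <- step_biomass(st, sp, s_now)
      audit[[k]] <- rbind(audit[[k]], tibble::tibble(
        year = yr, species = sp$name,
        growth = (1 + sp$rho) * sum(s_now * B_tilde),
        lag = -sp$rho * sum(s_now * s_prev[[j]] * B_tilde_prev[[j]]),
        recruit_weight = -sp$rho * sp$w_km1 * sum(s_now * R_cur[[j]]),
        recruitment = sp$w_k * sum(R_next),
        catch = sum(C),
        clamped = attr(B_new, "clamped"),
        biomass_next = sum(B_new)))
      total_clamped <- total_clamped + attr(B_new, "clamped")
      Bt_rec[k, , j] <- B_tilde
      C_rec[k, , j] <- C
      B_tilde_prev[[j]] <- B_tilde
      R_cur[[j]] <- R_next
      s_prev[[j]] <- s_now
      B_raw[[j]] <- as.numeric(B_new)
      B_tilde_now[[j]] <- B_tilde
    }

    # --- economics ---
    FV <- 0
    for (j in seq_len(n_sp)) {
      sp <- config$species[[j]]
      if (sp$role != "fished") next
      u <- if (yr < 0) rep(config$u_pre[j], n) else u_post[[j]]
      FV <- FV + fishery_profit(C_rec[k, , j], u, sp$price, config$econ)
    }
    B_res <- reserve_biomass(do.call(cbind, B_tilde_now), config)

    cap_active <- !is.null(cap_ev) && yr >= cap_ev$year
    if (cap_active && yr == cap_ev$year) {
      cap_fee <- cap_ev$fee %||% tour$fixed_fee
      cap_level <- dives_demanded(cap_fee, B_res, tour)
      tour <- tourism_params(tour$alpha, tour$beta, tour$gamma,
                             fee_policy = "capped", fixed_fee = cap_fee,
                             cap = cap_level)
      events_log[[length(events_log) + 1L]] <-
        list(type = "cap_dives", year = yr, fee = cap_fee, cap = cap_level)
    }
    if (cap_active) {
      fee <- tour$fixed_fee
      q <- min(tour$cap, dives_demanded(fee, B_res, tour))
      policy <- "capped"
    } else if (tour$fee_policy == "optimal") {
      fee <- optimal_fee(B_res, tour)
      q <- optimal_dives(B_res, tour)
      policy <- "optimal"
    } else {
      fee <- tour$fixed_fee
      q <- dives_demanded(fee, B_res, tour)
      policy <- "fixed"
    }
    TR <- tourism_revenue(fee, q)
    CS <- consumer_surplus(fee, q, B_res, tour)
    annual[[k]] <- tibble::tibble(
      year = yr, FV = FV, reserve_biomass = B_res, dives = q, fee = fee,
      TR = TR, CS = CS, TV = FV + TR + CS, policy = policy,
      clamped = total_clamped)
  }

  patches <- tidyr::expand_grid(
    year = years,
    species = vapply(config$species, `[[`, "", "name"),
    patch = seq_len(n))
  ord <- order(patches$year, match(patches$species,
                                   vapply(config$species, `[[`, "", "name")),
               patches$patch)
  patches <- patches[ord, ]
  patches$zone <- coast$zone[patches$patch]
  patches$biomass <- as.numeric(aperm(Bt_rec, c(2, 3, 1)))
  patches$catch <- as.numeric(aperm(C_rec, c(2, 3, 1)))

  res <- structure(
    list(annual = dplyr::bind_rows(annual),
         patches = tibble::as_tibble(patches),
         audit = dplyr::bind_rows(audit),
         config = config, events_log = events_log),
    class = "reserve_sim")
  total_clamped <- sum(res$annual$clamped)
  if (total_clamped > 0) {
    warning(sprintf("negative biomass clamped to zero (total %.3g g)",
                    total_clamped), call. = FALSE)
  }
  res
}

#' @export
print.reserve_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<reserve_sim> '%s': %d + %d years, %d species, %d patches\n",
              cfg$name, cfg$burn_in_years, cfg$post_years,
              length(cfg$species), cfg$coast$n_patches))
  pre <- mean(x$annual$TV[x$annual$year < 0 &
                            x$annual$year >= -10])
  fin <- x$annual$TV[nrow(x$annual)]
  cat(sprintf("  pre-reserve TV (last 10 yr mean): %.4g\n", pre))
  cat(sprintf("  final-year TV: %.4g  (payback year: %s)\n", fin,
              format(payback_year(x))))
  invisible(x)
}

#' First post-reserve year in which total value recovers
#'
#' Compares each post-reserve year's total value (fishery profit + tourism
#' revenue + consumer surplus) with the mean total value over the final 10
#' burn-in years, and returns the first year at or above that baseline.
#'
#' @param result A [run_scenario()] result.
#' @return Post-reserve year index (0 = implementation year), or
#'   `NA_integer_` if the baseline is never reached within the horizon.
#' @export
payback_year <- function(result) {
  stopifnot(inherits(result, "reserve_sim"))
  ann <- result$annual
  base_years <- ann$year < 0 & ann$year >= -10
  baseline <- mean(ann$TV[base_years])
  post <- ann[ann$year >= 0, ]
  hit <- which(post$TV >= baseline)
  if (!length(hit)) return(NA_integer_)
  as.integer(post$year[hit[1]])
}
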