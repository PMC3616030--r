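# Configuration files (YAML), CSV/JSON output and the run manifest.

scenario_schema <- list(
  top = c("name", "seed", "coast", "years", "partial_reduction",
          "include_partial_in_reserve", "econ", "tourism", "events",
          "species"),
  coast = c("n_patches", "patch_length", "fractions"),
  years = c("burn_in", "post"),
  econ = c("cost"),
  tourism = c("fee_policy", "fixed_fee", "alpha", "beta", "gamma",
              "calibration"),
  calibration = c("target_dives", "fee", "reference_biomass",
                  "choke_multiple", "biomass_share"),
  species = c("name", "role", "s_nat", "w_k", "w_km1", "rho", "R0",
              "sigma_L", "sigma_A", "h", "price", "u_pre",
              "u_pre_msy_multiple"),
  events = c("type", "year", "fee")
)

check_keys <- function(x, allowed, path) {
  bad <- setdiff(names(x), allowed)
  if (length(bad)) {
    stop(sprintf("unknown key(s) at %s: %s", path,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

need_key <- function(x, key, path) {
  if (is.null(x[[key]])) {
    stop(sprintf("missing required field `%s` at %s", key, path),
         call. = FALSE)
  }
  x[[key]]
}

#' Load a scenario configuration from a YAML file
#'
#' Parses and fully validates a scenario document. Harvest rates may be
#' given directly (`u_pre`) or as a multiple of the species'
#' numerically-located MSY rate (`u_pre_msy_multiple`); tourism demand may
#' be given as explicit `(alpha, beta, gamma)` or as a `calibration` block
#' (see [calibrate_demand()]) whose `reference_biomass` is either a number
#' (grams) or the keyword `"unfished_reserve"` (unfished biomass of the
#' tourism species summed over the no-take zone). Unknown keys are
#' rejected with their key path.
#'
#' @param path Path to a YAML scenario file, e.g. the bundled
#'   `system.file("extdata", "medes.yaml", package = "reservesim")`.
#' @return A validated [scenario_config()].
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  scenario_from_list(doc)
}

scenario_from_list <- function(doc) {
  check_keys(doc, scenario_schema$top, "top level")
  co <- need_key(doc, "coast", "top level")
  check_keys(co, scenario_schema$coast, "coast")
  coast <- build_zones(need_key(co, "n_patches", "coast"),
                       as.numeric(need_key(co, "fractions", "coast")),
                       patch_length = co$patch_length %||% 1)
  yr <- need_key(doc, "years", "top level")
  check_keys(yr, scenario_schema$years, "years")

  sp_docs <- need_key(doc, "species", "top level")
  species <- vector("list", length(sp_docs))
  u_pre <- numeric(length(sp_docs))
  for (i in seq_along(sp_docs)) {
    sd <- sp_docs[[i]]
    pathi <- sprintf("species[%d]", i)
    check_keys(sd, scenario_schema$species, pathi)
    species[[i]] <- species_params(
      name = need_key(sd, "name", pathi),
      s_nat = need_key(sd, "s_nat", pathi),
      w_k = need_key(sd, "w_k", pathi),
      w_km1 = sd[["w_km1"]] %||% 0,
      rho = need_key(sd, "rho", pathi),
      R0 = need_key(sd, "R0", pathi),
      sigma_L = need_key(sd, "sigma_L", pathi),
      sigma_A = need_key(sd, "sigma_A", pathi),
      h = need_key(sd, "h", pathi),
      price = sd[["price"]] %||% 0,
      role = need_key(sd, "role", pathi))
    if (!is.null(sd[["u_pre"]]) && !is.null(sd[["u_pre_msy_multiple"]])) {
      stop(sprintf("%s: give `u_pre` or `u_pre_msy_multiple`, not both",
                   pathi), call. = FALSE)
    }
    u_pre[i] <- if (!is.null(sd[["u_pre"]])) {
      sd[["u_pre"]]
    } else if (!is.null(sd[["u_pre_msy_multiple"]])) {
      min(1, sd[["u_pre_msy_multiple"]] * find_msy(species[[i]])$u_msy)
    } else {
      stop(sprintf("%s: missing `u_pre` (or `u_pre_msy_multiple`)", pathi),
           call. = FALSE)
    }
  }

  ec <- doc$econ %||% list(cost = 0)
  check_keys(ec, scenario_schema$econ, "econ")
  econ <- econ_params(cost = as.numeric(ec$cost %||% 0))

  to <- need_key(doc, "tourism", "top level")
  check_keys(to, scenario_schema$tourism, "tourism")
  fee_policy <- to$fee_policy %||% "fixed"
  if (!is.null(to$calibration)) {
    ca <- to$calibration
    check_keys(ca, scenario_schema$calibration, "tourism$calibration")
    B_ref <- need_key(ca, "reference_biomass", "tourism$calibration")
    if (identical(B_ref, "unfished_reserve")) {
      idx <- which(vapply(species, `[[`, "", "role") == "tourism")
      if (!length(idx)) {
        stop("reference_biomass = unfished_reserve needs a tourism species",
             call. = FALSE)
      }
      n_nt <- sum(coast$zone == "no_take")
      B_ref <- sum(vapply(species[idx], unfished_equilibrium, 0)) * n_nt
    }
    tourism <- calibrate_demand(
      target_dives = need_key(ca, "target_dives", "tourism$calibration"),
      fee = need_key(ca, "fee", "tourism$calibration"),
      B_ref = B_ref,
      choke_multiple = ca$choke_multiple %||% 2,
      biomass_share = ca$biomass_share %||% 0.5,
      fee_policy = fee_policy,
      fixed_fee = to$fixed_fee %||% need_key(ca, "fee",
                                             "tourism$calibration"))
  } else {
    tourism <- tourism_params(
      alpha = need_key(to, "alpha", "tourism"),
      beta = need_key(to, "beta", "tourism"),
      gamma = to$gamma %||% 0,
      fee_policy = fee_policy,
      fixed_fee = to$fixed_fee %||% 0)
  }

  events <- lapply(doc$events %||% list(), function(ev) {
    check_keys(ev, scenario_schema$events, "events[]")
    ev
  })

  scenario_config(
    coast = coast, species = species, u_pre = u_pre, econ = econ,
    tourism = tourism,
    burn_in_years = need_key(yr, "burn_in", "years"),
    post_years = need_key(yr, "post", "years"),
    partial_reduction = doc$partial_reduction %||% 0.5,
    events = events,
    include_partial_in_reserve = doc$include_partial_in_reserve %||% FALSE,
    name = doc$name %||% "scenario",
    seed = doc$seed %||% 1L)
}

scenario_to_list <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  zone <- config$coast$zone
  fr <- c(mean(zone == "no_take"), mean(zone == "partial"),
          mean(zone == "open"))
  list(
    name = config$name,
    seed = config$seed,
    coast = list(n_patches = config$coast$n_patches,
                 patch_length = config$coast$patch_length,
                 fractions = fr),
    years = list(burn_in = config$burn_in_years,
                 post = config$post_years),
    partial_reduction = config$partial_reduction,
    include_partial_in_reserve = config$include_partial_in_reserve,
    econ = list(cost = config$econ$cost),
    tourism = list(fee_policy = config$tourism$fee_policy,
                   fixed_fee = config$tourism$fixed_fee,
                   alpha = config$tourism$alpha,
                   beta = config$tourism$beta,
                   gamma = config$tourism$gamma),
    events = config$events,
    species = lapply(seq_along(config$species), function(i) {
      sp <- config$species[[i]]
      list(name = sp$name, role = sp$role, s_nat = sp$s_nat, w_k = sp$w_k,
           w_km1 = sp$w_km1, rho = sp$rho, R0 = sp$R0,
           sigma_L = sp$sigma_L, sigma_A = sp$sigma_A, h = sp$h,
           price = sp$price, u_pre = unname(config$u_pre[i]))
    })
  )
}

#' Serialise a scenario configuration to YAML
#'
#' Writes the fully-resolved configuration (harvest rates and demand
#' parameters resolved to numbers), so that loading the written file
#' reproduces the configuration exactly.
#'
#' @param config A [scenario_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scenario_config <- function(config, path) {
  yaml::write_yaml(scenario_to_list(config), path, precision = 15)
  invisible(path)
}

#' Write the annual economic time series to CSV
#'
#' One row per simulated year with columns `year`, `FV`, `reserve_biomass`,
#' `dives`, `fee`, `TR`, `CS`, `TV`, `policy`. Numbers are serialised at
#' full (round-trip) precision; an empty result yields a header-only file.
#'
#' @param result A [run_scenario()] result.
#' @param path Output CSV path.
#' @param patches_path Optional path for the long-format per-patch
#'   companion table (`year`, `species`, `patch`, `zone`, `biomass`,
#'   `catch`).
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(result, path, patches_path = NULL) {
  stopifnot(inherits(result, "reserve_sim"))
  cols <- c("year", "FV", "reserve_biomass", "dives", "fee", "TR", "CS",
            "TV", "policy")
  readr::write_csv(result$annual[, cols], path)
  if (!is.null(patches_path)) {
    readr::write_csv(result$patches, patches_path)
  }
  invisible(path)
}

#' Write a JSON summary of a run
#'
#' Records the scenario name, the [glance()] summary row and the fired
#' management events.
#'
#' @param result A [run_scenario()] result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(result, path) {
  stopifnot(inherits(result, "reserve_sim"))
  out <- c(list(scenario = result$config$name),
           as.list(glance(result)),
           list(events = result$events_log))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Reproducibility manifest for a run
#'
#' The configuration digest is the MD5 of the canonical (fully resolved)
#' YAML serialisation, so identical configurations always share a digest.
#'
#' @param config A [scenario_config()].
#' @param result Optional [run_scenario()] result (for the event log).
#' @param started,finished Optional POSIXct timestamps.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(config, result = NULL, started = Sys.time(),
                         finished = Sys.time()) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_scenario_config(config, tmp)
  digest <- unname(tools::md5sum(tmp))
  structure(
    list(scenario = config$name, config_digest = digest,
         seed = config$seed,
         version = as.character(utils::packageVersion("reservesim")),
         started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
         finished = format(finished, "%Y-%m-%dT%H:%M:%S%z"),
         events = if (is.null(result)) list() else result$events_log),
    class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest>\n")
  cat(sprintf("  scenario: %s\n  digest: %s\n  seed: %d\n  version: %s\n",
              x$scenario, x$config_digest, x$seed, x$version))
  invisible(x)
}

#' Write a manifest as plain text
#'
#' @param manifest A [run_manifest()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "run_manifest"))
  ev <- vapply(manifest$events, function(e)
    sprintf("%s year=%g fee=%g cap=%.6f", e$type, e$year, e$fee, e$cap), "")
  lines <- c(
    sprintf("scenario: %s", manifest$scenario),
    sprintf("config_digest: %s", manifest$config_digest),
    sprintf("seed: %d", manifest$seed),
    sprintf("version: %s", manifest$version),
    sprintf("started: %s", manifest$started),
    sprintf("finished: %s", manifest$finished),
    if (length(ev)) paste("event:", ev) else "events: none")
  writeLines(lines, path)
  invisible(path)
}
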