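# Linear-coastline geometry, Gaussian movement kernels, settlement and
# Beverton-Holt recruitment.

#' A linear coastline of equal-length patches
#'
#' @param n_patches Number of patches (`>= 3`).
#' @param patch_length Length of one patch (distance units; default 1).
#' @param zone Per-patch zone labels in `{"no_take", "partial", "open"}`;
#'   defaults to all open. See [build_zones()] for the zoned constructor.
#' @return An object of class `coastline`.
#' @export
coastline <- function(n_patches = 100, patch_length = 1,
                      zone = rep("open", n_patches)) {
  check_number(n_patches, "n_patches", lower = 3)
  check_number(patch_length, "patch_length", lower = .Machine$double.xmin)
  n_patches <- as.integer(n_patches)
  zone <- as.character(zone)
  if (length(zone) != n_patches) {
    stop("`zone` must have one label per patch", call. = FALSE)
  }
  bad <- setdiff(unique(zone), c("no_take", "partial", "open"))
  if (length(bad)) {
    stop("unknown zone label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(n_patches = n_patches, patch_length = patch_length,
                 zone = zone),
            class = "coastline")
}

#' @export
print.coastline <- function(x, ...) {
  tab <- table(factor(x$zone, c("no_take", "partial", "open")))
  cat(sprintf("<coastline> %d patches (length %g): %d no-take, %d partial, %d open\n",
              x$n_patches, x$patch_length, tab[["no_take"]], tab[["partial"]],
              tab[["open"]]))
  invisible(x)
}

#' Row-normalised Gaussian dispersal kernel
#'
#' Movement from patch i to patch j is weighted by
#' `exp(-d^2 / (2 sigma^2))` with `d = |i - j| * patch_length`
#' (centre-to-centre), then each row is normalised to sum to one so that no
#' individuals are lost off the ends of the coastline (mass near a boundary
#' is implicitly reflected back into the domain by the renormalisation).
#'
#' @param coast A [coastline()].
#' @param sigma Dispersal range (> 0), in patch-length units.
#' @return An object of class `dispersal_kernel`: list with the
#'   row-stochastic `matrix` and `sigma`.
#' @examples
#' k <- dispersal_matrix(coastline(10), sigma = 1)
#' rowSums(k$matrix)
#' @export
dispersal_matrix <- function(coast, sigma) {
  stopifnot(inherits(coast, "coastline"))
  check_number(sigma, "sigma", lower = .Machine$double.xmin)
  pos <- seq_len(coast$n_patches) * coast$patch_length
  d <- abs(outer(pos, pos, "-"))
  w <- exp(-d^2 / (2 * sigma^2))
  w <- w / rowSums(w)
  structure(list(matrix = w, sigma = sigma), class = "dispersal_kernel")
}

kernel_matrix <- function(kernel) {
  if (inherits(kernel, "dispersal_kernel")) kernel$matrix else kernel
}

#' Disperse larvae and settle them on the coastline
#'
#' Egg production equals the spawning biomass at the beginning of the year,
#' so eggs are carried in grams. Settlement in patch j is the kernel-weighted
#' sum of eggs over source patches; because the kernel is row-stochastic the
#' coastline total is conserved.
#'
#' @param eggs Per-patch spawning output (grams, `>= 0`).
#' @param kernel A [dispersal_matrix()] built with the larval range
#'   `sigma_L`.
#' @return Per-patch settled eggs (grams).
#' @export
settle_larvae <- function(eggs, kernel) {
  m <- kernel_matrix(kernel)
  check_vector(eggs, "eggs", len = nrow(m), lower = 0)
  as.numeric(eggs %*% m)
}

#' Redistribute adult biomass along the coastline
#'
#' Identical mechanics to [settle_larvae()] but applied to adult biomass
#' with the adult movement range `sigma_A`. The output is the post-movement
#' biomass used by both the biological update and the catch equation.
#'
#' @param biomass Per-patch biomass (grams, `>= 0`).
#' @param kernel A [dispersal_matrix()] built with `sigma_A`.
#' @return Per-patch biomass after movement (grams).
#' @export
move_adults <- function(biomass, kernel) {
  m <- kernel_matrix(kernel)
  check_vector(biomass, "biomass", len = nrow(m), lower = 0)
  as.numeric(biomass %*% m)
}

#' Beverton-Holt recruitment in the steepness parameterisation
#'
#' `R = 4 h R0 E / ((1 - h) E0 + (5h - 1) E)`, where steepness `h` is the
#' fraction of unfished recruitment produced when settlement falls to 20% of
#' its unfished level `E0`. `E` and `E0` share units (grams of settled
#' spawning output), so the form is unit-consistent.
#'
#' @param E Settled eggs per patch (grams, `>= 0`); vectorised.
#' @param h Steepness in `(0.2, 1]`.
#' @param R0 Unfished recruitment per patch (individuals).
#' @param E0 Settlement at the unfished equilibrium (grams, `> 0`); scalar
#'   or one value per patch.
#' @return Recruits per patch (individuals).
#' @examples
#' beverton_holt(E = 0.2 * 100, h = 0.75, R0 = 1000, E0 = 100)  # 750
#' @export
beverton_holt <- function(E, h, R0, E0) {
  check_vector(E, "E", lower = 0)
  check_number(h, "h", lower = 0.2 + 1e-12, upper = 1)
  check_number(R0, "R0", lower = 0)
  if (any(E0 <= 0)) stop("`E0` must be > 0", call. = FALSE)
  if (length(E0) != 1L && length(E0) != length(E)) {
    stop("`E0` must be scalar or match the length of `E`", call. = FALSE)
  }
  4 * h * R0 * E / ((1 - h) * E0 + (5 * h - 1) * E)
}
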