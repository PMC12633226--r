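#' Default synthetic particle-population configuration
#'
#' Emulates conditioned cell-culture media as a four-species mixture. The
#' exomere size distribution (truncated normal, mean 45.6 nm, sd 10.7 nm)
#' reflects pooled TEM measurements of TFF-isolated exomeres; the small-EV
#' (60, 15), large-EV (100, 25) and free-protein (point, 6 nm) distributions
#' are synthetic defaults anchored only to the ~60 and ~100 nm design sizes
#' and to typical serum-protein dimensions. Feed amounts are order-of-
#' magnitude placeholders in which free protein dominates, as it does in
#' conditioned media.
#'
#' @param amounts Named numeric vector of feed amounts overriding the
#'   defaults (names among `free_protein`, `exomere`, `small_ev`,
#'   `large_ev`).
#' @return A list of class `population_config`: per-species distribution,
#'   feed amount, tags (with `synthetic_default` marking invented
#'   parameters).
#' @export
default_population_config <- function(amounts = NULL) {
  cfg <- list(
    free_protein = list(dist = size_point(6), amount = 100,
                        tags = c("synthetic_default")),
    exomere = list(dist = size_truncnorm(45.6, 10.7), amount = 1,
                   tags = character(0)),
    small_ev = list(dist = size_truncnorm(60, 15), amount = 2,
                    tags = c("synthetic_default")),
    large_ev = list(dist = size_truncnorm(100, 25), amount = 2,
                    tags = c("synthetic_default"))
  )
  if (!is.null(amounts)) {
    bad <- setdiff(names(amounts), names(cfg))
    if (length(bad)) stop("unknown species in `amounts`: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    for (nm in names(amounts)) cfg[[nm]]$amount <- amounts[[nm]]
  }
  structure(cfg, class = "population_config")
}

#' Generate a synthetic particle population and its feed stream
#'
#' Deterministic given the configuration (the seed only matters for
#' downstream sampling operations and is recorded for provenance).
#'
#' @param config A [default_population_config()]-style list: per species a
#'   list with `dist` (a [size_distribution][size_point]), `amount`, and
#'   optional `tags`.
#' @param feed_volume_ml Feed volume in mL.
#' @return List with `species` (list of [particle_species()]) and `feed`
#'   (a [stream_state()]).
#' @export
generate_population <- function(config = default_population_config(),
                                feed_volume_ml = 360) {
  stopifnot(length(config) >= 1L, !is.null(names(config)))
  species <- lapply(names(config), function(nm) {
    entry <- config[[nm]]
    if (!inherits(entry$dist, "size_distribution")) {
      stop("species `", nm, "` has no valid size distribution", call. = FALSE)
    }
    if (is.null(entry$amount) || entry$amount < 0) {
      stop("species `", nm, "` has an invalid feed amount", call. = FALSE)
    }
    particle_species(nm, entry$dist, entry$amount,
                     tags = entry$tags %||% character(0))
  })
  names(species) <- names(config)
  feed <- stream_state(
    stats::setNames(vapply(species, `[[`, numeric(1), "feed_amount"),
                    names(species)),
    feed_volume_ml)
  list(species = species, feed = feed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sample TEM-style diameter measurements from a species
#'
#' Emulates pooled manual particle-diameter measurement: n independent
#' draws from the species' size distribution.
#'
#' @param species A [particle_species()] or
#'   [size_distribution][size_point].
#' @param n Number of measurements, >= 1.
#' @param seed Integer seed.
#' @return Numeric vector of n strictly positive diameters in nm.
#' @export
sample_tem_measurements <- function(species, n, seed) {
  dist <- if (inherits(species, "particle_species"))
    species$size_distribution else species
  size_sample(dist, n, seed = seed)
}

#' Generate a noisy synthetic sieving curve from a known correlation
#'
#' For each particle diameter, the true rejection on the membrane is
#' perturbed on the probit scale by Gaussian noise of sd `probit_noise_sd`,
#' then mapped back through the normal CDF and clipped away from 0 and 1 by
#' 1e-6 (exact 0/1 would be inadmissible observations). Used as the
#' parameter-recovery harness for [fit_correlation()].
#'
#' @param membrane A [membrane_spec()] or mean pore diameter in nm.
#' @param true_corr The generating [retention_correlation()].
#' @param particle_diameters Positive diameters in nm.
#' @param probit_noise_sd Noise sd on the probit scale, >= 0.
#' @param seed Integer seed.
#' @return A [rejection_observations()] data.frame.
#' @export
generate_sieving_curve <- function(membrane, true_corr, particle_diameters,
                                   probit_noise_sd = 0, seed = 1) {
  if (probit_noise_sd < 0) stop("`probit_noise_sd` must be >= 0", call. = FALSE)
  if (any(particle_diameters <= 0)) {
    stop("particle diameters must be positive", call. = FALSE)
  }
  d_pore <- pore_of(membrane)
  z_true <- stats::qnorm(
    rejection_coefficient(particle_diameters, membrane, true_corr))
  eps <- if (probit_noise_sd == 0) {
    0
  } else {
    withr::with_seed(as.integer(seed),
                     stats::rnorm(length(particle_diameters), 0, probit_noise_sd))
  }
  r <- stats::pnorm(z_true + eps)
  r <- pmin(pmax(r, 1e-6), 1 - 1e-6)
  rejection_observations(rep(d_pore, length(particle_diameters)),
                         particle_diameters, r)
}
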