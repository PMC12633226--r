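#' Per-species stream state
#'
#' A stream carries a nonnegative amount of each species (a single additive
#' unit; interpretation as mass or particle count is the caller's, since all
#' balances are linear) and a fluid volume in mL. Volume may be zero only for
#' degenerate streams (e.g. the permeate of a concentration step with X = 1).
#'
#' @param amounts Named numeric vector of per-species amounts, all >= 0.
#' @param volume_ml Stream volume in mL, >= 0.
#' @return An object of class `stream_state`.
#' @export
stream_state <- function(amounts, volume_ml) {
  if (is.null(names(amounts)) || any(!nzchar(names(amounts)))) {
    stop("`amounts` must be a named vector", call. = FALSE)
  }
  if (any(!is.finite(amounts)) || any(amounts < 0)) {
    stop("all amounts must be finite and nonnegative", call. = FALSE)
  }
  if (!is.numeric(volume_ml) || length(volume_ml) != 1L ||
      !is.finite(volume_ml) || volume_ml < 0) {
    stop("`volume_ml` must be a single nonnegative number", call. = FALSE)
  }
  structure(list(amounts = unlist(amounts), volume_ml = as.numeric(volume_ml)),
            class = "stream_state")
}

#' @export
print.stream_state <- function(x, ...) {
  cat(sprintf("<stream_state> %.4g mL\n", x$volume_ml))
  print(round(x$amounts, 6))
  invisible(x)
}

check_sievings <- function(stream, sievings) {
  stopifnot(inherits(stream, "stream_state"))
  sp <- names(stream$amounts)
  if (is.null(names(sievings)) || !all(sp %in% names(sievings))) {
    stop("`sievings` must be named and cover every species in the stream",
         call. = FALSE)
  }
  s <- sievings[sp]
  if (any(s < 0) || any(s > 1)) {
    stop("sieving coefficients must lie in [0, 1]", call. = FALSE)
  }
  s
}

#' Concentration (volume-reduction) mass balance
#'
#' Concentrates a well-mixed retentate from volume V to V/X at constant
#' observed sieving S per species. Integrating dM/dV = S M / V from V to V/X
#' gives the retained fraction (1/X)^S; the permeate receives the
#' complement and the displaced volume V - V/X.
#'
#' @param stream A [stream_state()].
#' @param mean_sievings Named per-species sieving coefficients in \[0, 1\].
#' @param X Volume reduction factor, >= 1.
#' @return List with `retentate` and `permeate` [stream_state()]s.
#' @export
concentrate <- function(stream, mean_sievings, X) {
  if (!is.numeric(X) || length(X) != 1L || !is.finite(X) || X < 1) {
    stop("`X` (volume reduction factor) must be >= 1", call. = FALSE)
  }
  s <- check_sievings(stream, mean_sievings)
  retained <- (1 / X)^s
  ret <- stream$amounts * retained
  list(
    retentate = stream_state(ret, stream$volume_ml / X),
    permeate = stream_state(stream$amounts - ret,
                            stream$volume_ml - stream$volume_ml / X)
  )
}

#' Constant-volume diafiltration mass balance
#'
#' Washes a retentate held at constant volume with N diavolumes of fresh
#' buffer. Each species washes out at rate S, so the retained fraction after
#' N diavolumes is exp(-N S); the permeate receives the complement and
#' volume N * V.
#'
#' @inheritParams concentrate
#' @param N Number of diavolumes, >= 0.
#' @return List with `retentate` and `permeate` [stream_state()]s.
#' @export
diafilter <- function(stream, mean_sievings, N) {
  if (!is.numeric(N) || length(N) != 1L || !is.finite(N) || N < 0) {
    stop("`N` (diavolumes) must be >= 0", call. = FALSE)
  }
  s <- check_sievings(stream, mean_sievings)
  retained <- exp(-N * s)
  ret <- stream$amounts * retained
  list(
    retentate = stream_state(ret, stream$volume_ml),
    permeate = stream_state(stream$amounts - ret, N * stream$volume_ml)
  )
}

#' Clarification step
#'
#' Applies a concentration step on the clarifying membrane; the permeate
#' advances to the fractionating cascade and the retentate (cell debris,
#' apoptotic bodies, anything rejected) is discarded.
#'
#' @inheritParams concentrate
#' @param membrane The clarifier [membrane_spec()].
#' @param corr A [retention_correlation()].
#' @param species List of [particle_species()] covering the stream's species.
#' @param X_clar Clarifier volume reduction factor, >= 1.
#' @param n_nodes Quadrature nodes for [mean_rejection()].
#' @return List with `discarded_retentate` and `advanced_permeate`.
#' @export
clarify <- function(stream, membrane, corr, species, X_clar = 10,
                    n_nodes = 64) {
  sv <- species_sievings(species, membrane, corr, n_nodes)
  out <- concentrate(stream, sv, X_clar)
  list(discarded_retentate = out$retentate, advanced_permeate = out$permeate)
}

species_sievings <- function(species, membrane, corr, n_nodes = 64) {
  stopifnot(length(species) >= 1L)
  vapply(species, function(sp) mean_sieving(sp, membrane, corr, n_nodes),
         numeric(1), USE.NAMES = FALSE) |>
    stats::setNames(vapply(species, `[[`, character(1), "name"))
}

# ---- cascade specification --------------------------------------------------

#' A single cascade stage
#'
#' @param membrane A [membrane_spec()].
#' @param X Volume reduction factor for the concentration step, >= 1.
#' @param diavolumes Diavolumes of buffer exchange after concentration, >= 0.
#' @param advance_stream Which output feeds the next stage: `"permeate"`
#'   (the cascade default) or `"retentate"`.
#' @param collect_retentate Whether the stage's final retentate is collected
#'   as a named fraction (FALSE for the clarifier, whose retentate is
#'   discarded, and for any stage whose retentate is waste).
#' @param fraction_label Label for the collected fraction; defaults to the
#'   membrane label.
#' @return An object of class `stage_spec`.
#' @export
stage_spec <- function(membrane, X = 10, diavolumes = 9,
                       advance_stream = c("permeate", "retentate"),
                       collect_retentate = TRUE,
                       fraction_label = membrane$label) {
  advance_stream <- match.arg(advance_stream)
  stopifnot(inherits(membrane, "membrane_spec"))
  if (X < 1) stop("`X` (volume_reduction_factor) must be >= 1", call. = FALSE)
  if (diavolumes < 0) stop("`diavolumes` must be >= 0", call. = FALSE)
  if (membrane$role == "clarifier" &&
      (advance_stream != "permeate" || collect_retentate)) {
    stop("a clarifier stage must advance its permeate and discard its ",
         "retentate", call. = FALSE)
  }
  structure(
    list(membrane = membrane, X = as.numeric(X),
         diavolumes = as.numeric(diavolumes),
         advance_stream = advance_stream,
         collect_retentate = isTRUE(collect_retentate),
         fraction_label = fraction_label),
    class = "stage_spec"
  )
}

#' An ordered filtration cascade
#'
#' The first stage must be the clarifier; each later stage consumes the
#' previous stage's advanced stream. Membrane labels must be unique.
#'
#' @param stages List of [stage_spec()] objects in processing order.
#' @return An object of class `cascade_spec`.
#' @export
cascade_spec <- function(stages) {
  stopifnot(length(stages) >= 1L,
            all(vapply(stages, inherits, logical(1), "stage_spec")))
  if (stages[[1]]$membrane$role != "clarifier") {
    stop("the first cascade stage must be the clarifier", call. = FALSE)
  }
  if (any(vapply(stages[-1], function(s) s$membrane$role == "clarifier",
                 logical(1)))) {
    stop("only the first stage may be a clarifier", call. = FALSE)
  }
  labels <- vapply(stages, function(s) s$membrane$label, character(1))
  if (anyDuplicated(labels)) {
    stop("membrane labels must be unique within a cascade", call. = FALSE)
  }
  structure(list(stages = stages), class = "cascade_spec")
}

#' @export
print.cascade_spec <- function(x, ...) {
  cat("<cascade_spec>", length(x$stages), "stages\n")
  for (s in x$stages) {
    cat(sprintf("  %-8s %5.3g nm  X=%-4.3g N=%-4.3g advance=%s%s\n",
                s$membrane$label, s$membrane$mean_pore_diameter_nm, s$X,
                s$diavolumes, s$advance_stream,
                if (s$collect_retentate)
                  paste0("  -> fraction ", s$fraction_label) else "  (discard)"))
  }
  invisible(x)
}

#' The default tandem TFF cascade
#'
#' 0.2 um clarifier, then four fractionating stages F1 (0.05 um), F2
#' (500 kDa), F3 (300 kDa), F4 (100 kDa), each concentrating by `X` and then
#' diafiltering with `diavolumes` diavolumes; retentates F1-F4 are collected,
#' the clarifier retentate and the terminal (F4) permeate are discarded.
#'
#' @param X Per-stage volume reduction factor (default 10).
#' @param diavolumes Per-stage diavolumes (default 9, the midpoint of the
#'   8-10 used in practice).
#' @param X_clar Clarifier volume reduction factor (default 10).
#' @return A [cascade_spec()].
#' @export
default_cascade <- function(X = 10, diavolumes = 9, X_clar = 10) {
  m <- default_membranes()
  fr_labels <- c("F1", "F2", "F3", "F4")
  stages <- c(
    list(stage_spec(m[["0.2 um"]], X = X_clar, diavolumes = 0,
                    advance_stream = "permeate", collect_retentate = FALSE)),
    lapply(seq_along(fr_labels), function(i) {
      stage_spec(m[[i + 1L]], X = X, diavolumes = diavolumes,
                 advance_stream = "permeate", collect_retentate = TRUE,
                 fraction_label = fr_labels[i])
    })
  )
  cascade_spec(stages)
}

# ---- cascade execution ------------------------------------------------------

#' Run a filtration cascade over a particle population
#'
#' Executes stages in order. The clarifier concentrates and advances its
#' permeate, discarding the retentate. Each subsequent stage concentrates
#' its input to volume/X, then diafilters the retentate with N diavolumes;
#' the (possibly collected) retentate is that stage's fraction and the
#' combined permeate (concentration plus diafiltration) advances. The
#' terminal stage's advanced stream is discarded. Per species, feed amount
#' equals the sum over collected fractions and discarded streams (global
#' conservation).
#'
#' @param species List of [particle_species()] defining size distributions
#'   (and default feed amounts).
#' @param cascade A [cascade_spec()].
#' @param corr A [retention_correlation()].
#' @param feed Optional [stream_state()]; defaults to the species' feed
#'   amounts in `feed_volume_ml` of fluid.
#' @param feed_volume_ml Feed volume used when `feed` is not given
#'   (default 360 mL).
#' @param n_nodes Quadrature nodes for population-mean sievings.
#' @return An object of class `cascade_result`: list with `feed`,
#'   `fractions` (named list of [stream_state()]), `discards` (named list),
#'   and `stage_log` (data.frame of per-stage, per-species balances).
#' @export
run_cascade <- function(species, cascade, corr, feed = NULL,
                        feed_volume_ml = 360, n_nodes = 64) {
  stopifnot(inherits(cascade, "cascade_spec"),
            inherits(corr, "retention_correlation"))
  sp_names <- vapply(species, `[[`, character(1), "name")
  if (anyDuplicated(sp_names)) stop("species names must be unique", call. = FALSE)
  if (is.null(feed)) {
    feed <- stream_state(
      stats::setNames(vapply(species, `[[`, numeric(1), "feed_amount"),
                      sp_names),
      feed_volume_ml)
  }
  stopifnot(inherits(feed, "stream_state"))
  if (!setequal(names(feed$amounts), sp_names)) {
    stop("feed species do not match the species list", call. = FALSE)
  }

  current <- feed
  fractions <- list()
  discards <- list()
  log_rows <- list()
  n_stages <- length(cascade$stages)

  for (i in seq_len(n_stages)) {
    st <- cascade$stages[[i]]
    sv <- species_sievings(species, st$membrane, corr, n_nodes)
    input <- current

    conc <- concentrate(input, sv, st$X)
    dia <- diafilter(conc$retentate, sv, st$diavolumes)
    retentate <- dia$retentate
    permeate <- stream_state(conc$permeate$amounts + dia$permeate$amounts,
                             conc$permeate$volume_ml + dia$permeate$volume_ml)

    if (st$advance_stream == "permeate") {
      advanced <- permeate
      side <- retentate
      side_is_retentate <- TRUE
    } else {
      advanced <- retentate
      side <- permeate
      side_is_retentate <- FALSE
    }

    if (st$collect_retentate && side_is_retentate) {
      fractions[[st$fraction_label]] <- side
    } else {
      discards[[paste0(st$membrane$label,
                       if (side_is_retentate) " retentate" else " permeate")]] <-
        side
    }

    log_rows[[i]] <- data.frame(
      stage = i,
      membrane = st$membrane$label,
      species = sp_names,
      sieving = unname(sv[sp_names]),
      input_amount = unname(input$amounts[sp_names]),
      retentate_amount = unname(retentate$amounts[sp_names]),
      permeate_amount = unname(permeate$amounts[sp_names]),
      stringsAsFactors = FALSE
    )
    current <- advanced
  }
  discards[["terminal permeate"]] <- current

  structure(
    list(feed = feed, fractions = fractions, discards = discards,
         stage_log = do.call(rbind, log_rows)),
    class = "cascade_result"
  )
}

#' @export
print.cascade_result <- function(x, ...) {
  cat("<cascade_result>", length(x$fractions), "fractions,",
      length(x$discards), "discarded streams\n")
  for (f in names(x$fractions)) {
    cat(sprintf("  %s: total amount %.4g in %.4g mL\n", f,
                sum(x$fractions[[f]]$amounts), x$fractions[[f]]$volume_ml))
  }
  invisible(x)
}

# ---- design -----------------------------------------------------------------

#' Find the enrichment window for a target particle size
#'
#' Scans adjacent pore-size pairs (largest to smallest) for the pair in
#' which a target particle passes the upstream membrane (rejection below
#' `threshold_R`) but is retained by the downstream, smaller-pore membrane
#' (rejection at or above `threshold_R`) — the retentate fraction between
#' them is where the target accumulates. If even the largest-pore membrane
#' retains the target, the window sits at the top of the cascade (no
#' upstream membrane). If no membrane reaches the threshold the result is an
#' explicit no-window outcome, not an error.
#'
#' @param target_diameter Target particle diameter in nm.
#' @param membranes List of [membrane_spec()] (any order; sorted internally
#'   by decreasing pore diameter).
#' @param corr A [retention_correlation()].
#' @param threshold_R Rejection threshold in (0, 1) defining "retained".
#' @return An object of class `enrichment_window`: list with `found`
#'   (logical), `upstream` and `downstream` ([membrane_spec()] or `NULL`),
#'   and `rejections` (named vector of the target's rejection on every
#'   membrane).
#' @export
design_enrichment_window <- function(target_diameter, membranes, corr,
                                     threshold_R = 0.85) {
  stopifnot(length(membranes) >= 2L,
            all(vapply(membranes, inherits, logical(1), "membrane_spec")))
  if (threshold_R <= 0 || threshold_R >= 1) {
    stop("`threshold_R` must lie in (0, 1)", call. = FALSE)
  }
  pores <- vapply(membranes, `[[`, numeric(1), "mean_pore_diameter_nm")
  ord <- order(pores, decreasing = TRUE)
  membranes <- membranes[ord]
  rej <- vapply(membranes, function(m)
    rejection_coefficient(target_diameter, m, corr), numeric(1))
  names(rej) <- vapply(membranes, `[[`, character(1), "label")

  retained <- rej >= threshold_R
  out <- list(found = FALSE, upstream = NULL, downstream = NULL,
              rejections = rej, threshold_R = threshold_R,
              target_diameter = target_diameter)
  if (retained[1]) {
    # retained even at the top of the cascade: boundary window
    out$found <- TRUE
    out$downstream <- membranes[[1]]
  } else {
    first <- which(retained)[1]
    if (!is.na(first)) {
      out$found <- TRUE
      out$upstream <- membranes[[first - 1L]]
      out$downstream <- membranes[[first]]
    }
  }
  structure(out, class = "enrichment_window")
}

#' @export
print.enrichment_window <- function(x, ...) {
  if (!x$found) {
    cat(sprintf("<enrichment_window> no window: max rejection of a %.4g nm target is %.3f (< %.3f)\n",
                x$target_diameter, max(x$rejections), x$threshold_R))
  } else if (is.null(x$upstream)) {
    cat(sprintf("<enrichment_window> %.4g nm target retained at the top of the cascade (%s)\n",
                x$target_diameter, x$downstream$label))
  } else {
    cat(sprintf("<enrichment_window> %.4g nm target enriched between %s (%.4g nm, passes) and %s (%.4g nm, retains)\n",
                x$target_diameter, x$upstream$label,
                x$upstream$mean_pore_diameter_nm, x$downstream$label,
                x$downstream$mean_pore_diameter_nm))
  }
  invisible(x)
}
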