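#' @keywords internal
#' Read a CSV with an exact required header, reporting offending rows
read_checked_csv <- function(path, required_cols, numeric_cols = character(0)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  missing <- setdiff(required_cols, names(tab))
  if (length(missing)) {
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (col in numeric_cols) {
    v <- tab[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad)) {
        stop("non-numeric value in column `", col, "` of ", path,
             " at data row ", bad[1], call. = FALSE)
      }
      tab[[col]] <- num
    }
  }
  tab[required_cols]
}

# Numbers serialized at full double precision (>= 9 significant digits).
write_num_csv <- function(tab, path) {
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(x) sprintf("%.15g", x))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write rejection-observation tables
#'
#' CSV header: `mean_pore_diameter_nm,particle_diameter_nm,rejection`.
#' An empty table (header only) reads as an empty observation set.
#'
#' @param path File path.
#' @return `read_observations_csv`: a [rejection_observations()] data.frame
#'   (possibly zero rows).
#' @export
read_observations_csv <- function(path) {
  tab <- read_checked_csv(
    path, c("mean_pore_diameter_nm", "particle_diameter_nm", "rejection"),
    numeric_cols = c("mean_pore_diameter_nm", "particle_diameter_nm",
                     "rejection"))
  rejection_observations(tab$mean_pore_diameter_nm, tab$particle_diameter_nm,
                         tab$rejection)
}

#' @rdname read_observations_csv
#' @param observations A [rejection_observations()] data.frame.
#' @export
write_observations_csv <- function(observations, path) {
  obs <- validate_observations(observations)
  write_num_csv(as.data.frame(obs), path)
}

#' Read / write particle-species tables
#'
#' CSV header: `name,family,param1,param2,feed_amount`. `family` is one of
#' `point` (param1 = diameter, param2 ignored/0), `truncnorm`
#' (mean, sd) or `lognormal` (median, gsd).
#'
#' @param path File path.
#' @return `read_species_csv`: a named list of [particle_species()].
#' @export
read_species_csv <- function(path) {
  tab <- read_checked_csv(path,
                          c("name", "family", "param1", "param2", "feed_amount"),
                          numeric_cols = c("param1", "param2", "feed_amount"))
  out <- lapply(seq_len(nrow(tab)), function(i) {
    dist <- switch(tab$family[i],
      point = size_point(tab$param1[i]),
      truncnorm = size_truncnorm(tab$param1[i], tab$param2[i]),
      lognormal = size_lognormal(tab$param1[i], tab$param2[i]),
      stop("unknown distribution family `", tab$family[i], "` at data row ",
           i, " of ", path, call. = FALSE))
    particle_species(tab$name[i], dist, tab$feed_amount[i])
  })
  names(out) <- tab$name
  out
}

#' @rdname read_species_csv
#' @param species A list of [particle_species()].
#' @export
write_species_csv <- function(species, path) {
  tab <- do.call(rbind, lapply(species, function(sp) {
    d <- sp$size_distribution
    p <- switch(d$family,
      point = c(d$pars$d, 0),
      truncnorm = c(d$pars$mean, d$pars$sd),
      lognormal = c(d$pars$median, d$pars$gsd))
    data.frame(name = sp$name, family = d$family, param1 = p[1], param2 = p[2],
               feed_amount = sp$feed_amount, stringsAsFactors = FALSE)
  }))
  write_num_csv(tab, path)
}

#' Write a fraction report as CSV
#'
#' Header: `fraction,species,recovery,purity,enrichment`.
#'
#' @param report A [build_report()] result.
#' @param path File path.
#' @export
write_report_csv <- function(report, path) {
  stopifnot(is.data.frame(report),
            all(c("fraction", "species", "recovery", "purity",
                  "enrichment") %in% names(report)))
  write_num_csv(as.data.frame(report), path)
}

#' @rdname write_report_csv
#' @export
read_report_csv <- function(path) {
  out <- read_checked_csv(path,
                          c("fraction", "species", "recovery", "purity",
                            "enrichment"),
                          numeric_cols = c("recovery", "purity", "enrichment"))
  class(out) <- c("fraction_report", "data.frame")
  out
}

# ---- cascade configuration --------------------------------------------------

#' Parse a cascade configuration file
#'
#' YAML schema:
#' ```yaml
#' feed:
#'   volume_ml: 360
#'   species: path/to/species.csv   # optional; species may come from code
#' stages:
#'   - membrane: "0.2 um"
#'     mean_pore_diameter_nm: 185   # optional if membrane is in the
#'     role: clarifier              # packaged MWCO table
#'     volume_reduction_factor: 10
#'     diavolumes: 0
#'     advance_stream: permeate
#'     collect_retentate: false
#'   - ...
#' ```
#' Unknown keys, a missing membrane label, `volume_reduction_factor < 1`
#' or negative `diavolumes` are configuration errors naming the offending
#' key and stage.
#'
#' @param path Path to the YAML file.
#' @return A list with `cascade` (a [cascade_spec()]), `feed_volume_ml`,
#'   and `species` (list of [particle_species()], or `NULL` when the config
#'   does not reference a species table).
#' @export
read_cascade_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), c("feed", "stages"))
  if (length(unknown)) {
    stop("unknown top-level key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(cfg$stages) || !length(cfg$stages)) {
    stop("config has no `stages`", call. = FALSE)
  }
  known_membranes <- default_membranes()
  stage_keys <- c("membrane", "mean_pore_diameter_nm", "role",
                  "volume_reduction_factor", "diavolumes", "advance_stream",
                  "collect_retentate", "fraction_label")
  stages <- lapply(seq_along(cfg$stages), function(i) {
    s <- cfg$stages[[i]]
    unknown <- setdiff(names(s), stage_keys)
    if (length(unknown)) {
      stop("stage ", i, ": unknown key(s) ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    if (is.null(s$membrane)) {
      stop("stage ", i, ": missing `membrane` label", call. = FALSE)
    }
    membrane <- if (!is.null(s$mean_pore_diameter_nm)) {
      membrane_spec(s$membrane, s$mean_pore_diameter_nm,
                    s$role %||% "fractionating")
    } else if (s$membrane %in% names(known_membranes)) {
      m <- known_membranes[[s$membrane]]
      if (!is.null(s$role)) m$role <- match.arg(s$role, c("fractionating",
                                                          "clarifier",
                                                          "terminal"))
      m
    } else {
      stop("stage ", i, ": membrane `", s$membrane,
           "` is not in the packaged MWCO table and no ",
           "`mean_pore_diameter_nm` was given", call. = FALSE)
    }
    X <- s$volume_reduction_factor %||% 10
    if (!is.numeric(X) || X < 1) {
      stop("stage ", i, " (", s$membrane,
           "): `volume_reduction_factor` must be >= 1", call. = FALSE)
    }
    N <- s$diavolumes %||% 9
    if (!is.numeric(N) || N < 0) {
      stop("stage ", i, " (", s$membrane, "): `diavolumes` must be >= 0",
           call. = FALSE)
    }
    stage_spec(membrane, X = X, diavolumes = N,
               advance_stream = s$advance_stream %||% "permeate",
               collect_retentate = s$collect_retentate %||%
                 (membrane$role != "clarifier"),
               fraction_label = s$fraction_label %||% membrane$label)
  })
  feed_volume <- cfg$feed$volume_ml %||% 360
  if (!is.numeric(feed_volume) || feed_volume <= 0) {
    stop("`feed.volume_ml` must be positive", call. = FALSE)
  }
  species <- if (!is.null(cfg$feed$species)) {
    sp_path <- cfg$feed$species
    if (!file.exists(sp_path)) {
      sp_path <- file.path(dirname(path), cfg$feed$species)
    }
    read_species_csv(sp_path)
  }
  list(cascade = cascade_spec(stages), feed_volume_ml = feed_volume,
       species = species)
}

#' Write a cascade configuration file
#'
#' Inverse of [read_cascade_config()] (species tables are referenced by
#' path, not inlined, and are written separately with
#' [write_species_csv()]).
#'
#' @param cascade A [cascade_spec()].
#' @param path Output YAML path.
#' @param feed_volume_ml Feed volume recorded in the config.
#' @param species_path Optional species CSV path to reference.
#' @export
write_cascade_config <- function(cascade, path, feed_volume_ml = 360,
                                 species_path = NULL) {
  stopifnot(inherits(cascade, "cascade_spec"))
  stages <- lapply(cascade$stages, function(s) {
    list(membrane = s$membrane$label,
         mean_pore_diameter_nm = s$membrane$mean_pore_diameter_nm,
         role = s$membrane$role,
         volume_reduction_factor = s$X,
         diavolumes = s$diavolumes,
         advance_stream = s$advance_stream,
         collect_retentate = s$collect_retentate,
         fraction_label = s$fraction_label)
  })
  feed <- list(volume_ml = feed_volume_ml)
  if (!is.null(species_path)) feed$species <- species_path
  yaml::write_yaml(list(feed = feed, stages = stages), path, precision = 15)
  invisible(path)
}
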