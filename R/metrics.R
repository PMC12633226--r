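#' Per-fraction recovery, purity and enrichment report
#'
#' For each collected fraction and species: recovery is the fraction of the
#' feed amount of that species ending up in the fraction; purity is the
#' species' share of the fraction's total amount; enrichment is that purity
#' divided by the species' purity in the feed. Empty fractions (total amount
#' zero) have undefined purity and are omitted from the report rather than
#' reported as zero.
#'
#' @param feed A [stream_state()]; species appearing in fractions must have
#'   positive feed amounts.
#' @param fractions Named list of [stream_state()]s (e.g.
#'   `cascade_result$fractions`).
#' @return A data.frame of class `fraction_report` with columns `fraction`,
#'   `species`, `recovery`, `purity`, `enrichment`.
#' @export
build_report <- function(feed, fractions) {
  stopifnot(inherits(feed, "stream_state"), length(fractions) >= 1L,
            !is.null(names(fractions)))
  feed_total <- sum(feed$amounts)
  if (feed_total <= 0) stop("feed is empty", call. = FALSE)
  rows <- list()
  for (fr in names(fractions)) {
    st <- fractions[[fr]]
    stopifnot(inherits(st, "stream_state"))
    sp <- names(st$amounts)
    if (any(!(sp %in% names(feed$amounts))) ||
        any(feed$amounts[sp] <= 0 & st$amounts > 0)) {
      stop("fraction ", fr, " contains species absent from the feed",
           call. = FALSE)
    }
    total <- sum(st$amounts)
    if (total <= 0) next  # purity undefined for an empty fraction
    purity <- st$amounts / total
    feed_purity <- feed$amounts[sp] / feed_total
    rows[[fr]] <- data.frame(
      fraction = fr,
      species = sp,
      recovery = unname(st$amounts / feed$amounts[sp]),
      purity = unname(purity),
      enrichment = unname(purity / feed_purity),
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(fraction = character(0), species = character(0),
               recovery = numeric(0), purity = numeric(0),
               enrichment = numeric(0))
  rownames(out) <- NULL
  class(out) <- c("fraction_report", "data.frame")
  out
}

#' Summarize pooled particle-diameter measurements
#'
#' Arithmetic mean and sample (n-1 denominator) standard deviation of a
#' pooled vector of diameters, as used to summarize manual TEM measurements.
#'
#' @param diameters Numeric vector of diameters in nm, all > 0, length >= 2.
#' @return A list of class `size_summary` with `n`, `mean`, `sd`.
#' @export
summarize_sizes <- function(diameters) {
  if (!is.numeric(diameters) || length(diameters) < 2L) {
    stop("need at least 2 diameters (sd undefined otherwise)", call. = FALSE)
  }
  if (any(!is.finite(diameters)) || any(diameters <= 0)) {
    stop("all diameters must be positive and finite", call. = FALSE)
  }
  structure(
    list(n = length(diameters), mean = mean(diameters),
         sd = stats::sd(diameters)),
    class = "size_summary"
  )
}

#' @export
print.size_summary <- function(x, ...) {
  cat(sprintf("<size_summary> n = %d: %.1f +/- %.1f nm (mean +/- SD)\n",
              x$n, x$mean, x$sd))
  invisible(x)
}

#' Write a size summary as a 3-column CSV
#'
#' Columns `n,mean_nm,sd_nm`.
#'
#' @param summary A [summarize_sizes()] result, or a list of them (rows).
#' @param path File path.
#' @export
write_size_summary_csv <- function(summary, path) {
  if (inherits(summary, "size_summary")) summary <- list(summary)
  tab <- data.frame(
    n = vapply(summary, `[[`, numeric(1), "n"),
    mean_nm = vapply(summary, `[[`, numeric(1), "mean"),
    sd_nm = vapply(summary, `[[`, numeric(1), "sd")
  )
  if (!is.null(names(summary))) tab <- cbind(label = names(summary), tab)
  write_num_csv(tab, path)
}
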