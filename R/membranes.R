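#' Hollow-fiber membrane specification
#'
#' A membrane is characterized by its nominal label (typically a molecular
#' weight cutoff, MWCO), a mean pore diameter in nanometres, and its role in
#' a fractionation cascade.
#'
#' @param label Character label, e.g. `"300 kDa"` or `"0.2 um"`.
#' @param mean_pore_diameter_nm Mean pore diameter in nm; must be positive.
#' @param role One of `"clarifier"`, `"fractionating"`, `"terminal"`.
#' @return An object of class `membrane_spec`.
#' @examples
#' membrane_spec("300 kDa", 15, "fractionating")
#' @export
membrane_spec <- function(label, mean_pore_diameter_nm,
                          role = c("fractionating", "clarifier", "terminal")) {
  role <- match.arg(role)
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  if (!is.numeric(mean_pore_diameter_nm) || length(mean_pore_diameter_nm) != 1L ||
      !is.finite(mean_pore_diameter_nm) || mean_pore_diameter_nm <= 0) {
    stop("`mean_pore_diameter_nm` must be a single positive number", call. = FALSE)
  }
  structure(
    list(label = label,
         mean_pore_diameter_nm = as.numeric(mean_pore_diameter_nm),
         role = role),
    class = "membrane_spec"
  )
}

#' @export
print.membrane_spec <- function(x, ...) {
  cat(sprintf("<membrane_spec> %s: mean pore %.4g nm (%s)\n",
              x$label, x$mean_pore_diameter_nm, x$role))
  invisible(x)
}

#' MWCO-to-mean-pore-diameter mapping for the tandem TFF filter series
#'
#' The five hollow-fiber filters of the tandem TFF process with their nominal
#' cutoffs and the mean pore diameters used by the retention model:
#' 0.2 um -> 185 nm (clarifier), 0.05 um -> 50 nm (F1), 500 kDa -> 25 nm (F2),
#' 300 kDa -> 15 nm (F3), 100 kDa -> 5 nm (F4, terminal).
#'
#' @return A data.frame with columns `label`, `mean_pore_diameter_nm`, `role`.
#' @export
mwco_pore_table <- function() {
  data.frame(
    label = c("0.2 um", "0.05 um", "500 kDa", "300 kDa", "100 kDa"),
    mean_pore_diameter_nm = c(185, 50, 25, 15, 5),
    role = c("clarifier", "fractionating", "fractionating",
             "fractionating", "terminal"),
    stringsAsFactors = FALSE
  )
}

#' Default membrane set of the tandem TFF process
#'
#' @return A named list of [membrane_spec()] objects in cascade order
#'   (largest to smallest pore).
#' @export
default_membranes <- function() {
  tab <- mwco_pore_table()
  out <- lapply(seq_len(nrow(tab)), function(i) {
    membrane_spec(tab$label[i], tab$mean_pore_diameter_nm[i], tab$role[i])
  })
  names(out) <- tab$label
  out
}

#' Read / write a membrane table CSV
#'
#' The CSV has header `label,mean_pore_diameter_nm,role`.
#'
#' @param path File path.
#' @return `read_membranes_csv` returns a named list of [membrane_spec()];
#'   `write_membranes_csv` returns `path` invisibly.
#' @export
read_membranes_csv <- function(path) {
  tab <- read_checked_csv(path, c("label", "mean_pore_diameter_nm", "role"),
                          numeric_cols = "mean_pore_diameter_nm")
  if (anyDuplicated(tab$label)) {
    stop("duplicate membrane labels in ", path, call. = FALSE)
  }
  out <- lapply(seq_len(nrow(tab)), function(i) {
    membrane_spec(tab$label[i], tab$mean_pore_diameter_nm[i], tab$role[i])
  })
  names(out) <- tab$label
  out
}

#' @rdname read_membranes_csv
#' @param membranes A list of [membrane_spec()] objects.
#' @export
write_membranes_csv <- function(membranes, path) {
  tab <- data.frame(
    label = vapply(membranes, `[[`, character(1), "label"),
    mean_pore_diameter_nm = vapply(membranes, `[[`, numeric(1),
                                   "mean_pore_diameter_nm"),
    role = vapply(membranes, `[[`, character(1), "role"),
    stringsAsFactors = FALSE
  )
  write_num_csv(tab, path)
}
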