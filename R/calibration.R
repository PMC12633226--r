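#' Rejection observations
#'
#' An observation ties a membrane (mean pore diameter), a particle diameter,
#' and the measured or calculated rejection coefficient. Rejections of
#' exactly 0 or 1 are inadmissible (infinite probit).
#'
#' @param mean_pore_diameter_nm,particle_diameter_nm Diameters in nm, > 0.
#' @param rejection Rejection fraction(s), strictly in (0, 1).
#' @return A data.frame of class `rejection_observations` with columns
#'   `mean_pore_diameter_nm`, `particle_diameter_nm`, `rejection`.
#' @export
rejection_observations <- function(mean_pore_diameter_nm, particle_diameter_nm,
                                   rejection) {
  n <- length(rejection)
  stopifnot(length(mean_pore_diameter_nm) == n,
            length(particle_diameter_nm) == n)
  if (any(mean_pore_diameter_nm <= 0) || any(particle_diameter_nm <= 0)) {
    stop("pore and particle diameters must be positive", call. = FALSE)
  }
  if (any(rejection <= 0) || any(rejection >= 1)) {
    stop("rejections must lie strictly in (0, 1): 0 and 1 have infinite probit",
         call. = FALSE)
  }
  out <- data.frame(
    mean_pore_diameter_nm = as.numeric(mean_pore_diameter_nm),
    particle_diameter_nm = as.numeric(particle_diameter_nm),
    rejection = as.numeric(rejection)
  )
  class(out) <- c("rejection_observations", "data.frame")
  out
}

#' The five packaged design-point rejection observations
#'
#' Rejection coefficients for a 35 nm particle on membranes of 5, 15 and
#' 25 nm mean pore diameter (0.90, 0.49, 0.28), and for ~60 nm and ~100 nm
#' EVs on the 15 nm (300 kDa) membrane (0.72, 0.88). These five design
#' points anchor the calibration of the retention correlation.
#'
#' @return A [rejection_observations()] data.frame with five rows.
#' @export
design_point_observations <- function() {
  rejection_observations(
    mean_pore_diameter_nm = c(5, 15, 25, 15, 15),
    particle_diameter_nm  = c(35, 35, 35, 60, 100),
    rejection             = c(0.90, 0.49, 0.28, 0.72, 0.88)
  )
}

#' Calibrate the retention correlation by probit-scale least squares
#'
#' Writing y_i = ln(d_particle,i / d_pore,i) and z_i = qnorm(R_i) (the probit
#' of the observed rejection), the correlation
#' R(d) = Phi(ln(d/(k d_pore)) / ln sigma_g) is linear on this scale:
#' y = ln(k) + ln(sigma_g) * z. The fit is ordinary least squares of y on z
#' (errors attributed to the size ratio), giving closed-form estimates
#' slope = ln(sigma_g) and intercept = ln(k). A nonpositive fitted slope
#' cannot define a valid correlation and is an error.
#'
#' @param observations A [rejection_observations()] data.frame (or any
#'   data.frame with its three columns); at least 2 rows with at least two
#'   distinct rejection values.
#' @return An object of class `fit_result`: list with `correlation`
#'   ([retention_correlation()]), `probit_residuals` (residuals of y on the
#'   probit scale), `rss`, `n_obs`, and `se` (named standard errors of
#'   `log_k` and `log_sigma_g`, `NA` when n = 2).
#' @export
fit_correlation <- function(observations) {
  obs <- validate_observations(observations)
  n <- nrow(obs)
  if (n < 2L) stop("need at least 2 observations to fit", call. = FALSE)
  y <- log(obs$particle_diameter_nm / obs$mean_pore_diameter_nm)
  z <- stats::qnorm(obs$rejection)
  if (max(z) - min(z) < 1e-12) {
    stop("all probit-rejection values identical: slope is unidentifiable",
         call. = FALSE)
  }
  fit <- stats::lm(y ~ z)
  intercept <- unname(stats::coef(fit)[1])
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope <= 0) {
    stop("fitted slope (ln sigma_g) is nonpositive: observations are ",
         "inconsistent with a valid retention correlation", call. = FALSE)
  }
  se <- if (n > 2L) {
    # closed-form OLS standard errors (avoids summary.lm's degenerate-fit
    # warning on exactly collinear synthetic data)
    sigma2 <- sum(stats::resid(fit)^2) / (n - 2)
    sxx <- sum((z - mean(z))^2)
    c(log_k = sqrt(sigma2 * (1 / n + mean(z)^2 / sxx)),
      log_sigma_g = sqrt(sigma2 / sxx))
  } else {
    c(log_k = NA_real_, log_sigma_g = NA_real_)
  }
  structure(
    list(correlation = retention_correlation(exp(intercept), exp(slope)),
         probit_residuals = unname(stats::resid(fit)),
         rss = sum(stats::resid(fit)^2),
         n_obs = n,
         se = se),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> n = %d, probit-scale RSS = %.4g\n", x$n_obs, x$rss))
  print(x$correlation)
  invisible(x)
}

validate_observations <- function(observations) {
  need <- c("mean_pore_diameter_nm", "particle_diameter_nm", "rejection")
  if (!is.data.frame(observations) || !all(need %in% names(observations))) {
    stop("`observations` must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  rejection_observations(observations$mean_pore_diameter_nm,
                         observations$particle_diameter_nm,
                         observations$rejection)
}

#' Leave-one-out prediction of a held-out rejection observation
#'
#' Refits the correlation on all observations except `held_out_index` and
#' predicts the rejection at the held-out (pore, particle) pair.
#'
#' @inheritParams fit_correlation
#' @param held_out_index Row index of the observation to hold out.
#' @return Predicted rejection fraction in (0, 1).
#' @export
loo_predict <- function(observations, held_out_index) {
  obs <- validate_observations(observations)
  n <- nrow(obs)
  if (n < 3L) stop("leave-one-out needs at least 3 observations", call. = FALSE)
  i <- held_out_index
  if (!is.numeric(i) || length(i) != 1L || i < 1 || i > n || i != round(i)) {
    stop("`held_out_index` out of range", call. = FALSE)
  }
  fit <- fit_correlation(obs[-i, , drop = FALSE])
  rejection_coefficient(obs$particle_diameter_nm[i],
                        obs$mean_pore_diameter_nm[i],
                        fit$correlation)
}

#' All leave-one-out predictions for an observation set
#'
#' @inheritParams fit_correlation
#' @return The observation data.frame with an added `loo_predicted` column.
#' @export
loo_table <- function(observations) {
  obs <- validate_observations(observations)
  obs$loo_predicted <- vapply(seq_len(nrow(obs)),
                              function(i) loo_predict(obs, i), numeric(1))
  obs
}

#' Read / write correlation parameters as a flat key-value file
#'
#' The file is YAML with keys `k` and `geometric_sd`.
#'
#' @param corr A [retention_correlation()].
#' @param path File path.
#' @export
write_correlation <- function(corr, path) {
  stopifnot(inherits(corr, "retention_correlation"))
  yaml::write_yaml(list(k = corr$pore_scale_factor_k,
                        geometric_sd = corr$geometric_sd),
                   path, precision = 15)
  invisible(path)
}

#' @rdname write_correlation
#' @export
read_correlation <- function(path) {
  vals <- yaml::read_yaml(path)
  for (key in c("k", "geometric_sd")) {
    if (is.null(vals[[key]]) || !is.numeric(vals[[key]])) {
      stop("correlation file ", path, " is missing numeric key `", key, "`",
           call. = FALSE)
    }
  }
  retention_correlation(vals$k, vals$geometric_sd)
}
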