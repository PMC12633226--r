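# Independent oracles, deliberately naive: brute-force integration and
# sampling against which the closed-form / quadrature paths are checked.

# Retained fraction under volume reduction, by fine-step midpoint
# integration of dM/dV = S * M / V as volume falls from V0 to V0/X.
ode_concentrate <- function(S, X, n_steps = 2e4) {
  V0 <- 1
  V <- seq(V0, V0 / X, length.out = n_steps + 1)
  M <- 1
  for (i in seq_len(n_steps)) {
    dV <- V[i + 1] - V[i]            # negative
    Vm <- V[i] + dV / 2
    Mm <- M + (dV / 2) * S * M / V[i]
    M <- M + dV * S * Mm / Vm
  }
  M
}

# Retained fraction under constant-volume diafiltration, by fine-step
# midpoint integration of dM = -S * (M/V) * dV_dia over N diavolumes
# (constant coefficients collapse the recurrence to a power).
ode_diafilter <- function(S, N, n_steps = 2e4) {
  d <- N / n_steps
  (1 - S * d + (S * d)^2 / 2)^n_steps
}

# Monte-Carlo population-mean rejection.
mc_mean_rejection <- function(dist, membrane, corr, n = 1e6, seed = 42) {
  d <- size_sample(dist, n, seed = seed)
  r <- rejection_coefficient(d, membrane, corr)
  list(mean = mean(r), se = stats::sd(r) / sqrt(n))
}

# Spreadsheet-style stage-by-stage cascade: same sievings, independent
# arithmetic (no stream_state machinery).
manual_cascade <- function(feed_amounts, sievings_by_stage, X, N, X_clar) {
  current <- feed_amounts
  fractions <- list()
  # clarifier: retained fraction (1/X_clar)^S discarded, rest advances
  s <- sievings_by_stage[[1]]
  current <- current * (1 - (1 / X_clar)^s)
  for (i in 2:length(sievings_by_stage)) {
    s <- sievings_by_stage[[i]]
    retained <- current * (1 / X)^s * exp(-N * s)
    fractions[[i - 1]] <- retained
    current <- current - retained
  }
  list(fractions = fractions, terminal = current)
}

calibrated_correlation <- function() fit_correlation(design_point_observations())$correlation
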