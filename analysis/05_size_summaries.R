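#!/usr/bin/env Rscript
# TEM-style pooled size summaries of simulated exomere measurements, and a
# parameter-recovery check of the calibration on noisy synthetic sieving
# curves. Writes: results/size_summaries.csv, results/recovered_parameters.csv

library(tffcascade)
dir.create("results", showWarnings = FALSE)

# Emulated manual diameter measurement of two exomere preparations: a
# tight (TFF-style) and a wide (UC-style) population, 10^4 particles each.
tff_style <- size_truncnorm(45.6, 10.7)
uc_style <- size_truncnorm(49.8, 22.0)
summaries <- list(
  tff_exomere = summarize_sizes(sample_tem_measurements(tff_style, 1e4,
                                                        seed = 2061)),
  uc_exomere = summarize_sizes(sample_tem_measurements(uc_style, 1e4,
                                                       seed = 2062))
)
write_size_summary_csv(summaries, "results/size_summaries.csv")
cat("Pooled size summaries of simulated measurements:\n")
for (nm in names(summaries)) { cat(" ", nm, ": "); print(summaries[[nm]]) }
cat("The wide (UC-style) population shows the larger SD, as expected.\n\n")

# Parameter recovery: noisy sieving curves from a known correlation.
truth <- read_correlation("results/correlation.yaml")
d <- exp(seq(log(3), log(400), length.out = 100))
rows <- lapply(c(0, 0.02, 0.05, 0.1), function(noise) {
  fit <- fit_correlation(generate_sieving_curve(15, truth, d,
                                                probit_noise_sd = noise,
                                                seed = 515))
  data.frame(probit_noise_sd = noise,
             k_hat = fit$correlation$pore_scale_factor_k,
             gsd_hat = fit$correlation$geometric_sd,
             se_log_k = fit$se["log_k"],
             se_log_gsd = fit$se["log_sigma_g"])
})
tab <- do.call(rbind, rows)
rownames(tab) <- NULL
tffcascade:::write_num_csv(tab, "results/recovered_parameters.csv")
cat(sprintf("Recovered parameters from 100-point sieving curves (truth: k = %.4g, gsd = %.4g):\n",
            truth$pore_scale_factor_k, truth$geometric_sd))
print(transform(tab, k_hat = round(k_hat, 4), gsd_hat = round(gsd_hat, 4),
                se_log_k = signif(se_log_k, 2),
                se_log_gsd = signif(se_log_gsd, 2)), row.names = FALSE)
cat("Noise-free curves are recovered to numerical precision; noisy fits\n",
    "drift by amounts consistent with their analytic standard errors.\n")
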