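#!/usr/bin/env Rscript
# Rejection-vs-diameter curves for the five cascade membranes under the
# calibrated correlation, plus population-mean rejections for the default
# particle classes. Writes: results/retention_curves.csv,
#                           results/population_rejections.csv

library(tffcascade)
dir.create("results", showWarnings = FALSE)

corr <- read_correlation("results/correlation.yaml")
membranes <- default_membranes()

d <- exp(seq(log(2), log(500), length.out = 200))
curves <- do.call(rbind, lapply(membranes, function(m) {
  data.frame(membrane = m$label, mean_pore_diameter_nm = m$mean_pore_diameter_nm,
             particle_diameter_nm = d,
             rejection = rejection_coefficient(d, m, corr))
}))
tffcascade:::write_num_csv(curves, "results/retention_curves.csv")

pop <- generate_population()
pr <- do.call(rbind, lapply(membranes, function(m) {
  data.frame(
    membrane = m$label,
    species = names(pop$species),
    mean_rejection = vapply(pop$species, function(sp)
      mean_rejection(sp, m, corr), numeric(1))
  )
}))
rownames(pr) <- NULL
tffcascade:::write_num_csv(pr, "results/population_rejections.csv")

cat("Population-mean rejection of each particle class on each membrane:\n")
wide <- stats::reshape(pr, idvar = "species", timevar = "membrane",
                       direction = "wide")
print(cbind(wide[1], round(wide[-1], 3)), row.names = FALSE)
cat("\nThe exomere class passes the 50/25 nm membranes readily, is half-\n",
    "retained near 15 nm, and is strongly rejected at 5 nm - the pattern\n",
    "that drives its accumulation in the final retentate fraction.\n")
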