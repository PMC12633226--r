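#!/usr/bin/env Rscript
# Simulate the five-stage tandem TFF cascade on the default synthetic
# particle population and report per-fraction recovery, purity, enrichment.
# Writes: results/fraction_report.csv, results/stage_log.csv

library(tffcascade)
dir.create("results", showWarnings = FALSE)

corr <- read_correlation("results/correlation.yaml")
cfg <- read_cascade_config(system.file("extdata", "default_cascade.yaml",
                                       package = "tffcascade"))
species <- cfg$species
feed <- stream_state(
  stats::setNames(vapply(species, `[[`, numeric(1), "feed_amount"),
                  names(species)),
  cfg$feed_volume_ml)

res <- run_cascade(species, cfg$cascade, corr, feed = feed)
print(res)

report <- build_report(res$feed, res$fractions)
write_report_csv(report, "results/fraction_report.csv")
tffcascade:::write_num_csv(res$stage_log, "results/stage_log.csv")

cat("\nPer-fraction report (recovery = share of feed amount; purity = share\n",
    "of the fraction; enrichment = purity relative to the feed):\n", sep = "")
print(transform(report, recovery = signif(recovery, 3),
                purity = signif(purity, 3), enrichment = signif(enrichment, 3)),
      row.names = FALSE)

exo <- report[report$species == "exomere", ]
feed_purity <- unname(feed$amounts["exomere"] / sum(feed$amounts))
cat(sprintf(
  "\nExomere recovery peaks in %s (%.0f%% of the feed exomeres); its purity\nthere is %.3f vs %.3f in the feed (enrichment %.0fx) and %.3f in F2.\n",
  exo$fraction[which.max(exo$recovery)], 100 * max(exo$recovery),
  exo$purity[exo$fraction == "F4"], feed_purity,
  exo$enrichment[exo$fraction == "F4"], exo$purity[exo$fraction == "F2"]))
cat("Free protein washes out almost completely during diafiltration; large\n",
    "species are captured upstream, so the terminal retentate favours the\n",
    "30-50 nm class.\n")
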