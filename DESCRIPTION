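Package: tffcascade
Title: Retention Modelling and Tandem Tangential-Flow-Filtration Cascade
    Simulation for Extracellular-Particle Fractionation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and simulation tools for size-based fractionation of
    extracellular particles (exomeres, small and large extracellular
    vesicles, free protein) by tandem tangential flow filtration (TFF).
    Implements a two-parameter log-normal probability retention
    correlation mapping particle diameter to membrane rejection,
    probit-scale least-squares calibration of that correlation to
    rejection observations with leave-one-out validation, constant-
    retention concentration and constant-volume diafiltration mass
    balances, simulation of multi-stage clarify/concentrate/diafilter
    cascades with per-species stream bookkeeping, fraction-level
    recovery/purity/enrichment reporting, and a seeded synthetic-data
    generator for particle populations, TEM-style size measurements and
    noisy sieving curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
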