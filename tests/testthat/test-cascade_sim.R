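corr_cal <- calibrated_correlation()

test_that("concentration follows the (1/X)^S mass balance", {
  st <- stream_state(c(a = 1, b = 1, c = 1), 100)
  out <- concentrate(st, c(a = 0, b = 1, c = 0.5), 10)
  expect_equal(unname(out$retentate$amounts["a"]), 1)        # impermeable
  expect_equal(unname(out$retentate$amounts["b"]), 0.1)      # tracks volume
  expect_equal(out$retentate$volume_ml, 10)
  expect_equal(out$permeate$volume_ml, 90)
  out4 <- concentrate(st, c(a = 0, b = 1, c = 0.5), 4)
  expect_equal(unname(out4$retentate$amounts["c"]), 0.5, tolerance = 1e-12)
  expect_error(concentrate(st, c(a = 0, b = 1, c = 0.5), 0.5), ">= 1")
})

test_that("diafiltration follows the exp(-N S) washout", {
  st <- stream_state(c(a = 1, b = 1, c = 1), 5)
  out0 <- diafilter(st, c(a = 0.2, b = 1, c = 0.5), 0)
  expect_equal(out0$retentate$amounts, st$amounts)
  out <- diafilter(st, c(a = 0.3, b = 1, c = 0), 10)
  expect_equal(unname(out$retentate$amounts["b"]), exp(-10), tolerance = 1e-12)
  expect_equal(unname(out$retentate$amounts["b"]), 4.54e-5, tolerance = 1e-3)
  expect_equal(unname(out$retentate$amounts["c"]), 1)
  expect_equal(out$retentate$volume_ml, 5)       # constant-volume operation
  expect_equal(out$permeate$volume_ml, 50)
  out8 <- diafilter(st, c(a = 0.3, b = 1, c = 0), 8)
  expect_equal(unname(out8$retentate$amounts["a"]), exp(-2.4),
               tolerance = 1e-12)
  expect_error(diafilter(st, c(a = 0.3, b = 1, c = 0), -1), ">= 0")
})

test_that("closed forms agree with fine-step ODE integration", {
  grid <- expand.grid(S = c(0, 0.1, 0.3, 0.5, 0.8, 1),
                      X = c(1, 2, 4, 10, 100),
                      N = c(0, 1, 5, 9, 10))
  for (i in seq_len(nrow(grid))) {
    S <- grid$S[i]; X <- grid$X[i]; N <- grid$N[i]
    expect_equal((1 / X)^S, ode_concentrate(S, X), tolerance = 1e-6)
    expect_equal(exp(-N * S), ode_diafilter(S, N), tolerance = 1e-6)
  }
})

test_that("each unit operation conserves mass exactly", {
  withr::with_seed(31, {
    for (rep in 1:25) {
      amt <- stats::setNames(stats::runif(3, 0, 10), c("a", "b", "c"))
      st <- stream_state(amt, stats::runif(1, 1, 500))
      s <- stats::setNames(stats::runif(3), c("a", "b", "c"))
      oc <- concentrate(st, s, stats::runif(1, 1, 50))
      expect_equal(oc$retentate$amounts + oc$permeate$amounts, st$amounts,
                   tolerance = 1e-12)
      od <- diafilter(st, s, stats::runif(1, 0, 12))
      expect_equal(od$retentate$amounts + od$permeate$amounts, st$amounts,
                   tolerance = 1e-12)
    }
  })
})

test_that("clarification discards the retentate and advances the permeate", {
  species <- list(
    particle_species("exomere", size_truncnorm(45.6, 10.7), 1),
    particle_species("debris", size_point(5e5), 1)
  )
  st <- stream_state(c(exomere = 1, debris = 1), 360)
  clar <- default_membranes()[["0.2 um"]]
  out <- clarify(st, clar, corr_cal, species, X_clar = 10)
  # debris (effectively infinite size, S = 0) stays in the discarded retentate
  expect_equal(unname(out$discarded_retentate$amounts["debris"]), 1)
  expect_equal(unname(out$advanced_permeate$amounts["debris"]), 0)
  # 45 nm particles sieve almost freely (S ~ 1): nearly (1 - 1/X) advances
  s_exo <- mean_sieving(species[[1]], clar, corr_cal)
  expect_gt(s_exo, 0.99)
  expect_gt(unname(out$advanced_permeate$amounts["exomere"]), 1 - (1 / 10)^s_exo - 1e-9)
  # X_clar = 1 drives no filtration at all
  out1 <- clarify(st, clar, corr_cal, species, X_clar = 1)
  expect_equal(out1$discarded_retentate$amounts, st$amounts)
  expect_equal(sum(out1$advanced_permeate$amounts), 0)
})

# membranes engineered so the test species sit at numerically exact S = 0 / 1
extreme_cascade <- function(X = 10, N = 10, X_clar = 1e9) {
  cascade_spec(list(
    stage_spec(membrane_spec("open clarifier", 1e8, "clarifier"),
               X = X_clar, diavolumes = 0, collect_retentate = FALSE),
    stage_spec(membrane_spec("tight F1", 1e-3), X = X, diavolumes = N,
               fraction_label = "F1"),
    stage_spec(membrane_spec("tight F2", 1e-4), X = X, diavolumes = N,
               fraction_label = "F2"),
    stage_spec(membrane_spec("tight F3", 1e-5), X = X, diavolumes = N,
               fraction_label = "F3"),
    stage_spec(membrane_spec("tight F4", 1e-6), X = X, diavolumes = N,
               fraction_label = "F4")
  ))
}

test_that("a fully rejected species is recovered entirely in F1", {
  species <- list(particle_species("big", size_point(120), 1))
  res <- run_cascade(species, extreme_cascade(), corr_cal)
  # up to the 1/X_clar sliver lost to the (wide-open) clarifier retentate
  expect_equal(unname(res$fractions$F1$amounts["big"]), 1, tolerance = 1e-6)
  for (f in c("F2", "F3", "F4")) {
    expect_equal(unname(res$fractions[[f]]$amounts["big"]), 0)
  }
})

test_that("a freely passing species leaves ~0.1 e^-10 per fraction, rest in terminal permeate", {
  # particle far below every fractionating pore: S = 1 on all four stages
  cascade <- cascade_spec(list(
    stage_spec(membrane_spec("open clarifier", 1e8, "clarifier"),
               X = 1e9, diavolumes = 0, collect_retentate = FALSE),
    stage_spec(membrane_spec("f1", 1e6), X = 10, diavolumes = 10,
               fraction_label = "F1"),
    stage_spec(membrane_spec("f2", 1e6 - 1), X = 10, diavolumes = 10,
               fraction_label = "F2"),
    stage_spec(membrane_spec("f3", 1e6 - 2), X = 10, diavolumes = 10,
               fraction_label = "F3"),
    stage_spec(membrane_spec("f4", 1e6 - 3), X = 10, diavolumes = 10,
               fraction_label = "F4")
  ))
  species <- list(particle_species("tiny", size_point(1e-3), 1))
  res <- run_cascade(species, cascade, corr_cal)
  per_stage <- 0.1 * exp(-10)
  for (f in c("F1", "F2", "F3", "F4")) {
    expect_equal(unname(res$fractions[[f]]$amounts["tiny"]), per_stage,
                 tolerance = 1e-4)
  }
  expect_gt(unname(res$discards[["terminal permeate"]]$amounts["tiny"]),
            1 - 5 * per_stage - 1e-6)
})

test_that("cascades conserve mass per stage and globally", {
  withr::with_seed(101, {
    for (rep in 1:100) {
      amounts <- stats::runif(3, 0.1, 100)
      species <- list(
        particle_species("p1", size_point(stats::runif(1, 3, 20)), amounts[1]),
        particle_species("p2", size_truncnorm(stats::runif(1, 30, 70),
                                              stats::runif(1, 5, 20)),
                         amounts[2]),
        particle_species("p3", size_lognormal(stats::runif(1, 60, 150),
                                              stats::runif(1, 1.1, 1.6)),
                         amounts[3])
      )
      cascade <- default_cascade(X = stats::runif(1, 1, 50),
                                 diavolumes = stats::runif(1, 0, 12),
                                 X_clar = stats::runif(1, 1, 20))
      res <- run_cascade(species, cascade, corr_cal, n_nodes = 16)
      total <- Reduce(`+`, lapply(c(res$fractions, res$discards),
                                  function(s) s$amounts))
      expect_equal(total, res$feed$amounts, tolerance = 1e-9)
      # per-stage: input = retentate + permeate
      lg <- res$stage_log
      expect_equal(lg$input_amount, lg$retentate_amount + lg$permeate_amount,
                   tolerance = 1e-9)
    }
  })
})

test_that("more diavolumes never increase a retained fraction", {
  st <- stream_state(c(a = 1, b = 2), 10)
  s <- c(a = 0.3, b = 0.9)
  prev <- diafilter(st, s, 0)$retentate$amounts
  for (N in c(1, 2, 5, 8, 10, 15)) {
    cur <- diafilter(st, s, N)$retentate$amounts
    expect_true(all(cur <= prev + 1e-15))
    prev <- cur
  }
})

test_that("larger particles are never less rejected at any stage", {
  cascade <- default_cascade()
  d <- sort(withr::with_seed(17, stats::runif(10, 3, 200)))
  for (st in cascade$stages) {
    r <- vapply(d, function(di)
      mean_rejection(size_point(di), st$membrane, corr_cal), numeric(1))
    expect_true(all(diff(r) >= 0))
  }
})

test_that("stage order matters: descending pore order is load-bearing", {
  pop <- generate_population()
  res_desc <- run_cascade(pop$species, default_cascade(), corr_cal,
                          feed = pop$feed)
  m <- default_membranes()
  # swap F2 (500 kDa) and F4 (100 kDa): run tight membrane early
  swapped <- cascade_spec(list(
    stage_spec(m[["0.2 um"]], X = 10, diavolumes = 0,
               collect_retentate = FALSE),
    stage_spec(m[["0.05 um"]], fraction_label = "F1"),
    stage_spec(m[["100 kDa"]], fraction_label = "F2"),
    stage_spec(m[["300 kDa"]], fraction_label = "F3"),
    stage_spec(m[["500 kDa"]], fraction_label = "F4")
  ))
  res_swap <- run_cascade(pop$species, swapped, corr_cal, feed = pop$feed)
  exo_desc <- unname(res_desc$fractions$F4$amounts["exomere"])
  exo_swap <- unname(res_swap$fractions$F4$amounts["exomere"])
  # with the tight filter moved upstream, exomeres are captured there instead
  expect_gt(exo_desc, 10 * exo_swap)
  expect_gt(unname(res_swap$fractions$F2$amounts["exomere"]), exo_swap)
})

test_that("run_cascade matches an independent stage-by-stage calculation", {
  pop <- generate_population()
  cascade <- default_cascade()
  sievings <- lapply(cascade$stages, function(st)
    vapply(pop$species, function(sp)
      mean_sieving(sp, st$membrane, corr_cal), numeric(1)))
  manual <- manual_cascade(pop$feed$amounts, sievings, X = 10, N = 9,
                           X_clar = 10)
  res <- run_cascade(pop$species, cascade, corr_cal, feed = pop$feed)
  for (i in 1:4) {
    expect_equal(res$fractions[[paste0("F", i)]]$amounts,
                 manual$fractions[[i]], tolerance = 1e-12)
  }
  expect_equal(res$discards[["terminal permeate"]]$amounts, manual$terminal,
               tolerance = 1e-12)
})

test_that("cascade topology violations are configuration errors", {
  m <- default_membranes()
  expect_error(cascade_spec(list(stage_spec(m[["300 kDa"]]))), "clarifier")
  expect_error(
    stage_spec(m[["0.2 um"]], collect_retentate = TRUE),
    "clarifier")
  expect_error(cascade_spec(list(
    stage_spec(m[["0.2 um"]], diavolumes = 0, collect_retentate = FALSE),
    stage_spec(m[["300 kDa"]]),
    stage_spec(membrane_spec("300 kDa", 15))
  )), "unique")
})

test_that("the enrichment window for a 35 nm target is between 15 and 5 nm", {
  w <- design_enrichment_window(35, default_membranes(), corr_cal,
                                threshold_R = 0.85)
  expect_true(w$found)
  expect_equal(w$upstream$mean_pore_diameter_nm, 15)
  expect_equal(w$downstream$mean_pore_diameter_nm, 5)
  expect_equal(w$downstream$label, "100 kDa")   # the F4 retentate position
})

test_that("window edge cases: top-of-cascade and no-window outcomes", {
  m <- default_membranes()
  big <- design_enrichment_window(5000, m, corr_cal, threshold_R = 0.85)
  expect_true(big$found)
  expect_null(big$upstream)
  expect_equal(big$downstream$mean_pore_diameter_nm, 185)
  # max achievable rejection of 35 nm (on the 5 nm membrane) is ~0.89 < 0.999
  none <- design_enrichment_window(35, m, corr_cal, threshold_R = 0.999)
  expect_false(none$found)
  expect_null(none$upstream); expect_null(none$downstream)
  expect_error(design_enrichment_window(35, m, corr_cal, threshold_R = 1.2),
               "0, 1")
})

test_that("exomeres come out purest and most recovered in F4", {
  pop <- generate_population()
  res <- run_cascade(pop$species, default_cascade(), corr_cal, feed = pop$feed)
  rep <- build_report(res$feed, res$fractions)
  exo <- rep[rep$species == "exomere", ]
  feed_purity <- res$feed$amounts["exomere"] / sum(res$feed$amounts)
  expect_gt(exo$purity[exo$fraction == "F4"], exo$purity[exo$fraction == "F2"])
  expect_gt(exo$purity[exo$fraction == "F4"], feed_purity)
  expect_equal(exo$fraction[which.max(exo$recovery)], "F4")
})
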