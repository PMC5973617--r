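test_that("configuration invariants are enforced with the field named", {
  expect_error(synthetic_config(gamma = -1), "gamma")
  expect_error(synthetic_config(f_m = 1.2), "f_m")
  expect_error(synthetic_config(k_micro = c(A = 0.1)), "k_micro")
  expect_error(synthetic_config(water_change_days = c(7, 14)),
               "water_change_days")
  expect_error(synthetic_config(compositions = c("A", "AZ")), "compositions")
})

test_that("a fixed seed gives bit-identical output", {
  cfg <- fast_config()
  e1 <- generate_experiment(cfg)
  e2 <- generate_experiment(cfg)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_results(e1, p1)
  write_results(e2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("adding replicates never changes existing microcosms", {
  small <- generate_experiment(fast_config(n_replicates = 2))
  large <- generate_experiment(fast_config(n_replicates = 3))
  key <- function(d) split(d, list(d$composition, d$detritivores_present))
  ks <- key(small); kl <- key(large)
  for (k in names(ks)) {
    a <- ks[[k]]; b <- kl[[k]][seq_len(nrow(ks[[k]])), ]
    num <- names(a)[vapply(a, is.numeric, logical(1))]
    for (cc in num) {
      expect_equal(unname(b[[cc]]), unname(a[[cc]]), tolerance = 1e-12,
                   label = paste(k, cc))
    }
  }
})

test_that("noise-free null mechanisms force exactly null diversity effects", {
  cfg <- synthetic_config(gamma = 1, preference_exponent = 0,
                          noise_mass_cv = 0, noise_filter_sd = 0,
                          noise_cl_sd = 0, larva_dm_cv = 0,
                          n_replicates = 1L, seed = 5)
  # contribution percentages are undefined (and warned about) when both
  # effects are exactly zero
  ps <- suppressWarnings(
    partition_experiment(compute_metrics(generate_experiment(cfg))))
  expect_lt(max(abs(ps$replicates$net)), 1e-9)
  expect_lt(max(abs(ps$replicates$CE)), 1e-9)
  expect_lt(max(abs(ps$replicates$SE)), 1e-9)
  expect_lt(max(abs(ps$replicates$fpom_net)), 1e-9)
})

test_that("mass is conserved microcosm by microcosm when noise is off", {
  cfg <- synthetic_config(noise_mass_cv = 0, noise_filter_sd = 0,
                          noise_cl_sd = 0, larva_dm_cv = 0,
                          n_replicates = 1L, seed = 5)
  exp <- generate_experiment(cfg)
  B0 <- cfg$n_larvae * cfg$larva_dm_mean
  for (i in seq_len(nrow(exp))) {
    out <- beflitter:::deterministic_outcome(
      cfg, exp$composition[i], exp$detritivores_present[i],
      B = if (exp$detritivores_present[i]) B0 else 0)
    sp <- out$species
    final <- as.numeric(exp[i, paste0("final_afdm__", sp)])
    # post-leach AFDM = final AFDM + microbial loss + consumed mass
    expect_lt(max(abs(out$postleach - (final + out$microbial + out$consumed))),
              1e-9)
    fpom <- sum(as.numeric(exp[i, grep("^fpom_mg__", names(exp))]))
    expect_equal(fpom, cfg$f_m * sum(out$microbial) +
                   cfg$f_d * sum(out$consumed), tolerance = 1e-9)
  }
})

test_that("switching consumption off makes the two arms identical", {
  cfg <- synthetic_config(consumption_rate = 0, noise_mass_cv = 0,
                          noise_filter_sd = 0, noise_cl_sd = 0,
                          larva_dm_cv = 0, n_replicates = 1L, seed = 5)
  exp <- generate_experiment(cfg)
  det <- exp[exp$detritivores_present, ]
  non <- exp[!exp$detritivores_present, ]
  cols <- grep("^final_afdm__|^fpom_mg__", names(exp), value = TRUE)
  for (cc in cols) {
    expect_equal(det[[cc]][order(det$composition)],
                 non[[cc]][order(non$composition)], tolerance = 1e-12)
  }
})

test_that("ground truth reflects the injected mechanisms", {
  # no mechanisms: every expected effect is zero
  gt0 <- ground_truth(synthetic_config(gamma = 1, preference_exponent = 0))
  expect_lt(max(abs(gt0$mixtures$net)), 1e-9)
  expect_lt(max(abs(gt0$mixtures$CE)), 1e-9)
  expect_lt(max(abs(gt0$mixtures$SE)), 1e-9)

  # complementarity only: CE > 0 everywhere and dominates |SE|
  gt1 <- ground_truth(synthetic_config(gamma = 1.3, preference_exponent = 0))
  expect_true(all(gt1$mixtures$CE > 0))
  expect_true(all(abs(gt1$mixtures$SE) < 0.1 * gt1$mixtures$CE))

  # preference tilted to the fastest-decomposing species (highest N):
  # positive selection wherever that species is present; the fixed
  # consumption total makes the reallocation zero-sum, so net = 0 and
  # CE = -SE
  gt2 <- ground_truth(synthetic_config(gamma = 1, preference_exponent = 2))
  withA <- grepl("A", gt2$mixtures$mixture)
  expect_true(all(gt2$mixtures$SE[withA] > 0))
  expect_lt(max(abs(gt2$mixtures$net)), 1e-9)
  expect_equal(gt2$mixtures$CE, -gt2$mixtures$SE, tolerance = 1e-9)

  # the detritivore-free arm never shows a diversity effect
  expect_true(all(gt1$mixtures$net_no_detritivores == 0))
})

test_that("the pipeline recovers ground truth exactly as noise vanishes", {
  cfg <- synthetic_config(noise_mass_cv = 0, noise_filter_sd = 0,
                          noise_cl_sd = 0, larva_dm_cv = 0,
                          n_replicates = 1L, seed = 5)
  gt <- ground_truth(cfg)
  ps <- partition_experiment(compute_metrics(generate_experiment(cfg)))
  m <- merge(ps$summary, gt$mixtures, by = "mixture")
  expect_equal(m$net_mean, m$net, tolerance = 1e-6)
  expect_equal(m$CE_mean, m$CE, tolerance = 1e-6)
  expect_equal(m$SE_mean, m$SE, tolerance = 1e-6)
  expect_equal(m$fpom_net_mean, m$fpom_net, tolerance = 1e-6)
  gr <- detritivore_growth(generate_experiment(cfg))
  expect_equal(mean(gr$growth_pct, na.rm = TRUE),
               mean(gt$growth$growth_pct), tolerance = 1e-6)
})

test_that("noisy experiments recover ground truth within Monte-Carlo error", {
  # pooled across mixtures and independent experiment replicates, since
  # within-experiment replicates share the estimated monoculture means
  cfg0 <- synthetic_config()
  gt <- ground_truth(cfg0)
  K <- 8
  est <- sapply(seq_len(K), function(s) {
    cfg <- synthetic_config(seed = 1000 + s)
    r <- partition_experiment(compute_metrics(generate_experiment(cfg)),
                              mixtures = gt$mixtures$mixture)$replicates
    c(net = mean(r$net), CE = mean(r$CE), SE = mean(r$SE))
  })
  gt_mean <- c(net = mean(gt$mixtures$net), CE = mean(gt$mixtures$CE),
               SE = mean(gt$mixtures$SE))
  for (q in c("net", "CE", "SE")) {
    mc_se <- stats::sd(est[q, ]) / sqrt(K)
    expect_lt(abs(mean(est[q, ]) - gt_mean[[q]]), 3 * mc_se + 1e-12)
  }
})
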