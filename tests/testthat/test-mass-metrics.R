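test_that("allometric dry mass follows the power law and rejects bad input", {
  p <- allometry_params()
  expect_equal(allometric_dm(1, p), p$a)                 # CL = 1 forces DM = a
  # independent log-space computation of a * 10^b
  expect_equal(allometric_dm(10, p), exp(log(p$a) + p$b * log(10)),
               tolerance = 1e-12)
  expect_error(allometric_dm(0, p), "positive")
  expect_error(allometric_dm(-3, p), "positive")
  # inverse allometry round-trips
  cl <- c(5, 9, 13.5)
  expect_equal(inverse_allometry(allometric_dm(cl, p), p), cl,
               tolerance = 1e-12)
  expect_error(allometry_params(a = -1), "positive")
})

test_that("leaching correction multiplies air-dry mass by the species factor", {
  exp <- two_species_experiment()
  init <- corrected_initial_afdm(exp)                    # A: 0.753, C: 0.843
  expect_equal(unname(init[1, ]), c(100 * 0.753, 50 * 0.843))
  # factor 1 is the identity
  init1 <- corrected_initial_afdm(exp, c(A = 1, C = 1))
  expect_equal(unname(init1[1, ]), c(100, 50))
  # hand-computed pair
  init2 <- corrected_initial_afdm(exp, c(A = 0.8, C = 0.9))
  expect_equal(unname(init2[2, ]), c(80, 45))
  expect_error(corrected_initial_afdm(exp, c(A = 0.753)),
               "no leaching factor for species C")
})

test_that("mass loss is corrected-initial minus final, normalised by detritivore mass", {
  exp <- two_species_experiment()
  ml <- mass_loss(exp)
  # corrected initial (75.3, 42.15), final AFDM (50, 40)
  expect_equal(ml$loss__A[1], 25.3)
  expect_equal(ml$loss__C[1], 2.15, tolerance = 1e-12)
  expect_equal(ml$total_loss[1], 27.45, tolerance = 1e-12)
  # three larvae of 6 mg: B = 18 mg -> normalised 27.45 / 18
  expect_equal(ml$norm_total_loss[1], 27.45 / 18, tolerance = 1e-9)
  expect_false(ml$mass_gain_flag[1])
  expect_true(is.na(ml$norm_total_loss[2]))              # no detritivores

  # final equal to corrected initial means zero loss
  exp0 <- as.data.frame(exp)
  exp0$final_afdm__A <- exp0$initial_airdry_dm__A * 0.753
  exp0$final_afdm__C <- exp0$initial_airdry_dm__C * 0.843
  exp0$final_dm__A <- exp0$final_afdm__A * 1.1
  exp0$final_dm__C <- exp0$final_afdm__C * 1.1
  ml0 <- mass_loss(validate_experiment(exp0))
  expect_equal(ml0$total_loss, c(0, 0), tolerance = 1e-12)
})

test_that("negative per-species losses are preserved and flagged, not clipped", {
  exp <- as.data.frame(two_species_experiment())
  exp$final_afdm__C <- 60                                # above corrected 42.15
  exp$final_dm__C <- 66
  ml <- mass_loss(validate_experiment(exp))
  expect_lt(ml$loss__C[1], 0)
  expect_true(all(ml$mass_gain_flag))
  expect_equal(ml$total_loss[1], ml$loss__A[1] + ml$loss__C[1])
})

test_that("FPOM production sums collection events and normalises by detritivore mass", {
  exp <- two_species_experiment()
  fp <- fpom_production(exp)
  expect_equal(fp$fpom_total, c(7, 7))
  expect_equal(fp$fpom_norm[1], 7 / 18, tolerance = 1e-9)
  expect_true(is.na(fp$fpom_norm[2]))

  # 7.0 mg with 17.5 mg of detritivore is 0.4 mg per mg
  exp2 <- as.data.frame(exp)
  cl <- cl_for_dm(17.5 / 3)
  exp2[1, c("case_length_mm__1", "case_length_mm__2", "case_length_mm__3")] <- cl
  expect_equal(fpom_production(validate_experiment(exp2))$fpom_norm[1], 0.4,
               tolerance = 1e-9)

  neg <- as.data.frame(exp)
  neg$fpom_mg__d14 <- -0.1
  expect_error(validate_experiment(neg), "negative mass")
  expect_error(fpom_production(neg), "negative FPOM filter mass")
})

test_that("detritivore growth is the percent change from the allometric initial mass", {
  exp <- as.data.frame(two_species_experiment())
  cl <- cl_for_dm(10 / 3)
  exp[1, c("case_length_mm__1", "case_length_mm__2", "case_length_mm__3")] <- cl
  exp$detritivore_final_dm[1] <- 15
  gr <- detritivore_growth(validate_experiment(exp))
  expect_equal(gr$growth_pct[1], 50, tolerance = 1e-9)   # 10 -> 15 mg
  exp$detritivore_final_dm[1] <- 10
  expect_equal(detritivore_growth(validate_experiment(exp))$growth_pct[1], 0,
               tolerance = 1e-9)
  # three larvae, summed allometric initial mass
  cls <- c(9, 10, 11)
  exp[1, c("case_length_mm__1", "case_length_mm__2", "case_length_mm__3")] <- cls
  gr3 <- detritivore_growth(validate_experiment(exp))
  expect_equal(gr3$detritivore_initial_dm[1],
               sum(0.0043 * cls^2.8041), tolerance = 1e-12)
  # an experiment with no detritivore arm at all
  none <- validate_experiment(exp[2, , drop = FALSE])
  expect_error(detritivore_growth(none), "no microcosms with detritivores")
})

test_that("metric invariants: additivity, monotonicity, normalisation scaling", {
  exp <- generate_experiment(fast_config())
  ml <- mass_loss(exp)
  sp_cols <- grep("^loss__", names(ml), value = TRUE)
  expect_equal(rowSums(ml[, sp_cols], na.rm = TRUE), ml$total_loss,
               tolerance = 1e-12)

  # raising any final AFDM strictly lowers the corresponding loss
  bump <- as.data.frame(exp)
  i <- which(!is.na(bump$final_afdm__Q))[1]
  bump$final_afdm__Q[i] <- bump$final_afdm__Q[i] + 1
  bump$final_dm__Q[i] <- bump$final_dm__Q[i] + 2
  ml2 <- mass_loss(validate_experiment(bump))
  expect_equal(ml2$loss__Q[i], ml$loss__Q[i] - 1, tolerance = 1e-9)

  # doubling detritivore mass halves normalised loss and FPOM
  dbl <- as.data.frame(exp)
  det <- dbl$detritivores_present
  cl_cols <- paste0("case_length_mm__", 1:3)
  p <- allometry_params()
  dbl[det, cl_cols] <- inverse_allometry(
    2 * allometric_dm(as.matrix(dbl[det, cl_cols]), p), p)
  ml_d <- mass_loss(validate_experiment(dbl))
  fp_d <- fpom_production(validate_experiment(dbl))
  fp <- fpom_production(exp)
  expect_equal(ml_d$norm_total_loss[det], ml$norm_total_loss[det] / 2,
               tolerance = 1e-9)
  expect_equal(fp_d$fpom_norm[det], fp$fpom_norm[det] / 2, tolerance = 1e-9)
})
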