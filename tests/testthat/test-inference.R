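test_that("the equal-variance fit reproduces the textbook ANOVA F", {
  d <- data.frame(y = c(0, 1, 2, 10, 11, 12),
                  g = rep(c("a", "b"), each = 3))
  fit <- hetero_oneway(y ~ g, d, equal_var = TRUE)
  expect_equal(fit$F, 150)                    # MS_between 150, MS_within 1
  expect_equal(fit$df1, 1)
  expect_equal(fit$df2, 4)
  # against aov on random data
  set.seed(11)
  for (i in 1:10) {
    dd <- data.frame(y = rnorm(30), g = sample(letters[1:3], 30, TRUE))
    if (min(table(dd$g)) < 2) next
    f1 <- hetero_oneway(y ~ g, dd, equal_var = TRUE)
    f2 <- summary(stats::aov(y ~ g, dd))[[1]]
    expect_equal(f1$F, f2[1, "F value"], tolerance = 1e-6)
    expect_equal(f1$p.value, f2[1, "Pr(>F)"], tolerance = 1e-6)
  }
})

test_that("the two-group heteroscedastic F equals the squared Welch t", {
  set.seed(21)
  for (i in 1:10) {
    d <- data.frame(y = c(rnorm(7, 0, 1), rnorm(12, 1, 3)),
                    g = rep(c("a", "b"), c(7, 12)))
    fit <- hetero_oneway(y ~ g, d, equal_var = FALSE)
    w <- stats::t.test(y ~ g, d)
    expect_equal(fit$F, unname(w$statistic)^2, tolerance = 1e-6)
  }
})

test_that("identical data in every group give F = 0", {
  d <- data.frame(y = rep(c(5, 6), 4), g = rep(c("a", "b"), each = 4))
  d$y <- rep(c(5, 6, 5, 6), 2)
  expect_equal(hetero_oneway(y ~ g, d)$F, 0)
  expect_error(hetero_oneway(y ~ g, data.frame(y = 1:2, g = c("a", "b"))),
               "fewer than 2 observations")
})

test_that("the closed-form REML fit agrees with gls + varIdent", {
  set.seed(31)
  d <- data.frame(y = c(rnorm(8, 0, 1), rnorm(10, 2, 3), rnorm(12, 5, 0.5)),
                  g = rep(c("a", "b", "c"), c(8, 10, 12)))
  fit <- hetero_oneway(y ~ g, d)
  ref <- nlme::gls(y ~ g, d, weights = nlme::varIdent(form = ~ 1 | g),
                   method = "REML")
  # per-group variances
  sds <- ref$sigma * coef(ref$modelStruct$varStruct, unconstrained = FALSE,
                          allCoef = TRUE)
  expect_equal(unname(fit$variances[names(sds)]), unname(sds^2),
               tolerance = 1e-6)
  # restricted log-likelihood
  expect_equal(fit$logLik, as.numeric(stats::logLik(ref)), tolerance = 1e-6)
  # Wald F for the group factor, containment denominator df
  a <- stats::anova(ref)
  expect_equal(fit$F, a["g", "F-value"], tolerance = 1e-5)
})

test_that("REML variance estimates recover generating group variances", {
  set.seed(41)
  sds <- c(a = 1, b = 2, c = 3)
  d <- data.frame(g = rep(names(sds), each = 200))
  d$y <- rnorm(600, mean = rep(c(0, 1, 2), each = 200),
               sd = rep(sds, each = 200))
  fit <- hetero_oneway(y ~ g, d)
  expect_equal(unname(sqrt(fit$variances)), unname(sds), tolerance = 0.15)
})

test_that("Tukey-Kramer comparisons separate distant groups and letter them", {
  d <- data.frame(y = c(0, 1, 2, 10, 11, 12),
                  g = rep(c("a", "b"), each = 3))
  tk <- tukey_pairwise(hetero_oneway(y ~ g, d, equal_var = TRUE))
  expect_lt(tk$comparisons$p.adj, 0.001)
  expect_setequal(unname(tk$letters), c("a", "b"))

  # literally identical groups: adjusted p = 1, a single shared letter
  d2 <- data.frame(y = rep(c(1, 2, 3), 2), g = rep(c("a", "b"), each = 3))
  tk2 <- tukey_pairwise(hetero_oneway(y ~ g, d2))
  expect_equal(tk2$comparisons$p.adj, 1, tolerance = 1e-9)
  expect_equal(unname(tk2$letters), c("a", "a"))

  # three groups 0, 0, 10 (sd 1, n = 10): letters a, a, b
  set.seed(51)
  d3 <- data.frame(y = c(rnorm(10, 0), rnorm(10, 0), rnorm(10, 10)),
                   g = rep(c("g1", "g2", "g3"), each = 10))
  tk3 <- tukey_pairwise(hetero_oneway(y ~ g, d3))
  expect_equal(unname(tk3$letters), c("a", "a", "b"))
})

test_that("adjusted p-values never fall below raw p-values", {
  set.seed(61)
  for (i in 1:15) {
    k <- sample(2:5, 1)
    d <- data.frame(y = rnorm(10 * k, mean = rep(rnorm(k, sd = 2), each = 10),
                              sd = rep(runif(k, 0.5, 3), each = 10)),
                    g = rep(paste0("g", 1:k), each = 10))
    tk <- tukey_pairwise(hetero_oneway(y ~ g, d))
    expect_true(all(tk$comparisons$p.adj >= tk$comparisons$p.raw - 1e-12))
    # letters consistent: significant pairs share no letter, others do
    L <- tk$letters
    for (r in seq_len(nrow(tk$comparisons))) {
      shared <- length(intersect(
        strsplit(L[[tk$comparisons$group1[r]]], "")[[1]],
        strsplit(L[[tk$comparisons$group2[r]]], "")[[1]]))
      if (tk$comparisons$p.adj[r] < 0.05) expect_equal(shared, 0)
      else expect_gt(shared, 0)
    }
  }
})

test_that("with two groups the Tukey adjustment reduces to the t-test", {
  set.seed(71)
  d <- data.frame(y = c(rnorm(8, 0, 1), rnorm(8, 1, 1)),
                  g = rep(c("a", "b"), each = 8))
  # balanced equal-variance: pooled t-test
  tk <- tukey_pairwise(hetero_oneway(y ~ g, d, equal_var = TRUE))
  tt <- stats::t.test(y ~ g, d, var.equal = TRUE)
  expect_equal(tk$comparisons$p.adj, tt$p.value, tolerance = 1e-6)
  # unequal variances: Welch t-test
  d$y[d$g == "b"] <- d$y[d$g == "b"] * 4
  tkw <- tukey_pairwise(hetero_oneway(y ~ g, d))
  tw <- stats::t.test(y ~ g, d)
  expect_equal(tkw$comparisons$p.adj, tw$p.value, tolerance = 1e-6)
})

test_that("welch_t matches the closed form and its scale property", {
  expect_equal(welch_t(3, 0.5, 5, 3, 0.7, 5)$t, 0)
  w <- welch_t(1.58, 0.05, 5, 1.62, 0.13, 5)
  expect_equal(w$t, -0.04 / sqrt(0.0025 + 0.0169), tolerance = 1e-12)
  w2 <- welch_t(1.58, 0.10, 5, 1.62, 0.26, 5)
  expect_equal(w2$t, w$t / 2, tolerance = 1e-12)
  expect_error(welch_t(1, 0, 5, 2, 0.1, 5), "degenerate")
})

test_that("trait-effect regressions fit OLS with the documented transforms", {
  # perfectly collinear, untransformed (exact fits trip lm's own caveat)
  r <- suppressWarnings(
    regress_effect_on_trait(c(2, 4, 6), c(1, 2, 3), log_transform = FALSE))
  expect_equal(r$slope, 2, tolerance = 1e-12)
  expect_equal(r$r.squared, 1, tolerance = 1e-12)
  # flat response without noise: F = 0
  r0 <- suppressWarnings(
    regress_effect_on_trait(c(5, 5, 5, 5), c(1, 2, 3, 4),
                            log_transform = FALSE))
  expect_equal(r0$F, 0)
  expect_equal(r0$p.value, 1)
  # log-log when everything is positive
  x <- c(1, 2, 4, 8); y <- 3 * x^2
  rl <- suppressWarnings(regress_effect_on_trait(y, x, log_transform = TRUE))
  expect_true(rl$transform_response && rl$transform_predictor)
  expect_equal(rl$slope, 2, tolerance = 1e-9)
  # non-positive effects: response left untransformed, with a warning
  expect_warning(
    rn <- regress_effect_on_trait(c(-1, 0.5, 1, 2), c(1, 2, 3, 4)),
    "untransformed")
  expect_false(rn$transform_response)
  expect_true(rn$transform_predictor)
  expect_error(regress_effect_on_trait(c(1, 2, 3), c(-1, 2, 3)),
               "non-positive predictor")
})

test_that("regression detects a simulated positive trait dependence", {
  set.seed(81)
  x <- runif(40, 0.04, 0.09)               # a phosphorus-like predictor
  y <- exp(1.5 * log(x) + rnorm(40, sd = 0.2) + 4)
  r <- regress_effect_on_trait(y, x)
  expect_gt(r$slope, 0)
  expect_lt(r$p.value, 0.05)
})
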