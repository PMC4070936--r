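test_that("instrument strength matches ordinary least squares", {
  # exact fit
  exact <- iv_dataset(g = c(0, 1, 2), x = c(0, 1, 2), y = c(0, 1, 0))
  s <- instrument_strength(exact)
  expect_equal(s$r2, 1)
  expect_identical(s$f_stat, Inf)
  # hand computation on a 3-point dataset
  hand <- iv_dataset(g = c(0, 1, 2), x = c(0.1, 0.8, 2.1), y = c(0, 1, 1))
  sxy <- sum((hand$g - 1) * (hand$x - 1)) # centred cross-product
  r2_hand <- sxy^2 / (sum((hand$g - 1)^2) * sum((hand$x - mean(hand$x))^2))
  sh <- instrument_strength(hand)
  expect_equal(sh$r2, r2_hand, tolerance = 1e-12)
  expect_equal(sh$f_stat, (3 - 2) * r2_hand / (1 - r2_hand), tolerance = 1e-12)
  # agrees with lm() and the F/R2 identity on random data
  for (seed in 1:5) {
    ds <- rand_ds(sample(10:60, 1), seed = 400 + seed)
    s <- instrument_strength(ds)
    sm <- summary(lm(x ~ g, data = ds))
    expect_equal(s$r2, sm$r.squared, tolerance = 1e-10)
    expect_equal(s$f_stat, unname(sm$fstatistic[1]), tolerance = 1e-8)
    expect_equal(s$f_stat, (nrow(ds) - 2) * s$r2 / (1 - s$r2))
  }
  expect_error(instrument_strength(iv_dataset(c(1, 1, 1), 1:3, c(0, 1, 0))),
               "constant")
})

test_that("two-stage and ratio estimates coincide for a single instrument", {
  # binary instrument, hand-computable: numerator log(p1/p0), denominator
  # the difference in mean exposure
  f <- iv_dataset(g = c(0, 0, 0, 0, 1, 1, 1, 1),
                  x = c(0, 1, 0, 1, 1, 2, 1, 2),
                  y = c(0, 1, 0, 1, 1, 1, 1, 0))
  rat <- ratio_estimate(f)
  expect_equal(rat$beta1_hat, log(0.75 / 0.5) / 1, tolerance = 1e-8)
  expect_equal(two_stage_estimate(f)$beta1_hat, rat$beta1_hat,
               tolerance = 1e-8)
  # simulated binary instrument
  set.seed(66)
  g <- rbinom(2000, 1, 0.4)
  x <- 0.5 * g + rnorm(2000)
  y <- rbinom(2000, 1, pmin(exp(-2.5 + 0.3 * x), 1))
  dsb <- iv_dataset(g, x, y)
  expect_equal(two_stage_estimate(dsb)$beta1_hat, ratio_estimate(dsb)$beta1_hat,
               tolerance = 1e-8)
  # the stage-2 covariate is an affine function of the instrument, so the
  # identity extends to a continuous instrument as well
  set.seed(67)
  g <- rnorm(2000)
  x <- 0.5 * g + rnorm(2000)
  y <- rbinom(2000, 1, pmin(exp(-2.5 + 0.3 * x), 1))
  dsc <- iv_dataset(g, x, y)
  expect_equal(two_stage_estimate(dsc)$beta1_hat, ratio_estimate(dsc)$beta1_hat,
               tolerance = 1e-8)
})

test_that("ratio estimate contracts: exact exposure, weak instrument, CI", {
  # x = g: denominator 1, so the ratio equals the outcome-model slope
  set.seed(68)
  g <- rnorm(3000)
  y <- rbinom(3000, 1, pmin(exp(-2.5 + 0.3 * g), 1))
  ds <- iv_dataset(g, g, y)
  fit <- glm(y ~ g, family = binomial("log"), start = c(log(mean(y)), 0))
  expect_equal(suppressWarnings(ratio_estimate(ds))$beta1_hat,
               unname(coef(fit)[2]), tolerance = 1e-6)
  # CI contains the point estimate and narrows with sample size
  est_small <- ratio_estimate(generate_dataset(dgp_config(2000, 0.1, seed = 9)))
  est_big <- ratio_estimate(generate_dataset(dgp_config(20000, 0.1, seed = 9)))
  for (e in list(est_small, est_big)) {
    expect_lte(e$ci_low, e$crr_hat)
    expect_gte(e$ci_high, e$crr_hat)
  }
  expect_lt(est_big$ci_high - est_big$ci_low,
            est_small$ci_high - est_small$ci_low)
  # constant exposure signal: instrument-exposure slope 0
  expect_error(suppressWarnings(
    ratio_estimate(iv_dataset(c(0, 1, 0, 1), c(1, 1, 1, 1), c(0, 1, 0, 1)))),
    "weak-instrument")
})

test_that("two-stage estimate is unbiased without confounding and null-safe", {
  # null: outcome independent of instrument and exposure
  set.seed(55)
  g <- rnorm(20000)
  x <- g * sqrt(0.1) + rnorm(20000) * sqrt(0.9)
  y <- rbinom(20000, 1, 0.05)
  e0 <- two_stage_estimate(iv_dataset(g, x, y))
  expect_lt(abs(e0$beta1_hat), 3 * e0$se)
  # recovery of beta1 = 0.2 in mean over replications
  est <- vapply(1:100, function(r) {
    two_stage_estimate(generate_dataset(
      dgp_config(20000, 0.1, seed = 46000 + r)))$beta1_hat
  }, 0)
  expect_lt(abs(mean(est) - 0.2), 0.03)
})

test_that("GMM point estimates carry the identification flag and roots", {
  # strong instrument: unique root near the truth with finite sandwich SE
  ds <- generate_dataset(dgp_config(50000, 0.5, seed = 3))
  e <- gmm_estimate(ds, "MGMM")
  expect_identical(e$multiplicity_flag, "UNIQUE")
  expect_lt(abs(e$beta1_hat - 0.2), 0.05)
  expect_equal(e$crr_hat, exp(e$beta1_hat))
  expect_true(is.finite(e$se))
  expect_lte(e$ci_low, e$crr_hat)
  expect_gte(e$ci_high, e$crr_hat)
  # weak instrument, multiple roots: all reported, smallest-|beta1| selected
  dm <- generate_dataset(dgp_config(5000, 0.005, seed = 502))
  em <- gmm_estimate(dm, "MGMM")
  expect_identical(em$multiplicity_flag, "MULTIPLE")
  expect_gte(length(em$roots), 2L)
  expect_identical(em$beta1_hat, em$roots[which.min(abs(em$roots))])
  for (r in em$roots) { # every reported root is a true sign change
    expect_true(mgmm_estfun(dm, r - 1e-6)$sign !=
                  mgmm_estfun(dm, r + 1e-6)$sign)
  }
  # no root: squared-moment minimisation with a positive attained minimum
  dn <- generate_dataset(dgp_config(5000, 0.005, seed = 504))
  en <- gmm_estimate(dn, "MGMM")
  expect_identical(en$multiplicity_flag, "NO_SOLUTION")
  expect_length(en$roots, 0)
  expect_gt(en$objective_minimum, 0)
  # degenerate data (no cases) is an error, not a silent zero
  expect_error(gmm_estimate(toy_fixture("allzero"), "MGMM"), "degenerate")
})

test_that("MGMM and LGMM estimate the same risk ratio when identified", {
  diffs <- c()
  for (s in 701:705) {
    ds <- generate_dataset(dgp_config(1e5, 0.5, seed = s))
    a <- scan_estfun(ds, "MGMM")
    b <- scan_estfun(ds, "LGMM")
    if (a$status == "UNIQUE" && b$status == "UNIQUE")
      diffs <- c(diffs, abs(a$roots - b$roots))
  }
  expect_gte(length(diffs), 3)
  expect_lt(median(diffs), 0.02)
})

test_that("the instrument-outcome Wald test behaves under null and alternative", {
  # null calibration: close-to-uniform p-values
  set.seed(900)
  pn <- vapply(1:400, function(i) {
    g <- rnorm(10000)
    y <- rbinom(10000, 1, 0.05)
    iv_outcome_test(iv_dataset(g, rnorm(10000), y))$p.value
  }, 0)
  ks <- suppressWarnings(ks.test(pn, "punif")$statistic)
  expect_lt(ks, 0.07)
  # strong effect: overwhelming rejection at the 5% level, and p < 0.001 in
  # a clear majority of replicates
  ps <- vapply(1:60, function(r) {
    iv_outcome_test(generate_dataset(
      dgp_config(10000, 0.1, beta1 = 0.5, seed = 47000 + r)))$p.value
  }, 0)
  expect_gte(mean(ps < 0.05), 0.90)
  expect_gte(mean(ps < 0.001), 0.55)
  # perfect separation surfaces as an explicit convergence failure
  sep <- iv_dataset(g = c(0, 0, 0, 1, 1, 1), x = c(0, 1, 0, 1, 0, 1),
                    y = c(0, 0, 0, 1, 1, 1))
  expect_error(suppressWarnings(iv_outcome_test(sep)),
               class = "ivcrr_convergence_error")
})
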