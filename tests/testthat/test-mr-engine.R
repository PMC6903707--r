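five_instruments <- function() {
  instrument_set(
    variant_id = sprintf("v%d", 1:5),
    beta_x = c(0.08, 0.12, 0.05, 0.10, 0.07),
    se_x = c(0.01, 0.012, 0.009, 0.011, 0.008),
    beta_y = c(0.020, 0.035, 0.010, 0.031, 0.015),
    se_y = c(0.010, 0.012, 0.009, 0.011, 0.008))
}

test_that("Wald ratio arithmetic, null case, and orientation invariance", {
  est <- wald_ratio(instrument_set("v", 0.1, 0.01, 0.05, 0.01))
  expect_equal(est$log_or, 0.5, tolerance = 1e-12)
  expect_equal(est$se, 0.1, tolerance = 1e-12)
  null <- wald_ratio(instrument_set("v", 1, 0.1, 0, 0.2))
  expect_equal(null$log_or, 0)
  expect_equal(null$or, 1)
  flipped <- wald_ratio(instrument_set("v", -0.1, 0.01, -0.05, 0.01))
  expect_equal(flipped$log_or, est$log_or, tolerance = 1e-14)
  expect_equal(flipped$se, est$se, tolerance = 1e-14)
  expect_error(wald_ratio(instrument_set("v", 0, 0.01, 0.05, 0.01)),
               "beta_x = 0")
})

test_that("IVW equals the weighted regression-through-origin oracle", {
  instr <- five_instruments()
  est <- ivw(instr)
  oracle <- lm(beta_y ~ beta_x - 1, data = instr, weights = 1 / instr$se_y^2)
  expect_equal(est$log_or, unname(coef(oracle)), tolerance = 1e-12)
  expect_equal(est$se, 1 / sqrt(sum(instr$beta_x^2 / instr$se_y^2)),
               tolerance = 1e-12)
  # Q against the oracle residuals
  q_oracle <- sum((resid(oracle) / instr$se_y)^2)
  expect_equal(est$q_stat, q_oracle, tolerance = 1e-10)
  expect_equal(est$q_p, pchisq(q_oracle, 4, lower.tail = FALSE),
               tolerance = 1e-10)

  # consensus: identical ratios collapse to that ratio exactly
  cons <- ivw(instrument_set(c("a", "b"), c(0.1, 0.2), c(0.01, 0.01),
                             c(0.05, 0.10), c(0.01, 0.02)))
  expect_equal(cons$log_or, 0.5, tolerance = 1e-14)
  # degenerate: one instrument equals the Wald ratio
  one <- instr[1, ]
  expect_equal(ivw(one)$log_or, wald_ratio(one)$log_or)
  expect_equal(ivw(one)$se, wald_ratio(one)$se)
  expect_true(is.na(ivw(one)$q_p))
  expect_error(ivw(instr[0, ]), "at least one|empty")
})

test_that("IVW invariances: joint sign flips and the single-instrument se bound", {
  instr <- five_instruments()
  est <- ivw(instr)
  flipped <- instr
  flipped$beta_x[2] <- -flipped$beta_x[2]
  flipped$beta_y[2] <- -flipped$beta_y[2]
  est_f <- ivw(flipped)
  expect_equal(est_f$log_or, est$log_or, tolerance = 1e-14)
  expect_equal(est_f$se, est$se, tolerance = 1e-14)
  wald_ses <- instr$se_y / abs(instr$beta_x)
  expect_lte(est$se, min(wald_ses))
})

test_that("MR-Egger matches the weighted-regression oracle and nests IVW", {
  instr <- five_instruments()
  # exact-fit case: beta_y = 0.01 + 0.5 * beta_x
  exact <- instr
  exact$beta_y <- 0.01 + 0.5 * exact$beta_x
  e <- mr_egger(exact)
  expect_equal(e$intercept, 0.01, tolerance = 1e-10)
  expect_equal(e$slope$log_or, 0.5, tolerance = 1e-10)
  expect_equal(e$residual_scale, 1)

  # pleiotropy fixture vs an independent weighted lm (QR) oracle
  six <- instrument_set(
    sprintf("v%d", 1:6),
    beta_x = c(0.08, 0.12, 0.05, 0.10, 0.07, 0.09),
    se_x = rep(0.01, 6),
    beta_y = c(0.021, 0.033 + 0.05, 0.012, 0.028, 0.018 + 0.05, 0.024),
    se_y = c(0.010, 0.012, 0.009, 0.011, 0.008, 0.010))
  eg <- mr_egger(six)
  w <- 1 / six$se_y^2
  oracle <- lm(beta_y ~ beta_x, data = six, weights = w)
  expect_equal(eg$slope$log_or, unname(coef(oracle)[2]), tolerance = 1e-10)
  expect_equal(eg$intercept, unname(coef(oracle)[1]), tolerance = 1e-10)
  scale <- max(1, summary(oracle)$sigma)
  se_oracle <- sqrt(diag(vcov(oracle))) / summary(oracle)$sigma * scale
  expect_equal(eg$intercept_se, unname(se_oracle[1]), tolerance = 1e-10)
  expect_equal(eg$slope$se, unname(se_oracle[2]), tolerance = 1e-10)
  expect_equal(eg$intercept_p,
               2 * pt(-abs(coef(oracle)[1] / se_oracle[1]), 4),
               tolerance = 1e-10, ignore_attr = TRUE)

  # nested-model identity: when the fitted intercept is exactly zero the
  # Egger slope equals the IVW estimate
  w5 <- 1 / instr$se_y^2
  centered <- instr
  fit_e <- lm(beta_y ~ beta_x, data = instr, weights = w5)
  centered$beta_y <- instr$beta_y - coef(fit_e)[1]
  eg0 <- mr_egger(centered)
  expect_equal(eg0$intercept, 0, tolerance = 1e-12)
  expect_equal(eg0$slope$log_or, ivw(centered)$log_or, tolerance = 1e-10)

  expect_error(mr_egger(instr[1:2, ]), "at least 3")
  same_x <- instrument_set(c("a", "b", "c"), rep(0.1, 3), rep(0.01, 3),
                           c(0.02, 0.03, 0.04), rep(0.01, 3))
  expect_error(mr_egger(same_x), "rank")
})

test_that("orientation harmonization flips exposure-negative instruments jointly", {
  instr <- instrument_set(c("a", "b"), c(-0.1, 0.2), c(0.01, 0.01),
                          c(0.05, 0.1), c(0.01, 0.02))
  h <- harmonize_orientation(instr)
  expect_equal(h$beta_x, c(0.1, 0.2))
  expect_equal(h$beta_y, c(-0.05, 0.1))
  expect_equal(ivw(h)$log_or, ivw(instr)$log_or, tolerance = 1e-14)
})

test_that("standard errors reconstructed from printed CIs round-trip", {
  expect_lt(abs(se_from_ci(1.36, 1.28, 1.45) - 0.0318), 2e-4)
  expect_lt(abs(se_from_ci(1.25, 1.20, 1.31) - 0.0224), 2e-4)
  # a log-symmetric CI round-trips exactly
  ci <- exp(log(1.3) + c(-1, 1) * 1.96 * 0.05)
  expect_equal(se_from_ci(1.3, ci[1], ci[2]), 0.05, tolerance = 1e-12)
  expect_equal(round(exp(log(1.3) + c(-1, 1) * 1.96 *
                           se_from_ci(1.3, ci[1], ci[2])), 3),
               round(ci, 3))
  expect_error(se_from_ci(1.2, 1.3, 1.4), "ci_low")
})

test_that("difference-of-odds-ratios test behaves and reproduces the published comparison", {
  a <- mr_estimate_from_or(1.36, 1.28, 1.45)
  b <- mr_estimate_from_or(1.25, 1.20, 1.31)
  expect_equal(or_difference_test(a, a), list(z = 0, p = 1))
  d <- or_difference_test(a, b)
  d_rev <- or_difference_test(b, a)
  expect_equal(d_rev$z, -d$z)
  expect_equal(d_rev$p, d$p)
  # overweight vs obese: printed p = 0.03
  expect_equal(round(d$p, 2), 0.03)
})

test_that("study-scale IVW recovers the simulated effect", {
  rec <- recovery_results()
  # nominal coverage of the conditional causal log-OR
  expect_gte(sum(rec$covered), 90)
  # the mean estimate matches the analytic marginal estimand: with a
  # logistic outcome model the IVW estimand is the marginal log-OR, which
  # sits slightly below the conditional parameter (non-collapsibility)
  theta_star <- marginal_estimand_oracle(
    simulation_config(n_individuals = 50000, seed = 1))
  expect_lt(abs(mean(rec$log_or) - theta_star), 0.02)
  expect_lt(theta_star, rec$theta)  # attenuation direction
})
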