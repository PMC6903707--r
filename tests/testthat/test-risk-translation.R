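test_that("risk calculators reproduce the published worked examples", {
  # 2.5 kg/m2 at OR 1.30 -> ~48% relative reduction
  expect_equal(round(100 * relative_risk_reduction(1.30, 2.5)), 48)
  expect_equal(relative_risk_reduction(1.36, 0), 0)

  d <- 2.3 / 1.7^2
  expect_equal(round_half_away(100 * relative_risk_reduction(1.36, d)), 22)
  expect_equal(round_half_away(100 * relative_risk_reduction(1.25, d)), 16)

  # prevalence after a 1-unit BMI reduction (P / beta)
  expect_equal(sprintf("%.1f", 100 * prevalence_after(0.052, 1.36, 1)),
               "3.8")
  expect_equal(sprintf("%.1f", 100 * prevalence_after(0.124, 1.25, 1)),
               "9.9")
  expect_equal(sprintf("%.1f", 100 * prevalence_after(0.024, 1.31, 1)),
               "1.8")
  expect_equal(prevalence_after(0.1, 1.0, 7), 0.1)

  # absolute reductions (P - P / beta)
  expect_equal(sprintf("%.1f", 100 * absolute_risk_reduction(0.124, 1.25, 1)),
               "2.5")
  expect_equal(sprintf("%.1f", 100 * absolute_risk_reduction(0.052, 1.36, 1)),
               "1.4")
  expect_equal(sprintf("%.1f", 100 * absolute_risk_reduction(0.024, 1.31, 1)),
               "0.6")
})

test_that("weight-needed inverses match the published table cells and rendering", {
  # obese, 50% relative: 8.98 kg -> 20 lbs / 9 kg
  w <- weight_for_relative_reduction(1.25, 0.5, 1.7)
  expect_equal(w$kg, 8.977, tolerance = 1e-3)
  r <- render_weight(w$kg)
  expect_equal(r$lbs, 20)
  expect_equal(r$kg, 9)

  # overweight, 25% relative: 2.70 kg -> 6 lbs / 3 kg
  w2 <- weight_for_relative_reduction(1.36, 0.25, 1.7)
  expect_equal(w2$kg, 2.704, tolerance = 1e-3)
  r2 <- render_weight(w2$kg)
  expect_equal(r2$lbs, 6)
  expect_equal(r2$kg, 3)

  # the kg display derives from the rounded pounds: 6.51 kg prints
  # 14 lbs / 6 kg (direct kg rounding would print 7)
  w50 <- weight_for_relative_reduction(1.36, 0.5, 1.7)
  r50 <- render_weight(w50$kg)
  expect_equal(r50$lbs, 14)
  expect_equal(r50$kg, 6)
  expect_equal(round_half_away(w50$kg), 7)

  # obese absolute rows of the weight table
  wa1 <- weight_for_absolute_reduction(0.124, 1.25, 0.01, 1.7)
  expect_equal(render_weight(wa1$kg)$lbs, 2)
  expect_equal(render_weight(wa1$kg)$kg, 1)
  wa2 <- weight_for_absolute_reduction(0.124, 1.25, 0.02, 1.7)
  expect_equal(render_weight(wa2$kg)$lbs, 5)
  expect_equal(render_weight(wa2$kg)$kg, 2)

  expect_error(weight_for_relative_reduction(0.9, 0.5, 1.7), "odds ratio")
  expect_error(weight_for_absolute_reduction(0.05, 1.3, 0.06, 1.7),
               "below zero")
})

test_that("forward and inverse calculators are exact inverses over a parameter grid", {
  for (beta in c(1.01, 1.1, 1.3, 1.7, 2)) {
    for (delta in c(0.1, 0.5, 1, 2.6, 5)) {
      for (P in c(0.005, 0.05, 0.12, 0.3)) {
        rrr <- relative_risk_reduction(beta, delta)
        w <- weight_for_relative_reduction(beta, rrr, 1.7)
        expect_equal(w$delta_bmi, delta, tolerance = 1e-12)
        expect_equal(relative_risk_reduction(beta, w$kg / 1.7^2), rrr,
                     tolerance = 1e-12)
        arr <- absolute_risk_reduction(P, beta, delta)
        wa <- weight_for_absolute_reduction(P, beta, arr, 1.7)
        expect_equal(wa$delta_bmi, delta, tolerance = 1e-12)
        # algebraic identity: absolute = P * relative
        expect_equal(arr, P * rrr, tolerance = 1e-12)
        # survival-factor multiplicativity
        r1 <- relative_risk_reduction(beta, delta / 3)
        r2 <- relative_risk_reduction(beta, 2 * delta / 3)
        expect_equal(1 - (1 - r1) * (1 - r2), rrr, tolerance = 1e-12)
      }
    }
  }
})

test_that("risk measures are strictly monotone in their arguments", {
  betas <- seq(1.05, 2, length.out = 8)
  deltas <- seq(0.2, 5, length.out = 8)
  expect_true(all(diff(relative_risk_reduction(betas, 1.5)) > 0))
  expect_true(all(diff(vapply(deltas, relative_risk_reduction,
                              0, or_per_unit = 1.3)) > 0))
  Ps <- seq(0.01, 0.3, length.out = 8)
  expect_true(all(diff(vapply(Ps, absolute_risk_reduction, 0,
                              or_per_unit = 1.3, delta_bmi = 1)) > 0))
  expect_true(all(diff(vapply(betas, function(b)
    absolute_risk_reduction(0.1, b, 1), 0)) > 0))
})

test_that("CI propagation brackets the point estimate and reproduces printed intervals", {
  d <- 2.3 / 1.7^2
  ci <- propagate_ci(relative_risk_reduction, c(1.28, 1.45), delta_bmi = d)
  point <- relative_risk_reduction(1.36, d)
  expect_true(ci[1] <= point && point <= ci[2])
  # the bounds are the operation evaluated at the OR bounds
  expect_equal(ci, c(relative_risk_reduction(1.28, d),
                     relative_risk_reduction(1.45, d)), tolerance = 1e-12)

  # prevalence-after and absolute-reduction intervals of the summary table
  ci_after <- propagate_ci(prevalence_after, c(1.28, 1.45),
                           baseline_prevalence = 0.052, delta_bmi = 1)
  expect_equal(sprintf("%.1f", 100 * ci_after), c("3.6", "4.1"))
  ci_abs <- propagate_ci(absolute_risk_reduction, c(1.11, 1.53),
                         baseline_prevalence = 0.024, delta_bmi = 1)
  expect_equal(sprintf("%.1f", 100 * ci_abs), c("0.2", "0.8"))

  # weight-needed bounds invert (weaker OR -> more weight) but come back
  # ordered
  wci <- propagate_ci(weight_for_relative_reduction, c(1.20, 1.31),
                      target = 0.25, height_m = 1.7)
  expect_true(wci$kg[1] < wci$kg[2])
  expect_equal(render_weight(wci$kg[1])$lbs, 7)
  expect_equal(render_weight(wci$kg[2])$lbs, 10)

  # degenerate CI collapses to the point value
  degen <- propagate_ci(relative_risk_reduction, c(1.3, 1.3),
                        delta_bmi = 1)
  expect_equal(degen[1], degen[2])
  expect_equal(degen[1], relative_risk_reduction(1.3, 1))
})

test_that("the translation table builder renders published-style rows", {
  ests <- list(
    overweight = list(or = 1.36, ci = c(1.28, 1.45), prevalence = 0.052),
    obese = list(or = 1.25, ci = c(1.20, 1.31), prevalence = 0.124))
  tabs <- risk_translation_tables(ests)
  t3 <- tabs$prevalence_reduction
  expect_equal(t3$prevalence_after_rendered[t3$category == "overweight"],
               "3.8% (3.6, 4.1)")
  expect_equal(t3$absolute_reduction_rendered[t3$category == "obese"],
               "2.5% (2.1, 2.9)")
  t4 <- tabs$risk_for_weight
  expect_equal(t4$relative_rendered[t4$category == "overweight" &
                                      t4$kg == 2.3], "22% (18, 26)")
  expect_equal(t4$relative_rendered[t4$category == "obese" &
                                      t4$kg == 2.3], "16% (14, 19)")
  t5 <- tabs$weight_for_risk
  expect_equal(t5$rendered[t5$category == "obese" &
                             t5$target == "25%, relative"],
               "8 lbs (7, 10)/4 kg (3, 5)")
  expect_equal(t5$rendered[t5$category == "obese" &
                             t5$target == "1%, absolute"],
               "2 lbs (2, 3)/1 kg (1, 1)")
})
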