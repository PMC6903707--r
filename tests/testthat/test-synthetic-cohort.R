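test_that("config validation rejects out-of-range parameters", {
  expect_error(simulation_config(n_individuals = 50, seed = 1), ">= 100")
  expect_error(simulation_config(n_individuals = 1000, seed = 1,
                                 target_prevalence = 1.2), "fraction")
  expect_error(simulation_config(n_individuals = 1000, seed = 1,
                                 n_instruments = 3,
                                 instrument_freqs = c(0.2, 0.3, 0.7)),
               "0.01, 0.5")
  expect_error(simulation_config(n_individuals = 1000), "seed")
})

test_that("generated cohorts are bit-reproducible given the seed", {
  a <- generate_cohort(simulation_config(n_individuals = 800, seed = 42))
  b <- generate_cohort(simulation_config(n_individuals = 800, seed = 42))
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$genotypes$dosage, b$genotypes$dosage)
  expect_identical(a$instrument_weights, b$instrument_weights)
  c_ <- generate_cohort(simulation_config(n_individuals = 800, seed = 43))
  expect_false(identical(a$cohort$bmi, c_$cohort$bmi))
})

test_that("study-scale cohort matches its calibration targets", {
  sim <- default_sim()
  ch <- sim$cohort
  expect_equal(nrow(ch), 50000)
  # case prevalence 4.9% +- 0.5pp
  expect_lt(abs(mean(ch$t2d_case) - 0.049), 0.005)
  # instruments jointly explain r2 ~ 0.013 of BMI
  D <- sim$genotypes$dosage
  na_idx <- which(is.na(D), arr.ind = TRUE)
  D[na_idx] <- colMeans(D, na.rm = TRUE)[na_idx[, 2]]
  r2 <- summary(lm(ch$bmi ~ D))$r.squared
  expect_lt(abs(r2 - 0.013), 0.004)
  # PRS discriminates cases at AUC 0.66 +- 0.03
  expect_lt(abs(auc_rank(ch$prs, ch$t2d_case) - 0.66), 0.03)
  # ... but is nearly independent of the instruments (r2 <= 0.01)
  expect_lt(summary(lm(ch$prs ~ D))$r.squared, 0.01)
  # family-history prevalence ~16.8%
  expect_lt(abs(mean(ch$family_history) - 0.168), 0.01)
  # family history co-varies with genetic risk, as the stratified tables assume
  expect_gt(mean(ch$prs[ch$family_history]),
            mean(ch$prs[!ch$family_history]) + 0.1)
  # BMI category proportions near the study's 0.349 / 0.431 / 0.220
  props <- c(mean(ch$bmi < 25), mean(ch$bmi >= 25 & ch$bmi < 30),
             mean(ch$bmi >= 30))
  expect_lt(max(abs(props - c(0.349, 0.431, 0.220))), 0.03)
  # the designated bad variant carries ~15% missingness, the rest ~0.5%
  miss <- colMeans(is.na(sim$genotypes$dosage))
  expect_gt(miss[1], 0.10)
  expect_lt(max(miss[-1]), 0.05)
})

test_that("unreachable calibration targets raise a named error", {
  expect_error(
    generate_cohort(simulation_config(n_individuals = 2000, seed = 5,
                                      target_prs_auc = 0.99)),
    "PRS AUC")
})

test_that("exclusion filter removes QC failures, non-T2D labels, and high-HbA1c controls", {
  toy <- data.frame(
    id = sprintf("i%d", 1:6),
    bmi = rep(25, 6),
    t2d_case = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    family_history = FALSE,
    prs = 0, age = 50, sex = FALSE,
    genotyping_array = "axiom", assessment_center = "center1",
    hba1c = c(35, 35, 40, 45, 35, 38.9),
    metformin = FALSE, insulin = FALSE,
    qc_exclude = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    diabetes_type_label = c("unlikely", "t1_possible", "unlikely",
                            "t2d_probable", "unlikely", "unlikely"),
    stringsAsFactors = FALSE)
  out <- apply_exclusions(toy)
  # kept: row 4 (case, hba1c 45: threshold applies to controls only),
  # row 5 (clean control), row 6 (control at 38.9, just under the cut)
  expect_identical(out$id, c("i4", "i5", "i6"))
  expect_identical(attr(out, "exclusion_counts"),
                   list(qc = 1L, diabetes_type = 1L, hba1c = 1L))
  # idempotent
  again <- apply_exclusions(out)
  expect_identical(again$id, out$id)
  expect_identical(attr(again, "exclusion_counts"),
                   list(qc = 0L, diabetes_type = 0L, hba1c = 0L))
})

test_that("null causal effect yields IVW intervals covering zero", {
  hits <- vapply(1:100, function(s) {
    sim <- generate_cohort(simulation_config(
      n_individuals = 10000, seed = 1000 + s,
      causal_log_or_per_bmi_unit = 0))
    iv <- ivw_from_sim(sim)$est
    abs(iv$log_or) <= qnorm(0.975) * iv$se
  }, TRUE)
  expect_gte(sum(hits), 90)
})

test_that("rank-based AUC agrees with the ROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(99)
  score <- rnorm(300)
  case <- runif(300) < plogis(score - 2)
  ref <- as.numeric(pROC::auc(pROC::roc(case, score, quiet = TRUE)))
  expect_equal(auc_rank(score, case), ref, tolerance = 1e-10)
  expect_error(auc_rank(score, rep(TRUE, 300)), "both")
})
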