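# shared fixtures and memoized heavy simulations

.cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .cache)) {
    assign(name, force(expr), envir = .cache)
  }
  get(name, envir = .cache)
}

# the study-scale reference cohort (default calibration, seed 1)
default_sim <- function() {
  cached("default_sim",
         generate_cohort(simulation_config(n_individuals = 50000, seed = 1)))
}

# a small genotype matrix with known dosages
toy_genotypes <- function(dosage, alleles = NULL) {
  if (is.null(colnames(dosage))) {
    colnames(dosage) <- sprintf("rs%d", seq_len(ncol(dosage)))
  }
  genotype_matrix(dosage, alleles)
}

random_genotypes <- function(n, J, freqs = runif(J, 0.1, 0.5),
                             prefix = "rs") {
  d <- matrix(rbinom(n * J, 2L, rep(freqs, each = n)), n, J,
              dimnames = list(NULL, sprintf("%s%d", prefix, seq_len(J))))
  genotype_matrix(d)
}

# Independent HWE mid-p oracle: brute-force enumeration of every
# heterozygote configuration using direct factorial arithmetic (a
# different code path from the package's log-space implementation).
hwe_midp_oracle <- function(aa, ab, bb) {
  n <- aa + ab + bb
  n_a <- 2 * aa + ab
  n_b <- 2 * bb + ab
  if (min(n_a, n_b) == 0) return(1)
  hets <- seq(n_a %% 2, min(n_a, n_b), by = 2)
  probs <- vapply(hets, function(h) {
    exp(lgamma(n + 1) - lgamma((n_a - h) / 2 + 1) - lgamma(h + 1) -
          lgamma((n_b - h) / 2 + 1) + h * log(2) +
          lgamma(n_a + 1) + lgamma(n_b + 1) - lgamma(2 * n + 1))
  }, 0)
  probs <- probs / sum(probs)
  obs <- probs[hets == ab]
  sum(probs[probs < obs * (1 - 1e-12)]) +
    0.5 * sum(probs[abs(probs - obs) <= obs * 1e-12])
}

# Analytic oracle for the marginal (population) log-OR per dosage that the
# IVW estimator targets under the generator's default model: integrates the
# logistic risk over the normal distribution of the non-genotype terms, then
# fits the 2-parameter logistic curve to the three genotype risk levels.
# Independent of the package's scan/estimator code.
marginal_estimand_oracle <- function(cfg) {
  theta <- cfg$causal_log_or_per_bmi_unit
  lam <- cfg$liability_effect
  cross <- 2 * theta * lam * cfg$family_effect_bmi * 0.5 +
    2 * theta * cfg$confounder_effect_logit * cfg$confounder_effect_bmi
  sb2 <- cfg$bmi_sd^2
  v_eta <- theta^2 * sb2 + lam^2 + cfg$confounder_effect_logit^2 + cross
  e_prev <- function(a, m, s2) {
    integrate(function(z) plogis(a + m + sqrt(s2) * z) * dnorm(z),
              -9, 9, rel.tol = 1e-10)$value
  }
  lo <- -30; hi <- 10
  for (i in 1:200) {
    a0 <- (lo + hi) / 2
    if (e_prev(a0, 0, v_eta) > cfg$target_prevalence) hi <- a0 else lo <- a0
  }
  set.seed(cfg$seed)
  f <- runif(cfg$n_instruments, 0.05, 0.5)
  b0 <- 1 / sqrt(2 * f * (1 - f))
  b <- b0 * sqrt(cfg$target_instrument_r2 * sb2 / sum(b0^2 * 2 * f * (1 - f)))
  star <- vapply(seq_along(f), function(j) {
    s2 <- theta^2 * (sb2 - b[j]^2 * 2 * f[j] * (1 - f[j])) + lam^2 +
      cfg$confounder_effect_logit^2 + cross
    k <- 0:2
    m <- theta * b[j] * (k - 2 * f[j])
    pk <- vapply(m, function(mm) e_prev(a0, mm, s2), 0)
    wk <- c((1 - f[j])^2, 2 * f[j] * (1 - f[j]), f[j]^2)
    fit <- suppressWarnings(glm(pk ~ k, family = quasibinomial,
                                weights = wk))
    unname(coef(fit)[2]) / b[j]
  }, 0)
  weighted.mean(star, b^2 * 2 * f * (1 - f))
}

# IVW estimate from a simulated cohort via the package's scans (no
# covariates; full-cohort exposure scan: the operation is subset-agnostic)
ivw_from_sim <- function(sim) {
  exp_scan <- linear_assoc(sim$genotypes, sim$cohort$bmi)
  out_scan <- logistic_assoc(sim$genotypes, sim$cohort$t2d_case)
  ok <- !exp_scan$failed & !out_scan$failed
  instr <- harmonize_orientation(instrument_set(
    exp_scan$variant_id[ok], exp_scan$beta[ok], exp_scan$se[ok],
    out_scan$beta[ok], out_scan$se[ok]))
  list(est = ivw(instr), exp_scan = exp_scan, n_ok = sum(ok))
}

# 100-seed study-scale recovery + nonlinear-MR calibration run, shared by
# the estimator-recovery properties and the acceptance suite
recovery_results <- function(n_seeds = 100L, n = 50000L) {
  cached("recovery", {
    theta <- log(1.3)
    res <- lapply(seq_len(n_seeds), function(s) {
      sim <- generate_cohort(simulation_config(n_individuals = n, seed = s))
      iv <- ivw_from_sim(sim)
      truth <- sim$instrument_weights$beta[
        match(iv$exp_scan$variant_id, sim$instrument_weights$variant_id)]
      within3 <- abs(iv$exp_scan$beta - truth) <= 3 * iv$exp_scan$se
      score <- allele_score(sim$genotypes, sim$instrument_weights)
      qmr <- quantile_mr(sim$cohort$bmi, sim$cohort$t2d_case, score,
                         n_quantiles = 50L)
      list(log_or = iv$est$log_or, se = iv$est$se,
           covered = abs(iv$est$log_or - theta) <= qnorm(0.975) * iv$est$se,
           frac_beta_within3 = mean(within3, na.rm = TRUE),
           q_p_lace = qmr$q_p_lace,
           trend_p_score_bmi = qmr$trend_p_score_bmi)
    })
    list(theta = theta,
         log_or = vapply(res, `[[`, 0, "log_or"),
         se = vapply(res, `[[`, 0, "se"),
         covered = vapply(res, `[[`, TRUE, "covered"),
         frac_beta_within3 = vapply(res, `[[`, 0, "frac_beta_within3"),
         q_p_lace = vapply(res, `[[`, 0, "q_p_lace"),
         trend_p_score_bmi = vapply(res, `[[`, 0, "trend_p_score_bmi"))
  })
}
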