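#' The 57 BMI instrument variants
#'
#' rsIDs of the 57 genome-wide-significant BMI-associated polymorphisms
#' (selected from an external GWAS and curated for MR use) that pass the
#' standard instrument quality-control thresholds (missingness < 10%,
#' Hardy-Weinberg mid-p > 1e-20). `rs9581854` is the instrument that is
#' conventionally absent from the smoking-adjusted BMI weight file and is
#' therefore dropped when building the weighted allele score.
#'
#' @format Character vector of length 57.
#' @export
bmi_instrument_rsids <- c(
  "rs7899106", "rs17094222", "rs11191560", "rs4256980", "rs2176598",
  "rs3817334", "rs12286929", "rs7138803", "rs11057405", "rs9581854",
  "rs12429545", "rs10132280", "rs12885454", "rs7141420", "rs3736485",
  "rs758747", "rs12446632", "rs2650492", "rs1558902", "rs1000940",
  "rs12940622", "rs1808579", "rs7243357", "rs6567160", "rs17724992",
  "rs29941", "rs2287019", "rs657452", "rs3101336", "rs17024393",
  "rs543874", "rs2820292", "rs13021737", "rs11126666", "rs1016287",
  "rs11688816", "rs2121279", "rs1528435", "rs7599312", "rs6804842",
  "rs3849570", "rs13078960", "rs16851483", "rs1516725", "rs10938397",
  "rs11727676", "rs2112347", "rs2207139", "rs13191362", "rs1167827",
  "rs17405819", "rs2033732", "rs4740619", "rs10968576", "rs6477694",
  "rs1928295", "rs10733682")

#' Simulation configuration
#'
#' Parameters of the synthetic cohort generator. Defaults reproduce the
#' statistical structure of the UK-Biobank-style study cohort the analysis
#' targets: ~4.9% type 2 diabetes prevalence, 57 independent instruments
#' jointly explaining r-squared ~0.013 of BMI, a diabetes polygenic risk
#' score (PRS) with AUC ~0.66 for case status and only ~0.003 r-squared
#' with the instruments, ~16.8% family-history prevalence, and BMI category
#' proportions (non-overweight / overweight / obese) near 0.35/0.43/0.22.
#'
#' @param n_individuals cohort size (>= 100).
#' @param n_instruments number of instrument variants (default 57; when 57,
#'   variants are named with [bmi_instrument_rsids]).
#' @param instrument_freqs effect-allele frequencies, strictly inside
#'   (0.01, 0.5); default: drawn uniformly on (0.05, 0.5) from the seed.
#' @param target_instrument_r2 joint BMI variance fraction explained by the
#'   instruments (default 0.013).
#' @param causal_log_or_per_bmi_unit causal log odds ratio of diabetes per
#'   1 kg/m2 of BMI on the conditional (logit) scale; default `log(1.3)`.
#' @param target_prevalence diabetes case fraction (default 0.049).
#' @param target_prs_auc AUC of the PRS for case status (default 0.66),
#'   calibrated by bisection on the PRS noise share (tolerance 0.01).
#' @param fh_heritable_share share of each relative's diabetes liability
#'   variance that is genetic (default 0.5).
#' @param fh_prevalence fraction of individuals with a family history of
#'   diabetes (default 0.168).
#' @param confounder_effect_bmi,confounder_effect_logit effect of a shared
#'   standard-normal confounder on BMI (kg/m2 per SD, default 1) and on the
#'   diabetes logit (default 0.3).
#' @param liability_effect loading of the genetic diabetes liability in the
#'   case model logit (default 0.85; bounds the maximal achievable PRS AUC,
#'   ~0.72 at default).
#' @param prs_instrument_r2 variance fraction of the PRS explained by the
#'   BMI instruments (default 0.003).
#' @param family_effect_bmi BMI loading (kg/m2 per SD) on the mid-parent
#'   genetic liability, inducing the family-history/BMI correlation
#'   (default 0.5).
#' @param bmi_mean,bmi_sd BMI distribution moments (defaults 26.7 and 4.3
#'   kg/m2, matching the cohort's BMI category proportions).
#' @param n_pcs number of genotype principal components to emit (default 10).
#' @param non_t2d_label_rate fraction of rows relabelled as possible type 1
#'   or gestational diabetes, to exercise the exclusion filter (default 0.01).
#' @param qc_exclude_rate fraction of rows flagged for sample-QC exclusion
#'   (default 0.005).
#' @param elevated_hba1c_rate fraction of controls given HbA1c >= 39
#'   mmol/mol (undiagnosed hyperglycemia; default 0.02).
#' @param missing_rate per-variant genotype missingness (default 0.005).
#' @param bad_variant_missing_rate missingness of one designated low-quality
#'   variant (default 0.15, so the missingness QC filter has something to
#'   catch).
#' @param bad_variant index of the designated low-quality variant
#'   (default 1).
#' @param seed integer seed; mandatory. The generator is bit-reproducible
#'   given the seed.
#' @return A validated list of class `simulation_config`.
#' @seealso [generate_cohort()]
#' @export
simulation_config <- function(n_individuals,
                              n_instruments = 57L,
                              instrument_freqs = NULL,
                              target_instrument_r2 = 0.013,
                              causal_log_or_per_bmi_unit = log(1.3),
                              target_prevalence = 0.049,
                              target_prs_auc = 0.66,
                              fh_heritable_share = 0.5,
                              fh_prevalence = 0.168,
                              confounder_effect_bmi = 1,
                              confounder_effect_logit = 0.3,
                              liability_effect = 0.85,
                              prs_instrument_r2 = 0.003,
                              family_effect_bmi = 0.5,
                              bmi_mean = 26.7,
                              bmi_sd = 4.3,
                              n_pcs = 10L,
                              non_t2d_label_rate = 0.01,
                              qc_exclude_rate = 0.005,
                              elevated_hba1c_rate = 0.02,
                              missing_rate = 0.005,
                              bad_variant_missing_rate = 0.15,
                              bad_variant = 1L,
                              seed) {
  if (missing(seed)) stop("`seed` is mandatory")
  stopifnot(is.numeric(seed), length(seed) == 1L, seed == round(seed))
  assert_scalar(n_individuals, "n_individuals")
  if (n_individuals < 100) stop("`n_individuals` must be >= 100")
  stopifnot(n_instruments >= 1)
  if (!is.null(instrument_freqs)) {
    stopifnot(length(instrument_freqs) == n_instruments)
    if (any(instrument_freqs <= 0.01 | instrument_freqs >= 0.5)) {
      stop("`instrument_freqs` must lie strictly inside (0.01, 0.5)")
    }
  }
  for (nm in c("target_instrument_r2", "target_prevalence", "target_prs_auc",
               "fh_heritable_share", "fh_prevalence", "prs_instrument_r2",
               "non_t2d_label_rate", "qc_exclude_rate",
               "elevated_hba1c_rate")) {
    assert_fraction(get(nm), nm)
  }
  assert_fraction(missing_rate, "missing_rate", open = FALSE)
  assert_fraction(bad_variant_missing_rate, "bad_variant_missing_rate",
                  open = FALSE)
  stopifnot(bmi_sd > 0, bmi_mean > 10, bmi_mean < 80,
            bad_variant >= 1, bad_variant <= n_instruments)
  cfg <- list(
    n_individuals = as.integer(n_individuals),
    n_instruments = as.integer(n_instruments),
    instrument_freqs = instrument_freqs,
    target_instrument_r2 = target_instrument_r2,
    causal_log_or_per_bmi_unit = causal_log_or_per_bmi_unit,
    target_prevalence = target_prevalence,
    target_prs_auc = target_prs_auc,
    fh_heritable_share = fh_heritable_share,
    fh_prevalence = fh_prevalence,
    confounder_effect_bmi = confounder_effect_bmi,
    confounder_effect_logit = confounder_effect_logit,
    liability_effect = liability_effect,
    prs_instrument_r2 = prs_instrument_r2,
    family_effect_bmi = family_effect_bmi,
    bmi_mean = bmi_mean, bmi_sd = bmi_sd,
    n_pcs = as.integer(n_pcs),
    non_t2d_label_rate = non_t2d_label_rate,
    qc_exclude_rate = qc_exclude_rate,
    elevated_hba1c_rate = elevated_hba1c_rate,
    missing_rate = missing_rate,
    bad_variant_missing_rate = bad_variant_missing_rate,
    bad_variant = as.integer(bad_variant),
    seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  cfg
}

diabetes_type_levels <- c("t2d_probable", "t2d_possible", "t1_possible",
                          "gestational_possible", "unlikely")

#' Generate a synthetic cohort, genotypes, and instrument weights
#'
#' Simulates a biobank-style cohort with the statistical structure the
#' stratified MR analysis assumes. Instrument genotypes are drawn
#' per-variant as binomial(2, f) under Hardy-Weinberg equilibrium; BMI is
#' the sum of an instrument component (scaled so the instruments' joint
#' in-sample r-squared matches `target_instrument_r2`), a confounder
#' effect, a familial (mid-parent genetic liability) component, and normal
#' noise. Case status is drawn from a logistic model in BMI, the genetic
#' diabetes liability, and the confounder, with the intercept calibrated by
#' bisection to the target prevalence (tolerance 0.002). The PRS is the
#' genetic liability plus noise, calibrated by bisection to the target AUC
#' (tolerance 0.01), with a small instrument component
#' (`prs_instrument_r2`). Family history is derived mechanistically from
#' two parents and a sibling whose liabilities share half the proband's
#' genetic component, thresholded at the prevalence-matched quantile.
#'
#' Output is bit-reproducible given `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return A list of class `mr_cohort_sim` with elements:
#'   \describe{
#'     \item{cohort}{data.frame, one row per individual: `id`, `bmi`,
#'       `t2d_case`, `family_history`, `prs`, `age`, `sex`,
#'       `genotyping_array`, `assessment_center`, `pc1`..`pcK`, `hba1c`,
#'       `metformin`, `insulin`, `qc_exclude`, `diabetes_type_label`.}
#'     \item{genotypes}{a [genotype_matrix()] with injected missingness.}
#'     \item{instrument_weights}{data.frame `variant_id`, `effect_allele`,
#'       `beta` (the true per-dosage BMI effects used in simulation).}
#'   }
#' @export
#' @examples
#' sim <- generate_cohort(simulation_config(n_individuals = 500, seed = 1))
#' mean(sim$cohort$t2d_case)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  n <- cfg$n_individuals
  J <- cfg$n_instruments
  set.seed(cfg$seed)

  f <- cfg$instrument_freqs %||% runif(J, 0.05, 0.5)
  ids <- if (J == 57L) bmi_instrument_rsids else sprintf("var%04d", seq_len(J))
  effect_allele <- sample(c("A", "C", "G", "T"), J, replace = TRUE)
  G <- matrix(rbinom(n * J, 2L, rep(f, each = n)), n, J,
              dimnames = list(NULL, ids))

  # instrument effects: beta_j ~ 1/sqrt(2 f (1-f)), rescaled so the joint
  # in-sample genetic variance is target_r2 * bmi variance
  beta0 <- 1 / sqrt(2 * f * (1 - f))
  gv0 <- drop(G %*% beta0)
  v0 <- var(gv0)
  if (v0 <= 0) stop("calibration failure: degenerate instrument genotypes ",
                    "(target: instrument r2)")
  beta <- beta0 * sqrt(cfg$target_instrument_r2 * cfg$bmi_sd^2 / v0)
  gv <- drop(G %*% beta)
  gv <- gv - mean(gv)

  U <- rnorm(n)
  father <- rnorm(n)
  mother <- rnorm(n)
  midparent <- (father + mother) / 2
  child_g <- midparent + sqrt(0.5) * rnorm(n)
  sibling <- midparent + sqrt(0.5) * rnorm(n)

  resid_var <- cfg$bmi_sd^2 * (1 - cfg$target_instrument_r2) -
    cfg$confounder_effect_bmi^2 - cfg$family_effect_bmi^2 * 0.5
  if (resid_var <= 0) {
    stop("BMI variance components exceed bmi_sd^2; reduce confounder or ",
         "family effects")
  }
  bmi <- cfg$bmi_mean + gv + cfg$confounder_effect_bmi * U +
    cfg$family_effect_bmi * midparent + rnorm(n, 0, sqrt(resid_var))
  bmi <- pmin(pmax(bmi, 10.01), 79.99)  # truncate to the plausible range

  theta <- cfg$causal_log_or_per_bmi_unit
  eta <- theta * (bmi - cfg$bmi_mean) + cfg$liability_effect * child_g +
    cfg$confounder_effect_logit * U
  alpha0 <- calibrate_bisection(
    function(a) mean(plogis(a + eta)),
    target = cfg$target_prevalence, lower = -30, upper = 10,
    tol = 0.002, label = "case prevalence")
  t2d_case <- runif(n) < plogis(alpha0 + eta)
  if (!any(t2d_case) || all(t2d_case)) {
    stop("calibration failure: degenerate case status ",
         "(target: case prevalence)")
  }

  # PRS: genetic liability + small instrument component + noise. The
  # liability share is found by bisection on the AUC for case status over a
  # held-out population-scale draw from the same model, so the calibration
  # does not depend on the cohort's sampling noise (important for small n).
  c_instr <- sqrt(cfg$prs_instrument_r2)
  z_g <- (gv - mean(gv)) / sd(gv)
  eps <- rnorm(n)
  n_cal <- max(n, 20000L)
  mid_cal <- rnorm(n_cal, 0, sqrt(0.5))
  child_cal <- mid_cal + sqrt(0.5) * rnorm(n_cal)
  u_cal <- rnorm(n_cal)
  bmi_c_cal <- rnorm(n_cal, 0, sqrt(cfg$target_instrument_r2) * cfg$bmi_sd) +
    cfg$confounder_effect_bmi * u_cal + cfg$family_effect_bmi * mid_cal +
    rnorm(n_cal, 0, sqrt(resid_var))
  eta_cal <- theta * bmi_c_cal + cfg$liability_effect * child_cal +
    cfg$confounder_effect_logit * u_cal
  case_cal <- runif(n_cal) < plogis(alpha0 + eta_cal)
  zg_cal <- rnorm(n_cal)
  eps_cal <- rnorm(n_cal)
  rho <- calibrate_bisection(
    function(rho) {
      auc_rank(rho * child_cal + c_instr * zg_cal +
                 sqrt(1 - rho^2 - c_instr^2) * eps_cal, case_cal)
    },
    target = cfg$target_prs_auc, lower = 0.01,
    upper = sqrt(1 - c_instr^2) - 1e-9,
    tol = 0.01, label = "PRS AUC")
  prs <- as.vector(scale(
    rho * child_g + c_instr * z_g + sqrt(1 - rho^2 - c_instr^2) * eps))

  # family history: any of father/mother/sibling affected; relatives'
  # liabilities share half the proband's genetic component, thresholded at
  # the prevalence-matched quantile of the per-individual maximum
  h <- sqrt(cfg$fh_heritable_share)
  e_sd <- sqrt(1 - cfg$fh_heritable_share)
  rel_liab <- cbind(h * father + e_sd * rnorm(n),
                    h * mother + e_sd * rnorm(n),
                    h * sibling + e_sd * rnorm(n))
  max_liab <- pmax(rel_liab[, 1], rel_liab[, 2], rel_liab[, 3])
  fh_threshold <- quantile(max_liab, 1 - cfg$fh_prevalence, names = FALSE,
                           type = 7)
  family_history <- max_liab > fh_threshold

  age <- floor(runif(n, 40, 70))
  sex <- runif(n) < 0.5
  genotyping_array <- sample(c("axiom", "bileve"), n, replace = TRUE,
                             prob = c(0.8, 0.2))
  assessment_center <- sample(sprintf("center%d", 1:3), n, replace = TRUE)
  pcs <- matrix(rnorm(n * cfg$n_pcs), n, cfg$n_pcs,
                dimnames = list(NULL, sprintf("pc%d", seq_len(cfg$n_pcs))))

  # HbA1c (mmol/mol): controls below the 39 screening threshold except an
  # `elevated_hba1c_rate` fraction with undiagnosed hyperglycemia
  hba1c <- ifelse(t2d_case,
                  pmax(rnorm(n, 53, 8), 39.5),
                  pmin(pmax(rnorm(n, 34.5, 2.5), 20), 38.5))
  elevated <- !t2d_case & runif(n) < cfg$elevated_hba1c_rate
  hba1c[elevated] <- pmax(rnorm(sum(elevated), 41, 1.5), 39)

  metformin <- t2d_case & runif(n) < 7923 / 13982
  insulin <- t2d_case & runif(n) < 2094 / 13982

  diabetes_type_label <- ifelse(
    t2d_case,
    ifelse(runif(n) < 0.8, "t2d_probable", "t2d_possible"),
    "unlikely")
  relabel <- runif(n) < cfg$non_t2d_label_rate
  diabetes_type_label[relabel] <- sample(
    c("t1_possible", "gestational_possible"), sum(relabel),
    replace = TRUE, prob = c(0.6, 0.4))
  t2d_case[relabel] <- FALSE
  metformin[relabel] <- FALSE
  insulin[relabel] <- FALSE

  qc_exclude <- runif(n) < cfg$qc_exclude_rate

  # inject genotype missingness (after phenotypes, which use the complete
  # matrix): a uniform per-variant rate plus one designated bad variant
  miss_rate <- rep(cfg$missing_rate, J)
  miss_rate[cfg$bad_variant] <- cfg$bad_variant_missing_rate
  miss <- matrix(runif(n * J), n, J) < rep(miss_rate, each = n)
  G[miss] <- NA_integer_

  cohort <- data.frame(
    id = sprintf("ind%06d", seq_len(n)),
    bmi = bmi,
    t2d_case = t2d_case,
    family_history = family_history,
    prs = prs,
    age = age,
    sex = sex,
    genotyping_array = genotyping_array,
    assessment_center = assessment_center,
    pcs,
    hba1c = hba1c,
    metformin = metformin,
    insulin = insulin,
    qc_exclude = qc_exclude,
    diabetes_type_label = factor(diabetes_type_label,
                                 levels = diabetes_type_levels),
    stringsAsFactors = FALSE)

  structure(list(
    cohort = cohort,
    genotypes = genotype_matrix(G, setNames(effect_allele, ids)),
    instrument_weights = data.frame(variant_id = ids,
                                    effect_allele = effect_allele,
                                    beta = beta,
                                    stringsAsFactors = FALSE),
    config = cfg,
    calibration = list(alpha0 = alpha0, prs_liability_share = rho,
                       fh_threshold = fh_threshold)),
    class = "mr_cohort_sim")
}

#' @export
print.mr_cohort_sim <- function(x, ...) {
  cat(sprintf(
    "synthetic MR cohort: n = %d, %d instruments, prevalence %.3f, seed %d\n",
    nrow(x$cohort), ncol(x$genotypes$dosage), mean(x$cohort$t2d_case),
    x$config$seed))
  invisible(x)
}

# monotone-objective bisection; errors after max_steps without meeting tol
calibrate_bisection <- function(fn, target, lower, upper, tol,
                                label, max_steps = 100L) {
  f_lo <- fn(lower)
  f_hi <- fn(upper)
  increasing <- f_hi >= f_lo
  if ((target - f_lo) * (target - f_hi) > 0 &&
      abs(f_lo - target) > tol && abs(f_hi - target) > tol) {
    stop(sprintf(
      "calibration failure: target %s = %g outside achievable range [%g, %g]",
      label, target, min(f_lo, f_hi), max(f_lo, f_hi)))
  }
  x <- NA_real_
  for (step in seq_len(max_steps)) {
    x <- (lower + upper) / 2
    fx <- fn(x)
    if (abs(fx - target) <= tol) return(x)
    if ((fx < target) == increasing) lower <- x else upper <- x
  }
  stop(sprintf(
    "calibration failure: bisection for %s did not converge in %d steps",
    label, max_steps))
}

#' Apply sample-level exclusion filters
#'
#' Removes individuals that the study design excludes: rows flagged by
#' sample QC, rows whose adjudicated diabetes type is possible type 1 or
#' gestational diabetes, and controls with HbA1c >= 39 mmol/mol
#' (indicative of undiagnosed diabetes or prediabetes; the threshold is
#' applied to controls only and is inclusive at 39).
#'
#' The operation is idempotent.
#'
#' @param cohort a cohort data.frame with columns `qc_exclude`,
#'   `diabetes_type_label`, `t2d_case`, `hba1c`.
#' @return The filtered cohort, with an attribute `exclusion_counts`: a
#'   named list `qc`, `diabetes_type`, `hba1c` of per-reason exclusion
#'   counts (reasons assessed in that order, each row counted once).
#' @export
#' @examples
#' sim <- generate_cohort(simulation_config(n_individuals = 500, seed = 1))
#' kept <- apply_exclusions(sim$cohort)
#' attr(kept, "exclusion_counts")
apply_exclusions <- function(cohort) {
  stopifnot(all(c("qc_exclude", "diabetes_type_label", "t2d_case",
                  "hba1c") %in% names(cohort)))
  qc <- cohort$qc_exclude
  type <- !qc & cohort$diabetes_type_label %in%
    c("t1_possible", "gestational_possible")
  hba1c <- !qc & !type & !cohort$t2d_case & cohort$hba1c >= 39
  keep <- !(qc | type | hba1c)
  out <- cohort[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) warning("all rows excluded; returning empty cohort")
  attr(out, "exclusion_counts") <- list(
    qc = sum(qc), diabetes_type = sum(type), hba1c = sum(hba1c))
  out
}
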