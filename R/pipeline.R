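#' Analysis configuration
#'
#' Settings for the end-to-end stratified MR analysis run by
#' [run_analysis()]. Exactly one input mode is used: `"simulate"` (a
#' [simulation_config()] describes the cohort) or `"files"` (paths to a
#' cohort TSV, a genotype TSV or VCF, and a weights TSV).
#'
#' @param mode `"simulate"` or `"files"`.
#' @param sim_config a [simulation_config()] (simulate mode).
#' @param cohort_file,genotype_file,weights_file input paths (files mode).
#' @param genotype_format `"tsv"` or `"vcf"` (files mode).
#' @param use_covariates adjust scans for the standard covariate set (age,
#'   sex, array, center, PCs); default `TRUE`.
#' @param n_pcs number of principal components among the covariates
#'   (default 10).
#' @param n_quantiles strata for nonlinear MR (default 50); set to `NULL`
#'   to skip the nonlinear stage (e.g. for small cohorts).
#' @param max_missing,min_hwe_midp instrument QC thresholds (defaults 0.1
#'   and 1e-20).
#' @param match_ratio,match_bins family-history matching parameters
#'   (defaults 4.5 and 10).
#' @param height_m height used in the risk-translation tables (default
#'   1.7 m).
#' @param output_dir directory for result files; created if absent. `NULL`
#'   keeps results in memory only.
#' @param seed integer seed governing every stochastic stage.
#' @return A validated list of class `analysis_config`.
#' @export
analysis_config <- function(mode = c("simulate", "files"),
                            sim_config = NULL,
                            cohort_file = NULL, genotype_file = NULL,
                            weights_file = NULL,
                            genotype_format = c("tsv", "vcf"),
                            use_covariates = TRUE,
                            n_pcs = 10L,
                            n_quantiles = 50L,
                            max_missing = 0.1,
                            min_hwe_midp = 1e-20,
                            match_ratio = 4.5,
                            match_bins = 10L,
                            height_m = 1.7,
                            output_dir = NULL,
                            seed) {
  mode <- match.arg(mode)
  genotype_format <- match.arg(genotype_format)
  if (missing(seed)) stop("`seed` is mandatory")
  if (mode == "simulate") {
    if (is.null(sim_config)) stop("simulate mode needs `sim_config`")
    if (!is.null(cohort_file) || !is.null(genotype_file)) {
      stop("exactly one input mode: file paths given in simulate mode")
    }
  } else {
    if (!is.null(sim_config)) {
      stop("exactly one input mode: `sim_config` given in files mode")
    }
    for (f in c(cohort_file, genotype_file, weights_file)) {
      if (!file.exists(f)) stop("input file not found: ", f)
    }
  }
  structure(list(
    mode = mode, sim_config = sim_config, cohort_file = cohort_file,
    genotype_file = genotype_file, weights_file = weights_file,
    genotype_format = genotype_format, use_covariates = use_covariates,
    n_pcs = as.integer(n_pcs),
    n_quantiles = if (!is.null(n_quantiles)) as.integer(n_quantiles),
    max_missing = max_missing, min_hwe_midp = min_hwe_midp,
    match_ratio = match_ratio, match_bins = as.integer(match_bins),
    height_m = height_m, output_dir = output_dir,
    seed = as.integer(seed)), class = "analysis_config")
}

#' Run the stratified MR analysis end to end
#'
#' Executes the full pipeline: obtain the cohort (simulate or load), apply
#' the exclusion filters, residualize BMI and the PRS on the instruments,
#' run instrument QC, assign strata (with decile-matched subsampling for
#' the family-history strata), and, for the full cohort and every stratum,
#' run the exposure scan on that stratum's controls, the outcome scan on
#' the stratum, and IVW + MR-Egger estimation. Nonlinear MR over quantiles
#' of the instrument-free exposure and the stratified prevalence and
#' risk-translation tables are computed on the analyzed cohort.
#'
#' Any stage failure aborts with the stage name; nothing is written unless
#' the whole run succeeds (so no partial outputs are left behind). Given
#' the same configuration and seed, every numeric output is reproduced
#' bit for bit.
#'
#' @param config an [analysis_config()].
#' @return (Invisibly) a list of class `mr_analysis` with elements
#'   `cohort` (analyzed rows), `exclusions`, `instrument_qc`,
#'   `mr_results` (data.frame: stratum, method, estimates, Q),
#'   `egger_intercepts`, `prevalence_tables`, `binned_prevalence`,
#'   `nonlinear`, `risk_tables`, `match_report`, `manifest`.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  inputs <- stage("input", pipeline_inputs(config))
  cohort <- inputs$cohort
  genotypes <- inputs$genotypes
  weights <- inputs$weights

  kept <- stage("exclusions", apply_exclusions(cohort))
  exclusions <- attr(kept, "exclusion_counts")
  keep_idx <- match(kept$id, cohort$id)
  genotypes$dosage <- genotypes$dosage[keep_idx, , drop = FALSE]
  cohort <- kept

  covars <- if (config$use_covariates) {
    covariate_matrix(cohort, config$n_pcs)
  }
  controls <- !cohort$t2d_case

  qc <- stage("instrument_qc", {
    scan <- linear_assoc(genotypes, cohort$bmi, covars)
    filter_instruments(scan, config$max_missing, config$min_hwe_midp)
  })
  instruments_pass <- as.character(qc)

  adj <- stage("collider_guard", {
    list(bmi = residualize(cohort$bmi, genotypes, instruments_pass),
         prs = residualize(cohort$prs, genotypes, instruments_pass))
  })
  labels <- stage("strata", assign_strata(cohort, adj$bmi, adj$prs))

  match <- stage("fh_matching", match_binary(
    cohort$family_history, genotypes, instruments_pass,
    ratio = config$match_ratio, n_bins = config$match_bins,
    seed = config$seed + 1L))

  strata <- pipeline_strata(cohort, labels, match$kept)

  mr_rows <- list()
  egger_rows <- list()
  for (nm in names(strata)) {
    idx <- strata[[nm]]
    res <- stage(paste0("mr/", nm), mr_for_subset(
      genotypes, cohort, covars, idx, instruments_pass))
    res$rows$stratum <- nm
    mr_rows[[nm]] <- res$rows
    if (!is.null(res$egger_intercept)) egger_rows[[nm]] <- res$egger_intercept
  }
  mr_results <- do.call(rbind, mr_rows)
  rownames(mr_results) <- NULL

  prev_tables <- stage("prevalence", list(
    overall = prevalence_table(cohort$t2d_case,
                               rep("overall", nrow(cohort)),
                               labels$bmi_cat),
    family_history = prevalence_table(
      cohort$t2d_case[match$kept],
      ifelse(cohort$family_history[match$kept], "fh_yes", "fh_no"),
      labels$bmi_cat[match$kept]),
    prs = prevalence_table(cohort$t2d_case, labels$prs_tertile,
                           labels$bmi_cat)))

  binned <- stage("binned_prevalence", {
    n_bins <- min(50L, max(1L, nrow(cohort) %/% 20L))
    binned_prevalence(adj$bmi, cohort$t2d_case,
                      ifelse(cohort$family_history, "fh_yes", "fh_no"),
                      n_bins = n_bins)
  })

  nonlinear <- NULL
  if (!is.null(config$n_quantiles) &&
      nrow(cohort) >= 20L * config$n_quantiles) {
    nonlinear <- stage("nonlinear_mr", {
      score <- suppressWarnings(allele_score(genotypes, weights))
      quantile_mr(cohort$bmi, cohort$t2d_case, score, covars,
                  config$n_quantiles)
    })
  }

  risk_tables <- stage("risk_translation", {
    ests <- list()
    for (cat in levels(labels$bmi_cat)) {
      row <- mr_results[mr_results$stratum == paste0("bmi_", cat) &
                          mr_results$method == "ivw", ]
      prev <- mean(cohort$t2d_case[labels$bmi_cat == cat])
      if (nrow(row) == 1L && is.finite(row$or) && row$ci_low > 0 &&
          is.finite(row$ci_high) && prev > 0) {
        ests[[cat]] <- list(or = row$or, ci = c(row$ci_low, row$ci_high),
                            prevalence = prev)
      }
    }
    if (length(ests)) {
      risk_translation_tables(ests, height_m = config$height_m)
    }
  })

  manifest <- list(
    package_version = as.character(packageVersion("mrstrat")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    mode = config$mode,
    n_input = length(keep_idx) + Reduce(`+`, exclusions),
    n_analyzed = nrow(cohort),
    exclusions = exclusions,
    n_instruments_pass = length(instruments_pass),
    instruments_rejected = attr(qc, "rejections"),
    config = config[setdiff(names(config), "sim_config")])

  bundle <- structure(list(
    cohort = cohort, exclusions = exclusions,
    instrument_qc = list(pass = instruments_pass,
                         rejections = attr(qc, "rejections")),
    mr_results = mr_results,
    egger_intercepts = egger_rows,
    prevalence_tables = prev_tables,
    binned_prevalence = binned,
    nonlinear = nonlinear,
    risk_tables = risk_tables,
    match_report = match$report,
    manifest = manifest), class = "mr_analysis")

  if (!is.null(config$output_dir)) {
    stage("write_outputs", write_analysis(bundle, config$output_dir))
  }
  invisible(bundle)
}

pipeline_inputs <- function(config) {
  if (config$mode == "simulate") {
    sim <- generate_cohort(config$sim_config)
    # the packaged weight convention: rs9581854 is absent from the
    # smoking-adjusted weight file, so the allele score drops it
    w <- sim$instrument_weights
    w <- w[w$variant_id != "rs9581854", , drop = FALSE]
    list(cohort = sim$cohort, genotypes = sim$genotypes, weights = w)
  } else {
    cohort <- read_cohort_tsv(config$cohort_file)
    genotypes <- if (config$genotype_format == "vcf") {
      read_genotypes_vcf(config$genotype_file)
    } else {
      read_genotypes_tsv(config$genotype_file)
    }
    gid <- attr(genotypes, "individual_ids")
    if (!is.null(gid)) {
      if (!all(cohort$id %in% gid)) {
        stop("genotype file does not cover all cohort individuals")
      }
      genotypes$dosage <- genotypes$dosage[match(cohort$id, gid), ,
                                           drop = FALSE]
    } else if (nrow(genotypes$dosage) != nrow(cohort)) {
      stop("genotype and cohort tables have different numbers of rows")
    }
    list(cohort = cohort, genotypes = genotypes,
         weights = read_weights_tsv(config$weights_file))
  }
}

pipeline_strata <- function(cohort, labels, fh_kept) {
  strata <- list(full_cohort = seq_len(nrow(cohort)))
  for (cat in levels(labels$bmi_cat)) {
    strata[[paste0("bmi_", cat)]] <- which(labels$bmi_cat == cat)
  }
  fh <- logical(nrow(cohort))
  fh[fh_kept] <- TRUE
  strata$fh_yes <- which(fh & cohort$family_history)
  strata$fh_no <- which(fh & !cohort$family_history)
  for (t in levels(labels$prs_tertile)) {
    strata[[paste0("prs_", t)]] <- which(labels$prs_tertile == t)
  }
  # medication strata: cases on exactly one drug, plus all controls
  strata$metformin_only <- which(labels$medication %in%
                                   c("metformin_only", "control"))
  strata$insulin_only <- which(labels$medication %in%
                                 c("insulin_only", "control"))
  strata
}

mr_for_subset <- function(genotypes, cohort, covars, idx, instrument_ids) {
  sub_geno <- genotypes
  sub_geno$dosage <- genotypes$dosage[idx, instrument_ids, drop = FALSE]
  sub_geno$effect_allele <- genotypes$effect_allele[instrument_ids]
  case <- cohort$t2d_case[idx]
  C <- if (!is.null(covars)) covars[idx, , drop = FALSE]
  na_row <- function(method, reason) data.frame(
    stratum = NA_character_, method = method, n = length(idx),
    n_cases = sum(case), n_instruments = NA_integer_, log_or = NA_real_,
    se = NA_real_, or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
    q_stat = NA_real_, q_p = NA_real_, note = reason,
    stringsAsFactors = FALSE)
  if (!any(case) || all(case)) {
    rows <- rbind(na_row("ivw", "single outcome class in stratum"),
                  na_row("egger", "single outcome class in stratum"))
    rows$stratum <- "unnamed"
    return(list(rows = rows, egger_intercept = NULL))
  }
  ctrl <- !case
  # drop constant covariate columns within the subset (e.g. a center with
  # no individuals here) to keep the design full rank
  prune <- function(M, rows) {
    if (is.null(M)) return(NULL)
    Ms <- M[rows, , drop = FALSE]
    keep <- apply(Ms, 2, function(col) max(col) > min(col))
    if (!any(keep)) NULL else Ms[, keep, drop = FALSE]
  }
  exp_scan <- linear_assoc(
    subset_genotypes(sub_geno, ctrl), cohort$bmi[idx][ctrl],
    prune(C, ctrl))
  out_scan <- logistic_assoc(sub_geno, case,
                             prune(C, seq_along(case)))
  ok <- !exp_scan$failed & !out_scan$failed & exp_scan$beta != 0 &
    exp_scan$se > 0 & out_scan$se > 0
  ok[is.na(ok)] <- FALSE
  if (!any(ok)) {
    rows <- rbind(na_row("ivw", "no usable instruments"),
                  na_row("egger", "no usable instruments"))
    rows$stratum <- "unnamed"
    return(list(rows = rows, egger_intercept = NULL))
  }
  instr <- harmonize_orientation(instrument_set(
    exp_scan$variant_id[ok], exp_scan$beta[ok], exp_scan$se[ok],
    out_scan$beta[ok], out_scan$se[ok]))
  est_ivw <- ivw(instr)
  row_of <- function(e, note = "") data.frame(
    stratum = "unnamed", method = e$method, n = length(idx),
    n_cases = sum(case), n_instruments = e$n_instruments,
    log_or = e$log_or, se = e$se, or = e$or, ci_low = e$ci95[1],
    ci_high = e$ci95[2], q_stat = e$q_stat, q_p = e$q_p, note = note,
    stringsAsFactors = FALSE)
  rows <- row_of(est_ivw)
  egger_int <- NULL
  if (nrow(instr) >= 3L) {
    est_egger <- mr_egger(instr)
    rows <- rbind(rows, row_of(est_egger$slope))
    egger_int <- list(intercept = est_egger$intercept,
                      intercept_se = est_egger$intercept_se,
                      intercept_p = est_egger$intercept_p)
  } else {
    rows <- rbind(rows, na_row("egger", "fewer than 3 instruments"))
  }
  list(rows = rows, egger_intercept = egger_int)
}

subset_genotypes <- function(genotypes, rows) {
  genotypes$dosage <- genotypes$dosage[rows, , drop = FALSE]
  genotypes
}

write_analysis <- function(bundle, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(output_dir, f)
  data.table::fwrite(bundle$mr_results, p("mr_results.tsv"), sep = "\t",
                     na = "NA", quote = FALSE)
  for (nm in names(bundle$prevalence_tables)) {
    data.table::fwrite(
      as.data.frame(bundle$prevalence_tables[[nm]]),
      p(sprintf("prevalence_%s.tsv", nm)), sep = "\t", na = "NA",
      quote = FALSE)
    writeLines(
      c(paste0("# ", nm),
        utils::capture.output(print(bundle$prevalence_tables[[nm]]))),
      p(sprintf("prevalence_%s.txt", nm)))
  }
  data.table::fwrite(bundle$binned_prevalence, p("binned_prevalence.tsv"),
                     sep = "\t", na = "NA", quote = FALSE)
  if (!is.null(bundle$nonlinear)) {
    data.table::fwrite(bundle$nonlinear$by_quantile,
                       p("nonlinear_quantiles.tsv"), sep = "\t", na = "NA",
                       quote = FALSE)
  }
  if (!is.null(bundle$risk_tables)) {
    data.table::fwrite(bundle$risk_tables$prevalence_reduction,
                       p("risk_prevalence_reduction.tsv"), sep = "\t",
                       na = "NA", quote = FALSE)
    data.table::fwrite(bundle$risk_tables$risk_for_weight,
                       p("risk_for_weight.tsv"), sep = "\t", na = "NA",
                       quote = FALSE)
    data.table::fwrite(bundle$risk_tables$weight_for_risk,
                       p("weight_for_risk.tsv"), sep = "\t", na = "NA",
                       quote = FALSE)
  }
  jsonlite::write_json(bundle$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(output_dir)
}

#' @export
print.mr_analysis <- function(x, ...) {
  cat(sprintf("stratified MR analysis: %d individuals analyzed, %d excluded\n",
              nrow(x$cohort), Reduce(`+`, x$exclusions)))
  cat(sprintf("instruments passing QC: %d\n",
              length(x$instrument_qc$pass)))
  ivw_rows <- x$mr_results[x$mr_results$method == "ivw", ]
  for (i in seq_len(nrow(ivw_rows))) {
    r <- ivw_rows[i, ]
    if (is.na(r$or)) {
      cat(sprintf("  %-22s IVW: NA (%s)\n", r$stratum, r$note))
    } else {
      cat(sprintf("  %-22s IVW OR %.3f (%.3f-%.3f), %d instruments\n",
                  r$stratum, r$or, r$ci_low, r$ci_high, r$n_instruments))
    }
  }
  invisible(x)
}
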