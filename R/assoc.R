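#' Per-variant association scans
#'
#' `linear_assoc()` regresses a quantitative phenotype on each variant's
#' dosage by ordinary least squares; `logistic_assoc()` fits a per-variant
#' maximum-likelihood logistic regression of case status on dosage. Both
#' adjust for an optional covariate matrix and use complete cases per
#' variant (rows missing that variant's dosage are dropped; mean imputation
#' is reserved for allele scores). The reported `beta`, `se`, `p` are the
#' dosage coefficient's; linear p-values use the t reference with residual
#' degrees of freedom, logistic p-values the Wald normal reference.
#'
#' Per-variant genotype QC statistics (missingness, exact Hardy-Weinberg
#' mid-p computed from dosages rounded to 0/1/2) are included so the output
#' feeds [filter_instruments()] directly.
#'
#' @param genotypes a [genotype_matrix()] (or a numeric dosage matrix with
#'   variant ids as column names).
#' @param phenotype numeric vector, one value per individual (no missing
#'   values).
#' @param case logical (or 0/1) case-status vector; both classes must be
#'   present.
#' @param covariates optional numeric covariate matrix (no missing values).
#'   An intercept is added internally; the augmented design must be full
#'   rank, otherwise an error names the collinear column.
#' @return A data.frame (one row per variant) with columns `variant_id`,
#'   `beta`, `se`, `p`, `n_used`, `missing_rate`, `hwe_midp`,
#'   `effect_allele`, `failed`. Variants whose fit fails (all dosages
#'   missing, perfect separation monitored via |beta| > 20, or
#'   non-convergence) carry `failed = TRUE` and `NA` estimates rather than
#'   aborting the scan.
#' @export
#' @examples
#' g <- genotype_matrix(cbind(rs1 = c(0, 0, 1, 1, 1, 2, 2, 2)))
#' linear_assoc(g, c(1, 2, 2, 3, 3, 4, 4, 5))
linear_assoc <- function(genotypes, phenotype, covariates = NULL) {
  scan_variants(genotypes, phenotype, covariates, family = "linear")
}

#' @rdname linear_assoc
#' @export
logistic_assoc <- function(genotypes, case, covariates = NULL) {
  case <- as.logical(case)
  if (length(unique(case)) < 2L) {
    stop("logistic_assoc() needs both cases and controls present")
  }
  scan_variants(genotypes, as.numeric(case), covariates, family = "logistic")
}

scan_variants <- function(genotypes, y, covariates, family) {
  if (!inherits(genotypes, "genotype_matrix")) {
    genotypes <- genotype_matrix(genotypes)
  }
  D <- genotypes$dosage
  n <- nrow(D)
  stopifnot(length(y) == n)
  if (anyNA(y)) stop("phenotype/case vector must have no missing values")
  C <- NULL
  if (!is.null(covariates)) {
    C <- as.matrix(covariates)
    stopifnot(nrow(C) == n)
    if (anyNA(C)) stop("covariates must have no missing values")
    if (is.null(colnames(C))) colnames(C) <- sprintf("cov%d", seq_len(ncol(C)))
    base <- cbind(`(intercept)` = 1, C)
    qrb <- qr(base)
    if (qrb$rank < ncol(base)) {
      dropped <- colnames(base)[qrb$pivot[-seq_len(qrb$rank)]]
      stop("covariate design is rank deficient; collinear column(s): ",
           paste(dropped, collapse = ", "))
    }
  }

  res <- lapply(seq_len(ncol(D)), function(j) {
    g <- D[, j]
    ok <- !is.na(g)
    miss <- 1 - mean(ok)
    hwe <- hwe_from_dosage(g[ok])
    if (!any(ok)) {
      return(list(beta = NA_real_, se = NA_real_, p = NA_real_,
                  n_used = 0L, missing_rate = miss, hwe_midp = hwe,
                  failed = TRUE))
    }
    X <- cbind(1, dosage = g[ok], if (!is.null(C)) C[ok, , drop = FALSE])
    fit <- tryCatch(
      fit_dosage(X, y[ok], family),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$beta) || abs(fit$beta) > 20) {
      return(list(beta = NA_real_, se = NA_real_, p = NA_real_,
                  n_used = sum(ok), missing_rate = miss, hwe_midp = hwe,
                  failed = TRUE))
    }
    c(fit, list(n_used = sum(ok), missing_rate = miss, hwe_midp = hwe,
                failed = FALSE))
  })

  out <- data.frame(
    variant_id = variant_ids(genotypes),
    beta = vapply(res, `[[`, 0, "beta"),
    se = vapply(res, `[[`, 0, "se"),
    p = vapply(res, `[[`, 0, "p"),
    n_used = vapply(res, `[[`, 0L, "n_used"),
    missing_rate = vapply(res, `[[`, 0, "missing_rate"),
    hwe_midp = vapply(res, `[[`, 0, "hwe_midp"),
    effect_allele = unname(genotypes$effect_allele),
    failed = vapply(res, `[[`, TRUE, "failed"),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

fit_dosage <- function(X, y, family) {
  p <- ncol(X)
  if (family == "linear") {
    fit <- lm.fit(X, y)
    if (fit$rank < p) stop("rank-deficient per-variant design")
    df <- length(y) - p
    XtXinv <- chol2inv(chol(crossprod(X)))
    s2 <- sum(fit$residuals^2) / max(df, 1L)
    se <- sqrt(s2 * XtXinv[2, 2])
    beta <- unname(fit$coefficients[2])
    pval <- if (df > 0 && se > 0) {
      2 * pt(-abs(beta / se), df)
    } else NA_real_
    list(beta = beta, se = se, p = pval)
  } else {
    fit <- suppressWarnings(glm.fit(
      X, y, family = binomial(),
      control = list(epsilon = 1e-10, maxit = 50L)))
    if (fit$rank < p) stop("rank-deficient per-variant design")
    beta <- unname(fit$coefficients[2])
    if (!fit$converged && abs(beta) <= 20) {
      stop("IRLS did not converge")
    }
    XtWXinv <- chol2inv(chol(crossprod(X * sqrt(fit$weights))))
    se <- sqrt(XtWXinv[2, 2])
    list(beta = beta, se = se, p = 2 * pnorm(-abs(beta / se)))
  }
}

hwe_from_dosage <- function(g) {
  if (!length(g)) return(1)
  k <- round(g)
  k[k < 0] <- 0
  k[k > 2] <- 2
  hwe_midp(sum(k == 0), sum(k == 1), sum(k == 2))
}

#' Instrument quality-control filter
#'
#' Keeps instruments that (i) are in the allowed candidate list, (ii) are
#' missing in fewer than `max_missing` of individuals (strict: a variant at
#' exactly the threshold is rejected), and (iii) have an exact
#' Hardy-Weinberg mid-p strictly greater than `min_hwe_midp`. Input order
#' is preserved.
#'
#' @param stats a data.frame of per-variant statistics as returned by
#'   [linear_assoc()] (needs `variant_id`, `missing_rate`, `hwe_midp`).
#' @param max_missing missingness threshold (default 0.1).
#' @param min_hwe_midp Hardy-Weinberg mid-p threshold (default 1e-20).
#' @param allowed_ids candidate instrument ids (default: all ids in
#'   `stats`).
#' @return Character vector of passing variant ids, with an attribute
#'   `rejections`: a data.frame of rejected ids and the first rule each
#'   failed (`not_allowed`, `missingness`, `hwe`).
#' @export
filter_instruments <- function(stats, max_missing = 0.1,
                               min_hwe_midp = 1e-20,
                               allowed_ids = stats$variant_id) {
  stopifnot(all(c("variant_id", "missing_rate", "hwe_midp") %in%
                  names(stats)))
  missing_stats <- setdiff(allowed_ids, stats$variant_id)
  if (length(missing_stats)) {
    stop("`stats` does not cover allowed ids: ",
         paste(missing_stats, collapse = ", "))
  }
  reason <- rep(NA_character_, nrow(stats))
  reason[!(stats$variant_id %in% allowed_ids)] <- "not_allowed"
  reason[is.na(reason) & !(stats$missing_rate < max_missing)] <- "missingness"
  reason[is.na(reason) & !(stats$hwe_midp > min_hwe_midp)] <- "hwe"
  keep <- is.na(reason)
  out <- stats$variant_id[keep]
  attr(out, "rejections") <- data.frame(
    variant_id = stats$variant_id[!keep],
    reason = reason[!keep],
    stringsAsFactors = FALSE)
  out
}

#' Build the standard covariate design from a cohort table
#'
#' Expands the study's default covariate set (age, sex, genotyping array,
#' assessment center, principal components) into a numeric matrix suitable
#' for [linear_assoc()]/[logistic_assoc()], dummy-coding the categorical
#' columns with the first level as reference.
#'
#' @param cohort cohort data.frame.
#' @param n_pcs number of `pc*` columns to include (default: all present).
#' @return Numeric matrix with one row per individual.
#' @export
covariate_matrix <- function(cohort, n_pcs = NULL) {
  pc_cols <- grep("^pc[0-9]+$", names(cohort), value = TRUE)
  if (!is.null(n_pcs)) pc_cols <- head(pc_cols, n_pcs)
  out <- cbind(age = as.numeric(cohort$age), sex = as.numeric(cohort$sex))
  for (col in c("genotyping_array", "assessment_center")) {
    fac <- factor(cohort[[col]])
    if (nlevels(fac) > 1L) {
      dummies <- sapply(levels(fac)[-1], function(l) as.numeric(fac == l))
      colnames(dummies) <- paste0(col, "_", levels(fac)[-1])
      out <- cbind(out, dummies)
    }
  }
  if (length(pc_cols)) {
    out <- cbind(out, as.matrix(cohort[pc_cols]))
  }
  out
}
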