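#' Assign stratum labels to a cohort
#'
#' Labels each individual with the stratifying categories used throughout
#' the analysis:
#' \itemize{
#'   \item BMI category by half-open intervals: non-overweight
#'     (`bmi < 25`), overweight (`25 <= bmi < 30`), obese (`bmi >= 30`);
#'   \item tertile of the instrument-adjusted polygenic risk score, with
#'     empirical cut-points over the analyzed cohort and ties broken by
#'     stable rank, so tertile sizes differ by at most 1;
#'   \item family history (copied through);
#'   \item case medication stratum: `metformin_only` (metformin and not
#'     insulin), `insulin_only` (insulin and not metformin), `both`,
#'     `none` for other cases, and `control` for non-cases. Medication
#'     strata select cases with exactly that drug plus all controls.
#' }
#'
#' Stratifying variables must be pre-adjusted for the instruments (see
#' [residualize()]) to avoid collider bias; the adjusted vectors are taken
#' explicitly so the caller cannot silently stratify on raw values.
#'
#' @param cohort cohort data.frame (`t2d_case`, `family_history`,
#'   `metformin`, `insulin`).
#' @param adjusted_bmi,adjusted_prs instrument-adjusted BMI and PRS,
#'   row-aligned with `cohort`.
#' @return A data.frame with columns `bmi_cat`, `prs_tertile`,
#'   `family_history`, `medication`.
#' @export
assign_strata <- function(cohort, adjusted_bmi, adjusted_prs) {
  n <- nrow(cohort)
  stopifnot(length(adjusted_bmi) == n, length(adjusted_prs) == n)
  bmi_cat <- cut(adjusted_bmi, breaks = c(-Inf, 25, 30, Inf),
                 labels = c("non_overweight", "overweight", "obese"),
                 right = FALSE)
  tert <- rank_bins(adjusted_prs, 3L)
  prs_tertile <- factor(c("low", "medium", "high")[tert],
                        levels = c("low", "medium", "high"))
  medication <- ifelse(!cohort$t2d_case, "control",
                ifelse(cohort$metformin & !cohort$insulin, "metformin_only",
                ifelse(cohort$insulin & !cohort$metformin, "insulin_only",
                ifelse(cohort$metformin & cohort$insulin, "both", "none"))))
  data.frame(bmi_cat = bmi_cat,
             prs_tertile = prs_tertile,
             family_history = cohort$family_history,
             medication = factor(medication,
                                 levels = c("control", "metformin_only",
                                            "insulin_only", "both", "none")),
             stringsAsFactors = FALSE)
}

#' Stratified prevalence and relative-risk table
#'
#' Cross-tabulates case prevalence over two stratifying factors and
#' reports each cell's relative risk with respect to the reference
#' (first-row, first-column) cell.
#'
#' @param case logical case-status vector.
#' @param row_factor,col_factor factors (or vectors coercible to factors)
#'   defining the rows and columns, row-aligned with `case`.
#' @return An object of class `prevalence_table`: a data.frame of cells
#'   (`row`, `col`, `n`, `n_cases`, `prevalence`, `relative_risk`). Empty
#'   cells have `NA` prevalence; the reference cell's relative risk is 1.
#'   `format()` renders prevalence to 1 decimal percent and relative risk
#'   to 1 decimal (the table's display precision), with empty cells shown
#'   as em-dashes.
#' @export
#' @examples
#' pt <- prevalence_table(c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE),
#'                        rep(c("no_fh", "fh"), each = 3),
#'                        rep(c("lean", "obese"), 3))
#' format(pt)
prevalence_table <- function(case, row_factor, col_factor) {
  case <- as.logical(case)
  row_factor <- as.factor(row_factor)
  col_factor <- as.factor(col_factor)
  stopifnot(length(case) == length(row_factor),
            length(case) == length(col_factor))
  cells <- expand.grid(row = levels(row_factor), col = levels(col_factor),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells$n <- as.vector(table(col_factor, row_factor)[
    cbind(cells$col, cells$row)])
  tab_cases <- table(col_factor[case], row_factor[case])
  cells$n_cases <- ifelse(cells$n > 0,
                          as.vector(tab_cases[cbind(cells$col, cells$row)]),
                          0L)
  cells$prevalence <- ifelse(cells$n > 0, cells$n_cases / cells$n, NA_real_)
  ref <- cells$prevalence[1]
  cells$relative_risk <- if (!is.na(ref) && ref > 0) {
    cells$prevalence / ref
  } else {
    ifelse(seq_len(nrow(cells)) == 1L & !is.na(cells$prevalence),
           1, NA_real_)
  }
  structure(cells, class = c("prevalence_table", "data.frame"))
}

#' @export
format.prevalence_table <- function(x, ...) {
  rows <- unique(x$row)
  cols <- unique(x$col)
  out <- matrix("—", length(rows), length(cols),
                dimnames = list(rows, cols))
  for (i in seq_len(nrow(x))) {
    if (is.na(x$prevalence[i])) next
    cell <- fmt_pct1(x$prevalence[i])
    if (!is.na(x$relative_risk[i]) && !(x$row[i] == rows[1] &&
                                        x$col[i] == cols[1])) {
      cell <- sprintf("%s (%s)", cell, fmt_rr1(x$relative_risk[i]))
    }
    out[x$row[i], x$col[i]] <- cell
  }
  out
}

#' @export
print.prevalence_table <- function(x, ...) {
  print(format(x), quote = FALSE)
  invisible(x)
}

#' Binned prevalence along BMI
#'
#' Within each group, sorts individuals by BMI, splits them into `n_bins`
#' contiguous bins of near-equal size (sizes differ by at most 1; the
#' larger bins are placed at the high-BMI end), and returns each bin's
#' mean BMI and case fraction, in BMI order. This is the summary behind
#' prevalence-versus-BMI curves.
#'
#' @param bmi numeric BMI vector.
#' @param case logical case-status vector.
#' @param group optional grouping vector (default: a single group).
#' @param n_bins number of bins per group (default 50). Each group must
#'   hold at least `n_bins` individuals.
#' @return A data.frame with columns `group`, `bin`, `n`, `mean_bmi`,
#'   `prevalence`.
#' @export
binned_prevalence <- function(bmi, case, group = NULL, n_bins = 50L) {
  stopifnot(length(bmi) == length(case))
  if (is.null(group)) group <- rep("all", length(bmi))
  case <- as.logical(case)
  out <- lapply(split(seq_along(bmi), group), function(idx) {
    n <- length(idx)
    if (n < n_bins) {
      stop(sprintf(
        "group of size %d is smaller than n_bins = %d; use fewer bins",
        n, n_bins))
    }
    ord <- idx[order(bmi[idx])]
    base <- n %/% n_bins
    extra <- n %% n_bins
    sizes <- rep(base, n_bins)
    if (extra > 0) {  # remainder individuals go to the highest-BMI bins
      sizes[(n_bins - extra + 1):n_bins] <- base + 1L
    }
    bin <- rep(seq_len(n_bins), times = sizes)
    data.frame(
      group = group[idx[1]],
      bin = seq_len(n_bins),
      n = sizes,
      mean_bmi = as.vector(tapply(bmi[ord], bin, mean)),
      prevalence = as.vector(tapply(case[ord], bin, mean)),
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
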