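#' Genotype dosage matrix
#'
#' A light container for an individuals-by-variants dosage matrix with the
#' per-variant effect allele. Dosages count copies of the effect allele and
#' lie in \[0, 2\]; missing genotypes are `NA`.
#'
#' @param dosage numeric matrix, rows = individuals, columns = variants.
#'   Column names are the variant identifiers (must be unique).
#' @param effect_allele character vector of effect alleles, one per variant
#'   (recycled names from `colnames(dosage)` if unnamed).
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosage` (the matrix) and `effect_allele` (named character vector).
#' @export
#' @examples
#' g <- genotype_matrix(matrix(c(0, 1, 2, 1), 2, 2,
#'                             dimnames = list(NULL, c("rs1", "rs2"))),
#'                      c(rs1 = "A", rs2 = "C"))
#' variant_ids(g)
genotype_matrix <- function(dosage, effect_allele = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(colnames(dosage))) {
    stop("`dosage` must have variant ids as column names")
  }
  if (anyDuplicated(colnames(dosage))) {
    stop("variant ids must be unique")
  }
  rng <- range(dosage, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) {
    bad <- which(dosage < 0 | dosage > 2, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "dosages must lie in [0, 2]: value %g at row %d, variant %s",
      dosage[bad[1], bad[2]], bad[1], colnames(dosage)[bad[2]]))
  }
  if (is.null(effect_allele)) {
    effect_allele <- setNames(rep("A", ncol(dosage)), colnames(dosage))
  }
  if (is.null(names(effect_allele))) {
    names(effect_allele) <- colnames(dosage)
  }
  effect_allele <- effect_allele[colnames(dosage)]
  structure(list(dosage = dosage, effect_allele = effect_allele),
            class = "genotype_matrix")
}

#' @rdname genotype_matrix
#' @param x a `genotype_matrix`.
#' @export
variant_ids <- function(x) colnames(x$dosage)

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d variants, %.2f%% missing\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

# mean-impute missing dosages per variant (used for allele scores,
# residualization and matching fits; per-variant regressions instead use
# complete cases)
impute_dosage <- function(x, ids = NULL) {
  d <- if (inherits(x, "genotype_matrix")) x$dosage else as.matrix(x)
  if (!is.null(ids)) {
    missing_ids <- setdiff(ids, colnames(d))
    if (length(missing_ids)) {
      stop("variants not present in genotypes: ",
           paste(missing_ids, collapse = ", "))
    }
    d <- d[, ids, drop = FALSE]
  }
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2]]
  }
  d
}
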