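# TSV/VCF readers and writers for the cohort, genotype, and weight tables.
# All files are plain text: booleans as 0/1, missing values as "NA".

cohort_required_cols <- c(
  "id", "bmi", "t2d_case", "family_history", "prs", "age", "sex",
  "genotyping_array", "assessment_center", "hba1c", "metformin", "insulin",
  "qc_exclude", "diabetes_type_label")

cohort_flag_cols <- c("t2d_case", "family_history", "sex", "metformin",
                      "insulin", "qc_exclude")

#' Read and write cohort tables
#'
#' Tab-separated cohort tables with a fixed header: the required columns
#' (`id`, `bmi`, `t2d_case`, `family_history`, `prs`, `age`, `sex`,
#' `genotyping_array`, `assessment_center`, `hba1c`, `metformin`,
#' `insulin`, `qc_exclude`, `diabetes_type_label`) plus any number of
#' principal-component columns `pc1`, `pc2`, .... Flags are written as
#' 0/1 and missing values as `NA`. Reading validates the header (missing
#' mandatory columns are an error, unknown columns a warning) and
#' round-trips `write_cohort_tsv()` output exactly.
#'
#' @param cohort cohort data.frame.
#' @param path file path.
#' @return `read_cohort_tsv()` returns the cohort data.frame;
#'   `write_cohort_tsv()` returns `path` invisibly.
#' @export
write_cohort_tsv <- function(cohort, path) {
  stopifnot(all(cohort_required_cols %in% names(cohort)))
  out <- cohort
  for (col in cohort_flag_cols) out[[col]] <- as.integer(out[[col]])
  out$diabetes_type_label <- as.character(out$diabetes_type_label)
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(path) {
  x <- as.data.frame(data.table::fread(path, sep = "\t", na.strings = "NA",
                                       showProgress = FALSE))
  missing_cols <- setdiff(cohort_required_cols, names(x))
  if (length(missing_cols)) {
    stop("cohort file is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  known <- c(cohort_required_cols, grep("^pc[0-9]+$", names(x), value = TRUE))
  unknown <- setdiff(names(x), known)
  if (length(unknown)) {
    warning("ignoring unknown cohort column(s): ",
            paste(unknown, collapse = ", "))
    x <- x[known]
  }
  for (col in cohort_flag_cols) x[[col]] <- as.logical(x[[col]])
  bad_label <- !(x$diabetes_type_label %in% diabetes_type_levels)
  if (any(bad_label)) {
    stop(sprintf("invalid diabetes_type_label at line %d: %s",
                 which(bad_label)[1] + 1L,
                 x$diabetes_type_label[which(bad_label)[1]]))
  }
  x$diabetes_type_label <- factor(x$diabetes_type_label,
                                  levels = diabetes_type_levels)
  if (any(!is.na(x$bmi) & (x$bmi <= 10 | x$bmi >= 80))) {
    stop("bmi outside (10, 80) at line ",
         which(x$bmi <= 10 | x$bmi >= 80)[1] + 1L)
  }
  x
}

#' Read and write genotype dosage matrices
#'
#' The TSV layout has one row per individual: a header line
#' (`id` followed by the variant ids), one annotation line whose first
#' field is `!effect_allele` carrying the per-variant effect alleles, then
#' the dosage rows (values in \[0, 2\], `NA` for missing). A value outside
#' \[0, 2\] is a parse error naming the row and variant.
#' `read_genotypes_vcf()` reads dosages from a VCF's `DS` FORMAT field
#' (effect allele = ALT; requires the `vcfR` package).
#'
#' @param genotypes a [genotype_matrix()].
#' @param path file path.
#' @return Readers return a [genotype_matrix()] (with individual ids as an
#'   `individual_ids` attribute when present); the writer returns `path`
#'   invisibly.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  ids <- attr(genotypes, "individual_ids") %||%
    sprintf("ind%06d", seq_len(nrow(genotypes$dosage)))
  writeLines(c(paste(c("id", variant_ids(genotypes)), collapse = "\t"),
               paste(c("!effect_allele", genotypes$effect_allele),
                     collapse = "\t")), path)
  data.table::fwrite(
    data.table::data.table(id = ids, genotypes$dosage),
    path, sep = "\t", na = "NA", quote = FALSE,
    col.names = FALSE, append = TRUE)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @export
read_genotypes_tsv <- function(path) {
  header <- strsplit(readLines(path, n = 2L), "\t", fixed = TRUE)
  if (header[[1]][1] != "id") {
    stop("genotype TSV must start with an 'id' header column")
  }
  vids <- header[[1]][-1]
  if (length(header) < 2L || header[[2]][1] != "!effect_allele") {
    stop("genotype TSV is missing the '!effect_allele' annotation line")
  }
  alleles <- setNames(header[[2]][-1], vids)
  x <- as.data.frame(data.table::fread(path, sep = "\t", skip = 2L,
                                       header = FALSE, na.strings = "NA",
                                       showProgress = FALSE))
  colnames(x) <- c("id", vids)
  d <- as.matrix(x[, -1, drop = FALSE])
  bad <- which(!is.na(d) & (d < 0 | d > 2), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "dosage out of [0, 2] at line %d, variant %s (value %g)",
      bad[1, 1] + 2L, vids[bad[1, 2]], d[bad[1, 1], bad[1, 2]]))
  }
  g <- genotype_matrix(d, alleles)
  attr(g, "individual_ids") <- as.character(x$id)
  g
}

#' @rdname write_genotypes_tsv
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_genotypes_vcf() requires the `vcfR` package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  if (is.null(ds) || all(is.na(ds))) {
    stop("VCF has no DS (dosage) FORMAT field")
  }
  fix <- vcfR::getFIX(v)
  d <- t(ds)
  colnames(d) <- unname(fix[, "ID"])
  g <- genotype_matrix(d, setNames(unname(fix[, "ALT"]), fix[, "ID"]))
  attr(g, "individual_ids") <- rownames(d)
  g
}

#' Read and write instrument weight tables
#'
#' Three-column TSV: `variant_id`, `effect_allele`, `beta` (the
#' per-effect-allele exposure weight).
#'
#' @param weights data.frame with the three columns.
#' @param path file path.
#' @return `read_weights_tsv()` returns the weights data.frame; the writer
#'   returns `path` invisibly.
#' @export
write_weights_tsv <- function(weights, path) {
  stopifnot(all(c("variant_id", "effect_allele", "beta") %in%
                  names(weights)))
  data.table::fwrite(weights[c("variant_id", "effect_allele", "beta")],
                     path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_weights_tsv
#' @export
read_weights_tsv <- function(path) {
  x <- as.data.frame(data.table::fread(path, sep = "\t", na.strings = "NA",
                                       showProgress = FALSE))
  missing_cols <- setdiff(c("variant_id", "effect_allele", "beta"), names(x))
  if (length(missing_cols)) {
    stop("weights file is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyNA(x$beta)) {
    stop("missing beta at line ", which(is.na(x$beta))[1] + 1L)
  }
  x
}
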