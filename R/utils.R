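# shared internal helpers

#' Round half away from zero
#'
#' Rounds to the nearest integer, with exact halves moved away from zero
#' (so 0.5 -> 1, -0.5 -> -1), unlike [base::round()]'s round-half-to-even.
#' This is the convention used for all rendered integer quantities
#' (matched subsample sizes, percent cells, pounds/kilograms).
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
#' @examples
#' round_half_away(c(0.5, 1.5, 2.5, -0.5, 31.5))
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Rank-based area under the ROC curve
#'
#' Mann-Whitney AUC of a continuous score for a binary outcome, computed
#' from ranks (ties averaged).
#'
#' @param score numeric score vector.
#' @param outcome logical (or 0/1) outcome vector, same length.
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(score, outcome) {
  outcome <- as.logical(outcome)
  stopifnot(length(score) == length(outcome), !anyNA(score), !anyNA(outcome))
  n1 <- sum(outcome)
  n0 <- sum(!outcome)
  if (n1 == 0L || n0 == 0L) {
    stop("auc_rank() needs both outcome classes present")
  }
  r <- rank(score)
  (sum(r[outcome]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring
# the caller's RNG state afterwards, so named substreams (e.g. matched
# subsampling) do not perturb draw order elsewhere.
with_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# stable equal-size binning: bin i gets ids by rank (ties broken by
# original order), bins differ in size by <= 1
rank_bins <- function(x, n_bins) {
  n <- length(x)
  r <- rank(x, ties.method = "first")
  as.integer(ceiling(n_bins * r / n))
}

fmt_pct1 <- function(x) sprintf("%.1f%%", 100 * x)
fmt_pct0 <- function(x) sprintf("%.0f%%", round_half_away(100 * x))
fmt_rr1 <- function(x) sprintf("%.1f×", x)

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_fraction <- function(x, name, open = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (open) x > 0 && x < 1 else x >= 0 && x <= 1)
  if (!ok) stop(sprintf("`%s` must be a fraction in (0, 1), got %s",
                        name, deparse(x)), call. = FALSE)
  invisible(x)
}

assert_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single non-missing number", name),
         call. = FALSE)
  }
  invisible(x)
}
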