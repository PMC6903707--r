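#' Remove the instrument contribution from a continuous variable
#'
#' Guards against collider bias before stratifying on a continuous
#' variable (BMI or polygenic risk score): the variable is regressed on
#' the instrument dosages by multiple linear regression, the predictions
#' are mean-centered, and the centered predictions are subtracted. The
#' output keeps the input's mean and has (in-sample) zero correlation with
#' every instrument, so strata defined on it are independent of the
#' instruments. Missing dosages are mean-imputed for this fit only.
#'
#' The operation is idempotent, and should be re-fit within any subset it
#' is used in (orthogonality must hold in the analyzed subset).
#'
#' @param values numeric vector, row-aligned with `genotypes`.
#' @param genotypes a [genotype_matrix()].
#' @param instrument_ids variants to regress out (default: all).
#' @return The adjusted vector.
#' @export
residualize <- function(values, genotypes,
                        instrument_ids = variant_ids(genotypes)) {
  D <- impute_dosage(genotypes, instrument_ids)
  stopifnot(length(values) == nrow(D), !anyNA(values))
  X <- cbind(`(intercept)` = 1, D)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dropped <- colnames(X)[qrx$pivot[-seq_len(qrx$rank)]]
    stop("instrument dosage matrix is rank deficient; collinear: ",
         paste(dropped, collapse = ", "))
  }
  fitted <- qr.fitted(qrx, values)
  values - (fitted - mean(fitted))
}

#' Decile-matched subsampling for a binary stratifying variable
#'
#' Guards against collider bias before stratifying on a binary variable
#' (family history): the variable is predicted from the instrument dosages
#' by multivariate logistic regression, individuals are binned into
#' `n_bins` prediction deciles (equal-size bins; ties broken by stable
#' rank), and within each bin the unexposed group is randomly subsampled
#' without replacement to `ratio` times the exposed count, rounded half
#' away from zero. All exposed individuals are kept. If a bin holds fewer
#' unexposed candidates than the target, all are kept and the shortfall is
#' recorded.
#'
#' Subsampling uses a dedicated seeded random stream, leaving the caller's
#' RNG state untouched.
#'
#' @param exposed logical vector (both classes must be present).
#' @param genotypes a [genotype_matrix()], row-aligned with `exposed`.
#' @param instrument_ids variants used for the prediction (default: all).
#' @param ratio target unexposed:exposed ratio per bin (default 4.5).
#' @param n_bins number of prediction bins (default 10).
#' @param seed integer seed for the subsampling stream.
#' @return A list of class `match_result`: `kept` (integer row indices, in
#'   increasing order) and `report` (class `match_report`) with
#'   `n_exposed_kept`, `n_unexposed_kept`, `n_excluded` and a `per_bin`
#'   data.frame (`bin`, `n_exposed`, `n_unexposed_available`,
#'   `n_unexposed_kept`, `shortfall`).
#' @export
match_binary <- function(exposed, genotypes,
                         instrument_ids = variant_ids(genotypes),
                         ratio = 4.5, n_bins = 10L, seed) {
  stopifnot(is.logical(exposed), !anyNA(exposed))
  if (!any(exposed) || all(exposed)) {
    stop("match_binary() needs both exposed and unexposed present")
  }
  D <- impute_dosage(genotypes, instrument_ids)
  stopifnot(length(exposed) == nrow(D))
  X <- cbind(1, D)
  fit <- suppressWarnings(glm.fit(X, as.numeric(exposed),
                                  family = binomial(),
                                  control = list(epsilon = 1e-10,
                                                 maxit = 50L)))
  if (!fit$converged) stop("logistic regression for matching did not converge")
  match_by_prediction(exposed, fit$fitted.values, ratio = ratio,
                      n_bins = n_bins, seed = seed)
}

#' @rdname match_binary
#' @param predictions numeric vector of exposure predictions (any monotone
#'   score; only ranks matter for binning). `match_by_prediction()` is the
#'   binning/subsampling core of `match_binary()`, exposed for use with
#'   externally computed predictions.
#' @export
match_by_prediction <- function(exposed, predictions, ratio = 4.5,
                                n_bins = 10L, seed) {
  stopifnot(is.logical(exposed), length(predictions) == length(exposed),
            ratio > 0, n_bins >= 1)
  if (missing(seed)) stop("`seed` is mandatory for the subsampling stream")
  bin <- rank_bins(predictions, n_bins)
  kept <- logical(length(exposed))
  kept[exposed] <- TRUE
  per_bin <- data.frame(bin = seq_len(n_bins), n_exposed = 0L,
                        n_unexposed_available = 0L, n_unexposed_kept = 0L,
                        shortfall = 0L)
  with_rng(seed, {
    for (b in seq_len(n_bins)) {
      in_bin <- bin == b
      n_exp <- sum(in_bin & exposed)
      unexp_idx <- which(in_bin & !exposed)
      target <- if (is.finite(ratio)) {
        as.integer(round_half_away(ratio * n_exp))
      } else {
        length(unexp_idx)
      }
      take <- min(target, length(unexp_idx))
      if (take > 0) {
        kept[unexp_idx[sample.int(length(unexp_idx), take)]] <- TRUE
      }
      per_bin[b, c("n_exposed", "n_unexposed_available",
                   "n_unexposed_kept", "shortfall")] <-
        c(n_exp, length(unexp_idx), take, target - take)
    }
  })
  report <- structure(list(
    n_exposed_kept = sum(exposed),
    n_unexposed_kept = sum(kept & !exposed),
    n_excluded = sum(!kept),
    per_bin = per_bin), class = "match_report")
  structure(list(kept = which(kept), report = report),
            class = "match_result")
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf(
    "matched subsample: %d exposed + %d unexposed kept, %d excluded\n",
    x$n_exposed_kept, x$n_unexposed_kept, x$n_excluded))
  if (any(x$per_bin$shortfall > 0)) {
    cat(sprintf("  %d bin(s) short of the target ratio\n",
                sum(x$per_bin$shortfall > 0)))
  }
  invisible(x)
}

#' @export
print.match_result <- function(x, ...) {
  print(x$report)
  invisible(x)
}
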