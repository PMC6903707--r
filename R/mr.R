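#' Instrument-level summary statistics for MR
#'
#' Bundles per-instrument exposure effects (kg/m2 BMI per dosage unit) and
#' outcome effects (diabetes log odds ratio per dosage unit) with their
#' standard errors, the input to the summary-statistic MR estimators.
#'
#' @param variant_id character vector of unique instrument ids.
#' @param beta_x,se_x exposure effect and standard error (se_x > 0).
#' @param beta_y,se_y outcome effect (log-OR) and standard error (se_y > 0).
#' @return A data.frame of class `instrument_set`.
#' @seealso [ivw()], [mr_egger()], [harmonize_orientation()]
#' @export
instrument_set <- function(variant_id, beta_x, se_x, beta_y, se_y) {
  x <- data.frame(variant_id = as.character(variant_id),
                  beta_x = beta_x, se_x = se_x,
                  beta_y = beta_y, se_y = se_y,
                  stringsAsFactors = FALSE)
  if (nrow(x) < 1L) stop("at least one instrument is required")
  if (anyDuplicated(x$variant_id)) stop("instrument ids must be unique")
  if (any(!is.finite(x$se_x)) || any(x$se_x <= 0) ||
      any(!is.finite(x$se_y)) || any(x$se_y <= 0)) {
    stop("all standard errors must be positive and finite")
  }
  class(x) <- c("instrument_set", "data.frame")
  x
}

#' Orient instruments so every exposure effect is positive
#'
#' Jointly flips the sign of (`beta_x`, `beta_y`) for instruments with
#' negative exposure effect. Ratio-based estimators (Wald, IVW) are
#' invariant to this, but the MR-Egger intercept is orientation-sensitive,
#' so a deterministic convention is applied before Egger regression.
#'
#' @param instruments an [instrument_set()].
#' @return The re-oriented `instrument_set`.
#' @export
harmonize_orientation <- function(instruments) {
  flip <- instruments$beta_x < 0
  instruments$beta_x[flip] <- -instruments$beta_x[flip]
  instruments$beta_y[flip] <- -instruments$beta_y[flip]
  instruments
}

new_mr_estimate <- function(log_or, se, n_instruments, method,
                            q_stat = NA_real_, q_p = NA_real_) {
  structure(list(
    log_or = log_or,
    se = se,
    or = exp(log_or),
    ci95 = exp(log_or + c(-1, 1) * qnorm(0.975) * se),
    n_instruments = as.integer(n_instruments),
    method = method,
    q_stat = q_stat,
    q_p = q_p), class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("MR (%s, %d instrument%s): OR %.3f (95%% CI %.3f-%.3f) per unit",
              x$method, x$n_instruments,
              if (x$n_instruments == 1L) "" else "s",
              x$or, x$ci95[1], x$ci95[2]))
  if (!is.na(x$q_p)) {
    cat(sprintf("; Cochran Q = %.2f (p = %.3g)", x$q_stat, x$q_p))
  }
  cat("\n")
  invisible(x)
}

#' Single-instrument Wald ratio estimate
#'
#' The causal log-OR from one instrument: `beta_y / beta_x`, with the
#' first-order standard error `se_y / |beta_x|` (exposure uncertainty
#' ignored).
#'
#' @param instrument a one-row [instrument_set()] (or any list/data.frame
#'   providing `beta_x`, `beta_y`, `se_y`).
#' @return An `mr_estimate` (`method = "wald"`).
#' @export
#' @examples
#' wald_ratio(instrument_set("rs1", 0.1, 0.01, 0.05, 0.01))
wald_ratio <- function(instrument) {
  if (is.data.frame(instrument) && nrow(instrument) != 1L) {
    stop("wald_ratio() takes a single instrument")
  }
  bx <- instrument$beta_x
  if (bx == 0) stop("Wald ratio undefined for beta_x = 0")
  new_mr_estimate(log_or = instrument$beta_y / bx,
                  se = instrument$se_y / abs(bx),
                  n_instruments = 1L, method = "wald")
}

#' Inverse-variance-weighted MR estimate
#'
#' Fixed-effect inverse-variance-weighted (IVW) combination of the
#' per-instrument Wald ratios, equivalent to weighted least squares of the
#' outcome effects on the exposure effects through the origin with weights
#' `1/se_y^2` (first-order weights; exposure standard errors ignored):
#' \deqn{\hat\beta = \frac{\sum_j \beta_{Xj}\beta_{Yj}/se_{Yj}^2}
#'   {\sum_j \beta_{Xj}^2/se_{Yj}^2}, \quad
#'   se(\hat\beta) = \Big(\sum_j \beta_{Xj}^2/se_{Yj}^2\Big)^{-1/2}.}
#' Cochran's Q statistic
#' \eqn{\sum_j ((\beta_{Yj} - \hat\beta\,\beta_{Xj})/se_{Yj})^2} tests
#' homogeneity of the per-instrument ratios against a chi-square with
#' (number of instruments - 1) degrees of freedom (undefined for a single
#' instrument, in which case the result equals [wald_ratio()]).
#'
#' @param instruments an [instrument_set()].
#' @return An `mr_estimate` (`method = "ivw"`).
#' @export
ivw <- function(instruments) {
  stopifnot(inherits(instruments, "data.frame"))
  if (nrow(instruments) < 1L) stop("empty instrument set")
  if (nrow(instruments) == 1L) {
    est <- wald_ratio(instruments)
    est$method <- "ivw"
    return(est)
  }
  w <- 1 / instruments$se_y^2
  denom <- sum(instruments$beta_x^2 * w)
  log_or <- sum(instruments$beta_x * instruments$beta_y * w) / denom
  se <- 1 / sqrt(denom)
  q <- sum(((instruments$beta_y - log_or * instruments$beta_x) /
              instruments$se_y)^2)
  q_p <- pchisq(q, df = nrow(instruments) - 1L, lower.tail = FALSE)
  new_mr_estimate(log_or, se, nrow(instruments), "ivw",
                  q_stat = q, q_p = max(q_p, .Machine$double.xmin))
}

#' MR-Egger regression with intercept (pleiotropy) test
#'
#' Weighted least squares of the outcome effects on the exposure effects
#' with a free intercept and weights `1/se_y^2`. A nonzero intercept
#' indicates directional horizontal pleiotropy; the slope is the
#' pleiotropy-adjusted causal estimate. Standard errors follow the
#' multiplicative random-effects convention: the weighted normal-equation
#' covariance is scaled by the residual standard deviation, floored at 1
#' (so SEs are never deflated below the fixed-effect ones). Intercept and
#' slope p-values use the t reference with (n - 2) degrees of freedom.
#'
#' Instruments should be oriented so all exposure effects are positive
#' (see [harmonize_orientation()]); an error is raised otherwise, because
#' the intercept is orientation-sensitive.
#'
#' @param instruments an [instrument_set()] with at least 3 instruments.
#' @return A list of class `mr_egger_result`: `slope` (an `mr_estimate`
#'   with `method = "egger"`), `intercept`, `intercept_se`, `intercept_p`,
#'   `residual_scale`.
#' @export
mr_egger <- function(instruments) {
  stopifnot(inherits(instruments, "data.frame"))
  k <- nrow(instruments)
  if (k < 3L) stop("MR-Egger needs at least 3 instruments")
  if (any(instruments$beta_x < 0)) {
    stop("MR-Egger requires all beta_x oriented positive; ",
         "apply harmonize_orientation() first")
  }
  bx <- instruments$beta_x
  by <- instruments$beta_y
  w <- 1 / instruments$se_y^2
  if (max(bx) - min(bx) < .Machine$double.eps^0.5 * max(abs(bx), 1)) {
    stop("rank deficiency: all exposure effects are equal")
  }
  xbar <- sum(w * bx) / sum(w)
  ybar <- sum(w * by) / sum(w)
  sxx <- sum(w * (bx - xbar)^2)
  slope <- sum(w * (bx - xbar) * (by - ybar)) / sxx
  intercept <- ybar - slope * xbar
  resid <- by - intercept - slope * bx
  scale <- max(1, sqrt(sum(w * resid^2) / (k - 2)))
  se_slope <- scale / sqrt(sxx)
  se_int <- scale * sqrt(1 / sum(w) + xbar^2 / sxx)
  q <- sum(w * resid^2)
  q_p <- if (k > 2L) {
    max(pchisq(q, df = k - 2L, lower.tail = FALSE), .Machine$double.xmin)
  } else NA_real_
  slope_est <- new_mr_estimate(slope, se_slope, k, "egger",
                               q_stat = q, q_p = q_p)
  structure(list(
    slope = slope_est,
    intercept = intercept,
    intercept_se = se_int,
    intercept_p = min(max(2 * pt(-abs(intercept / se_int), df = k - 2L),
                          .Machine$double.xmin), 1),
    residual_scale = scale), class = "mr_egger_result")
}

#' @export
print.mr_egger_result <- function(x, ...) {
  print(x$slope)
  cat(sprintf("  intercept %.4f (se %.4f, p = %.3g)\n",
              x$intercept, x$intercept_se, x$intercept_p))
  invisible(x)
}

#' Reconstruct a log-OR standard error from a printed 95% CI
#'
#' `se = (ln(ci_high) - ln(ci_low)) / (2 * 1.96)`, assuming the interval is
#' symmetric on the log scale (the convention for published odds ratios).
#' Useful for re-analysis of tabulated odds ratios.
#'
#' @param or_value point odds ratio.
#' @param ci_low,ci_high 95% confidence limits, with
#'   `0 < ci_low < or_value < ci_high`.
#' @return The standard error of `log(or_value)`.
#' @export
#' @examples
#' se_from_ci(1.36, 1.28, 1.45)
se_from_ci <- function(or_value, ci_low, ci_high) {
  if (!(0 < ci_low && ci_low < or_value && or_value < ci_high)) {
    stop("require 0 < ci_low < or_value < ci_high")
  }
  (log(ci_high) - log(ci_low)) / (2 * 1.96)
}

#' Difference-of-odds-ratios test between two MR estimates
#'
#' Two-sided z-test of equality of two independent log odds ratios:
#' `z = (log_or1 - log_or2) / sqrt(se1^2 + se2^2)`, normal reference.
#'
#' @param est1,est2 `mr_estimate` objects, or lists with `log_or` and `se`.
#' @return List with `z` and two-sided `p`.
#' @export
#' @examples
#' overweight <- mr_estimate_from_or(1.36, 1.28, 1.45)
#' obese <- mr_estimate_from_or(1.25, 1.20, 1.31)
#' or_difference_test(overweight, obese)
or_difference_test <- function(est1, est2) {
  stopifnot(est1$se > 0, est2$se > 0)
  z <- (est1$log_or - est2$log_or) / sqrt(est1$se^2 + est2$se^2)
  list(z = z, p = min(2 * pnorm(-abs(z)), 1))
}

#' Build an MR estimate from a printed OR and 95% CI
#'
#' Convenience constructor for re-analysis of tabulated results: the
#' standard error is reconstructed with [se_from_ci()].
#'
#' @param or_value point odds ratio.
#' @param ci_low,ci_high 95% confidence limits.
#' @param method label for the resulting estimate (default `"reported"`).
#' @return An `mr_estimate`.
#' @export
mr_estimate_from_or <- function(or_value, ci_low, ci_high,
                                method = "reported") {
  new_mr_estimate(log(or_value), se_from_ci(or_value, ci_low, ci_high),
                  n_instruments = NA_integer_, method = method)
}
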