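#' Risk-translation calculators
#'
#' Closed-form translation between an MR odds ratio per 1 kg/m2 of BMI and
#' the relative or absolute diabetes risk change predicted for a given BMI
#' (or weight) change, under the rare-disease approximation that the odds
#' ratio is close to the relative risk. With odds ratio \eqn{\beta} per
#' BMI unit and BMI reduction \eqn{\Delta}:
#' \itemize{
#'   \item relative risk reduction: \eqn{1 - \beta^{-\Delta}};
#'   \item prevalence after the reduction: \eqn{P / \beta^{\Delta}};
#'   \item absolute risk reduction: \eqn{P - P/\beta^{\Delta}};
#'   \item weight needed for a target relative reduction r:
#'     \eqn{\Delta = \ln(1/(1-r))/\ln\beta}, weight = \eqn{\Delta h^2};
#'   \item weight needed for a target absolute reduction a:
#'     \eqn{\Delta = \ln(P/(P-a))/\ln\beta}.
#' }
#' A weight change of w kg for an individual of height h meters is a BMI
#' change of `w / h^2`; pounds convert at exactly 0.45359237 kg/lb.
#'
#' @param or_per_unit odds ratio of diabetes per 1 kg/m2 BMI (> 0; > 1 for
#'   the weight-needed inverses).
#' @param delta_bmi BMI reduction in kg/m2 (>= 0).
#' @param baseline_prevalence baseline diabetes prevalence P, a fraction
#'   in (0, 1).
#' @param target target relative risk reduction, a fraction in (0, 1).
#' @param target_pp target absolute risk reduction (percentage points as a
#'   fraction), 0 < target_pp < P.
#' @param height_m height in meters.
#' @return `relative_risk_reduction()`, `prevalence_after()` and
#'   `absolute_risk_reduction()` return fractions.
#'   `weight_for_relative_reduction()` and `weight_for_absolute_reduction()`
#'   return a list with `kg`, `lbs` and `delta_bmi`.
#' @name risk_translation
#' @export
#' @examples
#' relative_risk_reduction(1.30, 2.5)            # ~0.48
#' prevalence_after(0.052, 1.36, 1)              # ~0.038
#' weight_for_relative_reduction(1.25, 0.5, 1.7) # ~9 kg / ~20 lbs
relative_risk_reduction <- function(or_per_unit, delta_bmi) {
  stopifnot(or_per_unit > 0, delta_bmi >= 0)
  1 - or_per_unit^(-delta_bmi)
}

#' @rdname risk_translation
#' @export
prevalence_after <- function(baseline_prevalence, or_per_unit, delta_bmi) {
  assert_fraction(baseline_prevalence, "baseline_prevalence")
  stopifnot(or_per_unit > 0, delta_bmi >= 0)
  baseline_prevalence / or_per_unit^delta_bmi
}

#' @rdname risk_translation
#' @export
absolute_risk_reduction <- function(baseline_prevalence, or_per_unit,
                                    delta_bmi) {
  baseline_prevalence -
    prevalence_after(baseline_prevalence, or_per_unit, delta_bmi)
}

KG_PER_LB <- 0.45359237

#' @rdname risk_translation
#' @export
weight_for_relative_reduction <- function(or_per_unit, target, height_m) {
  assert_fraction(target, "target")
  check_height(height_m)
  if (or_per_unit <= 1) {
    stop("no relative risk reduction achievable with odds ratio <= 1")
  }
  delta_bmi <- log(1 / (1 - target)) / log(or_per_unit)
  kg <- delta_bmi * height_m^2
  list(kg = kg, lbs = kg / KG_PER_LB, delta_bmi = delta_bmi)
}

#' @rdname risk_translation
#' @export
weight_for_absolute_reduction <- function(baseline_prevalence, or_per_unit,
                                          target_pp, height_m) {
  assert_fraction(baseline_prevalence, "baseline_prevalence")
  check_height(height_m)
  if (or_per_unit <= 1) {
    stop("no absolute risk reduction achievable with odds ratio <= 1")
  }
  if (target_pp <= 0 || target_pp >= baseline_prevalence) {
    stop("`target_pp` must lie in (0, baseline_prevalence): cannot reduce ",
         "prevalence below zero")
  }
  delta_bmi <- log(baseline_prevalence / (baseline_prevalence - target_pp)) /
    log(or_per_unit)
  kg <- delta_bmi * height_m^2
  list(kg = kg, lbs = kg / KG_PER_LB, delta_bmi = delta_bmi)
}

check_height <- function(height_m) {
  if (!is.numeric(height_m) || height_m <= 1.0 || height_m >= 2.5) {
    stop("`height_m` must be in (1.0, 2.5) meters")
  }
}

#' Propagate a 95% CI of the odds ratio through a risk calculator
#'
#' Evaluates a risk-translation operation at both confidence bounds of the
#' odds ratio and orders the two results, exploiting monotonicity of every
#' calculator in the odds ratio (the bounds invert for the weight-needed
#' inverses, where a weaker odds ratio implies more weight must be lost).
#'
#' @param op one of the risk-translation functions; its `or_per_unit`
#'   argument is filled from the CI bounds.
#' @param or_ci numeric length-2 vector, the odds-ratio 95% CI.
#' @param ... remaining arguments of `op`, passed through.
#' @return For scalar-valued `op`, a sorted numeric length-2 vector
#'   `c(low, high)`; for the weight calculators, a list with sorted `kg`,
#'   `lbs`, `delta_bmi` bound pairs.
#' @export
#' @examples
#' propagate_ci(relative_risk_reduction, c(1.28, 1.45),
#'              delta_bmi = 2.3 / 1.7^2)
propagate_ci <- function(op, or_ci, ...) {
  stopifnot(length(or_ci) == 2L, all(or_ci > 0), or_ci[1] <= or_ci[2])
  lo <- op(or_ci[1], ...)
  hi <- op(or_ci[2], ...)
  if (is.list(lo)) {
    out <- lapply(names(lo), function(nm) sort(c(lo[[nm]], hi[[nm]])))
    names(out) <- names(lo)
    out
  } else {
    sort(c(lo, hi))
  }
}

#' Render a weight-loss amount as printed pounds and kilograms
#'
#' Display convention for weight-needed tables: pounds are rounded to the
#' nearest integer first (half away from zero) and the displayed
#' kilograms are the rounded pounds converted back and rounded, which
#' keeps the printed lbs/kg pair self-consistent (e.g. 6.51 kg prints as
#' "14 lbs / 6 kg", whereas rounding kilograms directly would print 7).
#'
#' @param kg weight in kilograms.
#' @return List with integer `lbs` and `kg`.
#' @export
render_weight <- function(kg) {
  lbs <- round_half_away(kg / KG_PER_LB)
  list(lbs = lbs, kg = round_half_away(lbs * KG_PER_LB))
}

#' Risk-translation summary tables
#'
#' Builds the three standard translation tables from per-category MR odds
#' ratios and baseline prevalences: (1) prevalence before/after a
#' 1-kg/m2 BMI reduction with the absolute reduction; (2) relative and
#' absolute risk reductions for fixed weight losses; (3) weight needed for
#' fixed relative/absolute risk reductions. CIs are propagated from the
#' odds-ratio CIs with [propagate_ci()].
#'
#' @param estimates named list of categories; each element a list with
#'   `or` (point odds ratio), `ci` (length-2), `prevalence` (baseline
#'   fraction).
#' @param height_m height for the weight conversions (default 1.7 m).
#' @param weights_kg weight losses for table 2 (default
#'   `c(2.3, 4.5, 5.0, 9.1, 10.0)` kg).
#' @param relative_targets,absolute_targets targets for table 3 (defaults
#'   25%/50% relative and 1/2 percentage points absolute).
#' @return List of three data.frames: `prevalence_reduction`,
#'   `risk_for_weight`, `weight_for_risk`, carrying both raw values and
#'   rendered display strings.
#' @export
risk_translation_tables <- function(estimates, height_m = 1.7,
                                    weights_kg = c(2.3, 4.5, 5.0, 9.1, 10.0),
                                    relative_targets = c(0.25, 0.5),
                                    absolute_targets = c(0.01, 0.02)) {
  stopifnot(length(estimates) > 0, !is.null(names(estimates)))

  t3 <- do.call(rbind, lapply(names(estimates), function(cat) {
    e <- estimates[[cat]]
    after <- prevalence_after(e$prevalence, e$or, 1)
    after_ci <- propagate_ci(prevalence_after, e$ci,
                             baseline_prevalence = e$prevalence,
                             delta_bmi = 1)
    arr <- absolute_risk_reduction(e$prevalence, e$or, 1)
    arr_ci <- propagate_ci(absolute_risk_reduction, e$ci,
                           baseline_prevalence = e$prevalence,
                           delta_bmi = 1)
    data.frame(category = cat, or = e$or, prevalence = e$prevalence,
               prevalence_after = after,
               prevalence_after_rendered = sprintf(
                 "%s (%.1f, %.1f)", fmt_pct1(after), 100 * after_ci[1],
                 100 * after_ci[2]),
               absolute_reduction = arr,
               absolute_reduction_rendered = sprintf(
                 "%s (%.1f, %.1f)", fmt_pct1(arr), 100 * arr_ci[1],
                 100 * arr_ci[2]),
               stringsAsFactors = FALSE)
  }))

  t4 <- do.call(rbind, lapply(names(estimates), function(cat) {
    e <- estimates[[cat]]
    do.call(rbind, lapply(weights_kg, function(kg) {
      d <- kg / height_m^2
      rrr <- relative_risk_reduction(e$or, d)
      rrr_ci <- propagate_ci(relative_risk_reduction, e$ci, delta_bmi = d)
      arr <- absolute_risk_reduction(e$prevalence, e$or, d)
      arr_ci <- propagate_ci(absolute_risk_reduction, e$ci,
                             baseline_prevalence = e$prevalence,
                             delta_bmi = d)
      data.frame(category = cat, kg = kg,
                 lbs = round_half_away(kg / KG_PER_LB),
                 relative_reduction = rrr,
                 relative_rendered = sprintf(
                   "%s (%.0f, %.0f)", fmt_pct0(rrr),
                   round_half_away(100 * rrr_ci[1]),
                   round_half_away(100 * rrr_ci[2])),
                 absolute_reduction = arr,
                 absolute_rendered = sprintf(
                   "%s (%.1f, %.1f)", fmt_pct1(arr), 100 * arr_ci[1],
                   100 * arr_ci[2]),
                 stringsAsFactors = FALSE)
    }))
  }))

  # a target can be unreachable (OR bound <= 1, or an absolute target at
  # or above the baseline prevalence); such rows are kept but rendered NA
  t5 <- do.call(rbind, lapply(names(estimates), function(cat) {
    e <- estimates[[cat]]
    rel <- do.call(rbind, lapply(relative_targets, function(tg) {
      tryCatch({
        w <- weight_for_relative_reduction(e$or, tg, height_m)
        wci <- propagate_ci(weight_for_relative_reduction, e$ci,
                            target = tg, height_m = height_m)
        weight_row(cat, sprintf("%.0f%%, relative", 100 * tg), w, wci)
      }, error = function(err) {
        weight_na_row(cat, sprintf("%.0f%%, relative", 100 * tg))
      })
    }))
    abs_ <- do.call(rbind, lapply(absolute_targets, function(tg) {
      tryCatch({
        w <- weight_for_absolute_reduction(e$prevalence, e$or, tg, height_m)
        wci <- propagate_ci(weight_for_absolute_reduction, e$ci,
                            baseline_prevalence = e$prevalence,
                            target_pp = tg, height_m = height_m)
        weight_row(cat, sprintf("%.0f%%, absolute", 100 * tg), w, wci)
      }, error = function(err) {
        weight_na_row(cat, sprintf("%.0f%%, absolute", 100 * tg))
      })
    }))
    rbind(rel, abs_)
  }))

  list(prevalence_reduction = t3, risk_for_weight = t4,
       weight_for_risk = t5)
}

weight_na_row <- function(category, target) {
  data.frame(category = category, target = target, kg = NA_real_,
             lbs = NA_real_, rendered = "—", stringsAsFactors = FALSE)
}

weight_row <- function(category, target, w, wci) {
  r <- render_weight(w$kg)
  rlo <- render_weight(wci$kg[1])
  rhi <- render_weight(wci$kg[2])
  data.frame(
    category = category, target = target, kg = w$kg, lbs = w$lbs,
    rendered = sprintf("%d lbs (%d, %d)/%d kg (%d, %d)",
                       r$lbs, rlo$lbs, rhi$lbs, r$kg, rlo$kg, rhi$kg),
    stringsAsFactors = FALSE)
}
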