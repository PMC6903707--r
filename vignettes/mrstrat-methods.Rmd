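---
title: "Methods: stratified Mendelian randomization of BMI on type 2 diabetes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stratified Mendelian randomization of BMI on type 2 diabetes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrstrat)
```

# The model

Mendelian randomization treats genetic variants associated with an
exposure — here, 57 independent common variants associated with body mass
index (BMI) — as instrumental variables for the exposure's causal effect
on an outcome, here type 2 diabetes. For variant $j$, let $\beta_{Xj}$ be
its effect on BMI (kg/m² per effect-allele dosage, from a linear
regression) and $\beta_{Yj}$ its effect on diabetes (log odds ratio per
dosage, from a logistic regression). Under the instrumental-variable
assumptions each ratio $\beta_{Yj}/\beta_{Xj}$ estimates the causal log-OR
of diabetes per 1 kg/m² of BMI, and the fixed-effect inverse-variance
weighted (IVW) estimator pools them:

$$\hat\beta = \frac{\sum_j \beta_{Xj}\beta_{Yj}/se_{Yj}^2}
 {\sum_j \beta_{Xj}^2/se_{Yj}^2},\qquad
 se(\hat\beta) = \Big(\sum_j \beta_{Xj}^2/se_{Yj}^2\Big)^{-1/2},$$

equivalent to weighted regression of $\beta_{Yj}$ on $\beta_{Xj}$ through
the origin with weights $1/se_{Yj}^2$ (first-order weights: exposure
standard errors are ignored, the convention of the standard two-stage
toolchains; an exposure-SE-aware weighting would be a straightforward
extension but is deliberately not the default). Cochran's
$Q=\sum_j((\beta_{Yj}-\hat\beta\beta_{Xj})/se_{Yj})^2$ tests ratio
homogeneity against $\chi^2_{k-1}$. MR–Egger refits the same weighted
regression with a free intercept; a nonzero intercept indicates
directional horizontal pleiotropy. Egger standard errors follow the
multiplicative random-effects convention (normal-equation SEs scaled by
the residual standard deviation floored at 1), and its intercept test uses
a $t_{k-2}$ reference — appropriate at the modest instrument counts MR
works with, while the cross-stratum difference-of-odds-ratios test
$z=(\hat\beta_1-\hat\beta_2)/\sqrt{se_1^2+se_2^2}$ uses the large-sample
normal reference. P-values are reported raw, without multiplicity
adjustment.

Because the Egger intercept is orientation-sensitive, instruments are
deterministically re-oriented before estimation so every $\beta_{Xj}$ is
positive (`harmonize_orientation()`); ratio estimators are invariant to
this.

# Stratification and collider bias

The analysis estimates the MR odds ratio within strata of BMI
(non-overweight < 25, overweight 25–30, obese ≥ 30 kg/m², half-open
intervals), family history, polygenic risk score (PRS) tertile, and
case-medication status. Stratifying on a variable the instruments
influence would condition on a collider and induce spurious
instrument–outcome associations. Two guards are used:

* **Continuous stratifiers** (BMI, PRS): the instruments are regressed
  out — predictions of a multilinear regression on the 57 dosages are
  mean-centered and subtracted (`residualize()`). The output keeps the
  input's mean and is exactly orthogonal to every instrument in-sample.
  The regression is re-fit within whatever subset is analyzed, since
  orthogonality must hold in that subset.
* **Binary stratifiers** (family history): family history is predicted
  from the instruments by logistic regression, individuals are binned
  into 10 prediction deciles (equal-size bins; ties broken by stable
  rank, computed on the pooled cohort), and within each decile the
  no-family-history group is randomly subsampled to 4.5 times the
  family-history count, rounded half away from zero (`match_binary()`).
  Rounding half away from zero is chosen because it is deterministic and
  reproduces exact cohort-scale bookkeeping (4.5 × 48,238 = 217,071 with
  no tie ambiguity). Subsampling draws from a dedicated seeded stream so
  the rest of a pipeline run is unaffected by its draw order. Bins with
  too few unexposed keep everyone and record the shortfall.

Within each stratum the exposure scan runs on that stratum's controls
only — reusing outcome cases in the exposure regression would couple the
two samples and bias the ratio — while the outcome scan uses the whole
stratum.

# Nonlinearity

A single odds ratio could mask a risk "plateau". `quantile_mr()`
implements a stratified nonlinear MR: a weighted allele score (the 56
instruments with external weights; one conventional variant, rs9581854,
is absent from the weight file and dropped) is the single instrument; the
*IV-free exposure* — BMI residualized on the score and covariates — defines
50 equal-size strata without conditioning on the score; within each
stratum the localized average causal effect (LACE) is the ratio of the
score→disease logistic coefficient to the score→BMI linear coefficient,
with first-order SE. Fixed-effect Cochran Q across strata tests LACE
homogeneity, and an inverse-variance-weighted linear trend of LACE on
stratum mean BMI gives a directed test. The same machinery applied to the
per-stratum score→BMI coefficients checks the method's assumption that
the instrument's exposure effect is constant.

Design choices fixed here (the method family admits variants):
residual-based rather than doubly-ranked stratification; first-order LACE
standard errors; fixed-effect Q; precision-weighted linear trend on
stratum mean BMI; ties in the IV-free exposure broken by stable rank so
strata are deterministic.

# Risk translation

With MR odds ratio $\beta$ per kg/m² and baseline prevalence $P$, a BMI
reduction of $\Delta$ yields, under the rare-disease approximation
(OR ≈ RR, accurate at the prevalences involved):

* relative risk reduction $1-\beta^{-\Delta}$,
* post-reduction prevalence $P/\beta^{\Delta}$ and absolute reduction
  $P-P/\beta^{\Delta}$,
* inverse: weight needed for target relative reduction $r$ is
  $\Delta = \ln(1/(1-r))/\ln\beta$ (kg = $\Delta h^2$), and analogously
  $\ln(P/(P-a))/\ln\beta$ for an absolute target $a$.

All forward/inverse pairs are exact inverses (tested to 1e-12 on a
parameter grid). Confidence intervals are propagated by evaluating the
monotone calculator at both OR bounds and ordering the results; the
bounds invert for the weight-needed inverses. Display conventions follow
the published tables: percent cells rounded half away from zero (1
decimal in the prevalence table, integers elsewhere); pounds converted at
exactly 0.45359237 kg/lb, rounded first, with the displayed kilograms
derived from the rounded pounds (which reproduces printed pairings such
as "14 lbs / 6 kg" that direct kilogram rounding would miss). The
calculators apply the OR ≈ RR approximation as printed; a strict
odds-scale variant was considered and rejected as the default because the
published arithmetic is explicitly on the prevalence scale.

# The synthetic cohort generator

Real individual-level biobank data cannot be redistributed, so the
package ships a generative stand-in that reproduces the statistical
structure the analysis relies on. Defaults (all configurable through
`simulation_config()`):

| quantity | default | why |
|---|---|---|
| diabetes prevalence | 0.049 | the study cohort's case fraction |
| instrument r² on BMI | 0.013 | joint variance explained by the 57 instruments |
| causal effect θ | ln 1.3 per kg/m² | representative published MR estimate |
| PRS AUC for case status | 0.66 | discriminative power of the diabetes PRS |
| PRS r² on instruments | 0.003 | near-independence of PRS and BMI instruments |
| family-history prevalence | 0.168 | fraction reporting an affected parent/sibling |
| BMI mean, SD | 26.7, 4.3 kg/m² | reproduces the BMI category split 0.35/0.43/0.22 |
| liability effect λ | 0.85 | caps achievable PRS AUC at ≈ 0.72, comfortably above the 0.66 target |
| confounder effects | 1 kg/m², 0.3 logits per SD | moderate shared confounding |
| genotype missingness | 0.5%, one variant at 15% | gives the QC filter something to catch |

Genotypes are binomial(2, f) under Hardy–Weinberg equilibrium with
frequencies drawn on (0.05, 0.5); per-variant effects are proportional to
$1/\sqrt{2f(1-f)}$ (the usual GWAS architecture, making the r²
calibration a single scalar) and rescaled to the target joint r². BMI
adds a shared confounder, a familial component (a loading on the
mid-parent genetic liability, which induces the family-history/BMI
correlation the stratified tables assume), and normal noise; extreme
values are truncated to the plausible (10, 80) range. Case status is
Bernoulli from $\mathrm{logit}(p)=\alpha_0+\theta\,\mathrm{BMI}+\lambda
g+\delta U$ with $\alpha_0$ calibrated by bisection to the target
prevalence (tolerance 0.002, at most 100 steps, explicit error naming the
target otherwise). The PRS is the genetic liability $g$ plus a small
instrument component and noise, with the liability share calibrated by
bisection to the target AUC on a held-out population-scale draw from the
same model (≥ 20,000 individuals), so small fixture cohorts do not fail
calibration through sampling noise. Family history is mechanistic: two
parents and a sibling carry liabilities sharing half the proband's
genetic component ($h^2$ = 0.5 per relative), and family history is "any
relative above the prevalence-matched threshold" — rather than an
independent Bernoulli — so it co-varies with PRS and BMI as real family
history does. Everything is bit-reproducible given the seed.

The BMI moments deserve a note: 26.7/4.3 were chosen (over the more
obvious cohort-wide 27.4/4.8) because a normal with these moments
reproduces the published BMI category proportions (0.346/0.432/0.222
versus the printed 0.349/0.431/0.220); with 27.4/4.8 the obese fraction
would be ~0.29. The category split matters downstream (stratum sizes and
prevalences); the exact moments do not.

**What the generator does not emulate:** linkage disequilibrium between
instruments (they are independent, as MR assumes), age/sex/center effects
on BMI or diabetes (covariates exist but are pure noise — their
distributions are immaterial to the estimators, and tests exercise the
adjustment code paths, not covariate realism), genuine pleiotropy, and
assortative mating. Passing tests therefore demonstrate correctness of
the estimators and pipeline under the stated model, not robustness to
pleiotropy or population structure in real data.

# What "recovering θ" means under a logistic outcome

A subtlety worth stating precisely: with a logistic outcome model, the
per-variant marginal log-OR (what a GWAS-style logistic scan estimates)
is smaller in magnitude than the conditional coefficient θ, because odds
ratios are non-collapsible — marginalizing over the unmodelled liability,
confounder, and the rest of BMI's variation shrinks the coefficient even
without any confounding of the instrument. At the default calibration the
analytic marginal estimand (computed by Gauss quadrature over the
generator's model, independent of the estimation code) is ≈ 0.2255
against θ = ln 1.3 ≈ 0.2624, and study-scale simulations recover the
marginal value (mean IVW estimate within 0.02 of it; small residual
weak-instrument bias is pulled slightly upward by the positive
confounding). The 95% CI still covers θ itself in at least 90% of
simulated cohorts because the attenuation is below one standard error at
n = 50,000. The recovery tests assert both facts — coverage of θ, and
mean agreement with the analytic marginal estimand — rather than
pretending the marginal and conditional parameters coincide. Restricting the
exposure scan to controls (the pipeline's protocol, which avoids
case-overlap between the two scans) attenuates slightly further; the
pipeline inherits this property of the published protocol.

# Numerical choices and degenerate inputs

* Per-variant regressions use complete cases for that variant; mean
  imputation is used only where a composite is needed (allele scores,
  residualization, matching fits) — standard GWAS practice.
* Logistic fits: IRLS with tolerance 1e-10, 50 iterations; perfect
  separation is monitored as |β| > 20 and flagged per variant rather than
  crashing a scan. Single-class outcomes are hard errors.
* Linear Wald p-values use the t reference (exact in small fixtures,
  indistinguishable at cohort scale); logistic Wald p-values the normal.
* The Hardy–Weinberg mid-p is the exact conditional test: all
  heterozygote configurations consistent with the allele counts are
  enumerated in log space, and the mid-p sums strictly-less-probable
  configurations plus half the ties (including the observed one). Result
  clamped to (0, 1]; monomorphic variants return 1. QC thresholds are
  strict inequalities: missingness exactly 10% or mid-p exactly 1e-20
  both reject.
* Quantile/tertile/decile assignment always uses stable ranks
  (`ties.method = "first"`), so group sizes differ by at most one and
  results are deterministic; remainder individuals in the 50-bin
  prevalence curves go to the highest-BMI bins.
* A stratum with a single outcome class yields an NA result row with a
  recorded reason; the pipeline continues. Strata dropped from the
  nonlinear Q/trend tests are counted and reported.

# Problem sizes used by the test suite

The suite validates estimator arithmetic on ≤ 20-row fixtures against
independent oracles, collider-guard bookkeeping on a 287,394-row
constructed cohort, and statistical calibration on 100 simulated cohorts
of n = 50,000 (IVW coverage, exposure-effect recovery, nonlinear-MR Q and
trend calibration, with the null-effect variant at n = 10,000). These
sizes give binomial Monte-Carlo error comfortably inside the asserted
bands while keeping a full run to minutes.

# Known limitations

* The generator's instruments are unlinked and pleiotropy-free; MR–Egger
  is exercised on fixtures with injected pleiotropy, not on simulated
  cohorts with realistic pleiotropic architecture.
* The marginal/conditional OR distinction above means the pipeline's
  point estimates under-state θ by a few percent at realistic
  prevalences; this is a property of logistic MR generally, not of this
  implementation.
* Risk translation inherits the OR ≈ RR approximation; at prevalences
  well above ~15% the absolute-risk arithmetic becomes optimistic.
* Published-table reproduction is limited by the precision of printed
  inputs: a handful of cells were evidently computed from unrounded odds
  ratios and differ by one unit in the last digit when recomputed from
  the rounded printed values; the documentation of the test suite records
  exactly which.
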