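#' Exact Hardy-Weinberg equilibrium mid-p test
#'
#' Exact conditional test of Hardy-Weinberg equilibrium from genotype
#' counts. All heterozygote counts consistent with the observed allele
#' counts are enumerated; each configuration's probability under the
#' equilibrium null (conditional on the allele counts) is
#' \deqn{P(n_{AB}) = \frac{n!\,2^{n_{AB}}}{n_{AA}!\,n_{AB}!\,n_{BB}!}
#'   \cdot \frac{n_A!\,n_B!}{(2n)!}}
#' and the mid-p value sums the probabilities of all configurations
#' strictly less probable than the observed one, plus half the probability
#' of configurations exactly as probable (including the observed one
#' itself). The result is clamped to (0, 1]. Used as a genotyping-quality
#' filter; very small values indicate genotyping artefacts.
#'
#' @param n_hom_ref,n_het,n_hom_alt non-negative genotype counts
#'   (homozygous reference, heterozygous, homozygous alternate); the total
#'   must be positive.
#' @return The mid-p value in (0, 1]. A monomorphic variant (minor allele
#'   count 0) returns 1.
#' @export
#' @examples
#' hwe_midp(25, 50, 25)
#' hwe_midp(100, 0, 10)   # heterozygote deficit
hwe_midp <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  stopifnot(length(counts) == 3L, !anyNA(counts), all(counts >= 0),
            all(counts == round(counts)))
  n <- sum(counts)
  if (n == 0) stop("total genotype count must be positive")
  n_a <- 2 * n_hom_ref + n_het
  n_b <- 2 * n_hom_alt + n_het
  if (min(n_a, n_b) == 0) return(1)

  hets <- seq.int(n_a %% 2, min(n_a, n_b), by = 2L)
  log_prob <- lfactorial(n) + hets * log(2) -
    lfactorial((n_a - hets) / 2) - lfactorial(hets) -
    lfactorial((n_b - hets) / 2) +
    lfactorial(n_a) + lfactorial(n_b) - lfactorial(2 * n)
  prob <- exp(log_prob - max(log_prob))
  prob <- prob / sum(prob)

  p_obs <- prob[hets == n_het]
  lower <- prob < p_obs * (1 - 1e-12)
  equal <- abs(prob - p_obs) <= p_obs * 1e-12
  midp <- sum(prob[lower]) + 0.5 * sum(prob[equal])
  min(max(midp, .Machine$double.xmin), 1)
}
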