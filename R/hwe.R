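#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test for deviation from Hardy-Weinberg proportions,
#' computed by full enumeration of heterozygote counts conditional on the
#' observed allele counts. The p-value is the total probability of all
#' genotype configurations no more probable than the observed one
#' (probability-ordering, the standard convention for this test).
#'
#' @param n_AA,n_Aa,n_aa observed counts of the three genotype classes.
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("hwe_exact_test: need at least one genotype")
  nA <- 2 * n_AA + n_Aa          # minor-or-major allele count; symmetric
  na_ <- 2 * n - nA
  if (nA == 0 || na_ == 0) return(1)
  # heterozygote count shares the parity of the allele count
  h_max <- min(nA, na_)
  h <- seq(nA %% 2, h_max, by = 2)
  # log P(h | nA) up to a constant: n! 2^h / (hom1! h! hom2!)
  logp <- lgamma(n + 1) - lgamma((nA - h) / 2 + 1) - lgamma(h + 1) -
    lgamma((na_ - h) / 2 + 1) + h * log(2)
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- match(n_Aa, h)
  if (is.na(obs)) stop("inconsistent genotype counts")
  min(1, sum(prob[prob <= prob[obs] * (1 + 1e-12)]))
}
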