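#' Hardy-Weinberg exact test
#'
#' Two-sided exact test conditional on the allele counts: the p-value is
#' the sum of probabilities of all heterozygote counts (with the same
#' allele totals) that are no more probable than the observed one. The
#' conditional distribution is
#' `P(n_Aa | n, n_A) = n! / (n_AA! n_Aa! n_aa!) * 2^n_Aa / C(2n, n_A)`,
#' evaluated in log space.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (non-negative, total > 0).
#' @return Exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(is.na(counts)) || any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  n <- sum(counts)
  if (n == 0) stop("all genotype counts are zero", call. = FALSE)
  nA <- 2 * n_AA + n_Aa
  if (nA == 0 || nA == 2 * n) return(1)  # monomorphic: single configuration
  ## heterozygote counts sharing allele totals: same parity as nA,
  ## 0 <= het <= min(nA, 2n - nA)
  hmax <- min(nA, 2 * n - nA)
  hets <- seq.int(nA %% 2, hmax, by = 2)
  logp <- lgamma(n + 1) - lgamma((nA - hets) / 2 + 1) - lgamma(hets + 1) -
    lgamma(n - (nA + hets) / 2 + 1) + hets * log(2) -
    (lgamma(2 * n + 1) - lgamma(nA + 1) - lgamma(2 * n - nA + 1))
  p <- exp(logp)
  p <- p / sum(p)  # guard accumulated rounding
  obs <- p[match(n_Aa, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}
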