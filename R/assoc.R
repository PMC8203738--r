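#' Bonferroni significance threshold
#'
#' `0.05 / n` for `n` tested SNPs.
#'
#' @param n_snps Number of SNPs tested (> 0).
#' @return The genome-wide p-value threshold.
#' @export
bonferroni_threshold <- function(n_snps) {
  if (is.na(n_snps) || n_snps <= 0) stop("n_snps must be positive", call. = FALSE)
  0.05 / n_snps
}

#' Single-marker OLS association
#'
#' Ordinary least-squares stand-in for a mixed-model association fit
#' (no relatedness correction): `y ~ dosage`, two-sided t test on the
#' slope. PVE is computed with [pve()].
#'
#' @param dosages Numeric vector of genotype dosages (0/1/2).
#' @param phenotype Numeric phenotype vector, same length.
#' @return One-row tibble of class `assoc_stat`: `beta`, `se`, `p`,
#'   `maf`, `n`, `pve`.
#' @export
single_marker_regression <- function(dosages, phenotype) {
  ok <- !is.na(dosages) & !is.na(phenotype)
  d <- dosages[ok]; y <- phenotype[ok]
  n <- length(d)
  if (n < 3L) stop("need at least 3 complete observations", call. = FALSE)
  if (stats::var(d) == 0) stop("zero-variance dosage", call. = FALSE)
  fit <- stats::lm(y ~ d)
  cf <- summary(fit)$coefficients
  beta <- cf["d", "Estimate"]; se <- cf["d", "Std. Error"]
  p <- cf["d", "Pr(>|t|)"]
  maf <- min(mean(d) / 2, 1 - mean(d) / 2)
  out <- tibble::tibble(beta = beta, se = se, p = p, maf = maf, n = n,
                        pve = if (maf > 0 && se > 0) pve(beta, se, maf, n) else NA_real_)
  class(out) <- c("assoc_stat", class(out))
  out
}

#' Per-SNP phenotypic variance explained
#'
#' Summary-statistic PVE estimator:
#' `PVE = 100 * 2 beta^2 maf (1-maf) / (2 beta^2 maf (1-maf) + se^2 * 2 n * maf (1-maf))`,
#' which reduces to `100 * beta^2 / (beta^2 + n se^2)`.
#'
#' @param beta Effect estimate.
#' @param se Its standard error (> 0).
#' @param maf Minor allele frequency in (0, 0.5].
#' @param n Sample size (> 1).
#' @return PVE in percent, in `[0, 100)`.
#' @export
pve <- function(beta, se, maf, n) {
  if (any(is.na(c(beta, se, maf, n)))) stop("missing input", call. = FALSE)
  if (maf <= 0 || maf > 0.5) stop("maf must be in (0, 0.5]", call. = FALSE)
  if (se <= 0) stop("se must be positive", call. = FALSE)
  if (n <= 1) stop("n must exceed 1", call. = FALSE)
  num <- 2 * beta^2 * maf * (1 - maf)
  100 * num / (num + se^2 * 2 * n * maf * (1 - maf))
}
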