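#' Pairwise linkage disequilibrium r-squared
#'
#' From two aligned haplotype allele vectors: `D = p_AB - p_A p_B`,
#' `r2 = D^2 / (p_A (1-p_A) p_B (1-p_B))`. Haplotypes missing at either
#' site are dropped. Numerically identical to the squared Pearson
#' correlation of the 0/1 vectors.
#'
#' @param hapsA,hapsB 0/1 allele vectors of equal length.
#' @return r-squared in `[0, 1]`; `NA` if either site is monomorphic
#'   among the shared non-missing haplotypes.
#' @export
r2_pair <- function(hapsA, hapsB) {
  ok <- !is.na(hapsA) & !is.na(hapsB)
  a <- hapsA[ok]; b <- hapsB[ok]
  pa <- mean(a); pb <- mean(b)
  if (pa %in% c(0, 1) || pb %in% c(0, 1)) return(NA_real_)
  D <- mean(a * b) - pa * pb
  D^2 / (pa * (1 - pa) * pb * (1 - pb))
}

#' LD decay curve with accession subsampling
#'
#' The sample-size-controlled protocol: in each replicate,
#' `n_subsample` accessions are drawn without replacement, r-squared is
#' computed for every intra-chromosome SNP pair within `max_dist`
#' (on phased haplotypes, or genotype dosages with `use = "dosage"`),
#' pairs are binned by bp distance, and the final curve is the mean of
#' the per-replicate bin means. Deterministic under a fixed seed.
#'
#' @param panel A [hap_panel()].
#' @param pop Population label.
#' @param popmap A [pop_map()].
#' @param max_dist Maximum pair distance in bp (default 5e5).
#' @param bin Bin width in bp (default 500).
#' @param n_subsample Accessions per replicate (default 10).
#' @param reps Number of replicates (default 100).
#' @param seed Mandatory seed.
#' @param use `"haplotype"` (default) or `"dosage"`.
#' @return Tibble of class `ld_decay_curve`: `bin_start`, `bin_end`,
#'   `mean_r2`, `n_pairs` (summed over replicates); attributes
#'   `n_subsample`, `reps`.
#' @export
ld_decay_curve <- function(panel, pop, popmap, max_dist = 500000, bin = 500,
                           n_subsample = 10, reps = 100, seed,
                           use = c("haplotype", "dosage")) {
  use <- match.arg(use)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  samples <- pop_samples(popmap, pop)
  if (length(samples) < n_subsample) {
    stop("population smaller than the subsample size", call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  nb <- ceiling(max_dist / bin)
  acc_r2 <- matrix(NA_real_, reps, nb)
  acc_n <- matrix(0L, reps, nb)
  pos <- panel$pos
  for (rep in seq_len(reps)) {
    sub <- sample(samples, n_subsample)
    M <- if (use == "haplotype") {
      panel$alleles[hap_rows(panel, sub), , drop = FALSE]
    } else {
      dosage_matrix(panel)[sub, , drop = FALSE]
    }
    f <- colMeans(M, na.rm = TRUE)
    poly <- which(!is.na(f) & f > 0 & f < (if (use == "haplotype") 1 else 2))
    if (length(poly) < 2L) next
    Ms <- M[, poly, drop = FALSE]
    ps <- pos[poly]
    C2 <- suppressWarnings(stats::cor(Ms, use = "pairwise.complete.obs"))^2
    dmat <- abs(outer(ps, ps, "-"))
    sel <- upper.tri(dmat) & dmat > 0 & dmat <= max_dist & !is.na(C2)
    d <- dmat[sel]; r2 <- C2[sel]
    bidx <- pmin(nb, (d - 1) %/% bin + 1)
    sums <- tapply(r2, bidx, sum)
    cnts <- tapply(r2, bidx, length)
    ix <- as.integer(names(sums))
    acc_r2[rep, ix] <- sums / cnts
    acc_n[rep, ix] <- cnts
  }
  out <- tibble::tibble(
    bin_start = (seq_len(nb) - 1L) * bin,
    bin_end = seq_len(nb) * bin,
    mean_r2 = suppressWarnings(colMeans(acc_r2, na.rm = TRUE)),
    n_pairs = colSums(acc_n))
  out$mean_r2[is.nan(out$mean_r2)] <- NA_real_
  attr(out, "n_subsample") <- n_subsample
  attr(out, "reps") <- reps
  class(out) <- c("ld_decay_curve", class(out))
  out
}

#' Isotonic (non-increasing) smooth of an LD decay curve
#'
#' Pool-adjacent-violators fit constrained to be non-increasing in
#' distance, weighted by pair counts.
#'
#' @param curve An [ld_decay_curve()].
#' @return The curve with a `smooth_r2` column added.
#' @export
ld_smooth_isotonic <- function(curve) {
  ok <- !is.na(curve$mean_r2)
  fit <- stats::isoreg(curve$bin_start[ok], -curve$mean_r2[ok])
  curve$smooth_r2 <- NA_real_
  curve$smooth_r2[ok] <- -fit$yf
  curve
}
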