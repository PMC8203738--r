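#' Per-site nucleotide diversity
#'
#' Average number of pairwise differences at one site:
#' `ref * alt / choose(n, 2)` over the `n = ref + alt` non-missing alleles.
#'
#' @param ref_count,alt_count Allele counts at the site.
#' @return Per-site diversity; `NA` when fewer than 2 alleles observed.
#' @export
site_pi <- function(ref_count, alt_count) {
  n <- ref_count + alt_count
  out <- ref_count * alt_count / choose(n, 2)
  out[n < 2] <- NA_real_
  out
}

#' Windowed nucleotide diversity (theta-pi)
#'
#' Sliding-window sum of per-site diversity divided by the full window
#' length in bp (the VCFtools `--window-pi` convention: the denominator is
#' the window size, not the number of accessible sites). SNP-free windows
#' get 0.
#'
#' @param panel A [hap_panel()].
#' @param pop Population label; its samples are taken from `popmap`.
#' @param popmap A [pop_map()].
#' @param spec A [window_spec()] (default 20 kb / 10 kb).
#' @param chrom_len Chromosome length in bp (default: last SNP position).
#' @return A windowed track (`stat = "theta_pi"`), per-bp diversity.
#' @export
windowed_pi <- function(panel, pop, popmap, spec = window_spec(),
                        chrom_len = max(panel$pos)) {
  rows <- hap_rows(panel, pop_samples(popmap, pop))
  if (length(rows) < 4L) stop("population needs >= 2 samples", call. = FALSE)
  ac <- allele_counts(panel, rows)
  pis <- site_pi(ac$n_obs - ac$n_alt, ac$n_alt)
  windows <- make_windows(panel$chrom, chrom_len, spec)
  idx <- window_site_index(panel$pos, windows)
  val <- vapply(idx, function(i) sum(pis[i], na.rm = TRUE) / spec$size, numeric(1))
  new_windowed_track(windows$chrom, windows$start, windows$end,
                     lengths(idx), val, "theta_pi")
}

## Weir & Cockerham (1984) per-site variance components for two
## populations, from allele frequencies and observed heterozygosities.
## Returns a (sites x 3) matrix of a (among), b (between individuals
## within) and c (within individuals).
wc_components <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  n_i <- cbind(n1, n2)
  p_i <- cbind(p1, p2)
  h_i <- cbind(h1, h2)
  n_bar <- rowMeans(n_i)
  n_c <- (rowSums(n_i) - rowSums(n_i^2) / rowSums(n_i)) / (r - 1)
  p_bar <- rowSums(n_i * p_i) / rowSums(n_i)
  s2 <- rowSums(n_i * (p_i - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- rowSums(n_i * h_i) / rowSums(n_i)
  a <- n_bar / n_c *
    (s2 - (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4) / (n_bar - 1))
  b <- n_bar / (n_bar - 1) *
    (p_bar * (1 - p_bar) - (r - 1) / r * s2 - (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  c_ <- h_bar / 2
  cbind(a = a, b = b, c = c_)
}

#' Windowed Weir-Cockerham FST
#'
#' Per-site Weir & Cockerham (1984) variance components; the window value
#' is the ratio of averages `sum(a) / sum(a + b + c)`. Sites where the
#' components are undefined (a population with no calls, or a site
#' monomorphic across both populations) are skipped.
#'
#' @param panel A [hap_panel()].
#' @param popA,popB Population labels.
#' @param popmap A [pop_map()].
#' @param spec A [window_spec()].
#' @param chrom_len Chromosome length in bp.
#' @return A windowed track (`stat = "fst"`); windows with no usable sites
#'   are missing.
#' @export
weir_cockerham_fst <- function(panel, popA, popB, popmap, spec = window_spec(),
                               chrom_len = max(panel$pos)) {
  comp <- fst_site_components(panel, popA, popB, popmap)
  windows <- make_windows(panel$chrom, chrom_len, spec)
  idx <- window_site_index(panel$pos, windows)
  val <- vapply(idx, function(i) {
    a <- comp[i, 1]; tot <- comp[i, 1] + comp[i, 2] + comp[i, 3]
    ok <- !is.na(a) & !is.na(tot)
    if (!any(ok) || sum(tot[ok]) == 0) return(NA_real_)
    sum(a[ok]) / sum(tot[ok])
  }, numeric(1))
  new_windowed_track(windows$chrom, windows$start, windows$end,
                     lengths(idx), val, "fst")
}

## per-site WC components for two populations of a panel; rows with
## undefined values marked NA
fst_site_components <- function(panel, popA, popB, popmap) {
  dA <- dosage_matrix(panel)[pop_samples(popmap, popA), , drop = FALSE]
  dB <- dosage_matrix(panel)[pop_samples(popmap, popB), , drop = FALSE]
  if (nrow(dA) < 2L || nrow(dB) < 2L) stop("both populations need >= 2 samples", call. = FALSE)
  stat <- function(d) {
    n <- colSums(!is.na(d))
    p <- colMeans(d, na.rm = TRUE) / 2
    h <- colMeans(d == 1L, na.rm = TRUE)
    list(n = n, p = p, h = h)
  }
  A <- stat(dA); B <- stat(dB)
  comp <- wc_components(A$n, A$p, A$h, B$n, B$p, B$h)
  bad <- A$n < 1 | B$n < 1 | (A$p %in% c(0, 1) & B$p %in% c(0, 1) & A$p == B$p)
  comp[bad, ] <- NA_real_
  comp
}

#' Log2 diversity ratio between two windowed tracks
#'
#' `log2(pi_B / pi_A)` per window; windows where either diversity is zero
#' (or missing) become missing rather than infinite.
#'
#' @param trackB,trackA Windowed diversity tracks on identical grids
#'   (numerator and denominator populations).
#' @return A windowed track (`stat = "log2_pi_ratio"`); `n_snps` is the
#'   sum of the two inputs' SNP counts.
#' @export
pi_ratio_log2 <- function(trackB, trackA) {
  check_same_grid(trackA, trackB)
  v <- ifelse(is.na(trackA$value) | is.na(trackB$value) |
                trackA$value == 0 | trackB$value == 0,
              NA_real_, log2(trackB$value / trackA$value))
  new_windowed_track(trackA$chrom, trackA$start, trackA$end,
                     trackA$n_snps + trackB$n_snps, v, "log2_pi_ratio")
}

#' Sweep criteria for the FST + pi-ratio scan
#'
#' @param fst_quantile Z(FST) quantile; windows strictly above it qualify
#'   (default 0.95, the "top 5%").
#' @param ratio_quantile Size of the pi-ratio tail (default 0.05).
#' @param ratio_tail `"upper"` (default; reduced diversity in the swept
#'   population A raises `pi_B/pi_A`) or `"lower"` (the literal
#'   "bottom 5%" reading).
#' @param min_snps Windows with fewer SNPs are excluded (default 10).
#' @return A list of class `sweep_criteria`.
#' @export
sweep_criteria <- function(fst_quantile = 0.95, ratio_quantile = 0.05,
                           ratio_tail = c("upper", "lower"), min_snps = 10) {
  stopifnot(fst_quantile > 0, fst_quantile < 1,
            ratio_quantile > 0, ratio_quantile < 1, min_snps >= 0)
  structure(list(fst_quantile = fst_quantile, ratio_quantile = ratio_quantile,
                 ratio_tail = match.arg(ratio_tail), min_snps = as.integer(min_snps)),
            class = "sweep_criteria")
}

#' Candidate sweep regions from joint FST and pi-ratio tails
#'
#' Windows with at least `min_snps` SNPs that are simultaneously strictly
#' beyond the Z(FST) quantile and in the configured pi-ratio tail are
#' selected; adjacent or overlapping selected windows are merged
#' (bookended merge). Quantile thresholds are computed over the non-missing
#' windows that pass the SNP-count filter, with strict inequality (ties at
#' the threshold excluded).
#'
#' @param fst_z Z-transformed FST track ([z_transform()]).
#' @param ratio The [pi_ratio_log2()] track on the same grid.
#' @param crit A [sweep_criteria()].
#' @param n_snps_track Optional track whose `n_snps` column carries the
#'   SNP counts used for the `min_snps` rule (default: `fst_z`).
#' @return A [candidate_regions()] tibble tagged `"fst_pi"`.
#' @export
sweep_candidates_fst_pi <- function(fst_z, ratio, crit = sweep_criteria(),
                                    n_snps_track = fst_z) {
  check_same_grid(fst_z, ratio)
  eligible <- n_snps_track$n_snps >= crit$min_snps
  if (!any(eligible)) {
    warning("all windows excluded by the min_snps rule")
    return(candidate_regions())
  }
  fv <- ifelse(eligible, fst_z$value, NA_real_)
  rv <- ifelse(eligible, ratio$value, NA_real_)
  pass_f <- strictly_above_quantile(fv, crit$fst_quantile)
  pass_r <- if (crit$ratio_tail == "upper") {
    strictly_above_quantile(rv, 1 - crit$ratio_quantile)
  } else {
    thr <- stats::quantile(rv, crit$ratio_quantile, na.rm = TRUE, names = FALSE)
    !is.na(rv) & rv < thr
  }
  merge_windows_to_regions(fst_z[, c("chrom", "start", "end")],
                           pass_f & pass_r, "fst_pi")
}
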