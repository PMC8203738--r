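#' Extended haplotype homozygosity curve from a core site
#'
#' EHH at a site s away from the core is the probability that two
#' haplotypes drawn from the population are identical over the inclusive
#' interval `[core..s]`: `sum_i C(k_i, 2) / C(n, 2)` over haplotype
#' classes. The curve starts at 1 at distance 0 and is truncated once EHH
#' drops below `cutoff` (one point below the cutoff is kept so the
#' integration can interpolate the crossing) or at the chromosome end.
#' Haplotypes with a missing allele anywhere in the extension drop out of
#' both numerator and denominator. This is the cross-population flavor:
#' all haplotypes of the population form the starting class, with no
#' conditioning on the core allele.
#'
#' @param panel A phased [hap_panel()].
#' @param pop Population label.
#' @param popmap A [pop_map()].
#' @param core_site Site index of the core SNP.
#' @param direction `"left"` or `"right"`.
#' @param cutoff Truncation level (default 0.05).
#' @return Tibble of class `ehh_curve`: `distance` (bp from core), `ehh`.
#' @export
ehh <- function(panel, pop, popmap, core_site, direction = c("right", "left"),
                cutoff = 0.05) {
  require_phased(panel, "EHH")
  direction <- match.arg(direction)
  rows <- hap_rows(panel, pop_samples(popmap, pop))
  H <- panel$alleles[rows, , drop = FALSE]
  sites <- if (direction == "right") {
    seq.int(core_site, n_sites(panel))
  } else {
    seq.int(core_site, 1L)
  }
  res <- ehh_extend(H, sites, panel$pos, cutoff)
  out <- tibble::tibble(distance = res$distance, ehh = res$ehh)
  class(out) <- c("ehh_curve", class(out))
  out
}

## incremental class refinement along `sites` (first element = core);
## returns distances from core and EHH values, truncated one point past
## the cutoff crossing (compiled kernel)
ehh_extend <- function(H, sites, pos, cutoff, max_extend = Inf) {
  ehh_extend_cpp(H, as.integer(sites), as.numeric(pos), cutoff,
                 if (is.finite(max_extend)) max_extend else 1e18)
}

#' Integrated haplotype homozygosity
#'
#' Trapezoidal integral of an EHH curve over bp distance, truncated at the
#' linearly interpolated crossing of `cutoff`. A curve that starts below
#' the cutoff integrates to 0.
#'
#' @param curve An [ehh()] curve (or any tibble with `distance`, `ehh`).
#' @param cutoff Truncation level (default 0.05).
#' @return iHH in bp x EHH units.
#' @export
ihh <- function(curve, cutoff = 0.05) {
  d <- curve$distance; e <- curve$ehh
  n <- length(d)
  if (!n || e[1] < cutoff) return(0)
  below <- which(e < cutoff)
  last <- if (length(below)) below[1] - 1L else n
  total <- if (last > 1L) {
    sum((e[1:(last - 1L)] + e[2:last]) / 2 * diff(d[1:last]))
  } else 0
  if (length(below)) {
    i <- last  # interpolate the crossing and integrate up to it
    frac <- (e[i] - cutoff) / (e[i] - e[i + 1L])
    total <- total + (e[i] + cutoff) / 2 * (d[i + 1L] - d[i]) * frac
  }
  total
}

#' Cross-population EHH scan (XP-EHH)
#'
#' For every qualifying site, integrates EHH in both directions within
#' each population; the raw score is `ln(iHH_A / iHH_B)` and the
#' normalized score is its genome-wide Z-transform. Sites where either
#' integral is zero are skipped. Positive scores indicate longer
#' haplotypes (stronger sweep signal) in population A.
#'
#' @param panel A phased [hap_panel()].
#' @param popA,popB Population labels.
#' @param popmap A [pop_map()].
#' @param cutoff EHH truncation level (default 0.05).
#' @param min_maf Minimum overall minor allele frequency for a core site
#'   to be scored (default 0.05).
#' @param max_extend_bp Maximum extension distance from the core in bp
#'   (default `Inf`); bounding it caps the cost in regions of extreme
#'   haplotype homozygosity and truncates both populations identically.
#' @param core_step Score every `core_step`-th qualifying site (default 1
#'   = all sites); thinning trades resolution for speed.
#' @param edge_buffer_bp Cores closer than this to either end of the
#'   scanned interval are not scored (default 0). Near an end the EHH
#'   integral is truncated on one side only, which inflates the variance
#'   of the score; on short contigs a buffer keeps the standardized
#'   scores comparable.
#' @return Tibble of class `xpehh_result`: `pos`, `ihh_a`, `ihh_b`,
#'   `raw` (ln ratio), `z` (normalized score).
#' @export
xpehh_scan <- function(panel, popA, popB, popmap, cutoff = 0.05, min_maf = 0.05,
                       max_extend_bp = Inf, core_step = 1,
                       edge_buffer_bp = 0) {
  require_phased(panel, "XP-EHH")
  ac <- allele_counts(panel)
  use <- which(pmin(ac$freq, 1 - ac$freq) >= min_maf)
  if (edge_buffer_bp > 0) {
    lo <- min(panel$pos) + edge_buffer_bp
    hi <- max(panel$pos) - edge_buffer_bp
    use <- use[panel$pos[use] >= lo & panel$pos[use] <= hi]
  }
  if (core_step > 1) use <- use[seq(1L, length(use), by = as.integer(core_step))]
  if (!length(use)) stop("no qualifying core sites", call. = FALSE)
  HA <- panel$alleles[hap_rows(panel, pop_samples(popmap, popA)), , drop = FALSE]
  HB <- panel$alleles[hap_rows(panel, pop_samples(popmap, popB)), , drop = FALSE]
  if (nrow(HA) < 4L || nrow(HB) < 4L) stop("both populations need >= 2 samples", call. = FALSE)
  S <- n_sites(panel)
  ihh_both <- function(H, core) {
    r <- ehh_extend(H, seq.int(core, S), panel$pos, cutoff, max_extend_bp)
    l <- ehh_extend(H, seq.int(core, 1L), panel$pos, cutoff, max_extend_bp)
    ihh(list(distance = r$distance, ehh = r$ehh), cutoff) +
      ihh(list(distance = l$distance, ehh = l$ehh), cutoff)
  }
  ia <- vapply(use, function(s) ihh_both(HA, s), numeric(1))
  ib <- vapply(use, function(s) ihh_both(HB, s), numeric(1))
  ok <- ia > 0 & ib > 0
  if (!any(ok)) stop("no qualifying sites (zero iHH everywhere)", call. = FALSE)
  raw <- log(ia[ok] / ib[ok])
  z <- if (length(raw) > 1 && stats::sd(raw) > 0) {
    (raw - mean(raw)) / stats::sd(raw)
  } else {
    rep(0, length(raw))
  }
  out <- tibble::tibble(pos = panel$pos[use][ok], ihh_a = ia[ok], ihh_b = ib[ok],
                        raw = raw, z = z)
  attr(out, "chrom") <- panel$chrom
  class(out) <- c("xpehh_result", class(out))
  out
}

#' Window summary of XP-EHH extreme scores
#'
#' On a non-overlapping window grid (default 20 kb), the window value is
#' the fraction of scored sites with `|z| >= extreme`. Windows with no
#' scored sites are excluded; windows strictly above the
#' `1 - top_fraction` quantile of the ratio are selected and merged.
#'
#' @param result An [xpehh_scan()] result.
#' @param spec Window grid (default non-overlapping 20 kb).
#' @param extreme Extreme-score threshold on `|z|` (default 2).
#' @param top_fraction Fraction of windows to call (default 0.01).
#' @param chrom_len Chromosome length (default: last scored position).
#' @return A list with `track` (windowed extreme-score ratio) and
#'   `regions` (a [candidate_regions()] tibble tagged `"xpehh"`).
#' @export
xpehh_window_summary <- function(result, spec = window_spec(20000, 20000),
                                 extreme = 2, top_fraction = 0.01,
                                 chrom_len = max(result$pos)) {
  chrom <- attr(result, "chrom") %||% "chr"
  windows <- make_windows(chrom, chrom_len, spec)
  idx <- window_site_index(result$pos, windows)
  ratio <- vapply(idx, function(i) {
    if (!length(i)) return(NA_real_)
    mean(abs(result$z[i]) >= extreme)
  }, numeric(1))
  track <- new_windowed_track(windows$chrom, windows$start, windows$end,
                              lengths(idx), ratio, "xpehh_extreme_ratio")
  sel <- strictly_above_quantile(ratio, 1 - top_fraction)
  list(track = track,
       regions = merge_windows_to_regions(windows, sel, "xpehh"))
}
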