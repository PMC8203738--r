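#' Combined selective-sweep scan
#'
#' Runs the configured scans for sweeps in population A against reference
#' population B — the joint FST + log2 pi-ratio tail rule, the XP-EHH
#' extreme-score-ratio windows, and the XP-CLR composite-likelihood scan —
#' and merges their candidate regions with evidence tags.
#'
#' @param panel A [hap_panel()], already site-filtered as desired.
#' @param popmap A [pop_map()].
#' @param pop_a Population scanned for sweeps.
#' @param pop_b Reference population.
#' @param chrom_len Chromosome length in bp.
#' @param methods Subset of `c("fst_pi", "xpehh", "xpclr")`.
#' @param spec Sliding-window grid for diversity/FST (default 20 kb/10 kb).
#' @param criteria A [sweep_criteria()].
#' @param xpehh_args List of extra arguments to [xpehh_scan()].
#' @param xpehh_spec,xpehh_extreme,xpehh_top Window summary settings for
#'   XP-EHH (defaults: non-overlapping 20 kb, `|z| >= 2`, top 1%).
#' @param xpclr_cfg An [xpclr_config()].
#' @param xpclr_spec,xpclr_top Window summary settings for XP-CLR
#'   (defaults 20 kb / 2 kb, top 1%).
#' @param genes Optional gene annotation tibble for [annotate_genes()].
#' @return A list: `regions` (merged [candidate_regions()]), `tracks`
#'   (named list of windowed tracks and scan results), `per_method`
#'   (named list of each method's candidate set).
#' @export
scan_sweeps <- function(panel, popmap, pop_a, pop_b,
                        chrom_len = max(panel$pos),
                        methods = c("fst_pi", "xpehh", "xpclr"),
                        spec = window_spec(20000, 10000),
                        criteria = sweep_criteria(),
                        xpehh_args = list(),
                        xpehh_spec = window_spec(20000, 20000),
                        xpehh_extreme = 2, xpehh_top = 0.01,
                        xpclr_cfg = xpclr_config(),
                        xpclr_spec = window_spec(20000, 2000),
                        xpclr_top = 0.01,
                        genes = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  tracks <- list()
  per_method <- list()
  if ("fst_pi" %in% methods) {
    pi_a <- windowed_pi(panel, pop_a, popmap, spec, chrom_len)
    pi_b <- windowed_pi(panel, pop_b, popmap, spec, chrom_len)
    fst <- weir_cockerham_fst(panel, pop_a, pop_b, popmap, spec, chrom_len)
    ratio <- pi_ratio_log2(pi_b, pi_a)
    fz <- z_transform(fst)
    tracks$pi_a <- pi_a; tracks$pi_b <- pi_b
    tracks$fst <- fst; tracks$fst_z <- fz; tracks$pi_ratio <- ratio
    per_method$fst_pi <- sweep_candidates_fst_pi(fz, ratio, criteria)
  }
  if ("xpehh" %in% methods) {
    xe <- do.call(xpehh_scan,
                  c(list(panel, pop_a, pop_b, popmap), xpehh_args))
    xs <- xpehh_window_summary(xe, xpehh_spec, xpehh_extreme, xpehh_top,
                               chrom_len)
    tracks$xpehh <- xe; tracks$xpehh_ratio <- xs$track
    per_method$xpehh <- xs$regions
  }
  if ("xpclr" %in% methods) {
    xc <- xpclr_scan(panel, pop_b, pop_a, popmap, xpclr_cfg,
                     chrom_len = chrom_len)
    xw <- xpclr_window_summary(xc, xpclr_spec, xpclr_top, chrom_len)
    tracks$xpclr <- xc; tracks$xpclr_window <- xw$track
    per_method$xpclr <- xw$regions
  }
  regions <- merge_region_sets(per_method)
  if (!is.null(genes)) regions <- annotate_genes(regions, genes)
  list(regions = regions, tracks = tracks, per_method = per_method)
}
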