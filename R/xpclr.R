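#' XP-CLR configuration
#'
#' Mirrors the classic command-line contract `-w1 <gwin> <maxsnps>
#' <gridsize> <chrom> -p1 <corrLevel>`: a window measured in Morgans
#' around each grid point, a cap on SNPs per window, a bp spacing of test
#' points, and a correlation level above which linked SNP pairs are
#' down-weighted (1/2 each).
#'
#' @param w_morgan Window size in Morgans around a grid point (default
#'   0.0005; SNPs within `w_morgan / 2` each side enter the composite).
#' @param max_snps Maximum SNPs per window (default 200; the closest are
#'   kept).
#' @param grid_bp Spacing of test points in bp (default 200).
#' @param corr_thresh Dosage-correlation down-weight threshold (default
#'   0.9), applied in the reference population.
#' @param s_grid Selection-coefficient grid; must contain 0 (default 0
#'   plus 20 log-spaced points in `[1e-5, 0.1]`).
#' @param r_bp Uniform recombination rate, Morgans/bp (default 1e-8, i.e.
#'   1 cM/Mb).
#' @return A list of class `xpclr_config`.
#' @export
xpclr_config <- function(w_morgan = 0.0005, max_snps = 200, grid_bp = 200,
                         corr_thresh = 0.9,
                         s_grid = c(0, 10^seq(-5, -1, length.out = 20)),
                         r_bp = 1e-8) {
  stopifnot(w_morgan > 0, max_snps >= 1, grid_bp > 0, r_bp > 0)
  if (!any(s_grid == 0)) stop("s_grid must contain 0", call. = FALSE)
  structure(list(w_morgan = w_morgan, max_snps = as.integer(max_snps),
                 grid_bp = as.integer(grid_bp), corr_thresh = corr_thresh,
                 s_grid = sort(s_grid), r_bp = r_bp),
            class = "xpclr_config")
}

#' Genome-wide drift variance between two populations
#'
#' Method-of-moments estimate of the variance scale omega of the
#' conditional model `p_obj | p_ref ~ N(p_ref, omega * p_ref (1 - p_ref))`:
#' the mean over usable sites of `(p_obj - p_ref)^2 / (p_ref (1 - p_ref))`.
#' Sites fixed in the reference population are excluded.
#'
#' @param panel A [hap_panel()].
#' @param popRef,popObj Reference and object population labels.
#' @param popmap A [pop_map()].
#' @return omega (non-negative scalar).
#' @export
estimate_omega <- function(panel, popRef, popObj, popmap) {
  pr <- allele_counts(panel, hap_rows(panel, pop_samples(popmap, popRef)))$freq
  po <- allele_counts(panel, hap_rows(panel, pop_samples(popmap, popObj)))$freq
  ok <- !is.na(pr) & !is.na(po) & pr > 0 & pr < 1
  if (!any(ok)) stop("no usable sites (all fixed in reference)", call. = FALSE)
  mean((po[ok] - pr[ok])^2 / (pr[ok] * (1 - pr[ok])))
}

## log density of an observed frequency x under N(m, v) truncated to [0,1]
## with the tail mass placed on the boundaries; x in {0,1} uses the mass
log_tnorm_mass <- function(x, m, v) {
  sd <- sqrt(pmax(v, 1e-12))
  lp <- numeric(length(x))
  at0 <- x <= 0
  at1 <- x >= 1
  mid <- !at0 & !at1
  lp[at0] <- stats::pnorm(0, m[at0], sd[at0], log.p = TRUE)
  lp[at1] <- stats::pnorm(1, m[at1], sd[at1], lower.tail = FALSE, log.p = TRUE)
  lp[mid] <- stats::dnorm(x[mid], m[mid], sd[mid], log = TRUE)
  pmax(lp, -745)  # keep finite for the composite sum
}

## per-SNP log-likelihood under the sweep model: each object lineage
## escapes the sweep with probability c = 1 - exp(-r / s); non-escaping
## lineages descend from the single swept haplotype, which carries the
## derived allele with probability p1. Mixture of two truncated normals.
## The drift-scale variance is kept for both components (not shrunk by
## c^2): shrinking lets the likelihood grow without bound whenever the
## observation sits near a component mean, which would break the
## score-zero identity at p_obj == p_ref.
loglik_selected <- function(p2, p1, r, s, omega) {
  if (s == 0) return(log_tnorm_mass(p2, p1, omega * p1 * (1 - p1)))
  c_ <- 1 - exp(-r / s)
  v <- omega * p1 * (1 - p1)
  l1 <- log_tnorm_mass(p2, (1 - c_) + c_ * p1, v) + log(p1)
  l0 <- log_tnorm_mass(p2, c_ * p1, v) + log(1 - p1)
  hi <- pmax(l1, l0)
  hi + log1p(exp(pmin(l1, l0) - hi))
}

#' XP-CLR composite-likelihood selection scan
#'
#' At every grid point the composite log-likelihood of the object
#' population's allele frequencies is maximized over the selection grid
#' and compared with neutrality: `score = 2 (max_s CLL(s) - CLL(0))`.
#' The null model is the truncated-normal drift approximation with
#' variance `omega p_ref (1 - p_ref)`; under selection a lineage escapes
#' the sweep with probability `c = 1 - exp(-r/s)` (r = recombination
#' distance to the grid point in Morgans), giving a two-component mixture
#' centered at `c p_ref` and `(1 - c) + c p_ref`. SNP pairs whose
#' reference-population dosage correlation exceeds `corr_thresh`
#' contribute weight 1/2 each.
#'
#' @param panel A [hap_panel()] (phase not required).
#' @param popRef,popObj Reference and object populations.
#' @param popmap A [pop_map()].
#' @param cfg An [xpclr_config()].
#' @param omega Drift variance; estimated with [estimate_omega()] when `NULL`.
#' @param chrom_len Chromosome length (default: last SNP position).
#' @return Tibble of class `xpclr_track`: `pos` (grid point), `n_snps`,
#'   `score`, `s_hat` (argmax of the grid); attribute `omega`.
#' @export
xpclr_scan <- function(panel, popRef, popObj, popmap, cfg = xpclr_config(),
                       omega = NULL, chrom_len = max(panel$pos)) {
  if (is.null(omega)) omega <- estimate_omega(panel, popRef, popObj, popmap)
  pr <- allele_counts(panel, hap_rows(panel, pop_samples(popmap, popRef)))$freq
  po <- allele_counts(panel, hap_rows(panel, pop_samples(popmap, popObj)))$freq
  usable <- !is.na(pr) & !is.na(po) & pr > 0 & pr < 1
  Dref <- dosage_matrix(panel)[pop_samples(popmap, popRef), , drop = FALSE]
  grid <- seq.int(0L, as.integer(chrom_len), by = cfg$grid_bp)
  half_bp <- (cfg$w_morgan / 2) / cfg$r_bp
  pos <- panel$pos
  res <- lapply(grid, function(x) {
    idx <- which(usable & abs(pos - x) <= half_bp)
    if (!length(idx)) {
      return(list(n = 0L, score = NA_real_, s_hat = NA_real_))
    }
    if (length(idx) > cfg$max_snps) {
      idx <- idx[order(abs(pos[idx] - x))[seq_len(cfg$max_snps)]]
      idx <- sort(idx)
    }
    p1 <- pr[idx]; p2 <- po[idx]
    r <- pmax(abs(pos[idx] - x), 1) * cfg$r_bp
    w <- rep(1, length(idx))
    if (length(idx) > 1) {
      cm <- suppressWarnings(abs(stats::cor(Dref[, idx, drop = FALSE],
                                            use = "pairwise.complete.obs")))
      cm[is.na(cm)] <- 0
      k <- rowSums(cm > cfg$corr_thresh) - 1
      w <- 1 / (1 + k)
    }
    cll <- vapply(cfg$s_grid, function(s) {
      sum(w * loglik_selected(p2, p1, r, s, omega))
    }, numeric(1))
    null <- cll[cfg$s_grid == 0]
    list(n = length(idx), score = 2 * (max(cll) - null),
         s_hat = cfg$s_grid[which.max(cll)])
  })
  out <- tibble::tibble(pos = grid,
                        n_snps = vapply(res, `[[`, integer(1), "n"),
                        score = vapply(res, `[[`, numeric(1), "score"),
                        s_hat = vapply(res, `[[`, numeric(1), "s_hat"))
  attr(out, "omega") <- omega
  attr(out, "chrom") <- panel$chrom
  class(out) <- c("xpclr_track", class(out))
  out
}

#' Window summary of XP-CLR scores
#'
#' Window value = mean score of the grid points inside (default 20 kb
#' windows, 2 kb step); empty windows are missing; windows strictly above
#' the `1 - top_fraction` score quantile are merged into candidate
#' regions.
#'
#' @param track An [xpclr_scan()] track.
#' @param spec Window grid (default 20 kb / 2 kb).
#' @param top_fraction Fraction of windows to call (default 0.01).
#' @param chrom_len Chromosome length (default: last grid position).
#' @return A list with `track` (windowed mean score) and `regions`
#'   (a [candidate_regions()] tibble tagged `"xpclr"`).
#' @export
xpclr_window_summary <- function(track, spec = window_spec(20000, 2000),
                                 top_fraction = 0.01,
                                 chrom_len = max(track$pos)) {
  chrom <- attr(track, "chrom") %||% "chr"
  windows <- make_windows(chrom, chrom_len, spec)
  ## grid points are 0-based coordinates already
  idx <- lapply(seq_len(nrow(windows)), function(i) {
    which(track$pos >= windows$start[i] & track$pos < windows$end[i] &
            !is.na(track$score))
  })
  val <- vapply(idx, function(i) {
    if (!length(i)) NA_real_ else mean(track$score[i])
  }, numeric(1))
  wtrack <- new_windowed_track(windows$chrom, windows$start, windows$end,
                               lengths(idx), val, "xpclr_mean")
  sel <- strictly_above_quantile(val, 1 - top_fraction)
  list(track = wtrack,
       regions = merge_windows_to_regions(windows, sel, "xpclr"))
}
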