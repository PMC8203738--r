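# Independent brute-force oracles. These deliberately re-derive each
# statistic from first principles, sharing no code with the package paths
# they check.

# random biallelic panel; optionally with missing alleles
random_panel <- function(n_samples, n_sites, L = 100000, miss = 0,
                         chrom = "chrT", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pos <- sort(sample.int(L, n_sites))
  H <- matrix(rbinom(2 * n_samples * n_sites, 1,
                     rep(runif(n_sites, 0.1, 0.9), each = 2 * n_samples)),
              nrow = 2 * n_samples)
  if (miss > 0) H[runif(length(H)) < miss] <- NA
  hap_panel(chrom, pos, sprintf("t%02d", seq_len(n_samples)), H)
}

# windowed theta-pi by explicit pairwise Hamming counting over haplotypes
oracle_windowed_pi <- function(panel, rows, spec, chrom_len) {
  H <- panel$alleles[rows, , drop = FALSE]
  starts <- seq(0, chrom_len - 1, by = spec$step)
  starts <- starts[starts < chrom_len]
  vapply(starts, function(w0) {
    sites <- which(panel$pos - 1 >= w0 & panel$pos - 1 < w0 + spec$size)
    tot <- 0
    for (s in sites) {
      a <- H[, s]; a <- a[!is.na(a)]
      n <- length(a)
      if (n < 2) next
      diffs <- 0
      for (i in seq_len(n - 1)) for (j in (i + 1):n) diffs <- diffs + (a[i] != a[j])
      tot <- tot + diffs / choose(n, 2)
    }
    tot / spec$size
  }, numeric(1))
}

# direct transcription of the Weir & Cockerham (1984) two-population
# estimator from genotype counts
oracle_wc_fst_window <- function(panel, rowsA, rowsB, sites) {
  geno <- function(rows, s) {
    h <- matrix(panel$alleles[rows, s], nrow = 2)
    d <- colSums(h)
    d[colSums(is.na(h)) > 0] <- NA
    d
  }
  num <- den <- 0
  for (s in sites) {
    gA <- geno(rowsA, s); gB <- geno(rowsB, s)
    gA <- gA[!is.na(gA)]; gB <- gB[!is.na(gB)]
    n1 <- length(gA); n2 <- length(gB)
    if (n1 < 1 || n2 < 1) next
    p1 <- sum(gA) / (2 * n1); p2 <- sum(gB) / (2 * n2)
    if (p1 == p2 && p1 %in% c(0, 1)) next
    h1 <- mean(gA == 1); h2 <- mean(gB == 1)
    r <- 2
    nbar <- (n1 + n2) / 2
    nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
    a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                        (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    if (!is.finite(a + b + cc)) next  # degenerate site (e.g. one call per pop)
    num <- num + a
    den <- den + a + b + cc
  }
  if (den == 0) NA_real_ else num / den
}

# full-enumeration HWE exact test from multinomial coefficients
oracle_hwe <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  if (nA == 0 || nA == 2 * n) return(1)
  hets <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  pr <- vapply(hets, function(h) {
    aa <- (nA - h) / 2
    exp(lchoose(n, aa) + lchoose(n - aa, h) + h * log(2) - lchoose(2 * n, nA))
  }, numeric(1))
  pr <- pr / sum(pr)
  obs <- pr[hets == nAa]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

# naive EHH: rebuild haplotype classes from scratch at every extension by
# string comparison over the full core..site stretch
oracle_ehh_curve <- function(H, pos, core, direction) {
  sites <- if (direction == "right") core:ncol(H) else core:1
  d <- abs(pos[sites] - pos[core])
  e <- vapply(seq_along(sites), function(k) {
    span <- sites[seq_len(k)]
    keys <- apply(H[, span, drop = FALSE], 1, paste, collapse = ",")
    keep <- !grepl("NA", keys)
    n <- sum(keep)
    if (n < 2) return(NA_real_)
    sum(choose(table(keys[keep]), 2)) / choose(n, 2)
  }, numeric(1))
  list(distance = c(0, d[-1]), ehh = c(1, e[-1]))
}

# quadratic all-pairs exact IBD matcher (independent of match_runs)
oracle_ibd_pairs <- function(panel, min_len, chrom_len = max(panel$pos)) {
  S <- length(panel$pos)
  mid <- floor((panel$pos[-S] + panel$pos[-1]) / 2)
  lb <- c(0, mid); rb <- c(mid, chrom_len)
  out <- list()
  ns <- length(panel$samples)
  for (i in 1:(ns - 1)) for (j in (i + 1):ns) {
    for (h1 in 1:2) for (h2 in 1:2) {
      a <- panel$alleles[2 * i - 2 + h1, ]
      b <- panel$alleles[2 * j - 2 + h2, ]
      eq <- !is.na(a) & !is.na(b) & a == b
      s <- 1
      while (s <= S) {
        if (!eq[s]) { s <- s + 1; next }
        e <- s
        while (e < S && eq[e + 1]) e <- e + 1
        if (rb[e] - lb[s] >= min_len) {
          out[[length(out) + 1]] <- data.frame(
            sample1 = panel$samples[i], hap1 = h1,
            sample2 = panel$samples[j], hap2 = h2,
            start = lb[s], end = rb[e])
        }
        s <- e + 1
      }
    }
  }
  if (!length(out)) {
    return(data.frame(sample1 = character(), hap1 = integer(),
                      sample2 = character(), hap2 = integer(),
                      start = numeric(), end = numeric()))
  }
  do.call(rbind, out)
}

# bp-level union of interval sets (coarse integer membership)
oracle_union_bp <- function(df, L) {
  hit <- logical(L)
  for (k in seq_len(nrow(df))) {
    hit[(df$start[k] + 1):df$end[k]] <- TRUE
  }
  hit
}
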