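test_that("site_pi counts pairwise differences", {
  expect_equal(site_pi(2, 2), 4 / 6)
  expect_equal(site_pi(4, 0), 0)
  expect_equal(site_pi(1, 1), 1)
  expect_true(is.na(site_pi(1, 0)))
})

test_that("windowed_pi equals the brute-force pairwise oracle on random panels", {
  spec <- window_spec(20000, 10000)
  for (trial in 1:10) {
    p <- random_panel(sample(3:10, 1), sample(10:50, 1), L = 60000,
                      miss = ifelse(trial %% 2, 0, 0.1), seed = 100 + trial)
    pm <- pop_map(p$samples, rep("X", length(p$samples)))
    tr <- windowed_pi(p, "X", pm, spec, chrom_len = 60000)
    orc <- oracle_windowed_pi(p, seq_len(nrow(p$alleles)), spec, 60000)
    expect_equal(tr$value, orc, tolerance = 1e-12)
    expect_true(all(tr$value >= 0))
  }
})

test_that("windowed_pi hand example: two sites of pi 2/3 in one 20-kb window", {
  A <- rbind(c(0, 0), c(0, 0), c(1, 1), c(1, 1))  # 2+2 alleles at both sites
  p <- hap_panel("c", c(5000L, 6000L), c("a", "b"), A)
  pm <- pop_map(c("a", "b"), c("X", "X"))
  tr <- windowed_pi(p, "X", pm, window_spec(20000, 20000), chrom_len = 20000)
  expect_equal(tr$value, (2 / 3 + 2 / 3) / 20000, tolerance = 1e-12)
  # SNP-free window -> 0
  tr2 <- windowed_pi(p, "X", pm, window_spec(20000, 20000), chrom_len = 40000)
  expect_equal(tr2$value[2], 0)
  expect_error(windowed_pi(p, "Y", pm), "unknown")
})

test_that("weir_cockerham_fst equals an independent transcription of the 1984 formulas", {
  for (trial in 1:10) {
    p <- random_panel(12, 30, L = 20000, miss = ifelse(trial > 5, 0.08, 0),
                      seed = 200 + trial)
    pm <- pop_map(p$samples, rep(c("A", "B"), each = 6))
    tr <- weir_cockerham_fst(p, "A", "B", pm, window_spec(20000, 20000),
                             chrom_len = 20000)
    orc <- oracle_wc_fst_window(p, hap_rows(p, pop_samples(pm, "A")),
                                hap_rows(p, pop_samples(pm, "B")),
                                seq_along(p$pos))
    expect_equal(tr$value[1], orc, tolerance = 1e-12)
  }
})

test_that("FST is symmetric, bounded and behaves at the extremes", {
  p <- random_panel(20, 40, L = 20000, seed = 31)
  pm <- pop_map(p$samples, rep(c("A", "B"), each = 10))
  spec <- window_spec(20000, 20000)
  ab <- weir_cockerham_fst(p, "A", "B", pm, spec, chrom_len = 20000)
  ba <- weir_cockerham_fst(p, "B", "A", pm, spec, chrom_len = 20000)
  expect_equal(ab$value, ba$value, tolerance = 1e-12)
  expect_true(all(ab$value <= 1, na.rm = TRUE))

  # fixed difference -> FST 1
  n <- 100
  A <- cbind(rep(c(0L, 1L), each = n))
  p2 <- hap_panel("c", 10L, sprintf("s%d", 1:n), A)
  pm2 <- pop_map(p2$samples, rep(c("A", "B"), each = n / 2))
  f <- weir_cockerham_fst(p2, "A", "B", pm2, spec, chrom_len = 20000)
  expect_equal(f$value[1], 1, tolerance = 1e-6)

  # identical frequencies -> near zero (estimator noise, slightly negative)
  set.seed(5)
  A3 <- matrix(rbinom(200 * 20, 1, rep(runif(20, .2, .8), each = 200)), 200)
  p3 <- hap_panel("c", sort(sample.int(20000, 20)), sprintf("s%d", 1:100), A3)
  pm3 <- pop_map(p3$samples, rep(c("A", "B"), 50))
  f3 <- weir_cockerham_fst(p3, "A", "B", pm3, spec, chrom_len = 20000)
  expect_lt(abs(f3$value[1]), 0.05)
})

test_that("pi_ratio_log2 handles ratios, identities and zeros", {
  mk <- function(v) new_windowed_track("c", c(0, 10000), c(20000, 30000),
                                       c(5L, 5L), v, "theta_pi")
  expect_equal(pi_ratio_log2(mk(c(2e-3, 1e-3)), mk(c(1e-3, 1e-3)))$value,
               c(1, 0))
  expect_true(is.na(pi_ratio_log2(mk(c(2e-3, 1e-3)), mk(c(0, 1e-3)))$value[1]))
  bad <- new_windowed_track("c", 0, 20000, 5L, 1e-3, "theta_pi")
  expect_error(pi_ratio_log2(mk(c(1e-3, 1e-3)), bad), "grid")
})

test_that("z_transform standardizes exactly and rejects degenerate tracks", {
  mk <- function(v) new_windowed_track("c", seq(0, by = 1e4, length.out = length(v)),
                                       seq(2e4, by = 1e4, length.out = length(v)),
                                       10L, v, "x")
  z <- z_transform(mk(c(1, 2, 3)))
  expect_equal(z$value, c(-1, 0, 1))
  set.seed(8)
  v <- c(rnorm(50), NA)
  z2 <- z_transform(mk(v))
  expect_equal(mean(z2$value, na.rm = TRUE), 0, tolerance = 1e-12)
  expect_equal(sd(z2$value, na.rm = TRUE), 1, tolerance = 1e-12)
  expect_true(is.na(z2$value[51]))
  expect_error(z_transform(mk(rep(2, 5))), "variance")
})

test_that("sweep_candidates_fst_pi selects the joint tail and applies the SNP rule", {
  nw <- 40
  mkt <- function(v, n = 50L) {
    new_windowed_track("c", seq(0, by = 1e4, length.out = nw),
                       seq(2e4, by = 1e4, length.out = nw), n, v, "x")
  }
  set.seed(9)
  fstv <- rnorm(nw, 0, 0.1); ratio <- rnorm(nw, 0, 0.1)
  fstv[11:13] <- 5; ratio[11:13] <- 5       # windows 11-13 in both tails
  fz <- z_transform(mkt(fstv))
  crit <- sweep_criteria(fst_quantile = 0.9, ratio_quantile = 0.1)
  out <- sweep_candidates_fst_pi(fz, mkt(ratio), crit)
  expect_equal(nrow(out), 1L)
  expect_equal(out$start, 1e5)             # window 11 start (0-based)
  expect_equal(out$end, 1.4e5)             # window 13 end (bookended merge)
  expect_equal(out$evidence, "fst_pi")

  # a window that passes both tails but carries only 9 SNPs is excluded
  fstv2 <- seq(0, 1, length.out = nw); ratio2 <- rev(fstv2)  # opposed tails
  fstv2[12] <- 5; ratio2[12] <- 5                            # joint only at 12
  ns <- rep(50L, nw); ns[12] <- 9L
  out2 <- sweep_candidates_fst_pi(z_transform(mkt(fstv2, ns)), mkt(ratio2, ns), crit)
  expect_equal(nrow(out2), 0L)

  # disjoint tails -> empty
  r2 <- -ratio
  out3 <- sweep_candidates_fst_pi(fz, mkt(r2), crit)
  expect_equal(nrow(out3), 0L)

  # all excluded by min_snps -> warning + empty
  expect_warning(
    out4 <- sweep_candidates_fst_pi(z_transform(mkt(fstv, 3L)), mkt(ratio, 3L), crit),
    "min_snps")
  expect_equal(nrow(out4), 0L)
})
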