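# Small configurations keep the forward simulator affordable here; the
# full fixture is exercised in the acceptance suite.

small_cfg <- function(seed, sweep = NULL, introgression = NULL) {
  sim_config(L = 2e5, mu = 4e-7, r_bp = 2e-7,
             N = c(PL = 60, IL = 60, EC = 40, WC = 40),
             bottleneck_N = 15, bottleneck_gens = 30,
             il_split_gen = 20, ecwc_split_gen = 60, total_gens = 120,
             sweep = sweep, introgression = introgression,
             samples = c(PL = 10, IL = 10, EC = 10, WC = 10), seed = seed)
}

test_that("identical config and seed give identical output", {
  a <- simulate_panel(small_cfg(7))
  b <- simulate_panel(small_cfg(7))
  expect_identical(a$panel, b$panel)
  expect_identical(a$popmap, b$popmap)
  expect_identical(a$truth$tracts, b$truth$tracts)
})

test_that("panel obeys its structural invariants", {
  out <- simulate_panel(small_cfg(3))
  p <- out$panel
  expect_true(all(diff(p$pos) > 0))
  expect_equal(nrow(p$alleles), 2 * length(p$samples))
  expect_true(all(p$alleles %in% c(0L, 1L)))
  ac <- allele_counts(p)
  expect_true(all(ac$n_alt > 0 & ac$n_alt < nrow(p$alleles)))  # segregating
  expect_setequal(unique(out$popmap$pop), c("PL", "IL", "EC", "WC"))
})

test_that("no introgression config yields zero truth tracts", {
  out <- simulate_panel(small_cfg(11))
  expect_equal(nrow(out$truth$tracts), 0L)
  out2 <- simulate_panel(small_cfg(11, introgression = list(
    donor = "IL", recipient = "EC", f = 0, generation = 100, region = NULL)))
  expect_equal(nrow(out2$truth$tracts), 0L)
})

test_that("sustained quarter-size IL loses diversity relative to PL", {
  # IL held at a quarter of PL's size for its whole 100-generation history
  ratios <- vapply(1:8, function(s) {
    out <- simulate_panel(sim_config(
      L = 2e5, mu = 4e-7, r_bp = 2e-7,
      N = c(PL = 60, IL = 15, EC = 40, WC = 40),
      bottleneck_N = 15, bottleneck_gens = 30,
      il_split_gen = 20, ecwc_split_gen = 60, total_gens = 120,
      sweep = NULL, introgression = NULL,
      samples = c(PL = 10, IL = 7, EC = 10, WC = 10), seed = 300 + s))
    pi_of <- function(pop) {
      rows <- hap_rows(out$panel, pop_samples(out$popmap, pop))
      ac <- allele_counts(out$panel, rows)
      sum(site_pi(ac$n_obs - ac$n_alt, ac$n_alt), na.rm = TRUE)
    }
    pi_of("PL") / pi_of("IL")
  }, numeric(1))
  expect_gt(mean(ratios), 1)
  expect_gte(sum(ratios > 1), 7)
})

test_that("neutral single population keeps diversity near 4*N*mu", {
  theta <- 4 * 50 * 3e-7  # per bp
  est <- vapply(1:6, function(s) {
    sp <- simulate_single_pop(50, 3e-7, 2e-7, 1e5, 25, 20, seed = 600 + s)
    ac <- allele_counts(sp$panel)
    sum(site_pi(ac$n_obs - ac$n_alt, ac$n_alt), na.rm = TRUE) / 1e5
  }, numeric(1))
  expect_lt(abs(mean(est) - theta) / theta, 0.25)
})

test_that("sweep allele is driven to high frequency in the target population", {
  cfg <- small_cfg(5, sweep = list(pop = "WC", position = 1e5, s = 0.2,
                                   start_gen = 60, init_freq = 0.2,
                                   min_final_freq = 0.8, retries = 30))
  out <- simulate_panel(cfg)
  expect_equal(out$truth$sweep_pos, 1e5)
  i <- match(1e5, out$panel$pos)
  if (!is.na(i)) {  # site can be monomorphic-fixed in the sample and dropped
    wc <- hap_rows(out$panel, pop_samples(out$popmap, "WC"))
    expect_gte(mean(out$panel$alleles[wc, i]), 0.8)
  } else {
    succeed()
  }
})

test_that("whole-haplotype pulse leaves tracts with plausible lengths", {
  # after g generations the expected tract length is ~ 1/(r*g) bp (200 kb
  # here); chromosome-end truncation shortens and adjacent-tract merging
  # lengthens the observed mean -- factor-2 agreement pooled over seeds
  tl <- unlist(lapply(1:3, function(s) {
    cfg <- sim_config(L = 1e6, mu = 2e-7, r_bp = 2e-7,
                      N = c(PL = 60, IL = 60, EC = 100, WC = 40),
                      bottleneck_N = 20, bottleneck_gens = 20,
                      il_split_gen = 10, ecwc_split_gen = 40, total_gens = 140,
                      sweep = NULL,
                      introgression = list(donor = "IL", recipient = "EC",
                                           f = 0.2, generation = 115, region = NULL),
                      samples = c(PL = 5, IL = 5, EC = 25, WC = 5), seed = 80 + s)
    out <- simulate_panel(cfg)
    out$truth$tracts$end - out$truth$tracts$start
  }))
  expect_gt(length(tl), 30)
  expect_gt(mean(tl), 2e5 / 2)
  expect_lt(mean(tl), 2e5 * 2)
})

test_that("phenotype simulation recovers the planted architecture", {
  set.seed(1)
  n <- 400
  A <- matrix(rbinom(2 * n * 5, 1, 0.4), nrow = 2 * n)
  p <- hap_panel("c", c(10L, 20L, 30L, 40L, 50L), sprintf("s%03d", 1:n), A)

  # h2 -> 1: phenotype collapses onto the dosage
  ph <- simulate_phenotype(p, 3L, beta = 1, h2 = 0.999, seed = 2)
  expect_gt(cor(ph$value, dosage_matrix(p)[, 3]), 0.99)

  # beta = 0: no association
  cors <- vapply(1:10, function(s) {
    cor(simulate_phenotype(p, 3L, 0, 0.5, seed = s)$value, dosage_matrix(p)[, 3])
  }, numeric(1))
  expect_lt(abs(mean(cors)), 0.05)

  # h2 = 0.15 recovered by regression R^2
  r2s <- vapply(1:10, function(s) {
    y <- simulate_phenotype(p, 3L, 0.5, 0.15, seed = 100 + s)$value
    summary(lm(y ~ dosage_matrix(p)[, 3]))$r.squared
  }, numeric(1))
  expect_lt(abs(mean(r2s) - 0.15), 0.05)

  # monomorphic causal site errors
  A2 <- A; A2[, 5] <- 0L
  p2 <- hap_panel("c", p$pos, p$samples, A2)
  expect_error(simulate_phenotype(p2, 5L, 1, 0.5, seed = 1), "monomorphic")
})

test_that("default fixture echoes its configuration", {
  cfg <- sim_config(seed = 42)
  expect_equal(cfg$sweep$position, 500000)
  expect_equal(cfg$introgression$f, 0.2)
  expect_equal(sum(cfg$samples), 100)
  expect_error(sim_config(), "seed")
})
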