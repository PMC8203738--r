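test_that("identical samples share IBD over the whole chromosome (4 hap pairs)", {
  set.seed(12)
  h <- rbinom(50, 1, 0.5)
  A <- rbind(h, h, h, h)
  p <- hap_panel("c", sort(sample.int(1e6, 50)), c("a", "b"), A)
  seg <- detect_ibd_segments(p, min_length_bp = 1e5, chrom_len = 1e6)
  expect_equal(nrow(seg), 4L)
  expect_true(all(seg$start == 0))
  expect_true(all(seg$end == 1e6))
})

test_that("detected segments equal the quadratic all-pairs oracle", {
  for (trial in 1:4) {
    p <- random_panel(8, 120, L = 5e5, seed = 500 + trial)
    seg <- detect_ibd_segments(p, min_length_bp = 3e4, chrom_len = 5e5)
    orc <- oracle_ibd_pairs(p, 3e4, 5e5)
    key <- function(d) sort(paste(pmin(d$sample1, d$sample2),
                                  pmax(d$sample1, d$sample2),
                                  d$start, d$end))
    expect_identical(key(seg), key(orc))
  }
})

test_that("a planted shared tract is recovered with near-exact endpoints", {
  set.seed(31)
  n <- 10
  S <- 400
  pos <- sort(sample.int(1e6, S))
  H <- matrix(rbinom(2 * n * S, 1, rep(runif(S, 0.2, 0.8), each = 2 * n)), 2 * n)
  inwin <- which(pos >= 3e5 & pos < 6e5)
  H[3, inwin] <- H[7, inwin]  # sample 2 hap 1 <- sample 4 hap 1
  p <- hap_panel("c", pos, sprintf("s%d", 1:n), H)
  seg <- detect_ibd_segments(p, min_length_bp = 1e5, chrom_len = 1e6)
  hit <- seg[(seg$sample1 == "s2" & seg$sample2 == "s4") |
               (seg$sample1 == "s4" & seg$sample2 == "s2"), ]
  expect_gte(nrow(hit), 1L)
  main <- hit[which.max(hit$end - hit$start), ]
  gap <- max(diff(pos[max(1, min(inwin) - 2):min(S, max(inwin) + 2)]))
  expect_lt(abs(main$start - 3e5), gap + 1)
  expect_lt(abs(main$end - 6e5), gap + 1)
})

test_that("independent haplotypes yield no long segments", {
  hits <- vapply(1:10, function(s) {
    p <- random_panel(6, 1000, L = 1e6, seed = 700 + s)
    nrow(detect_ibd_segments(p, min_length_bp = 1e5, chrom_len = 1e6))
  }, numeric(1))
  expect_gte(sum(hits == 0), 9)
})

test_that("nIBD counts tracks per window normalized by donor number", {
  donors <- sprintf("d%02d", 1:10)
  seg <- ibd_segments(rep("c1", 4), 1, donors[1:4], 1, "chr1",
                      c(0, 1000, 2000, 3000), rep(9000, 4))
  tr <- nibd(seg, "c1", donors, window_spec(10000, 5000), chrom_len = 2e4)
  expect_equal(tr$value[1], 0.4)       # 4 tracks from 4 of 10 donors
  expect_equal(tr$value[3], 0)         # window [10k,20k): nothing

  # one donor sharing on both haplotypes -> 2 tracks -> 0.2
  seg2 <- ibd_segments(c("c1", "c1"), c(1, 2), c("d01", "d01"), c(1, 2),
                       "chr1", c(0, 0), c(9000, 9000))
  tr2 <- nibd(seg2, "c1", donors, window_spec(10000, 5000), chrom_len = 2e4)
  expect_equal(tr2$value[1], 0.2)
  # donor-counting mode collapses them
  tr3 <- nibd(seg2, "c1", donors, window_spec(10000, 5000), chrom_len = 2e4,
              count = "donors")
  expect_equal(tr3$value[1], 0.1)
  expect_error(nibd(seg, "d01", donors, chrom_len = 2e4), "donor")
})

test_that("rIBD is the nIBD difference and negates under donor swap", {
  donors_il <- sprintf("i%d", 1:5)
  donors_pl <- sprintf("p%d", 1:5)
  seg <- ibd_segments(c("c1", "c1", "c1"), 1,
                      c("i1", "i2", "p1"), 1, "chr1",
                      c(0, 0, 5000), c(8000, 12000, 9000))
  tr <- ribd_track(seg, "c1", donors_il, donors_pl,
                   window_spec(10000, 5000), chrom_len = 3e4)
  # window 1 [0,10k): 2 IL tracks (0.4), 1 PL track (0.2)
  expect_equal(tr$ribd[1], 2 / 5 - 1 / 5, tolerance = 1e-12)
  swapped <- ribd_track(seg, "c1", donors_pl, donors_il,
                        window_spec(10000, 5000), chrom_len = 3e4)
  expect_equal(swapped$ribd, -tr$ribd, tolerance = 1e-12)
  # identical donor sets -> all zero (and so Z is undefined)
  expect_error(ribd_track(seg, "c1", donors_il, donors_il,
                          window_spec(10000, 5000), chrom_len = 3e4), "disjoint")
})

test_that("introgression_regions flags Z>2 windows and merges them", {
  set.seed(10)
  nw <- 1000
  v <- rnorm(nw)
  v[301:305] <- 5
  tr <- tibble::tibble(chrom = "c", start = seq(0, by = 5000, length.out = nw),
                       end = seq(10000, by = 5000, length.out = nw),
                       ribd = v, z = (v - mean(v)) / sd(v))
  class(tr) <- c("ribd_track", class(tr))
  reg <- introgression_regions(tr, 2)
  big <- reg[which.max(reg$end - reg$start), ]
  expect_equal(big$start, tr$start[301])
  expect_equal(big$end, tr$end[305])
  expect_equal(big$evidence, "ribd")
  # threshold 0 on all-positive z -> one genome-spanning region
  tr2 <- tr; tr2$z <- abs(tr2$z) + 0.1
  reg2 <- introgression_regions(tr2, 0)
  expect_equal(nrow(reg2), 1L)
  expect_equal(reg2$start, 0L)
})

test_that("proportion_introgressed unions overlaps before summing", {
  expect_equal(proportion_introgressed(
    candidate_regions("c", 100000, 200000, "ribd"), 1e6), 0.1)
  expect_equal(proportion_introgressed(candidate_regions(), 1e6), 0)
  two <- candidate_regions(c("c", "c"), c(100000, 140000), c(160000, 200000), "ribd")
  expect_equal(proportion_introgressed(two, 1e6), 0.1)
})

test_that("rIBD elevates over a planted introgressed region in simulation", {
  cfg <- sim_config(L = 5e5, mu = 4e-7, r_bp = 2e-7,
                    N = c(PL = 60, IL = 60, EC = 60, WC = 40),
                    bottleneck_N = 20, bottleneck_gens = 30,
                    il_split_gen = 20, ecwc_split_gen = 70, total_gens = 170,
                    sweep = NULL,
                    introgression = list(donor = "IL", recipient = "EC",
                                         f = 0.25, generation = 140,
                                         region = c(150000, 250000)),
                    samples = c(PL = 15, IL = 15, EC = 15, WC = 5), seed = 3)
  out <- simulate_panel(cfg)
  pm <- out$popmap
  tr <- ribd_track(out$panel, pop_samples(pm, "EC"),
                   pop_samples(pm, "IL"), pop_samples(pm, "PL"),
                   window_spec(10000, 5000), chrom_len = 5e5,
                   min_length_bp = 3e4)
  inreg <- tr$start >= 150000 & tr$end <= 250000
  expect_gt(mean(tr$ribd[inreg]), mean(tr$ribd[!inreg]))
})
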