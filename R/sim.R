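#' Simulation configuration
#'
#' Parameters of the forward-in-time Wright-Fisher simulator. The default
#' values are the package's desk-scale study conditions: a four-population
#' history (an ancestral landrace pool PL, an improved-landrace branch IL
#' founded through a bottleneck, and two modern-cultivar branches EC and WC
#' split from IL), a hard sweep in WC, and a localized introgression pulse
#' from IL into EC. Mutation and recombination rates are scaled up relative
#' to the per-generation rates of a long-lived tree genome so that a 1-Mb,
#' 100-diploid panel carries realistic numbers of segregating sites; the
#' per-site peach-like rate 7.7e-9 can be supplied for unscaled runs.
#'
#' Timeline (forward generations, sampling at `total_gens`):
#' generation 0 founds PL at mutation-drift equilibrium; IL splits from PL
#' at `il_split_gen` through a bottleneck of size `bottleneck_N` lasting
#' `bottleneck_gens` generations; EC and WC split from IL at
#' `ecwc_split_gen`; the sweep allele enters WC at `sweep$start_gen`; the
#' introgression pulse hits EC at `introgression$generation`.
#'
#' @param L Sequence length in bp.
#' @param mu Per-bp per-generation mutation rate.
#' @param r_bp Recombination rate in Morgans per bp.
#' @param N Named diploid population sizes (`PL`, `IL`, `EC`, `WC`).
#' @param bottleneck_N,bottleneck_gens IL founding bottleneck size and duration.
#' @param il_split_gen,ecwc_split_gen,total_gens Split times and total length
#'   of the simulation, in forward generations.
#' @param sweep `NULL` or a list with `pop`, `position` (1-based bp), `s`
#'   (homozygote advantage; heterozygote `1 + s/2`), `start_gen`,
#'   `init_freq` (standing frequency at introduction), `min_final_freq`
#'   (success condition at sampling) and `retries`.
#' @param introgression `NULL` or a list with `donor`, `recipient`, `f`
#'   (fraction of recipient haplotypes replaced), `generation`, and
#'   optional `region = c(start, end)` (0-based half-open) restricting the
#'   replaced material; `NULL` region replaces whole haplotypes.
#' @param samples Named vector of diploid sample sizes per population.
#' @param seed Mandatory integer seed; identical configs give identical output.
#' @param chrom Chromosome name for the emitted panel.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(L = 1e6,
                       mu = 3e-7,
                       r_bp = 2e-7,
                       N = c(PL = 500, IL = 30, EC = 900, WC = 900),
                       bottleneck_N = 300,
                       bottleneck_gens = 10,
                       il_split_gen = 40,
                       ecwc_split_gen = 50,
                       total_gens = 220,
                       sweep = list(pop = "WC", position = 500000, s = 0.05,
                                    start_gen = 70, init_freq = 0.35,
                                    origin = "single",
                                    min_final_freq = 0.95, retries = 20),
                       introgression = list(donor = "IL", recipient = "EC",
                                            f = 0.2, generation = 170,
                                            region = c(250000, 350000)),
                       samples = c(PL = 25, IL = 25, EC = 25, WC = 25),
                       seed,
                       chrom = "chr1") {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(L > 0, mu >= 0, r_bp >= 0, all(N > 0),
            bottleneck_N > 0, bottleneck_gens >= 0,
            il_split_gen >= 0, ecwc_split_gen >= il_split_gen + bottleneck_gens,
            total_gens > ecwc_split_gen)
  if (!is.null(sweep)) {
    stopifnot(sweep$s >= 0, sweep$position >= 1, sweep$position <= L,
              sweep$init_freq > 0, sweep$init_freq < 1)
    sweep <- utils::modifyList(list(init_freq = 0.35, origin = "single",
                                    min_final_freq = 0.95,
                                    retries = 20, start_gen = ecwc_split_gen), sweep)
  }
  if (!is.null(introgression)) {
    stopifnot(introgression$f >= 0, introgression$f <= 1)
  }
  if (any(samples > N[names(samples)])) {
    stop("sample sizes cannot exceed population sizes", call. = FALSE)
  }
  structure(list(L = as.integer(L), mu = mu, r_bp = r_bp, N = N,
                 bottleneck_N = bottleneck_N, bottleneck_gens = bottleneck_gens,
                 il_split_gen = il_split_gen, ecwc_split_gen = ecwc_split_gen,
                 total_gens = total_gens, sweep = sweep,
                 introgression = introgression, samples = samples,
                 seed = as.integer(seed), chrom = chrom),
            class = "sim_config")
}

## ---- low-level engine ----------------------------------------------------

## registry of used positions (infinite-sites: collisions redrawn)
new_site_registry <- function(L) {
  e <- new.env(parent = emptyenv())
  e$used <- raw(L)
  e
}

draw_positions <- function(n, L, reg) {
  out <- integer(0)
  while (length(out) < n) {
    cand <- sample.int(L, n - length(out), replace = TRUE)
    cand <- unique(cand[reg$used[cand] == as.raw(0)])
    if (length(cand)) {
      reg$used[cand] <- as.raw(1)
      out <- c(out, cand)
    }
  }
  out
}

## equilibrium standing variation: S ~ Poisson(theta * a_{2N-1}),
## derived-allele counts from the neutral frequency spectrum (~ 1/i)
init_pop <- function(N, mu_total, L, reg) {
  n2 <- 2L * N
  theta <- 4 * N * mu_total
  a <- sum(1 / seq_len(n2 - 1L))
  S <- stats::rpois(1, theta * a)
  H <- matrix(0L, nrow = n2, ncol = S)
  if (S > 0) {
    counts <- sample.int(n2 - 1L, S, replace = TRUE, prob = 1 / seq_len(n2 - 1L))
    for (s in seq_len(S)) H[sample.int(n2, counts[s]), s] <- 1L
  }
  list(H = H, pos = draw_positions(S, L, reg), N = N,
       anc = NULL, marker_pos = NULL, sweep_pos = NA_integer_)
}

## evolve one population for `gens` generations; the generation loop
## (reproduction, recombination, mutation, selection, ancestry markers)
## runs in compiled code, drawing from R's RNG stream
evolve_pop <- function(state, gens, N_traj, mu_total, r_total, L, s = 0,
                       reg = NULL, prune_every = 5L) {
  if (gens == 0L) return(state)
  if (length(N_traj) == 1L) N_traj <- rep(N_traj, gens)
  res <- wf_epoch_cpp(state$H, as.numeric(state$pos), as.integer(N_traj),
                      mu_total, r_total, L, s,
                      if (is.na(state$sweep_pos)) -1 else as.numeric(state$sweep_pos),
                      state$anc, state$marker_pos, reg$used, as.integer(prune_every))
  state$H <- res$H
  state$pos <- res$pos
  if (!is.null(state$anc)) state$anc <- res$anc
  state$N <- N_traj[gens]
  state
}

## found a child population by sampling founder haplotypes from the parent
found_pop <- function(parent, N_child) {
  rows <- sample.int(nrow(parent$H), 2L * N_child, replace = TRUE)
  list(H = parent$H[rows, , drop = FALSE], pos = parent$pos, N = N_child,
       anc = NULL, marker_pos = NULL, sweep_pos = NA_integer_)
}

## place the sweep allele on `round(2N * init_freq)` haplotypes. A hard
## sweep requires a single mutational origin, so in "single" mode the
## initial carriers are copies of one randomly chosen haplotype (a young
## allele still riding its ancestral background); "standing" mode puts
## the allele on distinct random backgrounds (soft sweep).
introduce_sweep <- function(state, position, init_freq, reg,
                            origin = c("single", "standing"),
                            origin_span_bp = 4e5) {
  origin <- match.arg(origin)
  position <- as.numeric(position)
  hit <- match(position, state$pos)
  if (!is.na(hit)) {  # unlikely: a random mutation landed exactly there
    state$H <- state$H[, -hit, drop = FALSE]
    state$pos <- state$pos[-hit]
  }
  reg$used[position] <- as.raw(1)
  n2 <- nrow(state$H)
  k <- max(1L, round(n2 * init_freq))
  carriers <- sample.int(n2, k)
  if (origin == "single" && k > 1L) {
    ## share one ancestral core haplotype around the selected site only:
    ## carriers keep their own backgrounds outside the span, as lineage
    ## history would have recombined them apart already
    span <- which(abs(state$pos - position) <= origin_span_bp / 2)
    state$H[carriers[-1L], span] <- rep(state$H[carriers[1L], span],
                                        each = k - 1L)
  }
  col <- matrix(0L, n2, 1L)
  col[carriers, 1L] <- 1L
  state$H <- cbind(state$H, col)
  state$pos <- c(state$pos, position)
  state$sweep_pos <- position
  state
}

sweep_freq <- function(state) {
  sc <- match(state$sweep_pos, state$pos)
  if (is.na(sc)) 0 else mean(state$H[, sc])
}

## project haplotype rows defined over `pos_from` onto `pos_to` (union
## superset); absent sites are ancestral (0)
project_rows <- function(H, pos_from, pos_to) {
  out <- matrix(0L, nrow(H), length(pos_to))
  out[, match(pos_from, pos_to)] <- H
  out
}

## ---- panel assembly ------------------------------------------------------

sample_pop_rows <- function(state, k) {
  ind <- sample.int(state$N, k)
  rows <- as.vector(rbind(2L * ind - 1L, 2L * ind))
  list(rows = rows, ind = ind)
}

anc_tracts <- function(anc_rows, marker_pos, spacing, L, samples) {
  out <- list()
  for (i in seq_len(nrow(anc_rows))) {
    r <- rle(anc_rows[i, ] == 1L)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        sample = samples[(i + 1L) %/% 2L],
        hap = ((i - 1L) %% 2L) + 1L,
        start = max(0, marker_pos[starts[j]] - spacing / 2),
        end = min(L, marker_pos[ends[j]] + spacing / 2))
    }
  }
  if (!length(out)) {
    return(tibble::tibble(sample = character(), hap = integer(),
                          start = numeric(), end = numeric()))
  }
  dplyr::bind_rows(out)
}

#' Simulate a phased panel with known truth
#'
#' Runs the forward Wright-Fisher model described in [sim_config()]:
#' equilibrium standing variation, per-generation Poisson recombination and
#' infinite-sites mutation, a fitness-based hard sweep (`1 + s`
#' homozygote, `1 + s/2` heterozygote) and a donor-tracked introgression
#' pulse. When the sweep allele fails to reach `min_final_freq` the
#' post-introduction epoch is re-run (fresh draws from the same stream) up
#' to `retries` times.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `panel` ([hap_panel()]), `popmap`
#'   ([pop_map()]) and `truth` (list: `sweep_pos`, `sweep_pop`, `tracts`
#'   tibble of introgressed segments in sampled recipients, `config`).
#' @export
simulate_panel <- function(cfg) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)
  L <- cfg$L; mu_total <- cfg$mu * L; r_total <- cfg$r_bp * L
  reg <- new_site_registry(L)
  spacing <- 500
  marker_pos <- seq(spacing / 2, L, by = spacing)

  ## PL: ancestral pool, evolved to the end
  pl <- init_pop(cfg$N[["PL"]], mu_total, L, reg)
  pl <- evolve_pop(pl, cfg$il_split_gen, cfg$N[["PL"]], mu_total, r_total, L, reg = reg)
  pl_at_split <- pl
  pl <- evolve_pop(pl, cfg$total_gens - cfg$il_split_gen, cfg$N[["PL"]],
                   mu_total, r_total, L, reg = reg)

  ## IL: bottleneck founding, then recovery; snapshots for EC/WC founding
  ## and for the introgression pulse
  il <- found_pop(pl_at_split, cfg$bottleneck_N)
  il <- evolve_pop(il, cfg$bottleneck_gens, cfg$bottleneck_N, mu_total, r_total,
                   L, reg = reg)
  il <- evolve_pop(il, cfg$ecwc_split_gen - cfg$il_split_gen - cfg$bottleneck_gens,
                   cfg$N[["IL"]], mu_total, r_total, L, reg = reg)
  il_at_split <- il
  pulse_gen <- if (!is.null(cfg$introgression)) cfg$introgression$generation else NA
  if (!is.na(pulse_gen)) {
    il <- evolve_pop(il, pulse_gen - cfg$ecwc_split_gen, cfg$N[["IL"]],
                     mu_total, r_total, L, reg = reg)
    il_at_pulse <- il
    il <- evolve_pop(il, cfg$total_gens - pulse_gen, cfg$N[["IL"]],
                     mu_total, r_total, L, reg = reg)
  } else {
    il <- evolve_pop(il, cfg$total_gens - cfg$ecwc_split_gen, cfg$N[["IL"]],
                     mu_total, r_total, L, reg = reg)
  }

  ## EC: receives the pulse, ancestry-tracked afterwards
  ec <- found_pop(il_at_split, cfg$N[["EC"]])
  if (!is.na(pulse_gen) && cfg$introgression$f > 0) {
    ec <- evolve_pop(ec, pulse_gen - cfg$ecwc_split_gen, cfg$N[["EC"]],
                     mu_total, r_total, L, reg = reg)
    n2 <- nrow(ec$H)
    n_repl <- round(cfg$introgression$f * n2)
    upos <- sort(unique(c(ec$pos, il_at_pulse$pos)))
    ec$H <- project_rows(ec$H, ec$pos, upos)
    donorH <- project_rows(il_at_pulse$H, il_at_pulse$pos, upos)
    ec$pos <- upos
    ec$anc <- matrix(0L, n2, length(marker_pos))
    ec$marker_pos <- marker_pos
    if (n_repl > 0) {
      rows <- sample.int(n2, n_repl)
      drows <- sample.int(nrow(donorH), n_repl, replace = n_repl > nrow(donorH))
      regn <- cfg$introgression$region
      if (is.null(regn)) {
        ec$H[rows, ] <- donorH[drows, ]
        ec$anc[rows, ] <- 1L
      } else {
        incol <- which((upos - 1L) >= regn[1] & (upos - 1L) < regn[2])
        ec$H[rows, incol] <- donorH[drows, incol]
        inm <- which(marker_pos >= regn[1] & marker_pos < regn[2])
        ec$anc[rows, inm] <- 1L
      }
    }
    ec <- evolve_pop(ec, cfg$total_gens - pulse_gen, cfg$N[["EC"]],
                     mu_total, r_total, L, reg = reg)
  } else {
    ec <- evolve_pop(ec, cfg$total_gens - cfg$ecwc_split_gen, cfg$N[["EC"]],
                     mu_total, r_total, L, reg = reg)
  }

  ## WC: sweep branch, re-run on sweep loss
  run_wc <- function() {
    wc <- found_pop(il_at_split, cfg$N[["WC"]])
    gens <- cfg$total_gens - cfg$ecwc_split_gen
    if (is.null(cfg$sweep)) {
      return(evolve_pop(wc, gens, cfg$N[["WC"]], mu_total, r_total, L, reg = reg))
    }
    pre <- cfg$sweep$start_gen - cfg$ecwc_split_gen
    wc <- evolve_pop(wc, pre, cfg$N[["WC"]], mu_total, r_total, L, reg = reg)
    wc <- introduce_sweep(wc, cfg$sweep$position, cfg$sweep$init_freq, reg,
                          origin = cfg$sweep$origin)
    evolve_pop(wc, gens - pre, cfg$N[["WC"]], mu_total, r_total, L,
               s = cfg$sweep$s, reg = reg)
  }
  wc <- run_wc()
  if (!is.null(cfg$sweep)) {
    tries <- 0L
    while (sweep_freq(wc) < cfg$sweep$min_final_freq) {
      tries <- tries + 1L
      if (tries > cfg$sweep$retries) {
        stop("sweep allele lost in all ", cfg$sweep$retries, " retries", call. = FALSE)
      }
      wc <- run_wc()
    }
  }

  ## sample and assemble
  pops <- list(PL = pl, IL = il, EC = ec, WC = wc)
  samp <- lapply(names(pops), function(p) sample_pop_rows(pops[[p]], cfg$samples[[p]]))
  names(samp) <- names(pops)
  upos <- sort(unique(unlist(lapply(pops, `[[`, "pos"))))
  blocks <- lapply(names(pops), function(p) {
    project_rows(pops[[p]]$H[samp[[p]]$rows, , drop = FALSE], pops[[p]]$pos, upos)
  })
  A <- do.call(rbind, blocks)
  keep <- colSums(A) > 0L & colSums(A) < nrow(A)
  A <- A[, keep, drop = FALSE]
  upos <- upos[keep]
  samples <- unlist(lapply(names(pops), function(p) {
    sprintf("%s%02d", p, seq_len(cfg$samples[[p]]))
  }))
  panel <- hap_panel(cfg$chrom, upos, samples, A, phased = TRUE)
  popmap <- pop_map(samples, rep(names(pops), times = cfg$samples[names(pops)]))

  ec_samples <- samples[popmap$pop == "EC"]
  tracts <- if (!is.null(ec$anc)) {
    anc_tracts(ec$anc[samp$EC$rows, , drop = FALSE], marker_pos, spacing, L, ec_samples)
  } else {
    tibble::tibble(sample = character(), hap = integer(),
                   start = numeric(), end = numeric())
  }
  truth <- list(
    sweep_pos = if (!is.null(cfg$sweep)) cfg$sweep$position else NA_integer_,
    sweep_pop = if (!is.null(cfg$sweep)) cfg$sweep$pop else NA_character_,
    tracts = tracts, config = cfg)
  list(panel = panel, popmap = popmap, truth = truth)
}

#' Simulate a single neutral population
#'
#' Convenience wrapper: one population at constant size, no sweep, no
#' introgression. Used for calibration checks (e.g. pairwise diversity
#' close to `4 N mu`).
#'
#' @param N Diploid size.
#' @param mu Per-bp mutation rate.
#' @param r_bp Recombination rate, Morgans/bp.
#' @param L Length in bp.
#' @param gens Generations to evolve after the equilibrium start.
#' @param n_sample Diploids to sample.
#' @param seed Mandatory seed.
#' @param chrom Chromosome name.
#' @return A list with `panel` and `popmap` (single population "POP").
#' @export
simulate_single_pop <- function(N, mu, r_bp, L, gens, n_sample, seed,
                                chrom = "chr1") {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  reg <- new_site_registry(L)
  st <- init_pop(N, mu * L, L, reg)
  st <- evolve_pop(st, gens, N, mu * L, r_bp * L, L, reg = reg)
  sp <- sample_pop_rows(st, n_sample)
  A <- st$H[sp$rows, , drop = FALSE]
  keep <- which(colSums(A) > 0L & colSums(A) < nrow(A))
  keep <- keep[order(st$pos[keep])]
  samples <- sprintf("S%03d", seq_len(n_sample))
  list(panel = hap_panel(chrom, st$pos[keep], samples, A[, keep, drop = FALSE]),
       popmap = pop_map(samples, rep("POP", n_sample)))
}

#' Simulate a SNP-linked quantitative phenotype
#'
#' `y = beta * dosage + e`, with the environmental variance chosen so that
#' the causal SNP explains `h2` of `var(y)` in expectation:
#' `var(e) = beta^2 var(dosage) (1 - h2) / h2`.
#'
#' @param panel A [hap_panel()].
#' @param causal_site Site index of the causal SNP (must be polymorphic).
#' @param beta True allelic effect.
#' @param h2 Heritability of the causal SNP, in (0, 1).
#' @param seed Mandatory seed.
#' @return Tibble with columns `sample`, `value`, plus attributes
#'   `causal_site` and `beta`.
#' @export
simulate_phenotype <- function(panel, causal_site, beta, h2, seed) {
  if (h2 <= 0 || h2 >= 1) stop("h2 must be in (0, 1)", call. = FALSE)
  d <- dosage_matrix(panel, causal_site)[, 1]
  vg <- stats::var(d, na.rm = TRUE)
  if (is.na(vg) || vg == 0) stop("causal site is monomorphic", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ve <- beta^2 * vg * (1 - h2) / h2
  if (beta == 0) ve <- 1  # pure noise phenotype
  y <- beta * d + stats::rnorm(length(d), 0, sqrt(ve))
  out <- tibble::tibble(sample = panel$samples, value = as.numeric(y))
  attr(out, "causal_site") <- causal_site
  attr(out, "beta") <- beta
  out
}

#' The documented desk-scale fixture
#'
#' [sim_config()] defaults with a fixed seed: 4 populations of 25 sampled
#' diploids on 1 Mb, a hard sweep at 500 kb in WC and a 100-kb
#' introgressed segment from IL in 20% of EC haplotypes.
#'
#' @param seed Seed (default 42, the documented fixture).
#' @return As [simulate_panel()].
#' @export
default_fixture <- function(seed = 42) {
  simulate_panel(sim_config(seed = seed))
}
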