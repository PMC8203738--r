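---
title: "Scanning phased panels for selection, introgression and haplotype-trait signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning phased panels for selection, introgression and haplotype-trait signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

popscan implements the windowed population-genomic statistics that
domestication and breeding studies use to locate selected and introgressed
genome regions in phased SNP panels, together with a forward simulator that
generates panels with known truth for validating the whole chain. This
vignette records the models, the parameter choices that matter, and the
design decisions a user should know before trusting a scan.

```{r setup, message = FALSE}
library(popscan)
```

## The statistics

**Windowed diversity and differentiation.** Per-site nucleotide diversity is
the unbiased pairwise estimator `ref*alt / choose(n, 2)`; window values sum
the per-site values and divide by the *full window length* in bp, matching
the convention of the standard VCF windowing tools (the denominator is not
the number of accessible sites — comparisons across panels with different
missingness should keep that in mind). FST uses the Weir–Cockerham (1984)
variance components with the window value as a ratio of sums,
`sum(a) / sum(a+b+c)`, computed from diploid genotypes so that observed
heterozygosity enters the small-sample corrections. Windows default to
20 kb sliding with a 10-kb step, anchored at coordinate 0.

**The joint sweep rule.** A window is a sweep candidate for population A
against reference B when it simultaneously (i) holds at least `min_snps = 10`
SNPs, (ii) lies strictly above the 95% quantile of Z-transformed FST, and
(iii) lies in the 5% tail of `log2(pi_B / pi_A)`. Bookended selected windows
merge into regions. Two policies here are deliberate:

* *Tail orientation.* A sweep in A depresses `pi_A` and therefore *raises*
  `log2(pi_B/pi_A)`; the default tail is the upper one. The literal
  "bottom 5%" reading (which flags elevated diversity in A) remains
  selectable via `sweep_criteria(ratio_tail = "lower")` for users who want
  the opposite contrast.
* *Strict quantiles.* Thresholds are empirical quantiles over non-missing,
  SNP-sufficient windows, with strict inequality; ties at the threshold are
  excluded. This makes candidate calls deterministic and conservative: a
  constant track yields no candidates.
* Windows where either diversity is zero give a missing ratio rather than
  an infinite one, and missing windows are never selected.

**XP-EHH.** Extended haplotype homozygosity from a core site is the
probability that two haplotypes drawn from a population are identical over
the inclusive interval from the core, computed by incremental class
refinement; the curve starts at 1 and is truncated at the 0.05 crossing
(linearly interpolated for the integral). iHH integrates both directions;
the raw score is `ln(iHH_A / iHH_B)` and is standardized genome-wide.
Scores are antisymmetric in the population swap by construction. Window
summarization uses non-overlapping 20-kb windows, the fraction of sites
with `|z| >= 2` as the window value, and the top 1% of windows as
candidates. Cores are taken over all haplotypes of each population (no
ancestral-allele polarization — the scan is two-sided in `|z|`). Two
desk-scale controls are exposed: `max_extend_bp` bounds the integration
span (both populations are truncated identically), and `edge_buffer_bp`
excludes cores so close to the end of a short contig that the one-sided
truncation would inflate their score variance. On chromosome-scale data
both can be left at their permissive defaults.

**XP-CLR.** The composite-likelihood differentiation scan follows the
classic two-population model: the genome-wide drift scale `omega` is the
method-of-moments mean of `(p_obj - p_ref)^2 / (p_ref(1 - p_ref))`, and the
null density of an object-population frequency is a normal with that
variance, truncated to [0, 1] with the tail mass on the boundaries. Under
selection, a lineage at recombination distance `r` Morgans escapes the
sweep with probability `c = 1 - exp(-r/s)`; non-escaping lineages descend
from the swept haplotype, which carries the derived allele with probability
`p_ref`, giving a two-component mixture centred at `c*p_ref` and
`(1-c) + c*p_ref`. The drift-scale variance is kept for both components
rather than shrunk by `c^2`: shrinking lets the likelihood diverge whenever
an observation sits near a component mean, which would break the identity
that the score is exactly zero when object and reference frequencies agree.
The score at a grid point is `2 * (max_s CLL - CLL(0))`, maximized over a
logarithmic selection grid that includes 0, so scores are non-negative by
construction. SNP pairs whose reference-population dosage correlation
exceeds 0.9 contribute weight `1/(1 + k)` each (a fully correlated pair
contributes half weight each), mirroring the `-p1 0.9` contract of the
classic implementation; the `-w1 0.0005 200 200 1` window flags map to
`w_morgan`, `max_snps`, `grid_bp` and the chromosome index, all exposed in
`xpclr_config()` because the upstream semantics are ambiguous. The windowed
summary averages grid scores in 20-kb windows stepped by 2 kb and calls the
strict top 1%.

**rIBD.** Identity-by-descent sharing is counted in 10-kb windows stepped
by 5 kb: `nIBD` is the number of IBD tracks between a cultivar and any
donor overlapping the window divided by the number of donors, `rIBD` is
`nIBD_IL - nIBD_PL` per cultivar, and the track is the recipient-group mean
with a genome-wide Z-transform; windows with `Z > 2` merge into putative
introgressed regions. "Shared IBD number" counts *tracks* by default (a
donor sharing on both haplotypes counts twice), so `nIBD` may exceed 1;
the Z-normalization makes the scale immaterial, and a donor-counting mode
is available. The bundled detector reports maximal exact haplotype matches
(midpoint breakpoints, within-sample pairs excluded) and is intended for
error-free simulated data; real panels should come through an external
probabilistic IBD caller's segment file via `read_ibd_segments()`.

**LD decay.** Mean r-squared within 500 kb in 500-bp bins, computed on ten
accessions drawn without replacement per replicate and averaged over
replicates, controlling sample size across populations. r-squared is the
squared haplotype correlation (`D^2` over the product of allele variances);
a dosage mode covers unphased inputs. Each population should be
MAF-filtered on its own subset before the curve is computed — a
recently-bottlenecked population carries an excess of rare, young variants
whose pairwise r-squared is mechanically tiny and otherwise masks its
elevated haplotype-scale LD.

**Haplotype analysis.** Phased haplotypes over a gene region collapse into
classes; classes with frequency below 2 (haplotype count by default, an
accession-count mode as option) are removed, matching the convention of
dropping haplotypes carried by a single accession. Phenotype comparison is
one-way ANOVA followed by pairwise least-significant-difference t tests on
the pooled error mean square at an uncorrected alpha of 0.05 (the classical
LSD procedure; the output flags that no multiplicity correction is
applied), with compact letters assigned greedily by descending mean. A
carrier's value is attributed once to each class it carries (homozygotes
once); a diplotype-exclusive mode is available. The median-joining network
at epsilon 0 starts from the minimum-spanning network and adds
majority-rule median vectors of node triplets greedily while they shorten
the spanning tree; determinism comes from the fixed class order (descending
count, then allele string).

**Association support.** The mixed-model GWAS itself is out of scope; the
package consumes summary statistics, or produces them with a plain OLS
stand-in on simulated data. `pve()` implements the summary-statistic
estimator `100 * 2 b^2 p q / (2 b^2 p q + se^2 * 2 n p q)`, which reduces
to `100 * b^2 / (b^2 + n se^2)`; it is validated by simulation recovery of
a planted per-SNP heritability. The Bonferroni threshold is `0.05/n`, and
GWAS peak SNPs are linked to sweep regions when they overlap or sit within
(strictly less than) 100 kb of a region edge.

## The synthetic-population generator

The generator is a discrete-generation Wright–Fisher forward simulator
with per-meiosis Poisson crossovers, infinite-sites mutation (integer bp
positions, collisions redrawn against a genome-wide registry), fitness
`1 + s` / `1 + s/2` at a tracked sweep site, and a donor-tracked
introgression pulse. The ancestral population starts at mutation–drift
equilibrium (segregating-site count `theta * a_n`, frequencies from the
neutral spectrum, alleles placed independently), so LD at generation 0 is
absent and builds by drift during the run. Introgressed material is traced
through a 500-bp marker grid recombined alongside the genotypes, which
yields exact truth tracts for every sampled recipient haplotype.

**The default history** emulates a four-population domestication scenario:
a deep landrace pool (PL, N = 500), an improved-landrace branch founded at
generation 40 through a brief bottleneck (N = 300 for 10 generations) and
kept small afterwards (IL, N = 30 — the sustained small size is what
depresses its diversity and inflates its LD), modern branches EC and WC
(N = 900 each) splitting from IL at generation 50, a hard sweep in WC at
500 kb starting at generation 70, a 100-kb introgression pulse from IL
into 20% of EC haplotypes 50 generations before sampling, and 25 diploids
sampled per population at generation 220 on a 1-Mb chromosome.

**Rescaling.** Desk-scale simulation compresses time: mutation and
recombination rates (3e-7 and 2e-7 per bp per generation) are far above
per-generation rates of a real tree genome, so that a 1-Mb, 100-diploid
panel segregates several thousand SNPs and LD decays within the window
sizes the statistics use. Three timescale ratios control whether the
signals these scans target exist at this scale, and the defaults were chosen from
them rather than tuned:

* *Background drift vs. divergence time.* Window FST noise grows with
  `t/2N` since the EC/WC split; N = 900 over 170 generations keeps
  the background F near 0.1 so a sweep's local fixation stands out. The
  EC/WC split happens a few generations after the IL founding: a long
  shared interval at small Ne would both shallow their background
  coalescence (erasing the sweep valley) and fill the genome with
  EC-IL IBD sharing that masks introgression.
* *Sweep duration vs. background coalescence depth.* With s = 0.05 a
  selected allele needs roughly `(2/s) * ln(odds ratio)` ≈ 150 generations
  to move from 30% to fixation, and diversity inside the swept region
  reflects coalescence at that depth. The sweep footprint is visible only
  because the background coalesces much deeper (the early EC/WC split
  keeps their founding diversity near the deep PL pool). A long bottleneck
  interposed before the split would make background haplotypes as shallow
  as the sweep and erase the valley — the original motivation for the
  early-split topology.
* *Footprint width vs. window size.* Hitchhiking extends to roughly
  `1/(r * T)` bp for a sweep lasting T generations (about 35 kb here), a
  few analysis windows wide, concentrated enough to rank above the
  genome-wide noise of a 99-window genome.

**The sweep is introduced as a standing variant with a single-origin
core**: the allele is placed on `2N * init_freq` haplotypes whose alleles
within `origin_span_bp` (400 kb) of the site are copied from one randomly
chosen carrier — the local haplotype structure of a young allele that rose
to its standing frequency recently, without overwriting carrier backgrounds
elsewhere in the genome. An initial frequency of 0.35 lets s = 0.05 complete within the
150-generation epoch (the deterministic 0.35-to-0.95 sojourn at `s/2` per
generation is about 140 generations); runs whose final frequency falls
short of 0.95 are re-run (fresh draws from the same stream) up to
`retries` times. Partial sweeps would leave residual ancestral haplotypes
whose diversity blurs the valley, which is why completion is part of the
study condition. A
fully random-background mode (`origin = "standing"`, a soft sweep) is
available, and leaves a much weaker haplotype signal by design.

**The introgression pulse is regionally restricted by default** (donor
material enters only within a 100-kb interval). An unrestricted
whole-haplotype pulse spreads donor ancestry across the entire genome of
the recipient group, so the union of true tracts approaches the whole
sequence and recall against called regions becomes meaningless; a retained
localized segment emulates the outcome of post-introgression selection and
gives the rIBD statistic a well-defined target. The unrestricted mode
remains available (`region = NULL`) and is what the tract-length
calibration check uses (mean tract length about `1/(r*g)` bp after `g`
generations).

**What passing tests do and do not show.** The generator produces phased,
error-free, biallelic data with a uniform recombination map and a single
chromosome; there is no genotyping error, no phasing switch error, no
missingness unless injected, and no background selection. Passing recovery
tests therefore validates the *statistics and their wiring*, not robustness
to real-data artifacts. On real panels, IBD should come from a
probabilistic caller, and the desk-scale analysis settings (XP-CLR grid
spacing 4 kb rather than 200 bp; XP-EHH extension cap and edge buffer;
IBD minimum length 20 kb rather than 100 kb, matched to the shorter
desk-scale tracts) should be widened back to their chromosome-scale
defaults.

## Numerical choices and degenerate inputs

* Quantile thresholds use R's default type-7 empirical quantiles; strict
  inequality excludes ties, so constant tracks yield empty candidate sets.
* `z_transform()` refuses constant tracks rather than returning NaN, and
  missing windows stay missing through every summarization.
* The HWE exact test runs in log space and renormalizes the conditional
  distribution, so configurations up to hundreds of diploids are exact to
  machine precision; the two-sided p sums all heterozygote counts no more
  probable than the observed one (with a 1e-12 relative tolerance on the
  comparison to absorb rounding).
* EHH curves keep one point past the cutoff crossing so the iHH integral
  can interpolate the crossing linearly; sites with zero integral in either
  population are skipped rather than scored infinite.
* Interval arithmetic is 0-based half-open everywhere inside the package;
  VCF, GFF3 and IBD files are converted at the boundary, and BED output is
  native. Bookended intervals merge.
* Seeds are mandatory wherever randomness exists (simulation, subsampling,
  phenotypes); the RNG state of the caller is saved and restored.

## Problem sizes

The bundled validation runs use the 1-Mb fixture (about 3-5 thousand
segregating sites, 100 diploids) with 20 replicate simulations per
condition, XP-CLR on a 4-kb grid, XP-EHH on every second filtered site,
and LD curves from 10 accessions times 10 replicates. These sizes keep a
full run of the test suite in the tens of minutes on one CPU; all of them
are plain function arguments, and chromosome-scale data use the
documented defaults instead.

## Known limitations

* The IBD detector is exact-match only; real data needs an external caller.
* XP-CLR uses the observed sample frequency directly in the truncated
  normal density rather than integrating binomial sampling noise; with
  25-50 sampled diploids per population this is a mild approximation, and
  the selection grid caps at s = 0.1.
* The LSD comparison is uncorrected by design (classical LSD); treat the
  letters as descriptive when many classes are compared.
* The simulator offers no selfing, gene conversion, non-uniform maps or
  coalescent back-end; tract tracking is the reason forward simulation was
  chosen.
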