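#' Phased haplotype panel
#'
#' A `hap_panel` holds a matrix of phased biallelic alleles: two haplotype
#' rows per sample, one column per SNP. Positions are 1-based base-pair
#' coordinates, strictly increasing. Missing alleles are `NA`. This is the
#' substrate of every scan in the package.
#'
#' @param chrom Single chromosome identifier.
#' @param pos Integer vector of 1-based positions, strictly increasing.
#' @param samples Character vector of sample identifiers (unique).
#' @param alleles Integer matrix of 0/1/`NA`, `2 * length(samples)` rows
#'   (sample i owns rows `2i-1` and `2i`) and `length(pos)` columns.
#' @param phased Logical, one per site: whether all genotypes at the site
#'   were phased. Scans that read haplotype structure (EHH, IBD, haplotype
#'   classification) require every site to be phased.
#'
#' @return An object of class `hap_panel`.
#' @export
hap_panel <- function(chrom, pos, samples, alleles, phased = TRUE) {
  pos <- as.integer(pos)
  if (length(pos) > 1 && any(diff(pos) <= 0)) {
    stop("positions must be strictly increasing", call. = FALSE)
  }
  if (anyDuplicated(samples)) stop("duplicate sample ids", call. = FALSE)
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (nrow(alleles) != 2L * length(samples)) {
    stop("allele matrix must have two haplotype rows per sample", call. = FALSE)
  }
  if (ncol(alleles) != length(pos)) {
    stop("allele matrix width must equal number of positions", call. = FALSE)
  }
  bad <- alleles[!is.na(alleles)]
  if (length(bad) && !all(bad %in% c(0L, 1L))) {
    stop("alleles must be 0, 1 or NA (biallelic SNPs only)", call. = FALSE)
  }
  phased <- rep_len(as.logical(phased), length(pos))
  rownames(alleles) <- paste0(rep(samples, each = 2L), "_", rep(1:2, length(samples)))
  structure(
    list(chrom = as.character(chrom)[1], pos = pos,
         samples = as.character(samples), alleles = alleles, phased = phased),
    class = "hap_panel"
  )
}

#' @export
print.hap_panel <- function(x, ...) {
  cat("<hap_panel> ", x$chrom, ": ", length(x$pos), " SNPs, ",
      length(x$samples), " samples (", nrow(x$alleles), " haplotypes), ",
      if (all(x$phased)) "phased" else "partially unphased", "\n", sep = "")
  invisible(x)
}

#' @export
dim.hap_panel <- function(x) c(nrow(x$alleles), length(x$pos))

n_sites <- function(panel) length(panel$pos)
n_haps <- function(panel) nrow(panel$alleles)

is_phased_panel <- function(panel) all(panel$phased)

require_phased <- function(panel, what) {
  if (!is_phased_panel(panel)) {
    stop(what, " requires a fully phased panel", call. = FALSE)
  }
  invisible(TRUE)
}

#' Subset a panel by site index or by samples
#'
#' @param panel A [hap_panel()].
#' @param sites Integer site indices to keep (default all).
#' @param samples Character sample ids to keep (default all).
#' @return A `hap_panel`.
#' @export
panel_subset <- function(panel, sites = NULL, samples = NULL) {
  if (is.null(sites)) sites <- seq_along(panel$pos)
  if (is.null(samples)) samples <- panel$samples
  idx <- match(samples, panel$samples)
  if (anyNA(idx)) stop("unknown sample(s): ",
                       paste(samples[is.na(idx)], collapse = ", "), call. = FALSE)
  rows <- as.vector(rbind(2L * idx - 1L, 2L * idx))
  hap_panel(panel$chrom, panel$pos[sites], samples,
            panel$alleles[rows, sites, drop = FALSE], panel$phased[sites])
}

#' Haplotype row indices of a set of samples
#'
#' @param panel A [hap_panel()].
#' @param samples Character sample ids.
#' @return Integer indices into the allele matrix (two per sample, in
#'   sample order).
#' @export
hap_rows <- function(panel, samples) {
  idx <- match(samples, panel$samples)
  if (anyNA(idx)) stop("unknown sample(s): ",
                       paste(samples[is.na(idx)], collapse = ", "), call. = FALSE)
  as.vector(rbind(2L * idx - 1L, 2L * idx))
}

#' Per-site alternate allele counts and totals
#'
#' Counts use non-missing alleles only.
#'
#' @param panel A [hap_panel()].
#' @param rows Optional haplotype row indices (default: all haplotypes).
#' @return A tibble with columns `pos`, `n_alt`, `n_obs` (non-missing
#'   haplotypes) and `freq` (alternate allele frequency, `NaN` if no calls).
#' @export
allele_counts <- function(panel, rows = NULL) {
  H <- if (is.null(rows)) panel$alleles else panel$alleles[rows, , drop = FALSE]
  n_alt <- colSums(H, na.rm = TRUE)
  n_obs <- colSums(!is.na(H))
  tibble::tibble(pos = panel$pos, n_alt = n_alt, n_obs = n_obs,
                 freq = n_alt / n_obs)
}

#' Diploid genotype dosages
#'
#' @param panel A [hap_panel()].
#' @param sites Site indices (default all).
#' @return Matrix of 0/1/2 dosages, samples in rows (NA if either
#'   haplotype call is missing).
#' @export
dosage_matrix <- function(panel, sites = NULL) {
  if (is.null(sites)) sites <- seq_along(panel$pos)
  H <- panel$alleles[, sites, drop = FALSE]
  n <- length(panel$samples)
  D <- H[seq(1L, 2L * n, 2L), , drop = FALSE] + H[seq(2L, 2L * n, 2L), , drop = FALSE]
  rownames(D) <- panel$samples
  D
}

#' Population map
#'
#' A two-column tibble mapping sample ids to population labels
#' (conventionally PL, IL, EC, WC, OUT).
#'
#' @param sample Character sample ids (unique).
#' @param pop Character population labels (non-empty).
#' @return A tibble of class `pop_map` with columns `sample`, `pop`.
#' @export
pop_map <- function(sample, pop) {
  sample <- as.character(sample); pop <- as.character(pop)
  if (anyDuplicated(sample)) {
    stop("duplicate sample id(s): ",
         paste(unique(sample[duplicated(sample)]), collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(pop)) || anyNA(pop)) stop("empty population label", call. = FALSE)
  out <- tibble::tibble(sample = sample, pop = pop)
  class(out) <- c("pop_map", class(out))
  out
}

#' Samples belonging to a population
#'
#' @param popmap A [pop_map()].
#' @param pops Population label(s).
#' @return Character vector of sample ids; errors if a label is unknown.
#' @export
pop_samples <- function(popmap, pops) {
  unknown <- setdiff(pops, unique(popmap$pop))
  if (length(unknown)) {
    stop("unknown population(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  popmap$sample[popmap$pop %in% pops]
}
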