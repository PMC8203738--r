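#' Candidate region set
#'
#' Genomic intervals flagged by one or more scans, 0-based half-open,
#' carrying evidence tags (e.g. `fst_pi`, `xpclr`, `xpehh`, `ribd`) and,
#' after [annotate_genes()], overlapping gene ids. Tags and gene lists are
#' comma-separated strings so the tibble stays flat and BED-writable.
#'
#' @param chrom,start,end Interval columns (0-based half-open).
#' @param evidence Character evidence tag(s) per region (comma-separated).
#' @param genes Character gene id(s) per region (comma-separated, default "").
#' @return A tibble of class `candidate_regions`.
#' @export
candidate_regions <- function(chrom = character(), start = integer(),
                              end = integer(), evidence = character(),
                              genes = "") {
  n <- length(chrom)
  if (n > 0 && any(start < 0 | start >= end)) {
    stop("regions must satisfy 0 <= start < end", call. = FALSE)
  }
  out <- tibble::tibble(chrom = as.character(chrom),
                        start = as.integer(start), end = as.integer(end),
                        evidence = rep_len(as.character(evidence), n),
                        genes = rep_len(as.character(genes), n))
  class(out) <- c("candidate_regions", class(out))
  out
}

split_tags <- function(x) unique(unlist(strsplit(x[nzchar(x)], ",", fixed = TRUE)))
join_tags <- function(x) paste(sort(unique(x)), collapse = ",")

#' Merge several candidate region sets
#'
#' Takes the base-pair union: overlapping or bookended intervals are merged
#' and their evidence tags (and gene lists) unioned. Idempotent and
#' order-invariant.
#'
#' @param sets A list of [candidate_regions()] tibbles (or several passed
#'   via `...`).
#' @param ... Additional sets.
#' @return A single merged `candidate_regions` tibble.
#' @export
merge_region_sets <- function(sets, ...) {
  if (!is.null(sets) && inherits(sets, "data.frame")) sets <- list(sets)
  sets <- c(sets, list(...))
  all <- dplyr::bind_rows(sets)
  if (nrow(all) == 0L) return(candidate_regions())
  all <- all[order(all$chrom, all$start, all$end), , drop = FALSE]
  res <- list()
  cur <- as.list(all[1, ])
  push <- function(cur) {
    res[[length(res) + 1L]] <<- tibble::tibble(
      chrom = cur$chrom, start = cur$start, end = cur$end,
      evidence = join_tags(cur$evidence), genes = join_tags(cur$genes))
  }
  if (nrow(all) > 1) for (i in 2:nrow(all)) {
    if (all$chrom[i] == cur$chrom && all$start[i] <= cur$end) {
      cur$end <- max(cur$end, all$end[i])
      cur$evidence <- c(cur$evidence, all$evidence[i])
      cur$genes <- c(cur$genes, all$genes[i])
    } else {
      push(cur); cur <- as.list(all[i, ])
    }
  }
  cur$evidence <- split_tags(cur$evidence); cur$genes <- split_tags(cur$genes)
  push(cur)
  ## earlier pushes may still hold unsplit tag vectors; normalize
  m <- dplyr::bind_rows(res)
  m$evidence <- vapply(strsplit(m$evidence, ",", fixed = TRUE),
                       function(x) join_tags(x[nzchar(x)]), character(1))
  m$genes <- vapply(strsplit(m$genes, ",", fixed = TRUE),
                    function(x) join_tags(x[nzchar(x)]), character(1))
  candidate_regions(m$chrom, m$start, m$end, m$evidence, m$genes)
}

#' Attach overlapping genes to candidate regions
#'
#' A gene is attached to a region when their intervals share at least 1 bp.
#'
#' @param regions A [candidate_regions()] tibble.
#' @param genes A gene annotation tibble from [read_gene_annotations()]
#'   (columns `gene_id`, `chrom`, `start`, `end`).
#' @return The regions with the `genes` column filled.
#' @export
annotate_genes <- function(regions, genes) {
  if (nrow(regions) == 0L) return(regions)
  regions$genes <- vapply(seq_len(nrow(regions)), function(i) {
    hit <- genes$chrom == regions$chrom[i] &
      genes$start < regions$end[i] & genes$end > regions$start[i]
    join_tags(genes$gene_id[hit])
  }, character(1))
  regions
}

#' Flag GWAS peak SNPs that overlap or sit near sweep regions
#'
#' A peak SNP is flagged when it lies inside a candidate region or within
#' `max_dist` bp of its nearest edge (the "<100 kb" proximity rule).
#'
#' @param peak_snps Tibble or data frame with columns `chrom`, `pos`
#'   (1-based SNP positions).
#' @param regions A [candidate_regions()] tibble.
#' @param max_dist Maximum distance in bp (default 1e5); proximity is
#'   strict (`< max_dist`).
#' @return The input tibble with a logical `near_sweep` column, plus the
#'   flagged fraction as attribute `fraction`; [glance()] style summary via
#'   `attr(x, "fraction")`.
#' @export
gwas_overlap <- function(peak_snps, regions, max_dist = 100000) {
  peak_snps <- tibble::as_tibble(peak_snps)
  p0 <- peak_snps$pos - 1
  flag <- vapply(seq_len(nrow(peak_snps)), function(i) {
    r <- regions[regions$chrom == peak_snps$chrom[i], , drop = FALSE]
    if (nrow(r) == 0L) return(FALSE)
    d <- pmax(r$start - 1 - p0[i], p0[i] - r$end, 0)
    any(d < max_dist)
  }, logical(1))
  peak_snps$near_sweep <- flag
  attr(peak_snps, "fraction") <- if (nrow(peak_snps)) mean(flag) else NA_real_
  peak_snps
}

#' Fraction of a genome covered by regions
#'
#' Overlapping regions are unioned before summing.
#'
#' @param regions A [candidate_regions()] tibble.
#' @param genome_length Total genome length in bp.
#' @return Fraction in `[0, 1]`.
#' @export
proportion_introgressed <- function(regions, genome_length) {
  if (nrow(regions) == 0L) return(0)
  u <- merge_region_sets(list(regions))
  sum(u$end - u$start) / genome_length
}
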