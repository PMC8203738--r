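#' Genomic region
#'
#' 0-based half-open interval used internally everywhere; VCF and GFF
#' coordinates (1-based) are converted at the boundary.
#'
#' @param chrom Chromosome identifier.
#' @param start,end 0-based half-open bounds, `0 <= start < end`.
#' @return A list of class `genomic_region`.
#' @export
genomic_region <- function(chrom, start, end) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (is.na(start) || is.na(end) || start < 0 || start >= end) {
    stop("region must satisfy 0 <= start < end", call. = FALSE)
  }
  structure(list(chrom = as.character(chrom), start = start, end = end),
            class = "genomic_region")
}

#' Read a phased multi-sample VCF into a haplotype panel
#'
#' Only biallelic SNP records are retained (single-base REF and ALT);
#' indels and multi-allelic records are dropped. Unphased genotypes are
#' accepted but the affected sites are flagged, and scans that need phase
#' will refuse the panel.
#'
#' @param path VCF file (plain or gzipped text).
#' @param region Optional [genomic_region()]; only sites inside it are kept.
#' @return A [hap_panel()].
#' @export
read_vcf <- function(path, region = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (ncol(v@gt) < 2L) stop("VCF has no sample columns", call. = FALSE)
  fix <- v@fix
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  snp <- !is.na(ref) & !is.na(alt) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  chroms <- fix[, "CHROM"]; pos <- as.integer(fix[, "POS"])
  keep <- snp
  if (!is.null(region)) {
    keep <- keep & chroms == region$chrom &
      (pos - 1L) >= region$start & (pos - 1L) < region$end
  }
  if (!any(keep)) stop("no biallelic SNP records retained", call. = FALSE)
  if (length(unique(chroms[keep])) > 1L) {
    stop("VCF spans multiple chromosomes; supply a region", call. = FALSE)
  }
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, colnames(v@gt)[-1]))
  samples <- colnames(gt)
  S <- nrow(gt)
  A <- matrix(NA_integer_, nrow = 2L * length(samples), ncol = S)
  phased <- rep(TRUE, S)
  for (j in seq_along(samples)) {
    g <- gt[, j]
    g[is.na(g)] <- ".|."
    unph <- grepl("/", g, fixed = TRUE)
    phased <- phased & (!unph | g %in% c("./.", "."))
    parts <- strsplit(g, "[|/]")
    a1 <- vapply(parts, function(p) p[1], character(1))
    a2 <- vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_, character(1))
    conv <- function(a) {
      out <- suppressWarnings(as.integer(a))
      out[!a %in% c("0", "1")] <- NA_integer_
      out
    }
    A[2L * j - 1L, ] <- conv(a1)
    A[2L * j, ] <- conv(a2)
  }
  hap_panel(unique(chroms[keep]), pos[keep], samples, A, phased)
}

#' Write a haplotype panel as a plain-text VCF
#'
#' Minimal VCF v4.2 emitter (GT only); `read_vcf()` round-trips positions,
#' sample order and alleles exactly.
#'
#' @param panel A [hap_panel()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, path) {
  n <- length(panel$samples)
  h1 <- panel$alleles[seq(1L, 2L * n, 2L), , drop = FALSE]
  h2 <- panel$alleles[seq(2L, 2L * n, 2L), , drop = FALSE]
  sep <- ifelse(panel$phased, "|", "/")
  lines <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", panel$chrom, ">"),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$samples), collapse = "\t"))
  body <- vapply(seq_along(panel$pos), function(s) {
    a1 <- ifelse(is.na(h1[, s]), ".", h1[, s])
    a2 <- ifelse(is.na(h2[, s]), ".", h2[, s])
    paste(c(panel$chrom, panel$pos[s], ".", "A", "T", ".", "PASS", ".", "GT",
            paste0(a1, sep[s], a2)), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read a sample-to-population map
#'
#' Two-column whitespace/tab-separated file (`sample`, `population`);
#' a header line is detected and skipped when its first field is
#' `sample` (case-insensitive).
#'
#' @param path TSV file.
#' @return A [pop_map()] tibble.
#' @export
read_population_map <- function(path) {
  d <- utils::read.table(path, header = FALSE, col.names = c("sample", "pop"),
                         colClasses = "character")
  if (nrow(d) && tolower(d$sample[1]) == "sample") d <- d[-1, , drop = FALSE]
  if (nrow(d) == 0L) stop("empty population map", call. = FALSE)
  pop_map(d$sample, d$pop)
}

#' Read gene annotations from a GFF3 file
#'
#' Keeps features of type `gene` and converts the 1-based inclusive GFF
#' coordinates to 0-based half-open.
#'
#' @param path GFF3 file.
#' @return Tibble with columns `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_gene_annotations <- function(path) {
  g <- ape::read.gff(path)
  g <- g[g$type == "gene", , drop = FALSE]
  ids <- sub('.*ID=([^;]+).*', "\\1", g$attributes)
  if (any(!grepl("ID=", g$attributes))) {
    stop("gene feature without ID attribute", call. = FALSE)
  }
  if (anyDuplicated(ids)) stop("duplicate gene IDs", call. = FALSE)
  tibble::tibble(gene_id = ids, chrom = as.character(g$seqid),
                 start = as.integer(g$start) - 1L, end = as.integer(g$end),
                 strand = as.character(g$strand))
}

#' Read IBD segments (Beagle/RefinedIBD dialect)
#'
#' Nine tab-separated columns: sample1, hap1, sample2, hap2, chrom,
#' start, end, LOD, length (cM). Coordinates are read as 1-based inclusive
#' and converted to 0-based half-open.
#'
#' @param path TSV file.
#' @return Tibble of class `ibd_segments`: `sample1`, `hap1`, `sample2`,
#'   `hap2`, `chrom`, `start`, `end`, `lod`, `length_cm`.
#' @export
read_ibd_segments <- function(path) {
  d <- utils::read.table(path, header = FALSE, sep = "\t",
                         col.names = c("sample1", "hap1", "sample2", "hap2",
                                       "chrom", "start", "end", "lod", "length_cm"),
                         colClasses = c("character", "integer", "character", "integer",
                                        "character", "numeric", "numeric",
                                        "numeric", "numeric"))
  if (any(d$start >= d$end)) stop("IBD segment with start >= end", call. = FALSE)
  if (any(!d$hap1 %in% 1:2) || any(!d$hap2 %in% 1:2)) {
    stop("haplotype indices must be 1 or 2", call. = FALSE)
  }
  ibd_segments(d$sample1, d$hap1, d$sample2, d$hap2, d$chrom,
               d$start - 1, d$end, d$lod, d$length_cm)
}

ibd_segments <- function(sample1, hap1, sample2, hap2, chrom, start, end,
                         lod = NA_real_, length_cm = NA_real_) {
  out <- tibble::tibble(sample1 = as.character(sample1), hap1 = as.integer(hap1),
                        sample2 = as.character(sample2), hap2 = as.integer(hap2),
                        chrom = as.character(chrom),
                        start = as.numeric(start), end = as.numeric(end),
                        lod = as.numeric(lod), length_cm = as.numeric(length_cm))
  if (nrow(out) && any(out$start >= out$end)) {
    stop("IBD segment with start >= end", call. = FALSE)
  }
  class(out) <- c("ibd_segments", class(out))
  out
}

#' Write candidate regions as BED3(+)
#'
#' 0-based half-open, with evidence and gene columns appended.
#'
#' @param regions A [candidate_regions()] tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  header <- "#chrom\tstart\tend\tevidence\tgenes"
  body <- if (nrow(regions)) {
    paste(regions$chrom, regions$start, regions$end,
          regions$evidence, regions$genes, sep = "\t")
  } else character()
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write / read a windowed track TSV
#'
#' Columns `chrom`, `start`, `end`, `n_snps`, `value`; values round-trip
#' exactly (full double precision).
#'
#' @param track A windowed track tibble.
#' @param path File path.
#' @return `write_track_tsv()`: `path` invisibly; `read_track_tsv()`: the track.
#' @export
write_track_tsv <- function(track, path) {
  df <- as.data.frame(track[, c("chrom", "start", "end", "n_snps", "value")])
  df$value <- sprintf("%.17g", df$value)
  df$value[is.na(track$value)] <- "NA"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_track_tsv
#' @export
read_track_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = c("character", "integer", "integer",
                                        "integer", "numeric"))
  new_windowed_track(d$chrom, d$start, d$end, d$n_snps, d$value, "value")
}

#' Site filter configuration
#'
#' The standard SNP quality filters: minor allele frequency, per-site
#' missing rate, Hardy-Weinberg exact-test p-value and the biallelic
#' requirement (the latter is enforced at VCF read time).
#'
#' @param maf_min Minimum minor allele frequency (default 0.05).
#' @param max_missing_rate Maximum fraction of missing alleles (default 0.5).
#' @param hwe_p_min Sites with HWE exact p <= this are removed (default 1e-6).
#' @param require_biallelic Logical (default TRUE); panels are biallelic by
#'   construction.
#' @return A list of class `site_filter_config`.
#' @export
site_filter_config <- function(maf_min = 0.05, max_missing_rate = 0.5,
                               hwe_p_min = 1e-6, require_biallelic = TRUE) {
  if (maf_min < 0 || maf_min > 0.5) stop("maf_min must be in [0, 0.5]", call. = FALSE)
  if (max_missing_rate < 0 || max_missing_rate > 1) {
    stop("max_missing_rate must be in [0, 1]", call. = FALSE)
  }
  structure(list(maf_min = maf_min, max_missing_rate = max_missing_rate,
                 hwe_p_min = hwe_p_min, require_biallelic = isTRUE(require_biallelic)),
            class = "site_filter_config")
}

#' Filter panel sites by MAF, missing rate and HWE
#'
#' Retains sites with MAF >= `maf_min` (computed from non-missing alleles),
#' missing rate <= `max_missing_rate`, and HWE exact p > `hwe_p_min`
#' (genotype-level test on the diploid calls, ignoring phase). Site order
#' is preserved; the removal counts per rule are attached as attribute
#' `filter_report`. Idempotent.
#'
#' @param panel A [hap_panel()].
#' @param cfg A [site_filter_config()].
#' @return The filtered `hap_panel`.
#' @export
filter_sites <- function(panel, cfg = site_filter_config()) {
  if (n_sites(panel) == 0L) stop("empty panel", call. = FALSE)
  ac <- allele_counts(panel)
  maf <- pmin(ac$freq, 1 - ac$freq)
  miss <- 1 - ac$n_obs / n_haps(panel)
  fail_maf <- is.na(maf) | maf < cfg$maf_min
  fail_miss <- miss > cfg$max_missing_rate
  if (cfg$hwe_p_min > 0) {
    D <- dosage_matrix(panel)
    hwe_p <- vapply(seq_len(ncol(D)), function(s) {
      d <- D[, s]; d <- d[!is.na(d)]
      if (!length(d)) return(NA_real_)
      hwe_exact_test(sum(d == 0L), sum(d == 1L), sum(d == 2L))
    }, numeric(1))
    fail_hwe <- is.na(hwe_p) | hwe_p <= cfg$hwe_p_min
  } else {
    fail_hwe <- rep(FALSE, length(maf))  # p > 0 always holds
  }
  keep <- !(fail_maf | fail_miss | fail_hwe)
  out <- panel_subset(panel, sites = which(keep))
  attr(out, "filter_report") <- tibble::tibble(
    rule = c("maf", "missing_rate", "hwe", "retained"),
    n = c(sum(fail_maf), sum(fail_miss), sum(fail_hwe), sum(keep)))
  out
}
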