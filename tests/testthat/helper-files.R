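# tiny text fixtures written at test time

write_toy_vcf <- function(path, records, samples = c("s1", "s2")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records), path)
  path
}

vcf_rec <- function(pos, ref, alt, gts, chrom = "chr1") {
  paste(c(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT", gts), collapse = "\t")
}

write_toy_gff <- function(path, lines) {
  writeLines(c("##gff-version 3", lines), path)
  path
}

gff_rec <- function(chrom, type, start, end, id, strand = "+") {
  paste(chrom, "src", type, start, end, ".", strand, ".",
        paste0("ID=", id), sep = "\t")
}

ibd_row <- function(s1, h1, s2, h2, chrom, start, end, lod = 10, cm = 1) {
  paste(s1, h1, s2, h2, chrom, start, end, lod, cm, sep = "\t")
}
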