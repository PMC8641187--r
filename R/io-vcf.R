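#' Read genotypes from a VCF file
#'
#' Loads the GT field of a VCF (via `VariantAnnotation::readVcf`) together
#' with a sample-to-population map. Phased (`|`) and unphased (`/`)
#' separators are treated identically; `./.` (or `.`) becomes a missing
#' call. Multi-allelic records are rejected (default) or dropped,
#' per `multiallelic`.
#'
#' @param vcf_path path to a VCF 4.x file with a GT FORMAT field
#' @param pop_map_path path to a two-column TSV sample<TAB>population, or a
#'   named character vector as returned by [read_population_map()]
#' @param multiallelic `"reject"` (error naming the first offending
#'   position) or `"drop"` (remove such records)
#' @return [genotype_matrix]
#' @export
read_vcf <- function(vcf_path, pop_map_path, multiallelic = c("reject", "drop")) {
  multiallelic <- match.arg(multiallelic)
  if (!file.exists(vcf_path)) stopf("file not found: %s", vcf_path)
  pops <- if (is.character(pop_map_path) && length(pop_map_path) == 1 &&
              file.exists(pop_map_path)) read_population_map(pop_map_path)
          else pop_map_path

  vcf <- VariantAnnotation::readVcf(vcf_path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  n_alt <- lengths(rr$ALT)
  if (any(n_alt > 1)) {
    if (multiallelic == "reject") {
      i <- which(n_alt > 1)[1]
      stopf("multi-allelic record at %s:%d", as.character(GenomicRanges::seqnames(rr))[i],
            GenomicRanges::start(rr)[i])
    }
    vcf <- vcf[n_alt <= 1]
    rr <- SummarizedExperiment::rowRanges(vcf)
  }
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stopf("VCF has no GT field: %s", vcf_path)

  samples <- colnames(gt)
  absent <- setdiff(samples, names(pops))
  if (length(absent))
    stopf("sample(s) in VCF absent from population map: %s",
          paste(absent, collapse = ", "))

  code <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L, "0|1" = 1L,
            "1|0" = 1L, "1/1" = 2L, "1|1" = 2L)
  dosage <- matrix(code[gt], nrow = nrow(gt), ncol = ncol(gt))  # loci x samples
  dosage <- t(dosage)
  rownames(dosage) <- samples

  alt_chr <- vapply(rr$ALT, function(a)
    if (length(a)) as.character(a[[1]]) else "N", character(1))
  loci <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos_bp = GenomicRanges::start(rr),
    locus_id = names(rr) %||% paste0("v", seq_along(rr)),
    ref_allele = as.character(rr$REF),
    alt_allele = alt_chr, stringsAsFactors = FALSE)
  genotype_matrix(dosage, loci, pops[samples])
}

#' Write a genotype matrix as a minimal GT-only VCF
#'
#' Emits an uncompressed VCF 4.2 file with one GT FORMAT field; missing
#' calls become `./.`. Dosage 1 is written as the unphased heterozygote
#' `0/1`.
#'
#' @param g [genotype_matrix]
#' @param path output path (plain text `.vcf`)
#' @return invisibly, `path`
#' @export
write_vcf <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste0("##contig=<ID=", unique(g$loci$chrom), ">"),
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", g$samples), collapse = "\t")), con)
  gt_code <- c("0/0", "0/1", "1/1")
  d <- t(g$dosage)  # loci x samples
  gt <- matrix("./.", nrow = nrow(d), ncol = ncol(d))
  ok <- !is.na(d)
  gt[ok] <- gt_code[d[ok] + 1L]
  body <- paste(g$loci$chrom, g$loci$pos_bp, g$loci$locus_id,
                g$loci$ref_allele, g$loci$alt_allele, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}
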