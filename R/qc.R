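#' SNP quality-control thresholds
#'
#' Container for the three marker-level filters applied before the scan:
#' a locus survives iff pooled MAF > `maf_min`, call rate >= `call_rate_min`
#' and HWE exact p > `hwe_p_min`. Defaults are the common SNP-chip settings
#' (MAF > 0.01, call rate >= 90\%, HWE p > 1e-5).
#'
#' @param maf_min minimum (exclusive) minor allele frequency
#' @param call_rate_min minimum (inclusive) per-locus call rate
#' @param hwe_p_min minimum (exclusive) HWE exact-test p-value
#' @param hwe_mode `"pooled"`: one test over all samples (the behaviour of
#'   early PLINK runs without family information); `"per_population"`: test
#'   within each population and filter on the smallest p-value. Pooled
#'   testing in a strongly structured cohort rejects for the Wahlund
#'   heterozygote deficit rather than genotyping error, so per-population
#'   mode is preferable when population labels are trusted.
#' @return object of class `qc_thresholds`
#' @export
qc_thresholds <- function(maf_min = 0.01, call_rate_min = 0.90,
                          hwe_p_min = 1e-5,
                          hwe_mode = c("pooled", "per_population")) {
  vals <- c(maf_min, call_rate_min, hwe_p_min)
  if (any(vals < 0 | vals > 1)) stopf("all thresholds must be in [0, 1]")
  structure(list(maf_min = maf_min, call_rate_min = call_rate_min,
                 hwe_p_min = hwe_p_min, hwe_mode = match.arg(hwe_mode)),
            class = "qc_thresholds")
}

#' Per-locus minor allele frequency
#'
#' MAF = min(p, 1 - p) over all samples pooled. Loci with no non-missing
#' calls are `NA`.
#'
#' @param g [genotype_matrix]
#' @return numeric vector, one value per locus
#' @export
minor_allele_frequency <- function(g) {
  p <- allele_frequencies(g)$p
  pmin(p, 1 - p)
}

#' Per-locus call rate
#'
#' @param g [genotype_matrix]
#' @return numeric vector: non-missing samples / total samples, per locus
#' @export
call_rate <- function(g) {
  colMeans(!is.na(g$dosage))
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test: enumerates every heterozygote count compatible
#' with the observed allele counts, computes its conditional probability
#' under HWE, and sums the probabilities of all configurations no more
#' probable than the observed one (the summation of Wigginton, Cuthbert &
#' Abecasis 2005). Monomorphic loci return p = 1. Vectorised over loci.
#'
#' @param hom_ref,het,hom_alt genotype counts (equal-length vectors)
#' @return p-value(s) in (0, 1]
#' @export
hwe_exact_test <- function(hom_ref, het, hom_alt) {
  n <- length(het)
  stopifnot(length(hom_ref) == n, length(hom_alt) == n)
  if (any(hom_ref < 0 | het < 0 | hom_alt < 0, na.rm = TRUE))
    stopf("genotype counts must be non-negative")
  p <- numeric(n)
  for (i in seq_len(n)) {
    if (anyNA(c(hom_ref[i], het[i], hom_alt[i]))) { p[i] <- NA_real_; next }
    p[i] <- hwe_exact_one(hom_ref[i], het[i], hom_alt[i])
  }
  p
}

## One locus. Probabilities over het counts h (same parity as n_rare allele
## count) via the standard recurrence, normalised; p = sum of P(h) <= P(obs).
hwe_exact_one <- function(aa, ab, bb) {
  n <- aa + ab + bb
  if (n == 0) stopf("all genotype counts are zero")
  n_a <- 2 * aa + ab
  n_b <- 2 * bb + ab
  rare <- min(n_a, n_b)
  if (rare == 0) return(1.0)          # monomorphic
  h <- seq(rare %% 2, rare, by = 2)   # feasible het counts
  ## unnormalised log-probabilities: P(h) prop. 2^h / (h! ((na-h)/2)! ((nb-h)/2)!)
  lp <- h * log(2) - lfactorial(h) - lfactorial((n_a - h) / 2) -
    lfactorial((n_b - h) / 2)
  lp <- lp - max(lp)
  pr <- exp(lp); pr <- pr / sum(pr)
  p_obs <- pr[match(ab, h)]
  if (is.na(p_obs)) stopf("heterozygote count %d infeasible for allele counts", ab)
  min(1, sum(pr[pr <= p_obs + 1e-12]))
}

## Per-locus genotype counts for a dosage matrix (samples x loci).
genotype_counts <- function(dosage) {
  list(hom_ref = colSums(dosage == 0L, na.rm = TRUE),
       het     = colSums(dosage == 1L, na.rm = TRUE),
       hom_alt = colSums(dosage == 2L, na.rm = TRUE))
}

#' Per-locus HWE p-values for a genotype matrix
#'
#' @param g [genotype_matrix]
#' @param mode see [qc_thresholds()]; `"per_population"` returns, per locus,
#'   the minimum p over populations (a locus fails if any population does)
#' @return numeric vector of p-values
#' @export
hwe_pvalues <- function(g, mode = c("pooled", "per_population")) {
  mode <- match.arg(mode)
  if (mode == "pooled") {
    cc <- genotype_counts(g$dosage)
    return(hwe_exact_test(cc$hom_ref, cc$het, cc$hom_alt))
  }
  pmat <- sapply(unique(g$populations), function(pop) {
    d <- g$dosage[g$populations == pop, , drop = FALSE]
    cc <- genotype_counts(d)
    hwe_exact_test(cc$hom_ref, cc$het, cc$hom_alt)
  })
  apply(as.matrix(pmat), 1, min, na.rm = TRUE)
}

#' Apply marker-level QC filters
#'
#' A locus survives iff MAF > `maf_min` AND call rate >= `call_rate_min`
#' AND HWE p > `hwe_p_min`. The per-filter report counts each locus under
#' every criterion it fails.
#'
#' @param g [genotype_matrix]
#' @param thresholds [qc_thresholds()]
#' @return list with `genotypes` (filtered [genotype_matrix]), `report`
#'   (data.frame: locus_id, chrom, pos_bp, maf, call_rate, hwe_p,
#'   removed_by), and `counts` (removed per criterion, and retained)
#' @export
apply_qc_filters <- function(g, thresholds = qc_thresholds()) {
  t <- thresholds
  maf <- minor_allele_frequency(g)
  cr <- call_rate(g)
  hwe <- hwe_pvalues(g, t$hwe_mode)

  fail_maf <- is.na(maf) | !(maf > t$maf_min)
  fail_cr <- cr < t$call_rate_min
  fail_hwe <- is.na(hwe) | !(hwe > t$hwe_p_min)
  keep <- !(fail_maf | fail_cr | fail_hwe)

  removed_by <- character(nrow(g$loci))
  tags <- cbind(maf = fail_maf, call_rate = fail_cr, hwe = fail_hwe)
  removed_by <- apply(tags, 1, function(z)
    paste(colnames(tags)[z], collapse = ","))
  report <- data.frame(locus_id = g$loci$locus_id, chrom = g$loci$chrom,
                       pos_bp = g$loci$pos_bp, maf = maf, call_rate = cr,
                       hwe_p = hwe, removed_by = removed_by,
                       stringsAsFactors = FALSE)
  counts <- c(maf = sum(fail_maf), call_rate = sum(fail_cr),
              hwe = sum(fail_hwe), retained = sum(keep))
  if (!any(keep)) warnf("no loci survive QC")
  list(genotypes = subset_loci(g, which(keep)), report = report,
       counts = counts)
}

#' Write the QC exclusion report as TSV
#' @param qc result of [apply_qc_filters()]
#' @param path output TSV
#' @return invisibly, `path`
#' @export
write_exclusion_report <- function(qc, path) {
  data.table::fwrite(qc$report, path, sep = "\t")
  invisible(path)
}
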