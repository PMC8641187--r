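## Small in-code fixtures shared across test files.

`%||%` <- function(x, y) if (is.null(x)) y else x

## Genotype matrix from a dosage matrix given as rows = samples.
make_g <- function(dosage, pops, chrom = NULL, pos = NULL) {
  n_loci <- ncol(dosage)
  if (is.null(chrom)) chrom <- rep("1", n_loci)
  if (is.null(pos)) pos <- seq(1000L, by = 1000L, length.out = n_loci)
  if (is.null(rownames(dosage)))
    rownames(dosage) <- names(pops) %||% sprintf("s%02d", seq_len(nrow(dosage)))
  if (is.null(names(pops))) names(pops) <- rownames(dosage)
  genotype_matrix(dosage,
                  data.frame(chrom = chrom, pos_bp = pos,
                             locus_id = sprintf("m%03d", seq_len(n_loci)),
                             ref_allele = "A", alt_allele = "G",
                             stringsAsFactors = FALSE),
                  pops)
}

## Small two-group cohort used by several scan tests.
small_sim <- function(seed = 42, n_snps = 400, n_selected = 5) {
  cfg <- sim_config(
    n_chromosomes = 2, chrom_length_bp = 5e6, n_snps = n_snps,
    breeds = data.frame(
      label = c("A", "B", "C", "D"),
      group = c("indigenous", "indigenous", "commercial_meat",
                "commercial_milk"),
      sample_n = c(12, 12, 12, 12), ne = c(300, 300, 120, 120),
      stringsAsFactors = FALSE),
    generations_split = 30, generations_group = 15, group_ne = 500,
    n_selected_loci = n_selected, missing_rate = 0.01, seed = seed)
  simulate_cohort(cfg)
}

## Scalar reimplementation of the mean-squares estimator, kept deliberately
## naive and separate from the package internals: the oracle for FST tests.
oracle_fst_parts <- function(n, p) {
  s <- length(n)
  pbar <- sum(n * p) / sum(n)
  msp <- sum(n * (p - pbar)^2) / (s - 1)
  msg <- sum(n * p * (1 - p)) / (sum(n) - 1)
  list(msp = msp, msg = msg, nc = mean(n))
}

oracle_windowed_fst <- function(g, pops1, pops2, window_bp, step_bp) {
  rows <- list()
  for (ch in unique(g$loci$chrom)) {
    extent <- max(g$loci$pos_bp[g$loci$chrom == ch])
    start <- 1
    while (start <= extent) {
      in_win <- which(g$loci$chrom == ch & g$loci$pos_bp >= start &
                        g$loci$pos_bp < start + window_bp)
      num <- 0; den <- 0; nl <- 0L
      for (j in in_win) {
        d1 <- g$dosage[g$populations %in% pops1, j]
        d2 <- g$dosage[g$populations %in% pops2, j]
        n <- c(sum(!is.na(d1)), sum(!is.na(d2)))
        if (any(n < 1)) next
        p <- c(sum(d1, na.rm = TRUE) / (2 * n[1]),
               sum(d2, na.rm = TRUE) / (2 * n[2]))
        parts <- oracle_fst_parts(n, p)
        if (parts$msp == 0 && parts$msg == 0) next
        num <- num + (parts$msp - parts$msg)
        den <- den + (parts$msp + (parts$nc - 1) * parts$msg)
        nl <- nl + 1L
      }
      if (nl > 0)
        rows[[length(rows) + 1]] <- data.frame(
          chrom = ch, start_bp = start, value = num / den, n_loci = nl)
      start <- start + step_bp
    }
  }
  do.call(rbind, rows)
}
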