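#' LD-pruning parameters
#'
#' Sliding-window pairwise pruning in the style of PLINK's
#' `--indep-pairwise`: windows of `window_snps` consecutive loci advanced by
#' `step_snps`, removing one locus of any retained pair with r^2 above
#' `r2_max`. Defaults reproduce `indep-pairwise 100 50 0.1`.
#'
#' @param window_snps window size in SNPs
#' @param step_snps step in SNPs
#' @param r2_max maximum allowed squared dosage correlation
#' @return object of class `prune_params`
#' @export
prune_params <- function(window_snps = 100L, step_snps = 50L, r2_max = 0.1) {
  if (!(window_snps >= step_snps && step_snps >= 1))
    stopf("need window_snps >= step_snps >= 1")
  if (r2_max < 0 || r2_max > 1) stopf("r2_max must be in [0, 1]")
  structure(list(window_snps = as.integer(window_snps),
                 step_snps = as.integer(step_snps), r2_max = r2_max),
            class = "prune_params")
}

#' Greedy sliding-window LD pruning
#'
#' Within each window of `window_snps` consecutive loci (per chromosome,
#' position-sorted), while any retained pair has squared dosage correlation
#' above `r2_max`, the member of the worst offending pair with the lower
#' pooled MAF is removed (ties: the later position). Windows slide by
#' `step_snps`. r^2 is the squared Pearson correlation of dosage vectors
#' over pairwise-complete samples (composite, genotype-based LD). The
#' procedure is deterministic given its input.
#'
#' @param g [genotype_matrix]
#' @param params [prune_params()]
#' @return integer vector of retained locus indices (ascending)
#' @export
ld_prune <- function(g, params = prune_params()) {
  keep <- rep(TRUE, nrow(g$loci))
  maf <- minor_allele_frequency(g)
  for (chr in unique(g$loci$chrom)) {
    idx <- which(g$loci$chrom == chr)
    n <- length(idx)
    starts <- seq(1L, max(1L, n), by = params$step_snps)
    for (s in starts) {
      win <- idx[s:min(s + params$window_snps - 1L, n)]
      win <- win[keep[win]]
      if (length(win) >= 2) {
        r2 <- suppressWarnings(
          cor(g$dosage[, win, drop = FALSE],
              use = "pairwise.complete.obs"))^2
        diag(r2) <- 0
        r2[is.na(r2)] <- 0
        while (max(r2) > params$r2_max) {
          worst <- which(r2 == max(r2), arr.ind = TRUE)
          worst <- worst[order(worst[, 1], worst[, 2]), , drop = FALSE][1, ]
          a <- win[worst[1]]; b <- win[worst[2]]
          drop_locus <- if (isTRUE(maf[a] < maf[b])) a
            else if (isTRUE(maf[b] < maf[a])) b
            else max(a, b)  # tie: later position
          keep[drop_locus] <- FALSE
          k <- match(drop_locus, win)
          r2[k, ] <- 0; r2[, k] <- 0
        }
      }
      if (s + params$window_snps - 1L >= n) break
    }
  }
  which(keep)
}

#' Write a retained-locus list (one id per line, PLINK --extract style)
#' @param g [genotype_matrix]
#' @param retained integer indices from [ld_prune()]
#' @param path output path
#' @return invisibly, `path`
#' @export
write_retained_loci <- function(g, retained, path) {
  writeLines(g$loci$locus_id[retained], path)
  invisible(path)
}
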