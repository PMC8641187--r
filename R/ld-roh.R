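#' Squared genotype correlation between two loci
#'
#' Composite (genotype-based) LD: the squared Pearson correlation of the
#' two dosage vectors over pairwise-complete samples. Sign-invariant, so
#' allele orientation does not matter.
#'
#' @param x,y dosage vectors in \{0, 1, 2, NA\}
#' @return r^2 in [0, 1], or `NA` if fewer than 2 complete pairs or either
#'   locus has zero variance among them
#' @examples
#' genotype_r2(c(0, 1, 2, 2), c(0, 1, 2, 0))  # 25/121
#' @export
genotype_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
  cor(x[ok], y[ok])^2
}

#' LD-decay profile over fixed distance classes
#'
#' Assigns every intra-chromosome locus pair to a distance class (bins are
#' left-open, right-closed on the given upper edges, the first spanning
#' (0, edge1]) and reports the per-class mean r^2 among the samples of the
#' requested populations. Pairs beyond the last edge are ignored. For
#' tractability at chip scale, at most `max_pairs_per_class` pairs per
#' class are used, drawn by seeded uniform subsampling.
#'
#' @param g [genotype_matrix]
#' @param populations population labels (default: all)
#' @param class_edges_kb upper bin edges in kb
#'   (default 2.5, 5, 10, 20, 40, 80, 160)
#' @param max_pairs_per_class subsampling cap per class (default 10000)
#' @param seed subsampling seed
#' @return data.frame: `class_upper_kb`, `n_pairs` (used, after
#'   subsampling), `mean_r2` (`NA` for an empty class)
#' @export
ld_decay_profile <- function(g, populations = unique(g$populations),
                             class_edges_kb = c(2.5, 5, 10, 20, 40, 80, 160),
                             max_pairs_per_class = 10000L, seed = 1L) {
  gs <- if (setequal(populations, unique(g$populations))) g
        else subset_populations(g, populations)
  edges_bp <- sort(class_edges_kb) * 1000
  max_d <- max(edges_bp)
  loci <- gs$loci

  ## enumerate intra-chromosome pairs within max distance (loci are sorted)
  pair_i <- integer(0); pair_j <- integer(0)
  for (ch in unique(loci$chrom)) {
    sel <- which(loci$chrom == ch)
    pos <- loci$pos_bp[sel]
    hi <- findInterval(pos + max_d, pos)
    cnt <- hi - seq_along(pos)
    cnt[cnt < 0] <- 0L
    i0 <- rep(seq_along(pos), cnt)
    j0 <- sequence(cnt, from = seq_along(pos) + 1L)
    pair_i <- c(pair_i, sel[i0]); pair_j <- c(pair_j, sel[j0])
  }
  dist_bp <- loci$pos_bp[pair_j] - loci$pos_bp[pair_i]
  keep <- dist_bp > 0 & dist_bp <= max_d
  pair_i <- pair_i[keep]; pair_j <- pair_j[keep]; dist_bp <- dist_bp[keep]
  cls <- findInterval(dist_bp, edges_bp, left.open = TRUE) + 1L

  out <- data.frame(class_upper_kb = sort(class_edges_kb),
                    n_pairs = 0L, mean_r2 = NA_real_)
  set.seed(seed)
  for (k in seq_along(edges_bp)) {
    idx <- which(cls == k)
    if (!length(idx)) next
    if (length(idx) > max_pairs_per_class)
      idx <- sort(sample(idx, max_pairs_per_class))
    r2 <- vapply(idx, function(q)
      genotype_r2(gs$dosage[, pair_i[q]], gs$dosage[, pair_j[q]]),
      numeric(1))
    r2 <- r2[!is.na(r2)]
    out$n_pairs[k] <- length(r2)
    out$mean_r2[k] <- if (length(r2)) mean(r2) else NA_real_
  }
  out
}

#' Detect runs of homozygosity
#'
#' Per sample and chromosome, finds maximal stretches of consecutive SNPs
#' whose genotypes are homozygous, tolerating up to `max_het` heterozygous
#' and `max_missing` missing calls inside a run. A run is reported iff its
#' physical span (1-based inclusive, `end - start + 1`) is at least
#' `min_length_kb` kb, it contains at least `min_snps` SNPs, and (if set)
#' its SNP density is at least `min_density_snp_per_kb`. This is a
#' maximal-run definition with explicit tolerances, not the scanning-window
#' heuristic of PLINK `--homozyg`; for the tolerance defaults used here the
#' two agree on clean runs.
#'
#' @param g [genotype_matrix]
#' @param min_length_kb minimum span in kb (default 1000)
#' @param min_snps minimum SNP count in a run (default 50)
#' @param max_het heterozygous calls tolerated per run (default 0)
#' @param max_missing missing calls tolerated per run (default 1)
#' @param min_density_snp_per_kb optional minimum SNP density
#' @return data.frame: `sample`, `population`, `chrom`, `start_bp`,
#'   `end_bp`, `n_snps`, `length_bp`
#' @export
detect_roh <- function(g, min_length_kb = 1000, min_snps = 50L,
                       max_het = 0L, max_missing = 1L,
                       min_density_snp_per_kb = NULL) {
  segs <- list()
  for (ch in unique(g$loci$chrom)) {
    sel <- which(g$loci$chrom == ch)
    pos <- g$loci$pos_bp[sel]
    d <- g$dosage[, sel, drop = FALSE]
    for (si in seq_along(g$samples)) {
      runs <- homozygous_runs(d[si, ], max_het, max_missing)
      if (!nrow(runs)) next
      start <- pos[runs$from]; end <- pos[runs$to]
      n_snps <- runs$to - runs$from + 1L
      len <- end - start + 1L
      ok <- len >= min_length_kb * 1000 & n_snps >= min_snps
      if (!is.null(min_density_snp_per_kb))
        ok <- ok & (n_snps / (len / 1000) >= min_density_snp_per_kb)
      if (!any(ok)) next
      segs[[length(segs) + 1L]] <- data.frame(
        sample = g$samples[si],
        population = unname(g$populations[g$samples[si]]),
        chrom = ch, start_bp = start[ok], end_bp = end[ok],
        n_snps = n_snps[ok], length_bp = len[ok],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(segs))
    return(data.frame(sample = character(0), population = character(0),
                      chrom = character(0), start_bp = integer(0),
                      end_bp = integer(0), n_snps = integer(0),
                      length_bp = integer(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

## Maximal runs of indices [from, to] in a dosage vector where genotypes
## are in {0, 2}, allowing <= max_het values equal to 1 and <= max_missing
## NAs inside the run. Greedy left-to-right extension: a run starts at a
## homozygous call and is extended while the allowance is not exceeded;
## trailing het/missing calls are trimmed so runs start and end homozygous.
homozygous_runs <- function(geno, max_het, max_missing) {
  n <- length(geno)
  is_hom <- !is.na(geno) & geno != 1L
  is_het <- !is.na(geno) & geno == 1L
  from <- integer(0); to <- integer(0)
  i <- 1L
  while (i <= n) {
    if (!is_hom[i]) { i <- i + 1L; next }
    het <- 0L; mis <- 0L
    j <- i; last_hom <- i
    while (j < n) {
      nxt <- j + 1L
      if (is_hom[nxt]) { j <- nxt; last_hom <- nxt; next }
      if (is_het[nxt]) {
        if (het + 1L > max_het) break
        het <- het + 1L
      } else {
        if (mis + 1L > max_missing) break
        mis <- mis + 1L
      }
      j <- nxt
    }
    from <- c(from, i); to <- c(to, last_hom)
    i <- j + 1L
  }
  data.frame(from = from, to = to)
}

#' Mean ROH count per individual, by population
#'
#' @param segments output of [detect_roh()]
#' @param populations named character vector sample -> population (samples
#'   with zero segments count as 0)
#' @return data.frame: `population`, `n_samples`, `mean_segments`
#' @export
roh_counts_by_population <- function(segments, populations) {
  per_sample <- table(factor(segments$sample, levels = names(populations)))
  pops <- unique(unname(populations))
  out <- data.frame(
    population = pops,
    n_samples = vapply(pops, function(p) sum(populations == p), integer(1)),
    mean_segments = vapply(pops, function(p)
      mean(per_sample[names(populations)[populations == p]]), numeric(1)),
    stringsAsFactors = FALSE)
  out[out$n_samples > 0, , drop = FALSE]
}
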