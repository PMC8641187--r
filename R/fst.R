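#' Locus-level FST mean-square components
#'
#' From per-subpopulation sample sizes and alt-allele frequencies, computes
#' the components of the mean-squares FST estimator used throughout the
#' package:
#' \deqn{\bar p = \sum_i n_i p_i / \sum_i n_i}
#' \deqn{MSP = \frac{1}{s-1} \sum_i n_i (p_i - \bar p)^2}
#' \deqn{MSG = \frac{1}{(\sum_i n_i) - 1} \sum_i n_i p_i (1 - p_i)}
#' with `n_c` the arithmetic mean of the \eqn{n_i} (`nc = "mean"`, the
#' default) or the Weir-Cockerham variance-corrected size
#' \eqn{n_c = (\sum n_i - \sum n_i^2/\sum n_i)/(s-1)} (`nc = "wc"`).
#' The MSG denominator is \eqn{(\sum_i n_i) - 1} by default
#' (`msg_denom = "total_minus_1"`) with \eqn{\sum_i (n_i - 1)}
#' (`msg_denom = "sum_minus_1"`) as the classical alternative.
#'
#' @param n integer vector of diploid sample sizes per subpopulation
#' @param p alt-allele frequency per subpopulation
#' @param nc `"mean"` or `"wc"`
#' @param msg_denom `"total_minus_1"` or `"sum_minus_1"`
#' @return object of class `fst_components`: list with `msp`, `msg`, `n_c`,
#'   `s`, `p_bar`
#' @examples
#' locus_fst_components(n = c(20, 30), p = c(0.8, 0.3))
#' @export
locus_fst_components <- function(n, p, nc = c("mean", "wc"),
                                 msg_denom = c("total_minus_1", "sum_minus_1")) {
  nc <- match.arg(nc); msg_denom <- match.arg(msg_denom)
  s <- length(n)
  if (s < 2) stopf("need >= 2 subpopulations, got %d", s)
  if (length(p) != s) stopf("n and p must have equal length")
  if (any(n < 1)) stopf("every subpopulation needs n_i >= 1")
  if (anyNA(p)) stopf("undefined frequency in a subpopulation")
  n_tot <- sum(n)
  p_bar <- sum(n * p) / n_tot
  msp <- sum(n * (p - p_bar)^2) / (s - 1)
  denom <- if (msg_denom == "total_minus_1") n_tot - 1 else sum(n - 1)
  msg <- sum(n * p * (1 - p)) / denom
  n_c <- if (nc == "mean") mean(n) else (n_tot - sum(n^2) / n_tot) / (s - 1)
  structure(list(msp = msp, msg = msg, n_c = n_c, s = s, p_bar = p_bar),
            class = "fst_components")
}

#' Locus FST from mean-square components
#'
#' \deqn{F_{ST} = \frac{MSP - MSG}{MSP + (n_c - 1)\,MSG}}
#' Negative values (identical frequencies with finite samples) are retained.
#' A locus monomorphic across all subpopulations (MSP = MSG = 0) has an
#' undefined FST and returns `NA`.
#'
#' @param components `fst_components` from [locus_fst_components()]
#' @return FST value, or `NA` if undefined
#' @examples
#' locus_fst(locus_fst_components(c(20, 30), c(0.8, 0.3)))  # ~0.3667
#' @export
locus_fst <- function(components) {
  msp <- components$msp; msg <- components$msg; n_c <- components$n_c
  den <- msp + (n_c - 1) * msg
  if (den == 0) return(NA_real_)
  (msp - msg) / den
}

## Vectorised components over all loci of a genotype matrix, for a list of
## subpopulation sample index sets. Returns per-locus msp, msg, n_c and a
## defined flag (all subpopulations have n_i >= 1).
fst_components_matrix <- function(g, sample_sets, nc = "mean",
                                  msg_denom = "total_minus_1") {
  s <- length(sample_sets)
  L <- nrow(g$loci)
  nmat <- matrix(0, nrow = s, ncol = L)
  pmat <- matrix(NA_real_, nrow = s, ncol = L)
  for (i in seq_len(s)) {
    d <- g$dosage[sample_sets[[i]], , drop = FALSE]
    ni <- colSums(!is.na(d))
    nmat[i, ] <- ni
    pmat[i, ] <- ifelse(ni > 0, colSums(d, na.rm = TRUE) / (2 * ni), NA_real_)
  }
  defined <- colSums(nmat >= 1) == s & !colSums(is.na(pmat))
  n_tot <- colSums(nmat)
  p_bar <- colSums(nmat * pmat) / n_tot
  msp <- colSums(nmat * sweep(pmat, 2, p_bar, "-")^2) / (s - 1)
  denom <- if (msg_denom == "total_minus_1") n_tot - 1 else colSums(pmax(nmat - 1, 0))
  msg <- colSums(nmat * pmat * (1 - pmat)) / denom
  n_c <- if (nc == "mean") colMeans(nmat) else
    (n_tot - colSums(nmat^2) / n_tot) / (s - 1)
  ## loci monomorphic everywhere have undefined FST
  defined <- defined & !(msp == 0 & msg == 0)
  list(msp = ifelse(defined, msp, NA_real_),
       msg = ifelse(defined, msg, NA_real_),
       n_c = n_c, defined = defined,
       fst = ifelse(defined & (msp + (n_c - 1) * msg) != 0,
                    (msp - msg) / (msp + (n_c - 1) * msg), NA_real_))
}

#' Tile chromosomes with sliding windows
#'
#' Windows are half-open `[start, start + window_bp)` on 1-based
#' coordinates, starting at 1, 1 + step, 1 + 2 step, ... while the start
#' does not exceed the chromosome extent.
#'
#' @param chrom_extents named numeric vector: chromosome -> maximum
#'   position (bp) to cover
#' @param window_bp window size in bp
#' @param step_bp step in bp
#' @return data.frame with columns `chrom`, `start_bp`, `end_bp`
#' @examples
#' make_windows(c(`1` = 250000), 100000, 50000)  # 5 windows
#' @export
make_windows <- function(chrom_extents, window_bp, step_bp) {
  if (!(window_bp >= step_bp && step_bp >= 1))
    stopf("need window_bp >= step_bp >= 1")
  chroms <- names(chrom_extents)
  if (is.null(chroms)) stopf("chrom_extents must be named by chromosome")
  out <- lapply(chroms, function(ch) {
    starts <- seq(1, chrom_extents[[ch]], by = step_bp)
    data.frame(chrom = ch, start_bp = starts, end_bp = starts + window_bp,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

## Map loci to window indices for one chromosome's tiling.
## Returns a two-column matrix (locus index, window index), possibly with
## several rows per locus when windows overlap.
loci_window_pairs <- function(pos, window_bp, step_bp, n_windows) {
  j_hi <- (pos - 1) %/% step_bp            # last window with start <= pos
  j_lo <- pmax(0, ceiling((pos - window_bp) / step_bp))  # first with pos < start+window
  counts <- pmax(0L, j_hi - j_lo + 1L)
  li <- rep(seq_along(pos), counts)
  wi <- sequence(counts, from = as.integer(j_lo) + 1L)
  keep <- wi <= n_windows
  cbind(locus = li[keep], window = wi[keep])
}

#' Windowed FST between two population groups
#'
#' Computes per-locus mean-square components for the two groups (each
#' pooled as one subpopulation by default, or with its member populations
#' as separate subpopulations via `pool = FALSE`), then aggregates over
#' sliding windows. In `"weighted"` mode (the ratio-of-sums default,
#' matching windowed-FST conventions) the window value is
#' \eqn{\sum(MSP - MSG) / \sum(MSP + (n_c - 1) MSG)} over the window's
#' informative loci; `"mean"` mode averages defined locus FST values.
#' Windows with no informative locus are omitted.
#'
#' @param g [genotype_matrix]
#' @param scheme [population_scheme()]
#' @param groups character vector of two group labels to compare
#' @param window_bp,step_bp window tiling (defaults 100 kb / 50 kb)
#' @param mode `"weighted"` or `"mean"`
#' @param pool pool each group's populations into one subpopulation
#'   (default) or treat member populations as s > 2 subpopulations
#' @param nc,msg_denom estimator options, see [locus_fst_components()]
#' @param clamp_negative set negative window values to 0 for reporting
#' @return data.frame of window statistics: `chrom`, `start_bp`, `end_bp`,
#'   `n_loci`, `value`, `percentile_rank`
#' @export
windowed_fst <- function(g, scheme, groups, window_bp = 100000L,
                         step_bp = 50000L, mode = c("weighted", "mean"),
                         pool = TRUE, nc = "mean",
                         msg_denom = "total_minus_1",
                         clamp_negative = FALSE) {
  mode <- match.arg(mode)
  if (length(groups) != 2) stopf("groups must name exactly two groups")
  if (groups[1] == groups[2]) stopf("the two groups must differ")
  pops <- lapply(groups, function(gr) {
    if (!gr %in% names(scheme$groups)) stopf("group '%s' not in scheme", gr)
    scheme$groups[[gr]]
  })
  sample_sets <- if (pool) {
    lapply(pops, function(pp) which(g$populations %in% pp))
  } else {
    unlist(lapply(pops, function(pp)
      lapply(pp, function(one) which(g$populations %in% one))), recursive = FALSE)
  }
  if (any(!lengths(sample_sets))) stopf("a subpopulation has no samples")
  comp <- fst_components_matrix(g, sample_sets, nc = nc, msg_denom = msg_denom)
  window_aggregate(g$loci, comp, window_bp, step_bp, mode,
                   clamp_negative = clamp_negative)
}

## Shared window aggregation for FST components.
window_aggregate <- function(loci, comp, window_bp, step_bp, mode,
                             clamp_negative = FALSE) {
  extents <- tapply(loci$pos_bp, loci$chrom, max)
  chroms <- unique(loci$chrom)   # already natural-sorted in the container
  res <- lapply(chroms, function(ch) {
    sel <- which(loci$chrom == ch)
    pos <- loci$pos_bp[sel]
    starts <- seq(1, extents[[ch]], by = step_bp)
    pairs <- loci_window_pairs(pos, window_bp, step_bp, length(starts))
    li <- sel[pairs[, "locus"]]; wi <- pairs[, "window"]
    ok <- comp$defined[li]
    li <- li[ok]; wi <- wi[ok]
    if (!length(li)) return(NULL)
    num <- tapply(comp$msp[li] - comp$msg[li], wi, sum)
    den <- tapply(comp$msp[li] + (comp$n_c[li] - 1) * comp$msg[li], wi, sum)
    nl <- tapply(li, wi, length)
    w <- as.integer(names(num))
    value <- if (mode == "weighted") as.numeric(num) / as.numeric(den)
             else as.numeric(tapply(comp$fst[li], wi, mean, na.rm = TRUE))
    data.frame(chrom = ch, start_bp = starts[w], end_bp = starts[w] + window_bp,
               n_loci = as.integer(nl), value = value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out) || !nrow(out)) stopf("no informative locus in any window")
  if (clamp_negative) out$value <- pmax(out$value, 0)
  out$percentile_rank <- rank(out$value, ties.method = "max") / nrow(out)
  rownames(out) <- NULL
  out
}
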