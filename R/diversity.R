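#' Per-site nucleotide diversity
#'
#' The proportion of pairwise differences among the sampled chromosomes at
#' one site: \eqn{\pi = a (n - a) / \binom{n}{2}} for `a` alt alleles among
#' `n` non-missing chromosomes. Equals \eqn{2\hat p(1-\hat p)\,n/(n-1)}.
#' Vectorised.
#'
#' @param n_chr non-missing allele (chromosome) count, >= 2
#' @param alt_count alt-allele count, 0 <= alt_count <= n_chr
#' @return per-site diversity in [0, 1]; `NA` where `n_chr < 2`
#' @examples
#' site_pi(20, 8)  # 96/190
#' @export
site_pi <- function(n_chr, alt_count) {
  if (any(alt_count > n_chr, na.rm = TRUE))
    stopf("alt_count cannot exceed n_chr")
  ifelse(n_chr >= 2,
         alt_count * (n_chr - alt_count) / choose(n_chr, 2), NA_real_)
}

#' Windowed nucleotide diversity for a set of populations
#'
#' Chromosomes of all samples in `populations` are pooled; per-bp window
#' diversity is the sum of per-site values over the window's variant sites
#' divided by the window length (monomorphic and unassayed positions
#' contribute zero through the denominator, the convention of windowed-pi
#' implementations for chip data).
#'
#' @param g [genotype_matrix]
#' @param populations population labels to pool (default: all)
#' @param window_bp,step_bp tiling (defaults 50 kb / 25 kb)
#' @param drop_empty drop windows containing no usable site instead of
#'   reporting them as 0 (default `FALSE`: retained as 0)
#' @return data.frame of window statistics: `chrom`, `start_bp`, `end_bp`,
#'   `n_loci`, `value`, `percentile_rank`
#' @export
windowed_pi <- function(g, populations = unique(g$populations),
                        window_bp = 50000L, step_bp = 25000L,
                        drop_empty = FALSE) {
  gs <- if (setequal(populations, unique(g$populations))) g
        else subset_populations(g, populations)
  d <- gs$dosage
  n_chr <- 2L * colSums(!is.na(d))
  alt <- colSums(d, na.rm = TRUE)
  pi_site <- site_pi(n_chr, alt)
  usable <- !is.na(pi_site)

  loci <- g$loci
  extents <- tapply(loci$pos_bp, loci$chrom, max)
  chroms <- unique(loci$chrom)
  res <- lapply(chroms, function(ch) {
    sel <- which(loci$chrom == ch)
    starts <- seq(1, extents[[ch]], by = step_bp)
    pairs <- loci_window_pairs(loci$pos_bp[sel], window_bp, step_bp,
                               length(starts))
    li <- sel[pairs[, "locus"]]; wi <- pairs[, "window"]
    ok <- usable[li]
    li <- li[ok]; wi <- wi[ok]
    value <- numeric(length(starts))
    nl <- integer(length(starts))
    if (length(li)) {
      sums <- tapply(pi_site[li], wi, sum)
      cnts <- tapply(li, wi, length)
      w <- as.integer(names(sums))
      value[w] <- as.numeric(sums) / window_bp
      nl[w] <- as.integer(cnts)
    }
    data.frame(chrom = ch, start_bp = starts, end_bp = starts + window_bp,
               n_loci = nl, value = value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (drop_empty) out <- out[out$n_loci > 0, , drop = FALSE]
  out$percentile_rank <- rank(out$value, ties.method = "max") / nrow(out)
  rownames(out) <- NULL
  out
}

## Window identity key shared by the scan functions.
window_key <- function(w) paste(w$chrom, w$start_bp, w$end_bp, sep = ":")

#' Between-group diversity-difference scan
#'
#' Per shared window computes \eqn{\Delta\pi = \pi_{reference} -
#' \pi_{focal}}; large positive values indicate diversity loss (a candidate
#' sweep) in the focal group. Windows at or above the empirical
#' `1 - top_fraction` quantile (nearest-rank; threshold ties included) are
#' returned. Windows present in only one input are dropped with a message.
#'
#' @param pi_reference,pi_focal window tables from [windowed_pi()] on the
#'   same tiling; the focal group is the one being screened for sweeps
#' @param top_fraction upper tail fraction (default 0.01)
#' @return list with `windows` (all shared windows with `value` = delta-pi
#'   and `percentile_rank`) and `outliers` (the top windows)
#' @export
delta_pi_scan <- function(pi_reference, pi_focal, top_fraction = 0.01) {
  ka <- window_key(pi_reference); kb <- window_key(pi_focal)
  shared <- intersect(ka, kb)
  if (!length(shared)) stopf("the two window tilings are disjoint")
  dropped <- length(ka) - length(shared) + length(kb) - length(shared)
  if (dropped > 0)
    message(sprintf("delta_pi_scan: dropped %d window(s) absent from one input",
                    dropped))
  a <- pi_reference[match(shared, ka), ]
  b <- pi_focal[match(shared, kb), ]
  w <- a[, c("chrom", "start_bp", "end_bp")]
  w$n_loci <- pmax(a$n_loci, b$n_loci)
  w$value <- a$value - b$value
  w$percentile_rank <- rank(w$value, ties.method = "max") / nrow(w)
  rownames(w) <- NULL
  list(windows = w, outliers = empirical_outliers(w, top_fraction))
}

#' Empirical outlier windows of a scan statistic
#'
#' Threshold = the nearest-rank empirical `1 - top_fraction` quantile of
#' the window values; every window with value >= threshold is returned
#' (ties at the threshold all included).
#'
#' @param stats data.frame of window statistics with a `value` column
#' @param top_fraction upper tail fraction, e.g. 0.05 or 0.01
#' @return the outlier rows of `stats`, `percentile_rank` filled
#' @export
empirical_outliers <- function(stats, top_fraction = 0.05) {
  if (!nrow(stats)) stopf("empty window table")
  if (!(top_fraction > 0 && top_fraction < 1))
    stopf("top_fraction must be in (0, 1)")
  n <- nrow(stats)
  if (n < 1 / top_fraction)
    warnf("only %d windows for top fraction %g; quantile is coarse",
          n, top_fraction)
  v <- stats$value
  if (length(unique(v)) == 1)
    warnf("all window values identical; returning every window")
  ## nearest-rank upper-tail quantile: the ceiling(tf * n)-th largest value
  k <- min(n, max(1, ceiling(top_fraction * n)))
  thr <- sort(v, decreasing = TRUE)[k]
  out <- stats[v >= thr, , drop = FALSE]
  out$percentile_rank <- rank(v, ties.method = "max")[v >= thr] / n
  out[order(-out$value, out$chrom, out$start_bp), , drop = FALSE]
}
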