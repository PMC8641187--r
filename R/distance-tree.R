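#' Allele-sharing (IBS) distance matrix
#'
#' Sample level: `d(a, b) = 1 - shared alleles / (2 x complete loci)`,
#' which for dosage vectors equals `mean(|x - y|) / 2` over loci complete
#' in both samples. Population level: member-sample dosages are averaged
#' into an alt-frequency vector per population and
#' `d(a, b) = mean(|p_a - p_b|)`, the frequency analogue of the same
#' dissimilarity.
#'
#' @param g [genotype_matrix]
#' @param level `"population"` (default) or `"sample"`
#' @return symmetric numeric matrix with zero diagonal, labelled by
#'   population or sample
#' @export
ibs_distance <- function(g, level = c("population", "sample")) {
  level <- match.arg(level)
  if (level == "sample") {
    x <- g$dosage
    n <- nrow(x)
    if (n < 2) stopf("need >= 2 samples")
    d <- matrix(0, n, n, dimnames = list(g$samples, g$samples))
    if (!anyNA(x))  # fast path: Manhattan distance / (2 x loci)
      return(as.matrix(stats::dist(x, method = "manhattan")) / (2 * ncol(x)))
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
      ok <- !is.na(x[a, ]) & !is.na(x[b, ])
      if (!any(ok))
        stopf("samples %s and %s share no complete locus",
              g$samples[a], g$samples[b])
      d[a, b] <- d[b, a] <- mean(abs(x[a, ok] - x[b, ok])) / 2
    }
    return(d)
  }
  pops <- unique(unname(g$populations))
  if (length(pops) < 2) stopf("need >= 2 populations")
  freq <- sapply(pops, function(p) {
    dd <- g$dosage[g$populations == p, , drop = FALSE]
    nn <- colSums(!is.na(dd))
    ifelse(nn > 0, colSums(dd, na.rm = TRUE) / (2 * nn), NA_real_)
  })
  d <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (a in seq_len(length(pops) - 1)) for (b in (a + 1):length(pops)) {
    ok <- !is.na(freq[, a]) & !is.na(freq[, b])
    if (!any(ok)) stopf("populations %s and %s share no defined locus",
                        pops[a], pops[b])
    d[a, b] <- d[b, a] <- mean(abs(freq[ok, a] - freq[ok, b]))
  }
  d
}

#' Neighbour-joining tree
#'
#' Saitou-Nei neighbour joining in the Studier-Keppler formulation, with
#' two determinism/robustness conventions: ties in the Q matrix are broken
#' by the lexicographically smallest label-index pair, and a negative
#' branch length is clamped to zero with the deficit moved to its sibling
#' edge (disable with `clamp_negative = FALSE`). On an additive distance
#' matrix the tree's path lengths reproduce the input exactly. The result
#' is an unrooted `ape::phylo` object.
#'
#' @param d symmetric non-negative distance matrix with labels
#' @param clamp_negative clamp negative branch lengths (default TRUE)
#' @return an `ape` `phylo` tree
#' @export
nj_tree <- function(d, clamp_negative = TRUE) {
  d <- as.matrix(d)
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  if (nrow(d) < 3) stopf("need >= 3 labels")
  if (any(d < 0)) stopf("distance matrix has negative entries")
  if (max(abs(d - t(d))) > 1e-8) stopf("distance matrix is not symmetric")
  labels <- rownames(d)
  n0 <- nrow(d)
  ## each active node carries a newick fragment
  frag <- labels
  active <- seq_len(n0)
  D <- d
  while (length(active) > 3) {
    m <- length(active)
    Dm <- D[active, active, drop = FALSE]
    R <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(R, R, "+")
    diag(Q) <- Inf
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    i <- best[1]; j <- best[2]
    dij <- Dm[i, j]
    li <- dij / 2 + (R[i] - R[j]) / (2 * (m - 2))
    lj <- dij - li
    if (clamp_negative) {
      if (li < 0) { lj <- lj + li; li <- 0 }
      if (lj < 0) { li <- max(0, li + lj); lj <- 0 }
    }
    ai <- active[i]; aj <- active[j]
    new_frag <- sprintf("(%s:%s,%s:%s)", frag[ai], format_bl(li),
                        frag[aj], format_bl(lj))
    ## distances from the new node u to every other active node
    others <- active[-c(i, j)]
    du <- (D[ai, others] + D[aj, others] - dij) / 2
    D <- rbind(cbind(D, 0), 0)
    u <- nrow(D)
    D[u, others] <- du; D[others, u] <- du
    frag <- c(frag, new_frag)
    active <- c(others, u)
  }
  ## resolve the final three nodes around the central vertex
  a <- active[1]; b <- active[2]; c3 <- active[3]
  la <- (D[a, b] + D[a, c3] - D[b, c3]) / 2
  lb <- (D[a, b] + D[b, c3] - D[a, c3]) / 2
  lc <- (D[a, c3] + D[b, c3] - D[a, b]) / 2
  if (clamp_negative) { la <- max(la, 0); lb <- max(lb, 0); lc <- max(lc, 0) }
  newick <- sprintf("(%s:%s,%s:%s,%s:%s);", frag[a], format_bl(la),
                    frag[b], format_bl(lb), frag[c3], format_bl(lc))
  ape::read.tree(text = newick)
}

format_bl <- function(x) formatC(x, digits = 12, format = "g")

#' Bootstrap support for a neighbour-joining tree
#'
#' Resamples loci with replacement, rebuilds the distance matrix and NJ
#' tree per replicate, and annotates each internal bipartition of the
#' reference tree with the percentage of replicates containing it
#' (unrooted bipartition matching via `ape::prop.clades`). Supports are
#' stored in `node.label`.
#'
#' @param g [genotype_matrix]
#' @param replicates bootstrap replicate count (default 1000)
#' @param seed RNG seed
#' @param level `"population"` or `"sample"` (see [ibs_distance()])
#' @return list with `tree` (reference `phylo`, `node.label` = support
#'   percentages, root label empty) and `replicates`
#' @export
bootstrap_support <- function(g, replicates = 1000L, seed = 1L,
                              level = c("population", "sample")) {
  level <- match.arg(level)
  if (replicates < 1) stopf("replicates must be >= 1")
  ref <- nj_tree(ibs_distance(g, level))
  L <- nrow(g$loci)
  set.seed(seed)
  boots <- lapply(seq_len(replicates), function(r) {
    idx <- sample.int(L, L, replace = TRUE)
    gb <- g
    gb$dosage <- g$dosage[, idx, drop = FALSE]
    ## resampled loci need not be re-sorted: distances ignore coordinates
    nj_tree(ibs_distance(gb, level))
  })
  cnt <- ape::prop.clades(ref, boots, rooted = FALSE)
  cnt[is.na(cnt)] <- 0
  supp <- round(100 * cnt / replicates, 1)
  ref$node.label <- as.character(supp)
  ref$node.label[1] <- ""   # root of the unrooted representation
  list(tree = ref, replicates = replicates)
}

#' Write a tree to a Newick file
#'
#' Branch lengths are kept; any `node.label` support values become internal
#' labels. Labels with spaces are quoted by `ape::write.tree`.
#'
#' @param tree an `ape` `phylo` object (or the list from
#'   [bootstrap_support()])
#' @param path output file
#' @return invisibly, `path`
#' @export
write_newick <- function(tree, path) {
  if (is.list(tree) && !inherits(tree, "phylo") && !is.null(tree$tree))
    tree <- tree$tree
  ape::write.tree(tree, file = path)
  invisible(path)
}
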