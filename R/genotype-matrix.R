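#' Genotype matrix container
#'
#' The central data structure of the package: a samples x loci matrix of
#' diploid alt-allele dosages (0, 1, 2 or `NA` for a missing call) together
#' with locus coordinates and a sample-to-population label map. Loci are
#' stored sorted by chromosome (natural order) and 1-based physical
#' position; genomic windows elsewhere in the package are half-open
#' `[start, end)` intervals on the same 1-based coordinates.
#'
#' @param dosage integer matrix, samples in rows, loci in columns; values in
#'   \{0, 1, 2, NA\} counting copies of the alt allele.
#' @param loci data.frame with columns `chrom` (character), `pos_bp`
#'   (1-based integer position), `locus_id`, `ref_allele`, `alt_allele`.
#' @param populations named character vector mapping sample id to
#'   population label; names must cover `rownames(dosage)`.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosage`, `loci`, `samples`, `populations`.
#' @examples
#' g <- genotype_matrix(
#'   dosage = rbind(s1 = c(0L, 1L), s2 = c(2L, NA)),
#'   loci = data.frame(chrom = "1", pos_bp = c(100L, 200L),
#'                     locus_id = c("m1", "m2"),
#'                     ref_allele = "A", alt_allele = "G"),
#'   populations = c(s1 = "Moghani", s2 = "Texel"))
#' g
#' @export
genotype_matrix <- function(dosage, loci, populations) {
  if (is.null(rownames(dosage))) stopf("dosage must have sample ids as rownames")
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  need <- c("chrom", "pos_bp", "locus_id", "ref_allele", "alt_allele")
  missing_cols <- setdiff(need, names(loci))
  if (length(missing_cols))
    stopf("loci is missing column(s): %s", paste(missing_cols, collapse = ", "))
  if (ncol(dosage) != nrow(loci))
    stopf("dosage has %d loci but loci table has %d rows", ncol(dosage), nrow(loci))
  if (any(loci$pos_bp < 1)) stopf("locus positions must be >= 1 (1-based)")
  bad <- !(dosage %in% c(0L, 1L, 2L) | is.na(dosage))
  if (any(bad)) stopf("dosage contains values outside {0, 1, 2, NA}")
  storage.mode(dosage) <- "integer"

  samples <- rownames(dosage)
  absent <- setdiff(samples, names(populations))
  if (length(absent))
    stopf("sample(s) without a population label: %s",
          paste(head(absent, 5), collapse = ", "))
  populations <- populations[samples]

  ## canonical locus order: natural chromosome, then position, then id
  chrom_levels <- unique(loci$chrom[natural_chrom_order(loci$chrom)])
  ord <- order(match(loci$chrom, chrom_levels), loci$pos_bp, loci$locus_id)
  loci <- loci[ord, , drop = FALSE]
  dosage <- dosage[, ord, drop = FALSE]
  rownames(loci) <- NULL

  dup <- duplicated(loci[, c("chrom", "pos_bp")])
  if (any(dup))
    stopf("duplicate (chrom, pos) coordinates, first at %s:%d",
          loci$chrom[dup][1], loci$pos_bp[dup][1])
  colnames(dosage) <- loci$locus_id

  structure(list(dosage = dosage, loci = loci, samples = samples,
                 populations = populations),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d loci, %d chromosome(s), %d population(s)\n",
              length(x$samples), nrow(x$loci),
              length(unique(x$loci$chrom)), length(unique(x$populations))))
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Population grouping scheme
#'
#' Assigns population labels to named, disjoint groups (e.g. an
#' `indigenous` group of local breeds vs `meat` and `milk` commercial
#' groups), the unit of the pairwise group comparisons in the scan.
#'
#' @param groups named list of character vectors; names are group labels,
#'   values the population labels in each group.
#' @return object of class `population_scheme`
#' @examples
#' population_scheme(list(indigenous = c("Moghani", "Afshari", "Gezel"),
#'                        meat = c("DorsetHorn", "Texel")))
#' @export
population_scheme <- function(groups) {
  if (!length(groups) || is.null(names(groups)) || any(names(groups) == ""))
    stopf("groups must be a non-empty named list")
  if (any(!lengths(groups))) stopf("every group must be non-empty")
  all_pops <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_pops))
    stopf("groups must be disjoint; duplicated: %s",
          paste(unique(all_pops[duplicated(all_pops)]), collapse = ", "))
  structure(list(groups = lapply(groups, as.character)),
            class = "population_scheme")
}

#' @export
print.population_scheme <- function(x, ...) {
  for (g in names(x$groups))
    cat(sprintf("%s: %s\n", g, paste(x$groups[[g]], collapse = ", ")))
  invisible(x)
}

#' Read a population scheme from a JSON config
#'
#' The file holds one JSON object mapping group label to an array of
#' population labels.
#'
#' @param path JSON file path
#' @return `population_scheme`
#' @export
read_population_scheme <- function(path) {
  population_scheme(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Subset a genotype matrix to the samples of one group
#'
#' @param g `genotype_matrix`
#' @param scheme `population_scheme`
#' @param group group label defined in `scheme`
#' @return `genotype_matrix` with only the group's samples; sample order and
#'   loci unchanged.
#' @export
subset_by_group <- function(g, scheme, group) {
  if (!group %in% names(scheme$groups))
    stopf("group '%s' not defined in scheme (has: %s)", group,
          paste(names(scheme$groups), collapse = ", "))
  subset_populations(g, scheme$groups[[group]])
}

#' Subset a genotype matrix to a set of populations
#'
#' @param g `genotype_matrix`
#' @param populations character vector of population labels
#' @return `genotype_matrix`
#' @export
subset_populations <- function(g, populations) {
  unknown <- setdiff(populations, unique(g$populations))
  if (length(unknown))
    stopf("unknown population label(s): %s", paste(unknown, collapse = ", "))
  keep <- g$samples[g$populations %in% populations]
  if (!length(keep)) stopf("no samples left after subsetting")
  genotype_matrix(g$dosage[keep, , drop = FALSE], g$loci,
                  g$populations[keep])
}

#' Subset a genotype matrix to a set of loci
#'
#' @param g `genotype_matrix`
#' @param idx integer locus indices or character locus ids
#' @return `genotype_matrix`
#' @export
subset_loci <- function(g, idx) {
  if (is.character(idx)) {
    pos <- match(idx, g$loci$locus_id)
    if (anyNA(pos)) stopf("unknown locus id(s): %s",
                          paste(head(idx[is.na(pos)], 5), collapse = ", "))
    idx <- pos
  }
  genotype_matrix(g$dosage[, idx, drop = FALSE],
                  g$loci[idx, , drop = FALSE], g$populations)
}

#' Per-locus allele frequencies within a set of populations
#'
#' For each locus, counts the diploid samples with a non-missing call
#' (`n`) and the alt-allele frequency `p = alt copies / (2 n)` among the
#' requested populations. Loci with zero non-missing calls are flagged
#' undefined (`p = NA`).
#'
#' @param g `genotype_matrix`
#' @param populations character vector of population labels (default: all)
#' @return data.frame with columns `locus_id`, `chrom`, `pos_bp`, `n`
#'   (non-missing diploid count), `p` (alt frequency), `undefined` (logical)
#' @export
allele_frequencies <- function(g, populations = unique(g$populations)) {
  gs <- if (setequal(populations, unique(g$populations))) g
        else subset_populations(g, populations)
  d <- gs$dosage
  n <- colSums(!is.na(d))
  alt <- colSums(d, na.rm = TRUE)
  p <- ifelse(n > 0, alt / (2 * n), NA_real_)
  data.frame(locus_id = g$loci$locus_id, chrom = g$loci$chrom,
             pos_bp = g$loci$pos_bp, n = as.integer(n), p = p,
             undefined = n == 0L, stringsAsFactors = FALSE)
}
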