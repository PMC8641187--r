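#' Read PLINK text PED/MAP files
#'
#' Parses whitespace-delimited PED (6 header columns, then two allele
#' columns per locus, "0" = missing allele) and MAP (chrom, id, cM, bp)
#' files into a [genotype_matrix]. The PED family-ID column is used as the
#' population label. Because PED is unpolarised, the alt allele defaults to
#' the minor allele computed over all samples; a two-column reference file
#' (`locus_id<TAB>ref_allele`) can override the orientation. FST, pi, r2
#' and IBS distances are all invariant to this choice.
#'
#' @param ped_path path to .ped file
#' @param map_path path to .map file
#' @param ref_alleles optional path to a TSV `locus_id<TAB>ref_allele`
#'   fixing the ref (non-counted) allele per locus
#' @return [genotype_matrix]
#' @export
read_ped_map <- function(ped_path, map_path, ref_alleles = NULL) {
  for (p in c(ped_path, map_path))
    if (!file.exists(p)) stopf("file not found: %s", p)
  map <- data.table::fread(map_path, header = FALSE, colClasses = "character",
                           data.table = FALSE)
  if (ncol(map) < 4) stopf("MAP file must have 4 columns, found %d", ncol(map))
  n_loci <- nrow(map)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  expected <- 6L + 2L * n_loci
  nf <- lengths(fields)
  if (any(nf != expected))
    stopf("PED line %d has %d columns; expected %d (6 + 2 x %d MAP loci)",
          which(nf != expected)[1], nf[nf != expected][1], expected, n_loci)

  ped <- do.call(rbind, fields)
  fam <- ped[, 1]
  iid <- ped[, 2]
  if (anyDuplicated(iid)) iid <- paste(fam, iid, sep = "_")
  a1 <- ped[, 6L + 2L * seq_len(n_loci) - 1L, drop = FALSE]
  a2 <- ped[, 6L + 2L * seq_len(n_loci), drop = FALSE]

  ref <- alt <- character(n_loci)
  dosage <- matrix(NA_integer_, nrow = length(iid), ncol = n_loci)
  override <- NULL
  if (!is.null(ref_alleles)) {
    o <- data.table::fread(ref_alleles, header = FALSE, data.table = FALSE,
                           colClasses = "character")
    override <- setNames(o[[2]], o[[1]])
  }
  for (j in seq_len(n_loci)) {
    al <- c(a1[, j], a2[, j])
    obs <- al[al != "0"]
    alleles <- sort(unique(obs))
    if (length(alleles) > 2)
      stopf("locus %s is not biallelic (alleles: %s)", map[j, 2],
            paste(alleles, collapse = ","))
    if (length(alleles) == 0) alleles <- c("N", "N")
    if (length(alleles) == 1) alleles <- c(alleles, alleles)
    cnt <- c(sum(obs == alleles[1]), sum(obs == alleles[2]))
    ## alt = minor allele (ties broken by sort order) unless overridden
    if (cnt[1] < cnt[2]) { altj <- alleles[1]; refj <- alleles[2] }
    else                 { altj <- alleles[2]; refj <- alleles[1] }
    if (!is.null(override) && !is.na(override[map[j, 2]])) {
      refj <- unname(override[map[j, 2]])
      altj <- setdiff(alleles, refj)[1]
      if (is.na(altj)) altj <- refj
    }
    ref[j] <- refj; alt[j] <- altj
    miss <- a1[, j] == "0" | a2[, j] == "0"
    dj <- (a1[, j] == altj) + (a2[, j] == altj)
    dj[miss] <- NA_integer_
    dosage[, j] <- as.integer(dj)
  }
  rownames(dosage) <- iid
  loci <- data.frame(chrom = map[[1]], pos_bp = as.integer(map[[4]]),
                     locus_id = map[[2]], ref_allele = ref, alt_allele = alt,
                     stringsAsFactors = FALSE)
  genotype_matrix(dosage, loci, setNames(fam, iid))
}

#' Write PLINK text PED/MAP files
#'
#' Inverse of [read_ped_map()]: the population label is written as the
#' family ID, missing calls as "0 0".
#'
#' @param g [genotype_matrix]
#' @param ped_path,map_path output paths
#' @return invisibly, the two paths
#' @export
write_ped_map <- function(g, ped_path, map_path) {
  loci <- g$loci
  data.table::fwrite(data.frame(loci$chrom, loci$locus_id, 0L, loci$pos_bp),
                     map_path, sep = "\t", col.names = FALSE)
  n_loci <- nrow(loci)
  alle <- matrix("0", nrow = length(g$samples), ncol = 2L * n_loci)
  for (j in seq_len(n_loci)) {
    d <- g$dosage[, j]
    a1 <- ifelse(is.na(d), "0", ifelse(d >= 1, loci$alt_allele[j], loci$ref_allele[j]))
    a2 <- ifelse(is.na(d), "0", ifelse(d == 2, loci$alt_allele[j], loci$ref_allele[j]))
    alle[, 2L * j - 1L] <- a1
    alle[, 2L * j] <- a2
  }
  out <- cbind(unname(g$populations), g$samples, "0", "0", "0", "-9", alle)
  data.table::fwrite(as.data.frame(out), ped_path, sep = " ",
                     col.names = FALSE, quote = FALSE)
  invisible(c(ped_path, map_path))
}

#' Read a two-column sample-to-population map
#'
#' @param path TSV path with columns sample, population (no header)
#' @return named character vector sample -> population
#' @export
read_population_map <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  m <- data.table::fread(path, header = FALSE, data.table = FALSE,
                         colClasses = "character")
  if (ncol(m) < 2) stopf("population map must have 2 columns")
  setNames(m[[2]], m[[1]])
}

#' Write a two-column sample-to-population map
#' @param populations named character vector sample -> population
#' @param path output TSV path
#' @return invisibly, `path`
#' @export
write_population_map <- function(populations, path) {
  data.table::fwrite(data.frame(names(populations), unname(populations)),
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}
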