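#' Read gene intervals from BED or GFF3
#'
#' BED input is 0-based half-open and is converted to the package's
#' internal 1-based half-open convention (`[start+1, end+1)` covering the
#' same bases); GFF3 `gene` features are 1-based inclusive and become
#' `[start, end+1)`. Strand is recorded but ignored for overlap. Duplicate
#' gene ids are an error.
#'
#' @param path file path
#' @param format `"bed"` or `"gff3"` (default: guessed from the extension)
#' @return data.frame: `chrom`, `start_bp`, `end_bp` (1-based half-open),
#'   `gene_id`, `gene_name`, `strand`
#' @export
read_gene_intervals <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("gff", "gff3")) "gff3" else "bed"
  }
  validate_interval_lines(path, format)
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3")
  if (format == "gff3") {
    type_col <- S4Vectors::mcols(gr)$type
    if (!is.null(type_col)) gr <- gr[as.character(type_col) == "gene"]
    ids <- S4Vectors::mcols(gr)$ID %||% S4Vectors::mcols(gr)$gene_id
    nm <- S4Vectors::mcols(gr)$Name %||% ids
  } else {
    ids <- S4Vectors::mcols(gr)$name
    nm <- ids
  }
  if (is.null(ids) || anyNA(ids))
    stopf("every gene interval needs an id (BED name / GFF3 ID attribute)")
  ids <- as.character(ids)
  if (anyDuplicated(ids))
    stopf("duplicate gene_id: %s", ids[duplicated(ids)][1])
  ## rtracklayer ranges are 1-based inclusive; half-open end = end + 1
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start_bp = GenomicRanges::start(gr),
                    end_bp = GenomicRanges::end(gr) + 1L,
                    gene_id = ids, gene_name = as.character(nm),
                    strand = as.character(GenomicRanges::strand(gr)),
                    stringsAsFactors = FALSE)
  if (any(out$end_bp <= out$start_bp)) stopf("gene interval with end <= start")
  out
}

## Cheap structural validation so malformed lines are reported by number.
validate_interval_lines <- function(path, format) {
  lines <- readLines(path)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "#") || startsWith(ln, "track") ||
        startsWith(ln, "browser")) next
    f <- strsplit(ln, "\t")[[1]]
    if (format == "bed" && length(f) == 1) f <- strsplit(ln, "[ \t]+")[[1]]
    min_fields <- if (format == "bed") 3L else 9L
    ok <- length(f) >= min_fields &&
      !is.na(suppressWarnings(as.numeric(f[if (format == "bed") 2 else 4]))) &&
      !is.na(suppressWarnings(as.numeric(f[if (format == "bed") 3 else 5])))
    if (!ok) stopf("malformed %s line %d in %s", toupper(format), i, path)
  }
  invisible(TRUE)
}

#' Genes overlapping outlier regions
#'
#' A gene overlaps a region iff the two half-open intervals intersect in at
#' least 1 bp on the same chromosome (abutting intervals do not overlap).
#' Overlap is computed with `GenomicRanges::findOverlaps`.
#'
#' @param regions data.frame with `chrom`, `start_bp`, `end_bp` (1-based
#'   half-open), e.g. outlier windows from the scans
#' @param genes data.frame from [read_gene_intervals()]
#' @return data.frame with one row per (region, gene) overlap: region
#'   coordinates, `gene_id`, `gene_name`
#' @export
genes_in_regions <- function(regions, genes) {
  if (!nrow(regions) || !nrow(genes))
    return(data.frame(chrom = character(0), start_bp = integer(0),
                      end_bp = integer(0), gene_id = character(0),
                      gene_name = character(0), stringsAsFactors = FALSE))
  ## half-open [start, end) -> inclusive [start, end - 1]
  r <- GenomicRanges::GRanges(regions$chrom,
                              IRanges::IRanges(regions$start_bp,
                                               regions$end_bp - 1L))
  ge <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start_bp,
                                                genes$end_bp - 1L))
  ## differing chromosome sets between query and annotation are expected
  ## for chip data; the seqlevel-mismatch warning is noise here
  hits <- suppressWarnings(GenomicRanges::findOverlaps(r, ge, minoverlap = 1L))
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  out <- data.frame(chrom = regions$chrom[qi],
                    start_bp = regions$start_bp[qi],
                    end_bp = regions$end_bp[qi],
                    gene_id = genes$gene_id[si],
                    gene_name = genes$gene_name[si],
                    stringsAsFactors = FALSE)
  unique(out)
}

#' Read a GMT-style gene-set file
#'
#' Tab-separated lines: term id, description, then member gene ids.
#'
#' @param path GMT file path
#' @return named list of character vectors (term -> genes), with a
#'   `descriptions` attribute
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t")
  bad <- which(lengths(parts) < 3)
  if (length(bad)) stopf("malformed GMT line %d in %s", bad[1], path)
  terms <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(terms) <- vapply(parts, `[[`, character(1), 1)
  attr(terms, "descriptions") <-
    setNames(vapply(parts, `[[`, character(1), 2), names(terms))
  terms
}

#' Hypergeometric overrepresentation test with BH correction
#'
#' For each term, the one-sided upper-tail hypergeometric p-value
#' `P(X >= overlap)` of drawing `query_size` genes from the universe;
#' Benjamini-Hochberg step-up adjustment across the tested terms. Terms
#' with no gene in the universe are skipped.
#'
#' @param query_genes character vector of candidate genes (must be a
#'   subset of `universe`)
#' @param term_map named list term -> gene vector (see [read_gmt()])
#' @param universe character vector of all assayable genes
#' @param alpha significance threshold applied to the BH-adjusted p
#'   (default 0.05); all terms are returned with a `significant` flag
#' @return data.frame sorted by adjusted p: `term_id`, `overlap_count`,
#'   `term_size`, `query_size`, `universe_size`, `p_value`,
#'   `bh_adjusted_p`, `significant`
#' @export
enrichment_bh <- function(query_genes, term_map, universe, alpha = 0.05) {
  query_genes <- unique(query_genes); universe <- unique(universe)
  if (!length(query_genes)) stopf("empty query gene set")
  if (!length(universe)) stopf("empty universe")
  stray <- setdiff(query_genes, universe)
  if (length(stray))
    stopf("query gene(s) not in universe: %s",
          paste(head(stray, 5), collapse = ", "))
  N <- length(universe); q <- length(query_genes)
  rows <- lapply(names(term_map), function(tid) {
    tg <- intersect(term_map[[tid]], universe)
    K <- length(tg)
    if (K == 0) return(NULL)   # term absent from universe: skipped
    k <- length(intersect(tg, query_genes))
    p <- phyper(k - 1, K, N - K, q, lower.tail = FALSE)
    data.frame(term_id = tid, overlap_count = k, term_size = K,
               query_size = q, universe_size = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) stopf("no term overlaps the universe")
  rows$bh_adjusted_p <- p.adjust(rows$p_value, method = "BH")
  rows$significant <- rows$bh_adjusted_p < alpha
  rows[order(rows$bh_adjusted_p, rows$p_value, rows$term_id), ]
}
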