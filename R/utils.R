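#' @importFrom stats cor pbinom phyper rbeta rbinom runif setNames sd p.adjust
#' @importFrom utils write.table read.table head tail
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Natural sort order for chromosome names
#'
#' Orders "1", "2", ..., "10" numerically and mixed names ("X", "chr2")
#' lexicographically after numeric ones, so window tiling is deterministic.
#'
#' @param chrom character vector of chromosome names
#' @return integer permutation ordering `chrom`
#' @keywords internal
natural_chrom_order <- function(chrom) {
  stripped <- sub("^[Cc]hr", "", chrom)
  num <- suppressWarnings(as.numeric(stripped))
  order(is.na(num), num, stripped)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(ok, fmt, ...) if (!isTRUE(ok)) stopf(fmt, ...)

## Seed helper: derive a stream seed < 2^31 from a master seed and a tag.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647L)
}
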