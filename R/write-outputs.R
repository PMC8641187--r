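#' Write a window-statistics table as TSV
#'
#' Columns: chrom, start, end (1-based half-open), n_loci, value,
#' percentile_rank.
#'
#' @param stats window table from [windowed_fst()], [windowed_pi()] or
#'   [delta_pi_scan()]
#' @param path output TSV path
#' @return invisibly, `path`
#' @export
write_window_stats <- function(stats, path) {
  data.table::fwrite(stats, path, sep = "\t")
  invisible(path)
}

#' Write outlier windows as BED
#'
#' Internal 1-based half-open windows become 0-based half-open BED
#' intervals covering the same bases; the value goes in the score column.
#'
#' @param outliers outlier window table
#' @param path output BED path
#' @return invisibly, `path`
#' @export
write_outliers_bed <- function(outliers, path) {
  bed <- data.frame(outliers$chrom, outliers$start_bp - 1L,
                    outliers$end_bp - 1L,
                    sprintf("%s:%d-%d", outliers$chrom, outliers$start_bp,
                            outliers$end_bp),
                    outliers$value)
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write ROH segments as TSV (PLINK .hom-like columns)
#' @param segments output of [detect_roh()]
#' @param path output path
#' @return invisibly, `path`
#' @export
write_roh <- function(segments, path) {
  out <- data.frame(FID = segments$population, IID = segments$sample,
                    CHR = segments$chrom, POS1 = segments$start_bp,
                    POS2 = segments$end_bp,
                    KB = segments$length_bp / 1000,
                    NSNP = segments$n_snps)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Write an LD-decay profile as TSV
#' @param profile output of [ld_decay_profile()]
#' @param path output path
#' @return invisibly, `path`
#' @export
write_ld_profile <- function(profile, path) {
  data.table::fwrite(profile, path, sep = "\t")
  invisible(path)
}

#' Write a distance matrix as square TSV
#' @param d symmetric labelled matrix
#' @param path output path
#' @return invisibly, `path`
#' @export
write_distance_matrix <- function(d, path) {
  out <- data.frame(label = rownames(d), as.data.frame(d, check.names = FALSE))
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
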