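#' Pipeline run configuration
#'
#' Bundles every parameter of the end-to-end scan. The scan statistics
#' (FST, pi) are computed on the full post-QC SNP set; the LD-pruned set
#' feeds only the relatedness/structure stages (tree), since pruning exists
#' to de-cluster relatedness estimates, not the selection statistics.
#'
#' @param scheme [population_scheme()]; must contain a group named by
#'   `reference_group` and at least one other (focal) group
#' @param reference_group the group screened *against* (default
#'   `"indigenous"`); each remaining group is compared to it in turn
#' @param qc [qc_thresholds()]
#' @param prune [prune_params()]
#' @param fst_window_bp,fst_step_bp FST tiling (100 kb / 50 kb)
#' @param pi_window_bp,pi_step_bp pi tiling (50 kb / 25 kb)
#' @param outlier_fractions upper-tail fractions for FST outlier tiers
#'   (default c(0.01, 0.05))
#' @param delta_pi_top_fraction upper-tail fraction of the delta-pi scan
#'   (default 0.01)
#' @param delta_pi_focal which side of the difference is screened for
#'   sweeps: `"commercial"` (reference minus focal orientation; default,
#'   matching the simulated world where commercial breeds are selected) or
#'   `"reference"` (focal minus reference)
#' @param roh_min_length_kb,roh_min_snps,roh_max_het,roh_max_missing ROH
#'   parameters (defaults 1000 kb, 50 SNPs, 0 het, 1 missing)
#' @param ld_class_edges_kb LD decay bin edges (kb)
#' @param ld_max_pairs_per_class LD subsampling cap
#' @param tree_level `"population"` or `"sample"`
#' @param bootstrap_replicates NJ bootstrap replicates (default 1000)
#' @param gene_bed optional gene annotation path (BED/GFF3)
#' @param term_gmt optional GMT term map for enrichment
#' @param seed master seed
#' @param outdir output directory
#' @return object of class `run_config`
#' @export
run_config <- function(scheme,
                       reference_group = "indigenous",
                       qc = qc_thresholds(),
                       prune = prune_params(),
                       fst_window_bp = 100000L, fst_step_bp = 50000L,
                       pi_window_bp = 50000L, pi_step_bp = 25000L,
                       outlier_fractions = c(0.01, 0.05),
                       delta_pi_top_fraction = 0.01,
                       delta_pi_focal = c("commercial", "reference"),
                       roh_min_length_kb = 1000, roh_min_snps = 50L,
                       roh_max_het = 0L, roh_max_missing = 1L,
                       ld_class_edges_kb = c(2.5, 5, 10, 20, 40, 80, 160),
                       ld_max_pairs_per_class = 10000L,
                       tree_level = "population",
                       bootstrap_replicates = 1000L,
                       gene_bed = NULL, term_gmt = NULL,
                       seed = 1L, outdir = "sweepscan_run") {
  if (!inherits(scheme, "population_scheme")) stopf("scheme must be a population_scheme")
  if (!reference_group %in% names(scheme$groups))
    stopf("reference group '%s' not in scheme", reference_group)
  if (length(scheme$groups) < 2) stopf("scheme needs >= 2 groups")
  if (fst_window_bp < fst_step_bp || pi_window_bp < pi_step_bp)
    stopf("window must be >= step")
  if (any(outlier_fractions <= 0 | outlier_fractions >= 1))
    stopf("outlier fractions must be in (0, 1)")
  structure(list(scheme = scheme, reference_group = reference_group,
                 qc = qc, prune = prune,
                 fst_window_bp = fst_window_bp, fst_step_bp = fst_step_bp,
                 pi_window_bp = pi_window_bp, pi_step_bp = pi_step_bp,
                 outlier_fractions = outlier_fractions,
                 delta_pi_top_fraction = delta_pi_top_fraction,
                 delta_pi_focal = match.arg(delta_pi_focal),
                 roh_min_length_kb = roh_min_length_kb,
                 roh_min_snps = roh_min_snps, roh_max_het = roh_max_het,
                 roh_max_missing = roh_max_missing,
                 ld_class_edges_kb = ld_class_edges_kb,
                 ld_max_pairs_per_class = ld_max_pairs_per_class,
                 tree_level = tree_level,
                 bootstrap_replicates = bootstrap_replicates,
                 gene_bed = gene_bed, term_gmt = term_gmt,
                 seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

#' Run the full selection-signature scan
#'
#' Stages, in order: marker QC (once); for each focal group vs the
#' reference group a windowed FST scan with top-1\% and top-5\% outlier
#' tiers; windowed pi per group and a delta-pi scan (top 1\%); gene
#' annotation of the union of outlier regions plus optional enrichment;
#' LD pruning feeding an NJ tree with bootstrap supports; ROH and LD-decay
#' diagnostics per population. Every output is a text file under
#' `cfg$outdir` and is listed, with its row count, in `manifest.json`.
#' Stages whose outputs already exist are skipped when `resume = TRUE`.
#'
#' @param g [genotype_matrix] (e.g. from [read_ped_map()], [read_vcf()] or
#'   [simulate_cohort()])
#' @param cfg [run_config()]
#' @param resume skip stages whose output files already exist
#' @return invisibly, the manifest list
#' @export
run_scan_pipeline <- function(g, cfg, resume = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  ## pre-flight validation before any compute
  pops_needed <- unlist(cfg$scheme$groups)
  absent <- setdiff(pops_needed, unique(g$populations))
  if (length(absent))
    stopf("pre-flight: population(s) in scheme but not in data: %s",
          paste(absent, collapse = ", "))
  if (!is.null(cfg$gene_bed) && !file.exists(cfg$gene_bed))
    stopf("pre-flight: gene annotation not found: %s", cfg$gene_bed)
  if (!is.null(cfg$term_gmt) && !file.exists(cfg$term_gmt))
    stopf("pre-flight: term map not found: %s", cfg$term_gmt)

  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("sweepscan")),
                   seed = cfg$seed,
                   parameters = cfg[setdiff(names(cfg), "scheme")],
                   groups = cfg$scheme$groups,
                   files = list())
  out <- function(name) file.path(cfg$outdir, name)
  record <- function(name, n_rows) {
    manifest$files[[name]] <<- list(path = out(name), rows = n_rows)
  }
  stage <- function(name, files, fun) {
    if (resume && all(file.exists(vapply(files, out, character(1))))) {
      message(sprintf("[%s] outputs exist, skipped (resume)", name))
      return(invisible(NULL))
    }
    message(sprintf("[%s] running", name))
    tryCatch(fun(), error = function(e)
      stopf("stage '%s' failed: %s (partial outputs retained in %s)",
            name, conditionMessage(e), cfg$outdir))
  }

  ## --- QC -------------------------------------------------------------
  qc_res <- NULL
  stage("qc", "qc_exclusions.tsv", function() {
    qc_res <<- apply_qc_filters(g, cfg$qc)
    write_exclusion_report(qc_res, out("qc_exclusions.tsv"))
    record("qc_exclusions.tsv", nrow(qc_res$report))
  })
  if (is.null(qc_res)) qc_res <- apply_qc_filters(g, cfg$qc)  # resumed
  gq <- qc_res$genotypes
  manifest$qc_counts <- as.list(qc_res$counts)

  focal_groups <- setdiff(names(cfg$scheme$groups), cfg$reference_group)
  ref_pops <- cfg$scheme$groups[[cfg$reference_group]]
  all_outliers <- list()

  ## --- per-comparison scans -------------------------------------------
  pi_ref <- windowed_pi(gq, ref_pops, cfg$pi_window_bp, cfg$pi_step_bp)
  write_window_stats(pi_ref, out(sprintf("pi_%s.tsv", cfg$reference_group)))
  record(sprintf("pi_%s.tsv", cfg$reference_group), nrow(pi_ref))

  for (fg in focal_groups) {
    tag <- sprintf("%s_vs_%s", cfg$reference_group, fg)
    stage(paste0("fst_", tag), sprintf("fst_%s.tsv", tag), function() {
      fst <- windowed_fst(gq, cfg$scheme, c(cfg$reference_group, fg),
                          cfg$fst_window_bp, cfg$fst_step_bp)
      write_window_stats(fst, out(sprintf("fst_%s.tsv", tag)))
      record(sprintf("fst_%s.tsv", tag), nrow(fst))
      for (tf in cfg$outlier_fractions) {
        ol <- empirical_outliers(fst, tf)
        nm <- sprintf("fst_%s_top%g.bed", tag, 100 * tf)
        write_outliers_bed(ol, out(nm))
        record(nm, nrow(ol))
        all_outliers[[paste(tag, tf)]] <<- ol
      }
    })
    stage(paste0("pi_", fg), sprintf("pi_%s.tsv", fg), function() {
      pi_f <- windowed_pi(gq, cfg$scheme$groups[[fg]],
                          cfg$pi_window_bp, cfg$pi_step_bp)
      write_window_stats(pi_f, out(sprintf("pi_%s.tsv", fg)))
      record(sprintf("pi_%s.tsv", fg), nrow(pi_f))
      dp <- if (cfg$delta_pi_focal == "commercial")
        delta_pi_scan(pi_ref, pi_f, cfg$delta_pi_top_fraction)
      else delta_pi_scan(pi_f, pi_ref, cfg$delta_pi_top_fraction)
      write_window_stats(dp$windows, out(sprintf("delta_pi_%s.tsv", tag)))
      record(sprintf("delta_pi_%s.tsv", tag), nrow(dp$windows))
      nm <- sprintf("delta_pi_%s_top%g.bed", tag, 100 * cfg$delta_pi_top_fraction)
      write_outliers_bed(dp$outliers, out(nm))
      record(nm, nrow(dp$outliers))
      all_outliers[[paste("dpi", tag)]] <<- dp$outliers
    })
  }

  ## --- annotation ------------------------------------------------------
  if (!is.null(cfg$gene_bed) && length(all_outliers)) {
    stage("annotation", "outlier_genes.tsv", function() {
      genes <- read_gene_intervals(cfg$gene_bed)
      regions <- unique(do.call(rbind, lapply(all_outliers, function(o)
        o[, c("chrom", "start_bp", "end_bp")])))
      hits <- genes_in_regions(regions, genes)
      data.table::fwrite(hits, out("outlier_genes.tsv"), sep = "\t")
      record("outlier_genes.tsv", nrow(hits))
      if (!is.null(cfg$term_gmt)) {
        scanned <- make_windows(
          tapply(gq$loci$pos_bp, gq$loci$chrom, max),
          cfg$fst_window_bp, cfg$fst_step_bp)
        universe <- unique(genes_in_regions(scanned, genes)$gene_id)
        query <- intersect(unique(hits$gene_id), universe)
        if (length(query)) {
          enr <- enrichment_bh(query, read_gmt(cfg$term_gmt), universe)
          data.table::fwrite(enr, out("enrichment.tsv"), sep = "\t")
          record("enrichment.tsv", nrow(enr))
        }
      }
    })
  }

  ## --- structure diagnostics (pruned set) ------------------------------
  stage("tree", "nj_tree.nwk", function() {
    retained <- ld_prune(gq, cfg$prune)
    write_retained_loci(gq, retained, out("pruned_loci.txt"))
    record("pruned_loci.txt", length(retained))
    gp <- subset_loci(gq, retained)
    bs <- bootstrap_support(gp, cfg$bootstrap_replicates,
                            seed = derive_seed(cfg$seed, "bootstrap"),
                            level = cfg$tree_level)
    write_newick(bs, out("nj_tree.nwk"))
    record("nj_tree.nwk", 1L)
    write_distance_matrix(ibs_distance(gp, cfg$tree_level),
                          out("distances.tsv"))
    record("distances.tsv", length(unique(gq$populations)))
  })

  ## --- ROH and LD decay (full post-QC set) -----------------------------
  stage("roh", "roh_segments.tsv", function() {
    roh <- detect_roh(gq, cfg$roh_min_length_kb, cfg$roh_min_snps,
                      cfg$roh_max_het, cfg$roh_max_missing)
    write_roh(roh, out("roh_segments.tsv"))
    record("roh_segments.tsv", nrow(roh))
    counts <- roh_counts_by_population(roh, gq$populations)
    data.table::fwrite(counts, out("roh_counts.tsv"), sep = "\t")
    record("roh_counts.tsv", nrow(counts))
  })
  stage("ld", "ld_decay.tsv", function() {
    profiles <- lapply(unique(gq$populations), function(p)
      cbind(population = p,
            ld_decay_profile(gq, p, cfg$ld_class_edges_kb,
                             cfg$ld_max_pairs_per_class,
                             seed = derive_seed(cfg$seed, paste0("ld_", p)))))
    write_ld_profile(do.call(rbind, profiles), out("ld_decay.tsv"))
    record("ld_decay.tsv", sum(vapply(profiles, nrow, integer(1))))
  })

  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(manifest)
}
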