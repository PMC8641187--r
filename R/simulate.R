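#' Simulation configuration for a multi-breed SNP-chip cohort
#'
#' Describes the forward Wright-Fisher world the generator emulates: a
#' shared ancestral gene pool, an optional group-level divergence phase
#' (indigenous vs commercial lineages, so the indigenous breeds form a
#' clade), then independent per-breed drift, with deterministic directional
#' selection at a minority of loci in commercial breeds. The default breeds
#' and sample sizes reproduce a published 324-animal, 8-breed ovine chip
#' cohort: Moghani 34, Afshari 37, Gezel 35 (indigenous); DorsetHorn 21,
#' Texel 46 (commercial meat); Lacaune 103, East Friesian white 9, East
#' Friesian brown 39 (commercial milk).
#'
#' @param n_chromosomes number of autosomes (default 10)
#' @param chrom_length_bp chromosome length (default 1e8, giving chip-like
#'   SNP spacing of ~50 kb at the default locus count)
#' @param n_snps total SNP count (default 20000)
#' @param breeds data.frame with columns `label`, `group` (one of
#'   `indigenous`, `commercial_meat`, `commercial_milk`), `sample_n`, `ne`
#' @param generations_split per-breed drift generations (default 100: the
#'   logistic sweep time from p = 0.05 to p > 0.99 at s = 0.1 is ~100
#'   generations, so the default world contains *completed* sweeps, the
#'   signature the scan is designed to detect)
#' @param generations_group group-phase drift generations before the breed
#'   split (default 50)
#' @param group_ne effective size during the group phase (default 1500)
#' @param selection_coefficient_s per-generation selective advantage of the
#'   favoured (alt) allele at selected loci (default 0.1)
#' @param n_selected_loci loci under selection, split between the two
#'   commercial groups (default 30)
#' @param max_initial_freq selected loci are drawn among loci whose
#'   ancestral alt frequency is at most this value (default 0.3): a hard
#'   sweep starts from a low-to-moderate frequency; sweeping an
#'   already-common allele leaves no detectable footprint
#' @param missing_rate uniform missing-call rate (default 0.02)
#' @param ld_decay_bp if positive, SNPs copy a shared block-anchor genotype
#'   with probability `1/(1 + 4 Ne rho d)` (d = distance to anchor,
#'   `rho` = `ld_rho` per bp), yielding monotone LD decay and more LD in
#'   small-Ne breeds; 0 disables (loci independent, the default)
#' @param ld_rho recombination-like rate per bp for the LD kernel
#'   (default 1e-6)
#' @param seed master seed; all randomness derives from it
#' @return object of class `sim_config`
#' @export
sim_config <- function(n_chromosomes = 10L,
                       chrom_length_bp = 1e8,
                       n_snps = 20000L,
                       breeds = default_breeds(),
                       generations_split = 100L,
                       generations_group = 50L,
                       group_ne = 1500L,
                       selection_coefficient_s = 0.1,
                       n_selected_loci = 30L,
                       max_initial_freq = 0.3,
                       missing_rate = 0.02,
                       ld_decay_bp = 0,
                       ld_rho = 1e-6,
                       seed = 1L) {
  breeds <- as.data.frame(breeds, stringsAsFactors = FALSE)
  need <- c("label", "group", "sample_n", "ne")
  if (length(setdiff(need, names(breeds))))
    stopf("breeds needs columns: %s", paste(need, collapse = ", "))
  okg <- c("indigenous", "commercial_meat", "commercial_milk")
  if (any(!breeds$group %in% okg))
    stopf("breed group must be one of: %s", paste(okg, collapse = ", "))
  if (any(c(n_chromosomes, chrom_length_bp, n_snps, breeds$sample_n,
            breeds$ne) <= 0))
    stopf("all counts must be positive")
  if (selection_coefficient_s < 0) stopf("selection coefficient must be >= 0")
  if (missing_rate < 0 || missing_rate >= 1) stopf("missing_rate must be in [0, 1)")
  if (generations_split < 0 || generations_group < 0)
    stopf("generation counts must be >= 0")
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 chrom_length_bp = chrom_length_bp, n_snps = as.integer(n_snps),
                 breeds = breeds, generations_split = as.integer(generations_split),
                 generations_group = as.integer(generations_group),
                 group_ne = as.integer(group_ne),
                 selection_coefficient_s = selection_coefficient_s,
                 n_selected_loci = as.integer(n_selected_loci),
                 max_initial_freq = max_initial_freq,
                 missing_rate = missing_rate, ld_decay_bp = ld_decay_bp,
                 ld_rho = ld_rho, seed = as.integer(seed)),
            class = "sim_config")
}

#' Default breed table of the simulated cohort
#'
#' Sample sizes follow the published cohort (total 324, indigenous 106);
#' effective sizes encode stronger drift/inbreeding in the intensively
#' selected commercial breeds than in the indigenous ones.
#' @return data.frame with columns `label`, `group`, `sample_n`, `ne`
#' @export
default_breeds <- function() {
  data.frame(
    label = c("Moghani", "Afshari", "Gezel", "DorsetHorn", "Texel",
              "Lacaune", "EastFriesianWhite", "EastFriesianBrown"),
    group = c(rep("indigenous", 3), rep("commercial_meat", 2),
              rep("commercial_milk", 3)),
    sample_n = c(34L, 37L, 35L, 21L, 46L, 103L, 9L, 39L),
    ne = c(900L, 700L, 900L, 250L, 450L, 300L, 200L, 450L),
    stringsAsFactors = FALSE)
}

#' Read a simulation config from JSON
#' @param path JSON file whose keys match [sim_config()] arguments
#' @return `sim_config`
#' @export
read_sim_config <- function(path) {
  args <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(args$breeds)) args$breeds <- as.data.frame(args$breeds)
  do.call(sim_config, args)
}

## One Wright-Fisher binomial frequency update at size ne.
wf_step <- function(p, ne) rbinom(length(p), 2L * ne, p) / (2L * ne)

## Deterministic directional-selection update for the alt allele.
selection_step <- function(p, s) p * (1 + s) / (1 + s * p)

#' Simulate a multi-breed SNP-chip cohort with known selected loci
#'
#' Ancestral alt frequencies are Beta(0.5, 0.5) truncated to
#' `[0.05, 0.95]`. Each lineage drifts by binomial Wright-Fisher updates:
#' first an (optional) group phase in which the indigenous group and the
#' pooled commercial lineage diverge, then every breed independently at its
#' own Ne for `generations_split` generations. At each selected locus the
#' deterministic update `p' = p (1+s) / (1 + s p)` precedes drift in the
#' breeds of its assigned commercial group. Individuals are drawn as
#' Binomial(2, p) dosages; missing calls are applied uniformly. Fully
#' reproducible from `cfg$seed`.
#'
#' @param cfg [sim_config()]
#' @return list with `genotypes` ([genotype_matrix]), `truth`
#'   (data.frame: `chrom`, `pos_bp`, `locus_id`, `selected_in_group`,
#'   `selection_coefficient`), and `breed_frequencies` (breeds x loci
#'   matrix of realized alt frequencies, columns in `genotypes$loci`
#'   order)
#' @export
simulate_cohort <- function(cfg) {
  if (!inherits(cfg, "sim_config")) stopf("cfg must be a sim_config")
  set.seed(cfg$seed)
  L <- cfg$n_snps
  ## positions: uniform per chromosome, deduplicated
  chrom <- sort(sample.int(cfg$n_chromosomes, L, replace = TRUE))
  pos <- integer(L)
  for (ch in seq_len(cfg$n_chromosomes)) {
    k <- sum(chrom == ch)
    pos[chrom == ch] <- sort(sample.int(cfg$chrom_length_bp, k))
  }
  p0 <- rbeta(L, 0.5, 0.5)
  p0 <- pmin(pmax(p0, 0.05), 0.95)

  ## selected loci: hard sweeps start from low/moderate alt frequency
  sel_groups <- c("commercial_meat", "commercial_milk")
  n_sel <- cfg$n_selected_loci
  candidates <- which(p0 <= cfg$max_initial_freq)
  if (n_sel > length(candidates))
    stopf("not enough low-frequency loci for %d selected loci", n_sel)
  sel_idx <- sort(sample(candidates, n_sel))
  sel_group <- if (n_sel > 0) sample(rep_len(sel_groups, n_sel)) else character(0)

  ## phase 1: lineage (group) drift from the ancestral pool
  lineages <- c("indigenous", "commercial")
  lin_of <- function(grp) ifelse(grp == "indigenous", "indigenous", "commercial")
  p_lin <- list()
  for (ln in lineages) {
    p <- p0
    if (cfg$generations_group > 0)
      for (t in seq_len(cfg$generations_group)) p <- wf_step(p, cfg$group_ne)
    p_lin[[ln]] <- p
  }

  ## phase 2: per-breed drift (+ selection in the assigned commercial group)
  breeds <- cfg$breeds
  p_breed <- matrix(NA_real_, nrow = nrow(breeds), ncol = L,
                    dimnames = list(breeds$label, NULL))
  for (b in seq_len(nrow(breeds))) {
    p <- p_lin[[lin_of(breeds$group[b])]]
    sel_here <- sel_idx[sel_group == breeds$group[b]]
    for (t in seq_len(cfg$generations_split)) {
      if (length(sel_here))
        p[sel_here] <- selection_step(p[sel_here], cfg$selection_coefficient_s)
      p <- wf_step(p, breeds$ne[b])
    }
    p_breed[b, ] <- p
  }

  ## draw individuals
  n_tot <- sum(breeds$sample_n)
  dosage <- matrix(NA_integer_, nrow = n_tot, ncol = L)
  samples <- character(n_tot)
  pops <- character(n_tot)
  row <- 0L
  use_ld <- cfg$ld_decay_bp > 0
  for (b in seq_len(nrow(breeds))) {
    nb <- breeds$sample_n[b]
    idx <- row + seq_len(nb)
    pb <- p_breed[b, ]
    if (!use_ld) {
      dosage[idx, ] <- matrix(rbinom(nb * L, 2L, rep(pb, each = nb)),
                              nrow = nb)
    } else {
      dosage[idx, ] <- draw_ld_block_genotypes(
        nb, pb, chrom, pos, cfg$ld_decay_bp, cfg$ld_rho, breeds$ne[b])
    }
    samples[idx] <- sprintf("%s_%02d", breeds$label[b], seq_len(nb))
    pops[idx] <- breeds$label[b]
    row <- row + nb
  }
  if (cfg$missing_rate > 0) {
    miss <- runif(length(dosage)) < cfg$missing_rate
    dosage[miss] <- NA_integer_
  }
  rownames(dosage) <- samples
  loci <- data.frame(chrom = as.character(chrom), pos_bp = pos,
                     locus_id = sprintf("snp_%d_%d", chrom, pos),
                     ref_allele = "A", alt_allele = "G",
                     stringsAsFactors = FALSE)
  g <- genotype_matrix(dosage, loci, setNames(pops, samples))
  ## the container re-sorts loci; map truth through locus ids
  truth <- data.frame(chrom = as.character(chrom[sel_idx]),
                      pos_bp = pos[sel_idx],
                      locus_id = sprintf("snp_%d_%d", chrom[sel_idx], pos[sel_idx]),
                      selected_in_group = sel_group,
                      selection_coefficient = rep(cfg$selection_coefficient_s,
                                                  n_sel),
                      stringsAsFactors = FALSE)
  truth <- truth[order(match(truth$locus_id, g$loci$locus_id)), ]
  rownames(truth) <- NULL
  colnames(p_breed) <- loci$locus_id
  p_breed <- p_breed[, g$loci$locus_id, drop = FALSE]
  list(genotypes = g, truth = truth, breed_frequencies = p_breed)
}

## Block-anchor LD mode: within blocks of `block_bp`, each individual's SNP
## genotype copies the block-anchor genotype with probability
## 1/(1 + 4 Ne rho d) (d = distance to the anchor SNP), else is drawn
## independently from the SNP's own frequency. Produces monotone r2 decay
## with distance, stronger for small Ne.
draw_ld_block_genotypes <- function(nb, pb, chrom, pos, block_bp, rho, ne) {
  L <- length(pb)
  block <- paste(chrom, pos %/% block_bp)
  out <- matrix(NA_integer_, nrow = nb, ncol = L)
  for (bl in unique(block)) {
    ii <- which(block == bl)
    anchor <- ii[1]
    ga <- rbinom(nb, 2L, pb[anchor])
    out[, anchor] <- ga
    for (j in ii[-1]) {
      w <- 1 / (1 + 4 * ne * rho * (pos[j] - pos[anchor]))
      copy <- runif(nb) < w
      gj <- rbinom(nb, 2L, pb[j])
      gj[copy] <- ga[copy]
      out[, j] <- gj
    }
  }
  out
}

#' Write the fixture file set for a simulated cohort
#'
#' Emits PED/MAP, VCF, a sample-to-population map, a truth BED (0-based
#' half-open, one row per selected locus), a synthetic gene BED tiling the
#' chromosomes, and a GMT term map whose first term is enriched for genes
#' near selected loci. All files round-trip through the package's readers.
#'
#' @param g [genotype_matrix]
#' @param truth truth table from [simulate_cohort()]
#' @param outdir output directory (created if needed)
#' @param gene_every_bp spacing of synthetic gene tiles (default 250 kb)
#' @param gene_length_bp synthetic gene length (default 50 kb)
#' @return invisibly, named vector of the written paths
#' @export
write_fixtures <- function(g, truth, outdir, gene_every_bp = 250000,
                           gene_length_bp = 50000) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(ped = file.path(outdir, "cohort.ped"),
             map = file.path(outdir, "cohort.map"),
             vcf = file.path(outdir, "cohort.vcf"),
             pops = file.path(outdir, "populations.tsv"),
             truth = file.path(outdir, "truth.bed"),
             genes = file.path(outdir, "genes_synthetic.bed"),
             gmt = file.path(outdir, "terms_synthetic.gmt"))
  write_ped_map(g, paths["ped"], paths["map"])
  write_vcf(g, paths["vcf"])
  write_population_map(g$populations, paths["pops"])

  ## truth BED: 0-based half-open single-base intervals
  tb <- data.frame(truth$chrom, truth$pos_bp - 1L, truth$pos_bp,
                   truth$locus_id)
  data.table::fwrite(tb, paths["truth"], sep = "\t", col.names = FALSE)

  ## synthetic gene tiling
  genes <- list()
  for (ch in unique(g$loci$chrom)) {
    extent <- max(g$loci$pos_bp[g$loci$chrom == ch])
    starts1 <- as.integer(seq(1, extent, by = gene_every_bp))  # 1-based starts
    genes[[ch]] <- data.frame(
      chrom = ch, start0 = starts1 - 1L,
      end0 = as.integer(starts1 - 1L + gene_length_bp),
      gene_id = sprintf("GENE_%s_%06d", ch, seq_along(starts1)),
      stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, genes)
  data.table::fwrite(genes, paths["genes"], sep = "\t", col.names = FALSE)

  ## GMT: one term enriched for truth-adjacent genes + background terms
  gene_mid <- genes$start0 + gene_length_bp / 2
  near <- vapply(seq_len(nrow(genes)), function(i) {
    tr <- truth[truth$chrom == genes$chrom[i], ]
    nrow(tr) > 0 && any(abs(tr$pos_bp - gene_mid[i]) <= gene_every_bp)
  }, logical(1))
  sel_term <- genes$gene_id[near]
  other <- genes$gene_id[!near]
  set.seed(derive_seed(nrow(genes), "gmt"))
  lines <- c(
    paste(c("SWEEP_ADJACENT", "genes near selected loci", sel_term),
          collapse = "\t"),
    vapply(1:5, function(k)
      paste(c(sprintf("RANDOM_%02d", k), "random background term",
              sample(other, min(50, length(other)))), collapse = "\t"),
      character(1)))
  writeLines(lines, paths["gmt"])
  invisible(paths)
}

#' Score recovery of simulated selected loci by outlier windows
#'
#' @param outliers data.frame of outlier windows (`chrom`, `start_bp`,
#'   `end_bp`, half-open)
#' @param truth truth table from [simulate_cohort()]
#' @param genome_bp total scanned genome size in bp (for fold enrichment);
#'   if `NULL`, estimated as the number of distinct windows times the step
#'   implied by the outlier table is refused — pass it explicitly or via
#'   `all_windows`
#' @param all_windows optionally, the full window table the outliers were
#'   drawn from; fold enrichment then uses its window count
#' @return list: `recall` (fraction of truth loci inside an outlier
#'   window), `precision` (fraction of outlier windows containing a truth
#'   locus), `fold_enrichment` (truth density in outliers / genome-wide),
#'   `n_truth`, `n_outliers`
#' @export
score_recovery <- function(outliers, truth, genome_bp = NULL,
                           all_windows = NULL) {
  n_truth <- nrow(truth)
  if (!nrow(outliers))
    return(list(recall = 0, precision = NA_real_, fold_enrichment = NA_real_,
                n_truth = n_truth, n_outliers = 0L))
  in_any <- vapply(seq_len(n_truth), function(i) {
    any(outliers$chrom == truth$chrom[i] &
          outliers$start_bp <= truth$pos_bp[i] &
          truth$pos_bp[i] < outliers$end_bp)
  }, logical(1))
  hit_win <- vapply(seq_len(nrow(outliers)), function(j) {
    any(truth$chrom == outliers$chrom[j] &
          outliers$start_bp[j] <= truth$pos_bp &
          truth$pos_bp < outliers$end_bp[j])
  }, logical(1))
  recall <- mean(in_any)
  precision <- mean(hit_win)
  ## fold enrichment on non-redundant covered bases
  cov_bp <- covered_bp(outliers)
  tot_bp <- if (!is.null(genome_bp)) genome_bp
            else if (!is.null(all_windows)) covered_bp(all_windows)
            else stopf("provide genome_bp or all_windows for fold enrichment")
  dens_in <- sum(in_any) / cov_bp
  dens_all <- n_truth / tot_bp
  list(recall = recall, precision = precision,
       fold_enrichment = if (dens_all > 0) dens_in / dens_all else NA_real_,
       n_truth = n_truth, n_outliers = nrow(outliers))
}

## Total bases covered by a set of (possibly overlapping) windows.
covered_bp <- function(w) {
  total <- 0
  for (ch in unique(w$chrom)) {
    ww <- w[w$chrom == ch, , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(ww$start_bp, ww$end_bp - 1L))
    total <- total + sum(IRanges::width(ir))
  }
  total
}
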