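test_that("simulation is reproducible and respects its config", {
  cfg <- sim_config(n_chromosomes = 2, chrom_length_bp = 2e6, n_snps = 150,
                    breeds = default_breeds()[c(1, 4), ],
                    generations_split = 10, generations_group = 5,
                    n_selected_loci = 3, seed = 5)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$genotypes$dosage, s2$genotypes$dosage)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$breed_frequencies, s2$breed_frequencies)

  ## frequencies stay in [0, 1]; truth loci exist among the simulated loci
  expect_true(all(s1$breed_frequencies >= 0 & s1$breed_frequencies <= 1))
  expect_true(all(s1$truth$locus_id %in% s1$genotypes$loci$locus_id))
  expect_equal(nrow(s1$truth), 3L)

  ## no selected loci -> empty truth
  cfg0 <- sim_config(n_chromosomes = 1, chrom_length_bp = 1e6, n_snps = 50,
                     breeds = default_breeds()[c(1, 4), ],
                     generations_split = 5, generations_group = 0,
                     n_selected_loci = 0, seed = 6)
  expect_equal(nrow(simulate_cohort(cfg0)$truth), 0L)

  expect_error(sim_config(missing_rate = 1.2), "missing_rate")
  expect_error(sim_config(selection_coefficient_s = -0.1), "coefficient")
})

test_that("zero divergence time leaves the neutral estimator at -1/(n_c - 1)", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length_bp = 5e6, n_snps = 2500,
                    breeds = data.frame(
                      label = c("A", "B"),
                      group = c("indigenous", "commercial_meat"),
                      sample_n = c(30, 30), ne = c(500, 500),
                      stringsAsFactors = FALSE),
                    generations_split = 0, generations_group = 0,
                    n_selected_loci = 0, missing_rate = 0, seed = 15)
  sim <- simulate_cohort(cfg)
  g <- sim$genotypes
  af_a <- allele_frequencies(g, "A"); af_b <- allele_frequencies(g, "B")
  fst <- vapply(seq_len(nrow(g$loci)), function(j) {
    cc <- locus_fst_components(c(af_a$n[j], af_b$n[j]),
                               c(af_a$p[j], af_b$p[j]))
    locus_fst(cc)
  }, numeric(1))
  ## no-divergence limit of this estimator: E[MSP] = p(1-p)/2 and
  ## E[MSG] = p(1-p) under iid binomial sampling of both subpopulations,
  ## so mean locus FST -> -0.5/(n_c - 0.5) = -1/(2 n_c - 1) = -1/59
  expect_lt(abs(mean(fst, na.rm = TRUE) - (-1 / 59)), 0.01)
})

test_that("fixed neutral loci stay fixed; missingness matches its rate", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length_bp = 2e6, n_snps = 400,
                    breeds = data.frame(label = "A", group = "indigenous",
                                        sample_n = 40, ne = 30,
                                        stringsAsFactors = FALSE),
                    generations_split = 120, generations_group = 0,
                    n_selected_loci = 0, missing_rate = 0.05, seed = 44)
  sim <- simulate_cohort(cfg)
  p <- sim$breed_frequencies[1, ]
  fixed <- p %in% c(0, 1)
  expect_gt(sum(fixed), 0)   # strong drift fixes some loci
  af <- allele_frequencies(sim$genotypes, "A")
  expect_true(all(af$p[fixed & af$n > 0] %in% c(0, 1)))
  expect_equal(mean(is.na(sim$genotypes$dosage)), 0.05, tolerance = 0.15)
})

test_that("selected loci exceed neutral loci in FST across seeded replicates", {
  ## scaled-down replicate study of the directional property (20 seeds)
  wins <- vapply(1:20, function(seed) {
    cfg <- sim_config(n_chromosomes = 2, chrom_length_bp = 5e6, n_snps = 600,
                      breeds = data.frame(
                        label = c("A", "B", "C", "D"),
                        group = c("indigenous", "indigenous",
                                  "commercial_meat", "commercial_milk"),
                        sample_n = c(15, 15, 15, 15),
                        ne = c(600, 600, 250, 250), stringsAsFactors = FALSE),
                      generations_split = 100, generations_group = 50,
                      group_ne = 1000, n_selected_loci = 10,
                      selection_coefficient_s = 0.1, seed = 1000 + seed)
    sim <- simulate_cohort(cfg)
    g <- sim$genotypes
    af_i <- allele_frequencies(g, c("A", "B"))
    af_m <- allele_frequencies(g, "C")
    fst <- vapply(seq_len(nrow(g$loci)), function(j)
      locus_fst(locus_fst_components(c(af_i$n[j], af_m$n[j]),
                                     c(af_i$p[j], af_m$p[j]))),
      numeric(1))
    sel_meat <- g$loci$locus_id %in%
      sim$truth$locus_id[sim$truth$selected_in_group == "commercial_meat"]
    mean(fst[sel_meat], na.rm = TRUE) > mean(fst[!sel_meat], na.rm = TRUE)
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("write_fixtures emits a consistent, round-trippable file set", {
  sim <- small_sim(seed = 55, n_snps = 80, n_selected = 4)
  dir <- withr::local_tempdir()
  paths <- write_fixtures(sim$genotypes, sim$truth, dir)
  expect_true(all(file.exists(paths)))

  ## truth BED entries fall inside simulated chromosome extents
  tb <- read.table(paths[["truth"]], sep = "\t")
  for (i in seq_len(nrow(tb))) {
    ext <- max(sim$genotypes$loci$pos_bp[sim$genotypes$loci$chrom ==
                                           as.character(tb[i, 1])])
    expect_lte(tb[i, 3], ext)
  }
  ## gene BED parses and the GMT references its gene ids
  genes <- read_gene_intervals(paths[["genes"]])
  tm <- read_gmt(paths[["gmt"]])
  expect_true(all(unlist(tm) %in% genes$gene_id))
  expect_true("SWEEP_ADJACENT" %in% names(tm))
})

test_that("score_recovery counts coverage correctly", {
  truth <- data.frame(chrom = "1", pos_bp = c(150L, 950L),
                      locus_id = c("a", "b"),
                      selected_in_group = "commercial_meat",
                      selection_coefficient = 0.1)
  win <- data.frame(chrom = "1", start_bp = c(100L, 500L),
                    end_bp = c(200L, 600L))
  sc <- score_recovery(win, truth, genome_bp = 1000)
  expect_equal(sc$recall, 0.5)
  expect_equal(sc$precision, 0.5)
  ## covered 200 bp of 1000; 1 of 2 truth inside
  expect_equal(sc$fold_enrichment, (1 / 200) / (2 / 1000))

  ## exact cover -> recall and precision 1
  win2 <- data.frame(chrom = "1", start_bp = c(150L, 950L),
                     end_bp = c(151L, 951L))
  sc2 <- score_recovery(win2, truth, genome_bp = 1000)
  expect_equal(sc2$recall, 1); expect_equal(sc2$precision, 1)

  ## empty outliers
  sc0 <- score_recovery(win[0, ], truth, genome_bp = 1000)
  expect_equal(sc0$recall, 0)
  expect_true(is.na(sc0$precision))
})
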