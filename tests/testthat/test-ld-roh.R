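test_that("genotype_r2 matches hand computation and its invariances", {
  expect_equal(genotype_r2(c(0, 1, 2, 2), c(0, 1, 2, 0)), 25 / 121)
  x <- c(0, 1, 2, 0, 2)
  expect_equal(genotype_r2(x, x), 1)
  expect_equal(genotype_r2(x, 2 - x), 1)   # sign-invariant
  expect_equal(genotype_r2(x, c(0, 1, 2, 0, NA)),
               genotype_r2(c(0, 1, 2, 0), c(0, 1, 2, 0)))  # pairwise-complete
  expect_true(is.na(genotype_r2(c(1, 1, 1), x[1:3])))      # zero variance
  ## symmetry and label-swap invariance on random vectors
  set.seed(6)
  for (i in 1:20) {
    a <- rbinom(30, 2, 0.4); b <- rbinom(30, 2, 0.6)
    if (sd(a) == 0 || sd(b) == 0) next
    expect_equal(genotype_r2(a, b), genotype_r2(b, a))
    expect_equal(genotype_r2(a, b), genotype_r2(2 - a, b), tolerance = 1e-12)
  }
})

test_that("ld_decay_profile bins pairs by distance class", {
  ## two loci 3000 bp apart fall in the (2.5, 5] kb class
  set.seed(8)
  a <- rbinom(30, 2, 0.5); b <- rbinom(30, 2, 0.5)
  g <- make_g(cbind(a, b), pops = rep("p", 30), pos = c(1000L, 4000L))
  prof <- ld_decay_profile(g, "p")
  expect_equal(prof$n_pairs[prof$class_upper_kb == 5], 1L)
  expect_equal(sum(prof$n_pairs), 1L)
  expect_equal(prof$mean_r2[prof$class_upper_kb == 5], genotype_r2(a, b))
  expect_true(all(is.na(prof$mean_r2[prof$class_upper_kb != 5])))

  ## duplicated loci -> every populated class mean is 1
  x <- rbinom(40, 2, 0.5)
  pos <- c(1000L, 3000L, 7000L, 16000L, 36000L, 70000L, 150000L)
  gd <- make_g(matrix(rep(x, length(pos)), ncol = length(pos)),
               pops = rep("p", 40), pos = pos)
  profd <- ld_decay_profile(gd, "p")
  populated <- profd$n_pairs > 0
  expect_true(any(populated))
  expect_true(all(abs(profd$mean_r2[populated] - 1) < 1e-12))

  ## inter-chromosome pairs are never counted
  g2 <- make_g(cbind(a, b), pops = rep("p", 30), chrom = c("1", "2"),
               pos = c(1000L, 4000L))
  expect_equal(sum(ld_decay_profile(g2, "p")$n_pairs), 0L)
})

test_that("detect_roh finds homozygous runs with tolerances", {
  ## 60 homozygous SNPs spanning ~1.2 Mb -> one segment
  pos <- seq(10000L, by = 20000L, length.out = 60)  # span 1.18 Mb
  hom <- matrix(rep(c(0L, 2L), 30), nrow = 1)
  g <- make_g(hom, pops = "p", pos = pos)
  segs <- detect_roh(g, min_length_kb = 1000, min_snps = 50, max_het = 0,
                     max_missing = 0)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$n_snps, 60L)
  expect_equal(segs$start_bp, pos[1])
  expect_equal(segs$end_bp, pos[60])

  ## one central heterozygote with max_het = 0 -> two short sub-runs, none pass
  het1 <- hom; het1[1, 30] <- 1L
  expect_equal(nrow(detect_roh(make_g(het1, pops = "p", pos = pos),
                               1000, 50, 0, 0)), 0L)
  ## ... but tolerated when max_het = 1
  expect_equal(nrow(detect_roh(make_g(het1, pops = "p", pos = pos),
                               1000, 50, 1, 0)), 1L)

  ## all-heterozygous sample has no runs
  allhet <- matrix(1L, nrow = 1, ncol = 60)
  expect_equal(nrow(detect_roh(make_g(allhet, pops = "p", pos = pos),
                               1, 1, 0, 0)), 0L)

  ## every reported segment satisfies its own thresholds (self-check)
  sim <- small_sim(seed = 31, n_snps = 300)
  segs2 <- detect_roh(sim$genotypes, min_length_kb = 50, min_snps = 4,
                      max_het = 0, max_missing = 1)
  if (nrow(segs2)) {
    expect_true(all(segs2$length_bp >= 50 * 1000))
    expect_true(all(segs2$n_snps >= 4))
    expect_equal(segs2$length_bp, segs2$end_bp - segs2$start_bp + 1L)
  }
})

test_that("roh_counts_by_population averages per individual", {
  pops <- c(s1 = "p1", s2 = "p1", s3 = "p2")
  segs <- data.frame(sample = c("s1", "s1", "s1", "s2"),
                     population = "p1", chrom = "1",
                     start_bp = 1L, end_bp = 2L, n_snps = 5L, length_bp = 2L)
  out <- roh_counts_by_population(segs, pops)
  expect_equal(out$mean_segments[out$population == "p1"], 2.0)
  expect_equal(out$mean_segments[out$population == "p2"], 0.0)
  ## no segments anywhere
  out0 <- roh_counts_by_population(segs[0, ], pops)
  expect_true(all(out0$mean_segments == 0))
})

test_that("small-Ne populations show more ROH and higher short-range r2", {
  cfg <- sim_config(
    n_chromosomes = 2, chrom_length_bp = 1e7, n_snps = 2000,
    breeds = data.frame(
      label = c("bigNe", "smallNe"),
      group = c("indigenous", "commercial_meat"),
      sample_n = c(25, 25), ne = c(1500, 60), stringsAsFactors = FALSE),
    generations_split = 40, generations_group = 0,
    n_selected_loci = 0, missing_rate = 0, ld_decay_bp = 100000,
    ld_rho = 1e-6, seed = 77)
  sim <- simulate_cohort(cfg)
  g <- sim$genotypes

  roh <- detect_roh(g, min_length_kb = 100, min_snps = 15, max_het = 0,
                    max_missing = 1)
  counts <- roh_counts_by_population(roh, g$populations)
  expect_gt(counts$mean_segments[counts$population == "smallNe"],
            counts$mean_segments[counts$population == "bigNe"])

  prof_small <- ld_decay_profile(g, "smallNe", seed = 5)
  prof_big <- ld_decay_profile(g, "bigNe", seed = 5)
  short <- prof_small$class_upper_kb <= 20
  expect_gt(mean(prof_small$mean_r2[short], na.rm = TRUE),
            mean(prof_big$mean_r2[short], na.rm = TRUE))
  ## decay: short-range LD exceeds long-range LD in the small-Ne breed
  expect_gt(mean(prof_small$mean_r2[prof_small$class_upper_kb <= 10], na.rm = TRUE),
            mean(prof_small$mean_r2[prof_small$class_upper_kb > 40], na.rm = TRUE))
})
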