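test_that("PED/MAP parsing: missing codes, population labels, malformed rows", {
  dir <- withr::local_tempdir()
  writeLines(c("1\tm1\t0\t100", "1\tm2\t0\t200", "1\tm3\t0\t300"),
             file.path(dir, "t.map"))
  writeLines(c("pop1 s1 0 0 0 -9 A A A G G G",
               "pop2 s2 0 0 0 -9 A G 0 0 G G"),
             file.path(dir, "t.ped"))
  g <- read_ped_map(file.path(dir, "t.ped"), file.path(dir, "t.map"))
  expect_equal(dim(g), c(2L, 3L))
  expect_equal(sum(is.na(g$dosage)), 1L)           # exactly one "0 0" pair
  expect_equal(unname(g$populations), c("pop1", "pop2"))

  ## minor-allele orientation: locus m1 has alleles A,A,A,G -> alt = G
  expect_equal(g$loci$alt_allele[g$loci$locus_id == "m1"], "G")
  expect_equal(unname(g$dosage[, "m1"]), c(0L, 1L))

  ## row with wrong column count -> error naming the line
  writeLines(c("pop1 s1 0 0 0 -9 A A A G G G",
               "pop2 s2 0 0 0 -9 A G G G"),
             file.path(dir, "bad.ped"))
  expect_error(read_ped_map(file.path(dir, "bad.ped"), file.path(dir, "t.map")),
               "line 2")

  ## non-biallelic locus -> error listing the locus
  writeLines(c("pop1 s1 0 0 0 -9 A A A G G G",
               "pop2 s2 0 0 0 -9 A G C A G G"),
             file.path(dir, "tri.ped"))
  expect_error(read_ped_map(file.path(dir, "tri.ped"), file.path(dir, "t.map")),
               "m2")
})

test_that("VCF parsing: GT encoding, phased separators, multi-allelic policy", {
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "t.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "##contig=<ID=1>",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2", "s3", "s4"), collapse = "\t"),
    paste(c("1", "100", "v1", "A", "G", ".", "PASS", ".", "GT",
            "0/0", "0|1", "1/1", "./."), collapse = "\t")), vcf)
  pops <- c(s1 = "p1", s2 = "p1", s3 = "p2", s4 = "p2")
  g <- read_vcf(vcf, pops)
  expect_equal(unname(g$dosage[, 1]), c(0L, 1L, 2L, NA))

  ## multi-allelic record under reject policy -> error naming position
  vcf2 <- file.path(dir, "multi.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "##contig=<ID=1>",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1"), collapse = "\t"),
    paste(c("1", "555", "v1", "A", "G,T", ".", "PASS", ".", "GT", "0/1"),
          collapse = "\t")), vcf2)
  expect_error(read_vcf(vcf2, c(s1 = "p1")), "555")
  expect_equal(nrow(read_vcf(vcf2, c(s1 = "p1"),
                             multiallelic = "drop")$loci), 0L)

  ## sample absent from the population map -> error listing the sample
  expect_error(read_vcf(vcf, pops[1:3]), "s4")
})

test_that("PED/MAP and VCF round-trip the simulated dosage matrix", {
  sim <- small_sim(seed = 7, n_snps = 60)
  g <- sim$genotypes
  dir <- withr::local_tempdir()
  paths <- write_fixtures(g, sim$truth, dir)

  g_vcf <- read_vcf(paths[["vcf"]], paths[["pops"]])
  expect_identical(unname(g_vcf$dosage[g$samples, g$loci$locus_id]),
                   unname(g$dosage))
  expect_identical(g_vcf$populations, g$populations)
  expect_identical(g_vcf$loci[, c("chrom", "pos_bp", "locus_id")],
                   g$loci[, c("chrom", "pos_bp", "locus_id")])

  ## PED is unpolarised: identical up to per-locus allele orientation
  g_ped <- read_ped_map(paths[["ped"]], paths[["map"]])
  d <- g_ped$dosage[g$samples, g$loci$locus_id]
  same_or_flip <- vapply(seq_len(ncol(d)), function(j) {
    ok <- !is.na(g$dosage[, j])
    all(d[ok, j] == g$dosage[ok, j]) || all(d[ok, j] == 2L - g$dosage[ok, j])
  }, logical(1))
  expect_true(all(same_or_flip))
  expect_identical(g_ped$populations, g$populations)
})

test_that("allele_frequencies counts correctly and flags undefined loci", {
  g <- make_g(rbind(c(0L, NA), c(0L, NA), c(1L, NA), c(2L, NA)),
              pops = rep("p1", 4))
  af <- allele_frequencies(g, "p1")
  expect_equal(af$n, c(4L, 0L))
  expect_equal(af$p[1], 3 / 8)
  expect_true(af$undefined[2])
  expect_true(is.na(af$p[2]))

  ## 20 samples with 16 alt copies -> p = 0.4
  d <- matrix(0L, nrow = 20, ncol = 1); d[1:8, 1] <- 2L
  af2 <- allele_frequencies(make_g(d, rep("x", 20)))
  expect_equal(af2$p, 0.4)

  expect_error(allele_frequencies(g, "nope"), "nope")
})

test_that("allele_frequencies is invariant to sample and locus order; group p is the 2n-weighted mean", {
  sim <- small_sim(seed = 3, n_snps = 50)
  g <- sim$genotypes
  perm <- sample(length(g$samples))
  g2 <- genotype_matrix(g$dosage[perm, ], g$loci, g$populations[perm])
  af1 <- allele_frequencies(g, c("A", "B"))
  af2 <- allele_frequencies(g2, c("A", "B"))
  expect_equal(af1$p, af2$p)
  expect_equal(af1$n, af2$n)

  afA <- allele_frequencies(g, "A"); afB <- allele_frequencies(g, "B")
  pooled <- (2 * afA$n * afA$p + 2 * afB$n * afB$p) / (2 * afA$n + 2 * afB$n)
  expect_equal(af1$p, pooled, tolerance = 1e-12)
})

test_that("subset_by_group keeps order, loci; rejects unknown groups", {
  g <- make_g(rbind(c(0L, 1L), c(1L, 1L), c(2L, 0L), c(0L, 0L), c(1L, 2L)),
              pops = c("a", "b", "a", "c", "b"))
  scheme <- population_scheme(list(g1 = c("a", "b"), g2 = "c"))
  sub <- subset_by_group(g, scheme, "g1")
  expect_equal(sub$samples, g$samples[g$populations %in% c("a", "b")])
  expect_identical(sub$loci, g$loci)
  expect_error(subset_by_group(g, scheme, "g3"), "g3")

  u <- union(subset_by_group(g, scheme, "g1")$samples,
             subset_by_group(g, scheme, "g2")$samples)
  expect_setequal(u, g$samples[g$populations %in% c("a", "b", "c")])
})
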