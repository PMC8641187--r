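test_that("locus components and FST reproduce the hand-worked values", {
  cc <- locus_fst_components(n = c(20, 30), p = c(0.8, 0.3))
  expect_equal(cc$p_bar, 0.5)
  expect_equal(cc$msp, 3.0)
  expect_equal(cc$msg, 9.5 / 49)
  expect_equal(cc$n_c, 25)
  expect_equal(locus_fst(cc), 137.5 / 375, tolerance = 1e-12)

  ## identical frequencies: MSP = 0, FST = -1/(n_c - 1)
  cc2 <- locus_fst_components(c(10, 10), c(0.4, 0.4))
  expect_equal(cc2$msp, 0)
  expect_equal(locus_fst(cc2), -1 / 9)

  ## fixed difference: MSG = 0, MSP = n/2, FST = 1
  cc3 <- locus_fst_components(c(12, 12), c(1, 0))
  expect_equal(cc3$msg, 0)
  expect_equal(cc3$msp, 6)  # = n/2 for a fixed difference
  expect_equal(locus_fst(cc3), 1)

  ## monomorphic across subpopulations is undefined
  expect_true(is.na(locus_fst(locus_fst_components(c(5, 5), c(0, 0)))))

  ## estimator variants
  ccw <- locus_fst_components(c(20, 30), c(0.8, 0.3), nc = "wc")
  expect_equal(ccw$n_c, (50 - (400 + 900) / 50) / 1)
  ccm <- locus_fst_components(c(20, 30), c(0.8, 0.3), msg_denom = "sum_minus_1")
  expect_equal(ccm$msg, 9.5 / 48)

  expect_error(locus_fst_components(10, 0.5), ">= 2")
  expect_error(locus_fst_components(c(10, 10), c(0.5, NA)), "undefined")
})

test_that("locus FST is allele-swap invariant and symmetric in the groups", {
  set.seed(4)
  for (i in 1:25) {
    n <- sample(5:50, 2); p <- runif(2)
    f1 <- locus_fst(locus_fst_components(n, p))
    f2 <- locus_fst(locus_fst_components(n, 1 - p))
    expect_equal(f1, f2, tolerance = 1e-12)
  }
  for (i in 1:25) {
    n <- rep(sample(5:50, 1), 2); p <- runif(2)
    expect_equal(locus_fst(locus_fst_components(n, p)),
                 locus_fst(locus_fst_components(rev(n), rev(p))),
                 tolerance = 1e-12)
  }
})

test_that("equal-size two-group FST is monotone in |p1 - p2|", {
  n <- c(25, 25)
  for (centre in c(0.3, 0.5, 0.7)) {
    deltas <- seq(0, min(centre, 1 - centre) - 0.01, length.out = 12)
    fst <- vapply(deltas, function(d)
      locus_fst(locus_fst_components(n, c(centre - d, centre + d))),
      numeric(1))
    expect_true(all(diff(fst) >= -1e-12))
  }
})

test_that("make_windows tiles as specified", {
  w <- make_windows(c(`1` = 250000), 100000, 50000)
  expect_equal(w$start_bp, c(1, 50001, 100001, 150001, 200001))
  expect_equal(w$end_bp - w$start_bp, rep(100000, 5))

  ## window = step: each locus in exactly one window
  w2 <- make_windows(c(`1` = 1e5), 1e4, 1e4)
  pos <- seq(1, 1e5, by = 997)
  counts <- vapply(pos, function(p)
    sum(w2$start_bp <= p & p < w2$end_bp), integer(1))
  expect_true(all(counts == 1L))

  ## window = 2 x step: interior loci in exactly two windows
  w3 <- make_windows(c(`1` = 1e5), 2e4, 1e4)
  pos3 <- seq(20001, 80000, by = 997)
  counts3 <- vapply(pos3, function(p)
    sum(w3$start_bp <= p & p < w3$end_bp), integer(1))
  expect_true(all(counts3 == 2L))

  expect_error(make_windows(c(`1` = 1e5), 100, 200), "window")
})

test_that("windowed_fst: singleton and homogeneous windows behave as locus FST", {
  ## one locus, one window: window value = locus FST in both modes
  d <- rbind(matrix(c(2L, 2L, 2L, 1L), 4, 1), matrix(0L, 4, 1))
  g <- make_g(d, pops = c(rep("x", 4), rep("y", 4)), pos = 5000L)
  scheme <- population_scheme(list(gx = "x", gy = "y"))
  lf <- locus_fst(locus_fst_components(c(4, 4), c(7 / 8, 0)))
  for (mode in c("weighted", "mean")) {
    wf <- windowed_fst(g, scheme, c("gx", "gy"), 10000, 10000, mode = mode)
    expect_equal(nrow(wf), 1L)
    expect_equal(wf$value, lf, tolerance = 1e-12)
  }

  ## identical loci: weighted = mean
  d2 <- cbind(d, d, d)
  g2 <- make_g(d2, pops = c(rep("x", 4), rep("y", 4)),
               pos = c(1000L, 2000L, 3000L))
  ww <- windowed_fst(g2, scheme, c("gx", "gy"), 10000, 10000, "weighted")
  wm <- windowed_fst(g2, scheme, c("gx", "gy"), 10000, 10000, "mean")
  expect_equal(ww$value, wm$value, tolerance = 1e-12)
  expect_equal(ww$n_loci, 3L)

  ## two-locus window equals the hand ratio of sums
  n1 <- c(20, 30); p1 <- c(0.8, 0.3)   # msp 3, msg 9.5/49, nc 25
  n2 <- c(20, 30); p2 <- c(0.6, 0.5)   # hand: pbar 0.54, msp/msg below
  pb2 <- sum(n2 * p2) / 50
  msp2 <- sum(n2 * (p2 - pb2)^2)
  msg2 <- sum(n2 * p2 * (1 - p2)) / 49
  hand <- ((3 - 9.5 / 49) + (msp2 - msg2)) /
    ((3 + 24 * 9.5 / 49) + (msp2 + 24 * msg2))
  ## genotypes realizing those exact frequencies without heterozygote excess:
  mk <- function(n, p) {  # n diploids with alt freq p (2np integer by design)
    alt <- round(2 * n * p)
    c(rep(2L, alt %/% 2), rep(1L, alt %% 2), rep(0L, n - ceiling(alt / 2)))
  }
  dx <- cbind(c(mk(20, 0.8), mk(30, 0.3)), c(mk(20, 0.6), mk(30, 0.5)))
  gx <- make_g(dx, pops = c(rep("x", 20), rep("y", 30)),
               pos = c(1000L, 2000L))
  wfx <- windowed_fst(gx, population_scheme(list(gx = "x", gy = "y")),
                      c("gx", "gy"), 10000, 10000, "weighted")
  expect_equal(wfx$value, hand, tolerance = 1e-12)

  expect_error(windowed_fst(g, scheme, c("gx", "gx")), "differ")
})

test_that("windowed weighted FST equals the brute-force oracle on random fixtures", {
  set.seed(21)
  for (rep in 1:8) {
    sim <- small_sim(seed = 100 + rep, n_snps = 80, n_selected = 2)
    g <- sim$genotypes
    scheme <- population_scheme(list(ind = c("A", "B"), com = c("C", "D")))
    wf <- windowed_fst(g, scheme, c("ind", "com"), 250000, 125000)
    orc <- oracle_windowed_fst(g, c("A", "B"), c("C", "D"), 250000, 125000)
    key <- function(x) paste(x$chrom, x$start_bp)
    expect_setequal(key(wf), key(orc))
    m <- match(key(wf), key(orc))
    expect_equal(wf$value, orc$value[m], tolerance = 1e-9)
    expect_equal(wf$n_loci, orc$n_loci[m])
  }
})

test_that("s > 2 subpopulation mode uses breeds separately", {
  sim <- small_sim(seed = 5, n_snps = 40)
  g <- sim$genotypes
  scheme <- population_scheme(list(ind = c("A", "B"), com = c("C", "D")))
  pooled <- windowed_fst(g, scheme, c("ind", "com"), 1e6, 1e6, pool = TRUE)
  split <- windowed_fst(g, scheme, c("ind", "com"), 1e6, 1e6, pool = FALSE)
  expect_equal(nrow(pooled), nrow(split))
  expect_false(isTRUE(all.equal(pooled$value, split$value)))
})
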