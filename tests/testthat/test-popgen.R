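test_that("theta_pi matches direct pair counting on worked examples", {
  # monomorphic window: no segregating rows
  expect_identical(theta_pi(matrix(integer(0), 0, 4), 100), 0)
  # 2 haplotypes differing at 1 of 100 bp
  expect_equal(theta_pi(matrix(c(0L, 1L), 1, 2), 100), 0.01)
  # 4 haplotypes, allele counts 2/2, window 10 bp: (2*2 / C(4,2)) / 10
  expect_equal(theta_pi(matrix(c(0L, 0L, 1L, 1L), 1, 4), 10), 4 / 6 / 10)
  # all data missing at the only site
  expect_true(is.na(theta_pi(matrix(NA_integer_, 1, 4), 10)))
})

test_that("theta_pi equals the all-pairs brute force on random fixtures", {
  set.seed(301)
  for (rep in 1:100) {
    n <- sample(2:12, 1)
    s <- sample(1:50, 1)
    h <- matrix(sample(c(0L, 1L, NA), n * s, replace = TRUE,
                       prob = c(0.45, 0.45, 0.1)), s, n)
    L <- sample(50:1000, 1)
    expect_equal(theta_pi(h, L), bf_theta_pi(h, L))
  }
})

test_that("Watterson's estimator uses the harmonic normalisation", {
  expect_equal(theta_w(3, 2, 100), 0.03)
  expect_equal(theta_w(11, 4, 100), 11 / ((1 + 1/2 + 1/3) * 100))
  expect_identical(theta_w(0, 10, 1000), 0)
  expect_error(theta_w(3, 1, 100), "n must be")
})

test_that("Tajima's D: n = 2 identity, singleton excess sign, S = 0 sentinel", {
  expect_identical(tajimas_d(matrix(c(0L, 1L), 1, 2)), 0)
  expect_identical(tajimas_d(rbind(c(0L, 1L), c(1L, 0L))), 0)
  # n = 4, all sites singletons -> negative D; check the exact value
  # against an independent inline evaluation of the 1989 formula
  h <- rbind(c(1L, 0L, 0L, 0L), c(0L, 1L, 0L, 0L), c(0L, 0L, 1L, 0L))
  n <- 4; S <- 3
  kbar <- 3 * (2 * 1 * 3 / (4 * 3))
  a1 <- 1 + 1/2 + 1/3; a2 <- 1 + 1/4 + 1/9
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  expected <- (kbar - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  expect_equal(tajimas_d(h), expected)
  expect_lt(tajimas_d(h), 0)
  expect_true(is.na(tajimas_d(matrix(c(0L, 0L, 0L, 0L), 1, 4))))
})

test_that("Hudson Fst matches frequency-moment arithmetic", {
  # fixed difference -> 1
  expect_equal(hudson_fst(matrix(0L, 1, 4), matrix(1L, 1, 4)), 1)
  # both populations monomorphic for the same allele -> sentinel
  expect_true(is.na(hudson_fst(matrix(0L, 1, 4), matrix(0L, 1, 4))))
  # 6/2 vs 2/6 alt counts among 8 haplotypes each
  h1 <- matrix(c(rep(1L, 6), rep(0L, 2)), 1, 8)
  h2 <- matrix(c(rep(1L, 2), rep(0L, 6)), 1, 8)
  expect_equal(hudson_fst(h1, h2), bf_fst_one_site(6, 8, 2, 8))
  expect_equal(hudson_fst(h1, h2), 1 - (8/7 * 2 * 0.75 * 0.25) / 0.625)
})

test_that("Balding-Nichols divergence is recovered by windowed Hudson Fst", {
  bn <- simulate_balding_nichols(30, 1500, 0.2, seed = 5)
  h1 <- t(bn$haps[bn$pop == "pop1", ])
  h2 <- t(bn$haps[bn$pop == "pop2", ])
  expect_lt(abs(hudson_fst(h1, h2) - 0.2), 0.05)
})

test_that("ld_r2 matches 2x2 haplotype-table arithmetic", {
  expect_equal(ld_r2(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(ld_r2(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)
  # counts AB=3, Ab=1, aB=1, ab=3 (coding derived = 1)
  a <- c(1, 1, 1, 1, 0, 0, 0, 0)
  b <- c(1, 1, 1, 0, 1, 0, 0, 0)
  expect_equal(ld_r2(a, b), 0.25)
  expect_equal(ld_r2(a, b), bf_r2(3, 1, 1, 3))
  # monomorphic input -> sentinel
  expect_true(is.na(ld_r2(c(1, 1, 1, 1), c(0, 1, 0, 1))))
})

test_that("r2 stays within [0, 1] over random complete and missing fixtures", {
  set.seed(99)
  for (rep in 1:200) {
    n <- sample(4:30, 1)
    a <- sample(c(0L, 1L, NA), n, replace = TRUE, prob = c(0.45, 0.45, 0.1))
    b <- sample(c(0L, 1L, NA), n, replace = TRUE, prob = c(0.45, 0.45, 0.1))
    r2 <- ld_r2(a, b)
    if (!is.na(r2)) {
      expect_gte(r2, 0); expect_lte(r2, 1)
    }
  }
})

test_that("ld_decay bins, half-decay sentinel and order invariance", {
  # three sites in perfect LD
  codes <- matrix(rep(c(0L, 0L, 2L, 2L), 3), 3, 4, byrow = TRUE)
  gm <- gm_fixture(codes, pops = rep("wild", 4),
                   pos = c(1000L, 11000L, 26000L))
  dec <- ld_decay(gm, "wild", maxdist = 50000, bin = 1000)
  occ <- dec$bins[dec$bins$n_pairs > 0, ]
  expect_true(all(occ$mean_r2 == 1))
  expect_true(is.na(dec$half_decay))

  # single qualifying pair at 10 kb with r2 = 0.25
  codes2 <- rbind(c(2L, 2L, 2L, 2L, 0L, 0L, 0L, 0L),
                  c(2L, 2L, 2L, 0L, 2L, 0L, 0L, 0L))
  gm2 <- gm_fixture(codes2, pops = rep("wild", 8), pos = c(1000L, 11000L))
  dec2 <- ld_decay(gm2, "wild", maxdist = 50000, bin = 1000)
  occ2 <- dec2$bins[dec2$bins$n_pairs > 0, ]
  expect_identical(nrow(occ2), 1L)
  expect_equal(occ2$mean_r2, 0.25)
  expect_identical(occ2$n_pairs, 1L)

  # invariance to sample order
  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  # (the permuted matrix carries the same haplotype multiset)
  gm2p <- gm_fixture(codes2[, perm], pops = rep("wild", 8),
                     pos = c(1000L, 11000L))
  dec2p <- ld_decay(gm2p, "wild", maxdist = 50000, bin = 1000)
  expect_equal(dec2$bins$mean_r2, dec2p$bins$mean_r2)
})

test_that("MAF and distance gates exclude pairs from the decay scan", {
  # second site has MAF 0.1 - epsilon equivalent: 1/20 carriers
  codes <- rbind(rep(c(0L, 2L), 10),
                 c(2L, rep(0L, 19)))
  gm <- gm_fixture(codes, pops = rep("wild", 20), pos = c(1000L, 5000L))
  dec <- ld_decay(gm, "wild", maxdist = 250000, min_maf = 0.1)
  expect_identical(sum(dec$bins$n_pairs), 0L)
  # distance beyond maxdist is ignored
  codes2 <- matrix(rep(c(0L, 0L, 2L, 2L), 2), 2, 4, byrow = TRUE)
  gm2 <- gm_fixture(codes2, pops = rep("wild", 4), pos = c(1000L, 400000L))
  dec2 <- ld_decay(gm2, "wild", maxdist = 250000)
  expect_identical(sum(dec2$bins$n_pairs), 0L)
})

test_that("unlinked windows show near-zero background r2", {
  # independent coalescent windows: E[r2] between them is about 1/n
  set.seed(77)
  n <- 30
  w1 <- simulate_coalescent_window(n, 0.001, 20000)
  w2 <- simulate_coalescent_window(n, 0.001, 20000)
  keep_common <- function(h) {
    maf <- colMeans(h)
    h[, maf >= 0.1 & maf <= 0.9, drop = FALSE]
  }
  h1 <- keep_common(w1$haps); h2 <- keep_common(w2$haps)
  r2 <- outer(seq_len(ncol(h1)), seq_len(ncol(h2)),
              Vectorize(function(i, j) ld_r2(h1[, i], h2[, j])))
  expect_lt(mean(r2), 3 / n)
})

test_that("haplogroup partition groups by identity with missing wildcards", {
  # all identical -> one group
  gm <- gm_fixture(matrix(0L, 2, 5), pops = rep("wild", 5))
  expect_identical(length(haplogroup_partition(gm, "chr1", 0, 100)), 1L)

  # two distinct vectors -> two groups with correct memberships
  codes <- cbind(c(0L, 0L), c(0L, 0L), c(2L, 2L))
  gm2 <- gm_fixture(codes, pops = rep("wild", 3))
  grp <- haplogroup_partition(gm2, "chr1", 0, 100)
  expect_identical(length(grp), 2L)
  expect_identical(grp[[1]], c("s01", "s02"))
  expect_identical(grp[[2]], "s03")

  # a sample with one missing call compatible with both groups joins the larger
  codes3 <- cbind(c(0L, 0L), c(0L, 0L), c(2L, 0L), c(NA, 0L))
  gm3 <- gm_fixture(codes3, pops = rep("wild", 4))
  grp3 <- haplogroup_partition(gm3, "chr1", 0, 100)
  expect_identical(grp3[[1]], c("s01", "s02", "s04"))

  expect_error(haplogroup_partition(gm, "chr1", 500, 600), "no genotyped site")
})

test_that("adding missing calls leaves theta_pi unchanged where pairs persist", {
  h <- rbind(c(0L, 1L, 0L, 1L), c(1L, 1L, 0L, 0L))
  base <- theta_pi(h, 100)
  # knock out one haplotype at a monomorphic-after-removal site? No:
  # remove a symmetric pair so per-site pair composition is preserved at
  # site 1 while site 2 loses calls
  h2 <- h
  h2[2, ] <- NA
  # site 1 untouched: its contribution is identical
  sc1 <- theta_pi(h[1, , drop = FALSE], 100)
  sc1b <- theta_pi(h2[1, , drop = FALSE], 100)
  expect_identical(sc1, sc1b)
})

test_that("window_stats tiles windows and reports sentinels for data-free spans", {
  codes <- rbind(c(0L, 2L, 0L, 2L), c(2L, 0L, 0L, 2L), c(0L, 2L, 2L, 2L))
  gm <- gm_fixture(codes, pops = c("wild", "wild", "elite", "elite"),
                   pos = c(100L, 200L, 60100L))
  st <- window_stats(gm, window = 50000, step = 25000,
                     chrom_len = c(chr1 = 100000))
  expect_identical(st$start, c(0, 25000, 50000, 75000))
  expect_identical(st$end, c(50000, 75000, 100000, 100000))
  # wild group: sites 1-2 polymorphic in window 1
  expect_identical(st$S_wild[1], 2)
  # window 2 (25k-75k) holds only site 3
  expect_identical(st$S_wild[2], 1)
  # no variant record in window 4 (75k-100k): monomorphic, pi = 0
  expect_identical(st$pi_wild[4], 0)
  expect_true(is.na(st$D_wild[4]))
  # fully missing window data -> sentinel
  codes_na <- matrix(NA_integer_, 1, 4)
  gm_na <- gm_fixture(codes_na, pops = c("wild", "wild", "elite", "elite"),
                      pos = 500L)
  st_na <- window_stats(gm_na, window = 1000, step = 1000,
                        chrom_len = c(chr1 = 1000))
  expect_true(is.na(st_na$pi_wild[1]))
})

test_that("window_stats theta estimates agree with the direct estimators", {
  set.seed(13)
  w <- simulate_coalescent_window(8, 0.002, 50000, seed = 13)
  codes <- t(w$haps) * 2L
  gm <- gm_fixture(codes, pops = rep("wild", 8), pos = w$pos,
                   ref = rep("A", length(w$pos)), alt = rep("G", length(w$pos)))
  st <- window_stats(gm, window = 50000, step = 50000,
                     chrom_len = c(chr1 = 50000))
  h <- t(w$haps)
  expect_equal(st$pi_wild[1], theta_pi(h, 50000))
  expect_equal(st$tw_wild[1], theta_w(nrow(h), 8, 50000))
  expect_equal(st$D_wild[1], tajimas_d(h))
})
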