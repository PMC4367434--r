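test_that("minor allele frequency is computed over non-missing calls", {
  expect_equal(minorAlleleFreq(c(0, 1, 2, 2)), 0.375)   # p = 5/8
  expect_equal(minorAlleleFreq(c(0, 0, 0)), 0)
  expect_equal(minorAlleleFreq(c(1, 1)), 0.5)
  expect_equal(minorAlleleFreq(c(0, NA, 1)), 0.25)
  expect_error(minorAlleleFreq(c(NA_real_, NA_real_)), "missing")
})

test_that("MAF filter keeps >= threshold and drops monomorphic markers", {
  map <- data.frame(chrom = "1", id = c("a", "b", "c"), pos = c(1e5, 2e5, 3e5))
  # MAFs: 0 (monomorphic), 0.04, 0.30 over 25 individuals
  calls <- rbind(rep(0, 25), c(rep(0, 23), 1, 1), c(rep(0, 10), rep(1, 15)))
  g <- SnpGenotypes(calls, map)
  expect_equal(unname(round(minorAlleleFreq(g), 2)), c(0, 0.04, 0.30))
  kept <- suppressMessages(mafFilter(g, 0.05))
  expect_equal(rownames(kept), "c")
  # threshold 0: polymorphic markers all kept, monomorphic still removed
  kept0 <- suppressMessages(mafFilter(g, 0))
  expect_equal(rownames(kept0), c("b", "c"))
  # marker exactly at the threshold is retained
  kept04 <- suppressMessages(mafFilter(g, 0.04))
  expect_equal(rownames(kept04), c("b", "c"))
  expect_error(mafFilter(g, 0.5), "0.5")
  expect_error(suppressMessages(mafFilter(g, 0.45)), "no markers survive")
})

test_that("genotype r2 equals squared Pearson correlation of dosages", {
  res <- r2Genotype(c(0, 1, 2, 2), c(0, 1, 1, 2))
  expect_equal(res$r2, 4 / 5.5)
  expect_equal(res$n_obs, 4L)
  expect_identical(res$reason, NA_character_)

  expect_equal(r2Genotype(c(0, 1, 2, 1), c(0, 1, 2, 1))$r2, 1)
  expect_equal(r2Genotype(c(0, 1, 2, 1), c(2, 1, 0, 1))$r2, 1)

  skip1 <- r2Genotype(c(0, 1, 2, 1), c(1, 1, 1, 1))
  expect_true(is.na(skip1$r2))
  expect_match(skip1$reason, "monomorphic")

  skip2 <- r2Genotype(c(0, 1, NA, NA), c(1, 0, 1, 0))
  expect_true(is.na(skip2$r2))
  expect_match(skip2$reason, "insufficient")
})

test_that("haplotype r2 matches the frequency formula", {
  # full coupling: pA = pB = pAB = 0.5
  a <- rep(c(1, 0), 5); b <- rep(c(1, 0), 5)
  expect_equal(r2Haplotype(a, b)$r2, 1)
  # independence: pAB = pA * pB exactly
  a2 <- c(1, 1, 0, 0, 1, 1, 0, 0)
  b2 <- c(1, 0, 1, 0, 1, 0, 1, 0)
  expect_equal(r2Haplotype(a2, b2)$r2, 0)
  # pA = 0.6, pB = 0.5, pAB = 0.4 -> 0.01 / 0.06
  a3 <- c(1, 1, 1, 1, 1, 1, 0, 0, 0, 0)
  b3 <- c(1, 1, 1, 1, 0, 0, 1, 0, 0, 0)
  res <- r2Haplotype(a3, b3)
  expect_equal(res$r2, 1 / 6)
  expect_equal(res$n_obs, 5)
})

test_that("r2 is symmetric and invariant to allele relabelling", {
  set.seed(21)
  for (i in 1:20) {
    x <- stats::rbinom(15, 2, 0.4); y <- stats::rbinom(15, 2, 0.6)
    x[sample(15, 2)] <- NA
    a <- r2Genotype(x, y); b <- r2Genotype(y, x)
    expect_identical(a$r2, b$r2)
    if (!is.na(a$r2)) {
      expect_equal(r2Genotype(2 - x, y)$r2, a$r2, tolerance = 1e-12)
      expect_equal(r2Genotype(x, 2 - y)$r2, a$r2, tolerance = 1e-12)
    }
  }
})

test_that("pair enumeration respects the distance window and chromosomes", {
  set.seed(31)
  map <- data.frame(chrom = "1", id = paste0("m", 1:4),
                    pos = c(1e5, 2e5, 3e5, 4e6))
  calls <- matrix(stats::rbinom(4 * 30, 2, 0.5), nrow = 4)
  g <- SnpGenotypes(calls, map)
  pairs <- ldPairs(g, minDist = 5e4, maxDist = 5e5)
  expect_equal(nrow(pairs), 3L)
  expect_equal(sort(pairs$dist), c(1e5, 1e5, 2e5))
  expect_equal(pairs$pos_a, c(1e5, 1e5, 2e5))   # deterministic order

  # markers on different chromosomes are never paired
  map2 <- data.frame(chrom = c("1", "2"), id = c("a", "b"), pos = c(1e5, 2e5))
  g2 <- SnpGenotypes(matrix(stats::rbinom(2 * 30, 2, 0.5), nrow = 2), map2)
  expect_equal(nrow(ldPairs(g2, minDist = 1, maxDist = 1e6)), 0L)
})

test_that("matrix pair enumeration agrees with the scalar kernels", {
  set.seed(41)
  for (phased in c(FALSE, TRUE)) {
    g <- if (phased) randomHaplotypes(15, 12, missingRate = 0.1)
         else randomGenotypes(15, 12, missingRate = 0.1)
    pairs <- ldPairs(g, minDist = 1, maxDist = 2e7)
    calls <- genotypeCalls(g)
    mm <- markerMap(g)
    for (r in sample(nrow(pairs), min(40, nrow(pairs)))) {
      i <- which(mm$pos == pairs$pos_a[r]); j <- which(mm$pos == pairs$pos_b[r])
      ref <- if (phased) r2Haplotype(calls[i, ], calls[j, ])
             else r2Genotype(calls[i, ], calls[j, ])
      expect_equal(pairs$r2[r], ref$r2, tolerance = 1e-12)
      expect_equal(pairs$n_obs[r], ref$n_obs)
    }
  }
})

test_that("thread count does not change the pair stream", {
  g <- suppressMessages(simulateWrightFisher(
    popSize = 60, sampleN = 30, nMarkers = 200, chromLengthBp = 2e7,
    recombRatePerBp = 1e-8, generations = 60, seed = 99))
  gf <- suppressMessages(mafFilter(g, 0.05))
  p1 <- suppressMessages(ldPairs(gf, threads = 1, blockSize = 32))
  p4 <- suppressMessages(ldPairs(gf, threads = 4, blockSize = 32))
  expect_equal(p1, p4)
})

test_that("genotype r2 converges to the haplotype r2 of the source pool", {
  # individuals are random pairings of haplotypes from a pool with known
  # two-locus frequencies; the unphased estimator tracks the phased one
  set.seed(51)
  pool <- cbind(c(1, 1, 0, 0), c(1, 0, 1, 0))
  w <- c(0.4, 0.2, 0.15, 0.25)
  target <- r2Haplotype(rep(pool[, 1], round(w * 10000)),
                        rep(pool[, 2], round(w * 10000)))$r2
  n <- 4000
  h1 <- sample(4, n, TRUE, prob = w); h2 <- sample(4, n, TRUE, prob = w)
  x <- pool[h1, 1] + pool[h2, 1]
  y <- pool[h1, 2] + pool[h2, 2]
  expect_equal(r2Genotype(x, y)$r2, target, tolerance = 0.05)
})
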