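writeTmp <- function(lines) {
  f <- tempfile()
  writeLines(lines, f)
  f
}

test_that("ped/map parsing recodes against the minor allele", {
  map <- writeTmp(c("1 snpA 0 100", "1 snpB 0 200"))
  ped <- writeTmp("F1 I1 0 0 1 -9 A A A G")
  g <- suppressMessages(readPlink(ped, map))
  expect_false(isPhased(g))
  expect_equal(unname(genotypeCalls(g)[, 1]), c(0, 1))
  expect_equal(markerMap(g)$pos, c(100L, 200L))
  expect_equal(sampleIds(g), "I1")
})

test_that("a genotype with a 0 allele is missing", {
  map <- writeTmp("1 snpA 0 100")
  ped <- writeTmp(c("F1 I1 0 0 1 -9 0 A", "F1 I2 0 0 1 -9 A G"))
  g <- suppressMessages(readPlink(ped, map))
  expect_true(is.na(genotypeCalls(g)[1, 1]))
  expect_false(is.na(genotypeCalls(g)[1, 2]))
})

test_that("map dialects, ragged lines and bad codes are handled", {
  map3 <- writeTmp(c("1 a 100", "1 b 200"))
  ped <- writeTmp("F1 I1 0 0 1 -9 A A A G")
  g <- suppressMessages(readPlink(ped, map3))
  expect_equal(nMarkers(g), 2L)
  expect_true(all(is.na(markerMap(g)$cM)))

  map2 <- writeTmp(c("1 a 0 100", "1 b 0 200", "1 c 0 300"))
  expect_error(suppressMessages(readPlink(ped, map2)), "marker count mismatch")

  pedRagged <- writeTmp(c("F1 I1 0 0 1 -9 A A A G", "F1 I2 0 0 1 -9 A A"))
  expect_error(suppressMessages(readPlink(pedRagged, map3)), "ragged ped line 2")

  pedBad <- writeTmp("F1 I1 0 0 1 -9 A A X G")
  expect_error(suppressMessages(readPlink(pedBad, map3)), "allele code")

  pedTri <- writeTmp(c("F1 I1 0 0 1 -9 A A C G", "F1 I2 0 0 1 -9 A A T G"))
  expect_error(suppressMessages(readPlink(pedTri, map3)), "snp|'b'")
})

test_that("markers are sorted by position within chromosome, keeping origin", {
  map <- writeTmp(c("2 a 0 500", "2 b 0 100", "1 c 0 900"))
  ped <- writeTmp("F1 I1 0 0 1 -9 A G A A G G")
  g <- suppressMessages(readPlink(ped, map))
  mm <- markerMap(g)
  expect_equal(mm$id, c("b", "a", "c"))     # chrom appearance order, bp sorted
  expect_equal(mm$origIndex, c(2L, 1L, 3L))
})

test_that("PLINK round trip is lossless", {
  set.seed(11)
  g <- randomGenotypes(12, 25, nChrom = 2L)
  ped <- tempfile(); map <- tempfile()
  writePlink(recodeMinor(g), ped, map)
  g2 <- suppressMessages(readPlink(ped, map))
  expect_equal(unname(genotypeCalls(g2)), unname(genotypeCalls(recodeMinor(g))))
  expect_equal(markerMap(g2)$pos, markerMap(g)$pos)
  expect_equal(markerMap(g2)$chrom, markerMap(g)$chrom)

  # with missing data the NA mask survives
  gm <- recodeMinor(randomGenotypes(10, 10, missingRate = 0.1))
  writePlink(gm, ped, map)
  g3 <- suppressMessages(readPlink(ped, map))
  expect_equal(is.na(unname(genotypeCalls(g3))), is.na(unname(genotypeCalls(gm))))

  expect_error(writePlink(g[0, ], ped, map), "empty")
})

test_that("phased ped files round-trip haplotype-ordered alleles", {
  g <- suppressMessages(simulateWrightFisher(
    30, 12, 20, 2e6, 1e-8, 15, seed = 8, phased = TRUE, missingRate = 0.05))
  ped <- tempfile(); map <- tempfile()
  writePlink(g, ped, map)
  g2 <- suppressMessages(readPlink(ped, map, phased = TRUE))
  expect_true(isPhased(g2))
  expect_equal(unname(genotypeCalls(g2)), unname(genotypeCalls(g)))
})

test_that("minor-allele recoding is idempotent", {
  set.seed(4)
  g <- randomGenotypes(15, 20)
  r1 <- recodeMinor(g)
  r2 <- recodeMinor(r1)
  expect_identical(genotypeCalls(r1), genotypeCalls(r2))
  expect_true(all(minorAlleleFreq(r1) <= 0.5 + 1e-12))
})

test_that("LD tables map columns, drop bad rows, and round-trip", {
  f <- writeTmp("1 1000 51000 0.25")
  tab <- readLDTable(f, columns = c(chrom = 1, pos_a = 2, pos_b = 3, r2 = 4),
                     n = 50)
  expect_equal(tab$dist, 50000)
  expect_equal(tab$r2, 0.25)
  expect_equal(tab$n_obs, 50)

  f2 <- writeTmp(c("1 1000 51000 0.25", "1 1000 61000 1.7"))
  expect_message(
    tab2 <- readLDTable(f2, columns = c(chrom = 1, pos_a = 2, pos_b = 3, r2 = 4),
                        n = 50),
    "1 LD row")
  expect_equal(nrow(tab2), 1L)

  hdr <- writeTmp("chrom\tpos_a\tpos_b\tr2")
  expect_error(readLDTable(hdr, n = 50), "no LD records")
  expect_error(readLDTable(f, columns = c(chrom = 1, r2 = 4), n = 50),
               "pos_a|dist")

  pairs <- data.frame(chrom = "1", pos_a = c(100, 200), pos_b = c(5100, 9200),
                      dist = c(5000, 9000), r2 = c(0.25, 0.125), n_obs = 50)
  out <- tempfile()
  writeLDTable(pairs, out)
  back <- readLDTable(out)
  expect_equal(back$r2, pairs$r2)
  expect_equal(back$dist, pairs$dist)
  expect_equal(back$n_obs, pairs$n_obs)
})

test_that("trajectory files serialize with fixed formats and round-trip", {
  est <- data.frame(gen_ago = c(50, 100), ne = c(100, 120.04),
                    mean_dist = c(1e6, 5e5), mean_r2_adj = c(0.2, 0.25),
                    sd_r2_adj = c(0, 0.0125), n_pairs = c(10L, 7L))
  f <- tempfile()
  writeTrajectory(est, f)
  lines <- readLines(f)
  expect_equal(lines[1], "GenAgo\tNe\tAvgDist\tAvgR2\tSdR2\tNPairs")
  expect_equal(length(strsplit(lines[2], "\t")[[1]]), 6L)
  expect_equal(lines[2], "50.0\t100.0\t1000000.0\t0.200000\t0.000000\t10")
  back <- readTrajectory(f)
  expect_equal(back$ne, c(100, 120.0))
  expect_equal(back$n_pairs, c(10L, 7L))

  expect_error(writeTrajectory(est[0, ], f), "nothing to write")
})
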