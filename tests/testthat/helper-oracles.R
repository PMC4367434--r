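# Independent oracles and fixture builders used across the suite.

# textbook Pearson-then-square on pairwise-complete observations, via cor()
bruteR2Genotype <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) return(NA_real_)
  r <- suppressWarnings(stats::cor(x[ok], y[ok]))
  r * r
}

# exhaustive 2x2 haplotype-frequency counting
bruteR2Haplotype <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 6L) return(NA_real_)
  tab <- table(factor(a, levels = 0:1), factor(b, levels = 0:1))
  pA <- sum(tab["1", ]) / n
  pB <- sum(tab[, "1"]) / n
  den <- pA * (1 - pA) * pB * (1 - pB)
  if (den == 0) return(NA_real_)
  pAB <- tab["1", "1"] / n
  (pAB - pA * pB)^2 / den
}

# random unphased fixture: m markers x n individuals, arbitrary chromosomes
randomGenotypes <- function(n, m, nChrom = 1L, missingRate = 0) {
  p <- stats::runif(m, 0.1, 0.9)
  calls <- matrix(stats::rbinom(n * m, 2L, rep(p, n)), nrow = m)
  if (missingRate > 0) calls[stats::runif(length(calls)) < missingRate] <- NA
  chrom <- as.character(rep_len(seq_len(nChrom), m))
  pos <- unlist(lapply(split(seq_len(m), chrom), function(i)
    sort(sample.int(1e7, length(i)))), use.names = FALSE)
  map <- data.frame(chrom = sort(chrom), id = paste0("m", seq_len(m)),
                    pos = pos, stringsAsFactors = FALSE)
  SnpGenotypes(calls, map)
}

# random phased fixture: m markers x 2n haplotypes
randomHaplotypes <- function(n, m, missingRate = 0) {
  p <- stats::runif(m, 0.1, 0.9)
  calls <- matrix(stats::rbinom(2L * n * m, 1L, rep(p, 2L * n)), nrow = m)
  if (missingRate > 0) {
    drop <- matrix(stats::runif(m * n) < missingRate, nrow = m)
    idx <- which(drop, arr.ind = TRUE)
    calls[cbind(idx[, 1L], 2L * idx[, 2L] - 1L)] <- NA
    calls[cbind(idx[, 1L], 2L * idx[, 2L])] <- NA
  }
  map <- data.frame(chrom = "1", id = paste0("m", seq_len(m)),
                    pos = sort(sample.int(1e7, m)), stringsAsFactors = FALSE)
  SnpGenotypes(calls, map, phased = TRUE)
}
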