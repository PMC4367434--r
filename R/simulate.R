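## Synthetic data with known ground truth: Wright-Fisher forward simulation
## and analytic LD profiles.

#' Recode calls against the per-locus minor allele
#'
#' Flips dosages (c -> 2 - c) or haplotype indicators (a -> 1 - a) at every
#' marker where the counted allele has frequency > 0.5, so the counted
#' allele is the minor one.  Idempotent; r2 is invariant to the recoding.
#'
#' @param x a \linkS4class{SnpGenotypes} object.
#' @return the recoded object.
#' @export
recodeMinor <- function(x) {
  stopifnot(is(x, "SnpGenotypes"))
  calls <- genotypeCalls(x)
  n <- rowSums(!is.na(calls))
  denom <- if (isPhased(x)) n else 2 * n
  p <- rowSums(calls, na.rm = TRUE) / pmax(denom, 1)
  flip <- !is.na(p) & p > 0.5
  if (any(flip)) {
    top <- if (isPhased(x)) 1 else 2
    calls[flip, ] <- top - calls[flip, , drop = FALSE]
    SummarizedExperiment::assay(x, "calls") <- calls
  }
  x
}

# one Wright-Fisher generation: parents hap (2Np x m) -> 2Nc offspring
# gametes with Poisson(lambda) crossovers at uniform breakpoints on [0, L]
.wfGeneration <- function(hap, Nc, pos, L, lambda) {
  Np <- nrow(hap) %/% 2L
  nG <- 2L * Nc
  par <- sample.int(Np, nG, replace = TRUE)
  hapA <- hap[2L * par - 1L, , drop = FALSE]
  hapB <- hap[2L * par, , drop = FALSE]
  start <- sample(c(TRUE, FALSE), nG, replace = TRUE)
  k <- stats::rpois(nG, lambda)
  P <- matrix(start, nrow = nG, ncol = length(pos))
  for (g in which(k > 0L)) {
    br <- sort(stats::runif(k[g], 0, L))
    seg <- findInterval(pos, br)
    P[g, ] <- xor(start[g], seg %% 2L == 1L)
  }
  out <- hapB
  out[P] <- hapA[P]
  out
}

#' Forward Wright-Fisher simulation with recombination
#'
#' Simulates 2N haplotypes of one chromosome forward in time under the
#' neutral Wright-Fisher model: discrete generations, random mating, no
#' selection, no mutation (segregating sites are fixed at the start with
#' allele frequency exactly 0.5 at uniformly spaced markers).  Each
#' offspring haplotype is a gamete of a random parent, formed with a
#' Poisson(chromLengthBp * recombRatePerBp) number of crossovers at uniform
#' breakpoints.  After \code{generations} rounds, \code{sampleN} diploids
#' are drawn without replacement.  Monomorphic (fixed) markers are retained;
#' the MAF filter is a separate, tested step.
#'
#' With a demographic profile, the population size switches at the given
#' change points, enabling simulations of Ne trends rather than constant
#' size.
#'
#' @param popSize census/effective size N (diploids).
#' @param sampleN individuals sampled at the end (<= final N).
#' @param nMarkers markers, uniformly spaced on the chromosome.
#' @param chromLengthBp chromosome length in bp.
#' @param recombRatePerBp recombination rate in Morgans/bp.
#' @param generations rounds of random mating.
#' @param seed mandatory RNG seed; identical seeds give bit-identical
#'   output.
#' @param demography optional data.frame with columns \code{generation},
#'   \code{N}: from each \code{generation} (1-based) onward the population
#'   has size \code{N}.
#' @param phased return the sampled haplotypes (phased) instead of dosages.
#' @param missingRate fraction of calls set to missing at random (default 0).
#' @return a \linkS4class{SnpGenotypes} object, minor-allele coded; the
#'   simulation parameters are stored in \code{metadata(x)$simulation}.
#' @examples
#' g <- simulateWrightFisher(popSize = 50, sampleN = 20, nMarkers = 30,
#'                           chromLengthBp = 5e6, recombRatePerBp = 1e-8,
#'                           generations = 20, seed = 42)
#' @export
simulateWrightFisher <- function(popSize, sampleN, nMarkers, chromLengthBp,
                                 recombRatePerBp, generations, seed,
                                 demography = NULL, phased = FALSE,
                                 missingRate = 0) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  stopifnot(popSize >= 1, nMarkers >= 1, chromLengthBp >= nMarkers,
            recombRatePerBp >= 0, generations >= 0,
            missingRate >= 0, missingRate < 1)
  sizes <- rep(as.integer(popSize), generations)
  if (!is.null(demography)) {
    stopifnot(all(c("generation", "N") %in% names(demography)))
    for (r in seq_len(nrow(demography))) {
      g0 <- demography$generation[r]
      if (g0 >= 1 && g0 <= generations)
        sizes[g0:generations] <- as.integer(demography$N[r])
    }
  }
  finalN <- if (generations > 0) sizes[generations] else as.integer(popSize)
  if (sampleN > finalN)
    stop("sampleN (", sampleN, ") exceeds final population size (", finalN, ")")
  set.seed(as.integer(seed))
  L <- as.numeric(chromLengthBp)
  spacing <- L / nMarkers
  pos <- as.integer(round(spacing * seq_len(nMarkers)))
  lambda <- L * recombRatePerBp
  # initial population: exact frequency 0.5 at every marker
  N0 <- as.integer(popSize)
  hap <- matrix(0L, nrow = 2L * N0, ncol = nMarkers)
  for (j in seq_len(nMarkers))
    hap[sample.int(2L * N0, N0), j] <- 1L
  for (g in seq_len(generations))
    hap <- .wfGeneration(hap, sizes[g], pos, L, lambda)
  idx <- sample.int(finalN, sampleN)
  h1 <- hap[2L * idx - 1L, , drop = FALSE]
  h2 <- hap[2L * idx, , drop = FALSE]
  map <- data.frame(chrom = "1", id = sprintf("snp%04d", seq_len(nMarkers)),
                    pos = pos, stringsAsFactors = FALSE)
  if (phased) {
    calls <- matrix(NA_real_, nrow = nMarkers, ncol = 2L * sampleN)
    calls[, 2L * seq_len(sampleN) - 1L] <- t(h1)
    calls[, 2L * seq_len(sampleN)] <- t(h2)
  } else {
    calls <- t(h1 + h2)
  }
  if (missingRate > 0) {
    if (phased) {
      drop <- which(stats::runif(nMarkers * sampleN) < missingRate)
      ind <- (drop - 1L) %/% nMarkers + 1L
      row <- (drop - 1L) %% nMarkers + 1L
      calls[cbind(row, 2L * ind - 1L)] <- NA
      calls[cbind(row, 2L * ind)] <- NA
    } else {
      calls[stats::runif(length(calls)) < missingRate] <- NA
    }
  }
  g <- SnpGenotypes(calls, map, phased = phased,
                    sampleIds = sprintf("I%03d", seq_len(sampleN)))
  g <- recodeMinor(g)
  S4Vectors::metadata(g)$simulation <- list(
    popSize = popSize, sampleN = sampleN, nMarkers = nMarkers,
    chromLengthBp = chromLengthBp, recombRatePerBp = recombRatePerBp,
    generations = generations, seed = seed, demography = demography,
    missingRate = missingRate)
  message("simulated Wright-Fisher population (seed ", seed, "): N = ",
          popSize, ", ", generations, " generations, ", nMarkers,
          " markers on ", chromLengthBp, " bp")
  g
}

#' Analytic LD profile with known Ne
#'
#' Emits, for every bin of a \linkS4class{BinScheme}, pairwise LD records at
#' the bin's midpoint distance with
#'
#'   r2 = 1 / (alpha + 4 * Ne * f(c)) + 1 / (beta * n)
#'
#' where f(c) is the mapped recombination fraction of that distance.  Running
#' the estimation pipeline on this profile with the same alpha, beta and
#' mapping must return exactly \code{Ne} in every bin — an end-to-end
#' analytic round trip of the Sved inversion.
#'
#' @param Ne true effective population size.
#' @param alpha,beta,n correction parameters the profile embeds.
#' @param scheme a \linkS4class{BinScheme}.
#' @param mapFunction,k distance mapping (must match the estimation run).
#' @param pairsPerBin identical records emitted per bin (>= 1).
#' @return data.frame of pairwise LD records as \code{\link{ldPairs}}.
#' @examples
#' sch <- makeBins(5e4, 4e6, 10, 1.5)
#' prof <- generateLDProfile(100, 1, 1, 50, sch)
#' range(runTrajectory(prof, sch)$ne)   # 100 100
#' @export
generateLDProfile <- function(Ne, alpha = 1, beta = 1, n = 50, scheme,
                              mapFunction = "linear", k = 1e-8,
                              pairsPerBin = 2L) {
  stopifnot(Ne > 0, alpha > 0, beta > 0, n > 0, pairsPerBin >= 1,
            is(scheme, "BinScheme"))
  bt <- binTable(scheme)
  delta <- round(bt$mid)
  # keep the rounded midpoint inside its half-open bin
  delta <- pmax(pmin(delta, ceiling(bt$hi) - 1), floor(bt$lo) + 1)
  cc <- mapDistance(delta, method = mapFunction, k = k)
  r2 <- 1 / (alpha + 4 * Ne * cc) + 1 / (beta * n)
  i <- rep(seq_len(nrow(bt)), each = pairsPerBin)
  data.frame(chrom = "1", pos_a = 1, pos_b = 1 + delta[i],
             dist = delta[i], r2 = r2[i], n_obs = n,
             stringsAsFactors = FALSE)
}
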