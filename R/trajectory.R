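## Invert Sved's E(r2) = 1/(1 + 4 Ne c) into an Ne trajectory.

#' Effective population size from binned LD
#'
#' For each distance bin, the recombination fraction c_t is mapped from the
#' bin's mean pair distance (\code{\link{mapDistance}}) and Sved's
#' drift-recombination expectation E(r2) = 1/(alpha + 4 Ne c) is inverted:
#'
#'   Ne = (1 / (4 c_t)) * (1 / mean_r2_adj - alpha)
#'
#' where alpha corrects for the occurrence of mutation (1: none; 2 or 2.2:
#' alternative mutation models).  The generations-ago coordinate of the bin
#' is t = 1 / (2 c_t): LD over greater recombinational distances is
#' informative about more recent generations.  Bins whose mean adjusted r2
#' or Ne is non-positive are flagged invalid.
#'
#' @param summary data.frame from \code{\link{summarizeBins}}.
#' @param mapFunction mapping function name (see
#'   \code{\link{registerMapFunction}}).
#' @param k Morgans per bp (default 1e-8).
#' @param alpha mutation correction, one of 1, 2, 2.2 (any positive value
#'   with \code{expert = TRUE}).
#' @param expert allow alpha outside the conventional set.
#' @return data.frame with columns \code{gen_ago}, \code{ne},
#'   \code{mean_dist}, \code{mean_r2_adj}, \code{sd_r2_adj}, \code{n_pairs},
#'   \code{valid}.
#' @export
estimateNe <- function(summary, mapFunction = "linear", k = 1e-8, alpha = 1,
                       expert = FALSE) {
  stopifnot(is.data.frame(summary), nrow(summary) >= 1L)
  if (!expert && !alpha %in% c(1, 2, 2.2))
    stop("alpha must be one of 1, 2, 2.2 (use expert = TRUE to override)")
  if (alpha <= 0) stop("alpha must be > 0")
  ct <- mapDistance(summary$mean_dist, method = mapFunction, k = k)
  ne <- (1 / (4 * ct)) * (1 / summary$mean_r2_adj - alpha)
  t <- 1 / (2 * ct)
  valid <- summary$mean_r2_adj > 0 & ne > 0
  data.frame(gen_ago = t, ne = ne,
             mean_dist = summary$mean_dist,
             mean_r2_adj = summary$mean_r2_adj,
             sd_r2_adj = summary$sd_r2_adj,
             n_pairs = summary$n_pairs,
             valid = valid)
}

#' Run the binning + Ne estimation stage
#'
#' Composes \code{\link{summarizeBins}} and \code{\link{estimateNe}} on a
#' stream of pairwise LD records.  The result contains only valid estimates,
#' sorted by generations ago (most recent first); invalid bins (non-positive
#' mean adjusted r2 or Ne) are retained in \code{attr(, "excluded")} for
#' diagnostics.
#'
#' @param pairs data.frame of pairwise LD records (\code{\link{ldPairs}},
#'   \code{\link{readLDTable}} or \code{\link{generateLDProfile}}).
#' @param scheme a \linkS4class{BinScheme}.
#' @param mapFunction,k,alpha see \code{\link{estimateNe}}.
#' @param beta see \code{\link{adjustR2}}.
#' @param roundGenerations round \code{gen_ago} to the nearest integer
#'   (for comparisons at a named generation).
#' @return data.frame of valid estimates, columns as in
#'   \code{\link{estimateNe}} minus \code{valid}.
#' @examples
#' sch <- makeBins(5e4, 4e6, 20, 1.5)
#' prof <- generateLDProfile(Ne = 100, alpha = 1, beta = 1, n = 50, sch)
#' traj <- runTrajectory(prof, sch)
#' all(abs(traj$ne - 100) < 1e-6)
#' @export
runTrajectory <- function(pairs, scheme, mapFunction = "linear", k = 1e-8,
                          alpha = 1, beta = 1, roundGenerations = FALSE) {
  summ <- summarizeBins(pairs, scheme, beta = beta)
  est <- estimateNe(summ, mapFunction = mapFunction, k = k, alpha = alpha)
  if (!any(est$valid)) stop("no valid Ne estimates")
  excl <- est[!est$valid, setdiff(names(est), "valid"), drop = FALSE]
  est <- est[est$valid, setdiff(names(est), "valid"), drop = FALSE]
  est <- est[order(est$gen_ago), , drop = FALSE]
  rownames(est) <- NULL
  if (roundGenerations) est$gen_ago <- round(est$gen_ago)
  attr(est, "excluded") <- excl
  est
}

#' Full Ne-trajectory pipeline from genotypes
#'
#' Convenience wrapper: MAF filter, pairwise LD, distance binning and Sved
#' inversion in one call.
#'
#' @param x a \linkS4class{SnpGenotypes} object.
#' @param maf MAF threshold (default 0.05; see \code{\link{mafFilter}}).
#' @param minDist,maxDist pair distance window in bp (defaults 5e4, 4e6).
#' @param totBins,binExp binning parameters (defaults 30 bins, exponent 1.5;
#'   see \code{\link{makeBins}}).
#' @param alpha mutation correction (default 1).
#' @param beta phase correction; default 2 for phased input, 1 for unphased.
#' @param mapFunction,k distance mapping (defaults linear, 1e-8 M/bp).
#' @param chromosomes optional chromosome subset.
#' @param threads worker processes for the LD stage.
#' @param roundGenerations see \code{\link{runTrajectory}}.
#' @return as \code{\link{runTrajectory}}.
#' @export
neTrajectory <- function(x, maf = 0.05, minDist = 5e4, maxDist = 4e6,
                         totBins = 30L, binExp = 1.5, alpha = 1,
                         beta = NULL, mapFunction = "linear", k = 1e-8,
                         chromosomes = NULL, threads = 1L,
                         roundGenerations = FALSE) {
  stopifnot(is(x, "SnpGenotypes"))
  if (is.null(beta)) beta <- if (isPhased(x)) 2 else 1
  xf <- mafFilter(x, maf)
  pairs <- ldPairs(xf, minDist = minDist, maxDist = maxDist,
                   chromosomes = chromosomes, threads = threads)
  scheme <- makeBins(minDist, maxDist, totBins, binExp)
  runTrajectory(pairs, scheme, mapFunction = mapFunction, k = k,
                alpha = alpha, beta = beta,
                roundGenerations = roundGenerations)
}
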