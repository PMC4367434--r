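## Power-law distance binning and the sample-size correction.

#' Build a power-law distance-bin scheme
#'
#' Bin i covers [lo_i, hi_i) with
#' lo_i = minD + (maxD - minD) * ((i-1)/totBins)^x and
#' hi_i = minD + (maxD - minD) * (i/totBins)^x; the last bin is closed at
#' maxD.  x = 1 gives equal-width bins; x > 1 gives wider bins at larger
#' distances, which evens out the number of SNP pairs per bin on typical
#' SNP-chip marker densities.
#'
#' @param minD,maxD distance range in bp, minD < maxD.
#' @param totBins number of bins (>= 1).
#' @param x positive bin-width exponent.
#' @return a \linkS4class{BinScheme}.
#' @examples
#' binTable(makeBins(0, 100, 10, 1))  # equal widths of 10
#' binTable(makeBins(0, 100, 10, 2))  # widths 1, 3, 5, ...
#' @export
makeBins <- function(minD, maxD, totBins = 30L, x = 1.5) {
  if (!is.numeric(minD) || !is.numeric(maxD) || minD >= maxD)
    stop("need minD < maxD")
  if (!is.numeric(totBins) || totBins < 1)
    stop("totBins must be >= 1")
  if (!is.numeric(x) || x <= 0) stop("bin exponent x must be > 0")
  totBins <- as.integer(totBins)
  edges <- minD + (maxD - minD) * (seq(0L, totBins) / totBins)^x
  new("BinScheme", minD = as.numeric(minD), maxD = as.numeric(maxD),
      totBins = totBins, x = as.numeric(x), edges = edges)
}

# bin index per distance; NA outside [minD, maxD].  Half-open [lo, hi)
# except the last bin, closed at maxD.
.assignBins <- function(dist, scheme) {
  idx <- findInterval(dist, scheme@edges, rightmost.closed = TRUE)
  idx[idx < 1L | idx > scheme@totBins] <- NA_integer_
  idx[dist < scheme@minD | dist > scheme@maxD] <- NA_integer_
  idx
}

#' Sample-size/phase correction of r2
#'
#' Subtracts the sampling inflation 1/(beta * n) from an observed r2, where
#' n is the number of individuals behind the estimate and beta = 2 when the
#' gametic phase is known, beta = 1 when it is not.  The result may be
#' negative; downstream, bins whose mean adjusted r2 is non-positive are
#' flagged invalid.
#'
#' @param r2 observed r2 value(s).
#' @param n_obs individuals with complete data behind each value (>= 1).
#' @param beta 2 (phased) or 1 (unphased).
#' @return adjusted r2 value(s).
#' @examples
#' adjustR2(0.25, 50, 1)  # 0.23
#' adjustR2(0.25, 25, 2)  # 0.23
#' @export
adjustR2 <- function(r2, n_obs, beta = 1) {
  if (any(n_obs < 1)) stop("n_obs must be >= 1")
  if (!all(beta %in% c(1, 2)))
    warning("beta is conventionally 1 (unphased) or 2 (phased)")
  if (any(beta <= 0)) stop("beta must be > 0")
  r2 - 1 / (beta * n_obs)
}

#' Aggregate adjusted r2 by distance bin
#'
#' Each pair's r2 is first adjusted for sample size with its own n_obs
#' (\code{\link{adjustR2}}), then the pair is assigned to the unique bin
#' containing its distance.  Per bin, the mean distance and the mean and
#' standard deviation (n-1 denominator; 0 for a single pair) of adjusted r2
#' are computed.  Empty bins are omitted with a warning.
#'
#' @param pairs data.frame with columns \code{dist}, \code{r2},
#'   \code{n_obs} (as from \code{\link{ldPairs}} or
#'   \code{\link{readLDTable}}).
#' @param scheme a \linkS4class{BinScheme}.
#' @param beta phase correction, see \code{\link{adjustR2}}.
#' @return data.frame with columns \code{bin}, \code{n_pairs},
#'   \code{mean_dist}, \code{mean_r2_adj}, \code{sd_r2_adj}.
#' @export
summarizeBins <- function(pairs, scheme, beta = 1) {
  stopifnot(is.data.frame(pairs), is(scheme, "BinScheme"))
  r2adj <- adjustR2(pairs$r2, pairs$n_obs, beta)
  bin <- .assignBins(pairs$dist, scheme)
  keep <- !is.na(bin)
  if (!any(keep)) stop("no pairs in range [", scheme@minD, ", ", scheme@maxD, "]")
  bin <- bin[keep]; r2adj <- r2adj[keep]; dist <- pairs$dist[keep]
  f <- factor(bin, levels = seq_len(scheme@totBins))
  np <- as.integer(table(f))
  out <- data.frame(
    bin = seq_len(scheme@totBins),
    n_pairs = np,
    mean_dist = as.numeric(tapply(dist, f, mean)),
    mean_r2_adj = as.numeric(tapply(r2adj, f, mean)),
    sd_r2_adj = as.numeric(tapply(r2adj, f, stats::sd)))
  out$sd_r2_adj[out$n_pairs == 1L] <- 0
  empty <- out$n_pairs == 0L
  if (any(empty))
    warning(sum(empty), " empty bin(s) omitted: ",
            paste(utils::head(which(empty), 10), collapse = ", "))
  out[!empty, , drop = FALSE]
}
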