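## Pairwise LD: allele frequencies, MAF filtering, r2, pair enumeration.

#' Minor allele frequency
#'
#' For unphased data the per-marker allele frequency is
#' p = sum(dosages) / (2 * n_nonmissing); for phased data it is the mean of
#' the allele indicator over non-missing haplotypes.  The MAF is
#' min(p, 1 - p).
#'
#' @param x a \linkS4class{SnpGenotypes} object, or a numeric vector of
#'   dosages (0/1/2, NA missing) for a single marker.
#' @return numeric vector of MAFs in [0, 0.5], named by marker id for
#'   \code{SnpGenotypes} input.
#' @examples
#' minorAlleleFreq(c(0, 1, 2, 2))   # p = 5/8, MAF = 0.375
#' @export
setGeneric("minorAlleleFreq", function(x) standardGeneric("minorAlleleFreq"))

#' @rdname minorAlleleFreq
#' @export
setMethod("minorAlleleFreq", "numeric", function(x) {
  n <- sum(!is.na(x))
  if (n == 0L) stop("all calls missing: MAF undefined")
  p <- sum(x, na.rm = TRUE) / (2 * n)
  min(p, 1 - p)
})

#' @rdname minorAlleleFreq
#' @export
setMethod("minorAlleleFreq", "SnpGenotypes", function(x) {
  calls <- genotypeCalls(x)
  n <- rowSums(!is.na(calls))
  if (any(n == 0L))
    stop("all calls missing at marker(s): ",
         paste(utils::head(rownames(calls)[n == 0L], 5), collapse = ", "))
  denom <- if (isPhased(x)) n else 2 * n
  p <- rowSums(calls, na.rm = TRUE) / denom
  maf <- pmin(p, 1 - p)
  names(maf) <- rownames(calls)
  maf
})

#' Filter markers by minor allele frequency
#'
#' Retains markers with MAF >= \code{threshold} (markers exactly at the
#' threshold are kept).  Monomorphic markers (MAF = 0) are always removed
#' because r2 is undefined for them.  A per-chromosome removal report is
#' emitted as a message.
#'
#' @param x a \linkS4class{SnpGenotypes} object.
#' @param threshold MAF threshold in [0, 0.5); default 0.05.
#' @return the filtered \linkS4class{SnpGenotypes} object.
#' @export
mafFilter <- function(x, threshold = 0.05) {
  stopifnot(is(x, "SnpGenotypes"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold >= 0.5)
    stop("MAF threshold must be in [0, 0.5)")
  maf <- minorAlleleFreq(x)
  keep <- maf >= threshold & maf > 0
  if (!any(keep)) stop("no markers survive MAF filter (threshold ", threshold, ")")
  mm <- markerMap(x)
  rem <- table(mm$chrom[!keep])
  if (length(rem))
    message("MAF filter removed ", sum(!keep), " marker(s): ",
            paste(sprintf("%s:%d", names(rem), as.integer(rem)), collapse = ", "))
  x[keep, ]
}

## scalar r2 kernels ---------------------------------------------------------

#' Genotype-count r2 between two markers
#'
#' Squared Pearson product-moment correlation of the allele-dosage vectors of
#' two markers over individuals with complete data at both (pairwise-complete
#' deletion).  This is the unphased LD estimator (identical to PLINK's
#' \code{--r2}): it correlates genotypic allele counts and is not influenced
#' by double heterozygotes.
#'
#' @param x,y numeric dosage vectors (0/1/2, NA missing) of equal length.
#' @return list with \code{r2} (in [0,1], or NA when skipped), \code{n_obs}
#'   (complete pairs) and \code{reason} (NA, or why the pair was skipped:
#'   fewer than 3 complete observations, or a locus monomorphic among them).
#' @examples
#' r2Genotype(c(0, 1, 2, 2), c(0, 1, 1, 2))$r2   # 8/11
#' @export
r2Genotype <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3L)
    return(list(r2 = NA_real_, n_obs = n, reason = "insufficient observations"))
  xs <- x[ok]; ys <- y[ok]
  sx <- sum(xs); sy <- sum(ys)
  vx <- n * sum(xs * xs) - sx * sx
  vy <- n * sum(ys * ys) - sy * sy
  if (vx <= 0 || vy <= 0)
    return(list(r2 = NA_real_, n_obs = n,
                reason = "monomorphic in complete observations"))
  cv <- n * sum(xs * ys) - sx * sy
  r2 <- (cv * cv) / (vx * vy)
  list(r2 = min(max(r2, 0), 1), n_obs = n, reason = NA_character_)
}

#' Haplotype-frequency r2 between two markers
#'
#' The phased LD estimator: with allele frequencies p_A, p_B and haplotype
#' frequency p_AB computed over haplotypes non-missing at both markers,
#' r2 = (p_AB - p_A p_B)^2 / (p_A (1-p_A) p_B (1-p_B)).
#'
#' @param a,b binary haplotype vectors (0/1, NA missing) of equal length
#'   (two entries per individual).
#' @return list as in \code{\link{r2Genotype}}; \code{n_obs} is the complete
#'   haplotype count divided by 2 (individuals).
#' @export
r2Haplotype <- function(a, b) {
  stopifnot(length(a) == length(b))
  ok <- !is.na(a) & !is.na(b)
  nh <- sum(ok)
  if (nh < 6L)
    return(list(r2 = NA_real_, n_obs = nh / 2,
                reason = "insufficient observations"))
  as <- a[ok]; bs <- b[ok]
  pA <- mean(as); pB <- mean(bs)
  den <- pA * (1 - pA) * pB * (1 - pB)
  if (den <= 0)
    return(list(r2 = NA_real_, n_obs = nh / 2,
                reason = "monomorphic in complete observations"))
  pAB <- mean(as * bs)
  D <- pAB - pA * pB
  list(r2 = min(max(D * D / den, 0), 1), n_obs = nh / 2,
       reason = NA_character_)
}

## block-wise pair enumeration ----------------------------------------------

# crossprod kernel for one leading-marker block of an unphased chromosome
# matrix C (samples x markers).  ii: leading columns; jj: partner columns.
# Returns r2 and n matrices (|ii| x |jj|) with NA where skipped.
.blockGenotype <- function(M, X0, X2, ii, jj) {
  n  <- crossprod(M[, ii, drop = FALSE],  M[, jj, drop = FALSE])
  Sx <- crossprod(X0[, ii, drop = FALSE], M[, jj, drop = FALSE])
  Sy <- crossprod(M[, ii, drop = FALSE],  X0[, jj, drop = FALSE])
  Sxx <- crossprod(X2[, ii, drop = FALSE], M[, jj, drop = FALSE])
  Syy <- crossprod(M[, ii, drop = FALSE],  X2[, jj, drop = FALSE])
  Sxy <- crossprod(X0[, ii, drop = FALSE], X0[, jj, drop = FALSE])
  vx <- n * Sxx - Sx * Sx
  vy <- n * Syy - Sy * Sy
  cv <- n * Sxy - Sx * Sy
  r2 <- (cv * cv) / (vx * vy)
  r2[n < 3 | vx <= 0 | vy <= 0] <- NA_real_
  list(r2 = pmin(pmax(r2, 0), 1), n = n,
       lown = n < 3, mono = n >= 3 & (vx <= 0 | vy <= 0))
}

# same for phased data; H is haplotypes x markers.  n_obs = complete
# haplotypes / 2.
.blockHaplotype <- function(M, H0, ii, jj) {
  n   <- crossprod(M[, ii, drop = FALSE],  M[, jj, drop = FALSE])
  nA  <- crossprod(H0[, ii, drop = FALSE], M[, jj, drop = FALSE])
  nB  <- crossprod(M[, ii, drop = FALSE],  H0[, jj, drop = FALSE])
  nAB <- crossprod(H0[, ii, drop = FALSE], H0[, jj, drop = FALSE])
  pA <- nA / n; pB <- nB / n
  den <- pA * (1 - pA) * pB * (1 - pB)
  D <- nAB / n - pA * pB
  r2 <- (D * D) / den
  bad <- n < 6 | den <= 0
  r2[bad] <- NA_real_
  list(r2 = pmin(pmax(r2, 0), 1), n = n / 2,
       lown = n < 6, mono = n >= 6 & den <= 0)
}

#' Enumerate within-chromosome SNP pairs and compute their LD
#'
#' Streams every pair of markers on the same chromosome whose physical
#' distance delta = pos_b - pos_a satisfies
#' \code{minDist <= delta <= maxDist} (and delta > 0), computing r2 with the
#' genotype-count estimator (unphased data) or the haplotype-frequency
#' estimator (phased data).  Pairs are never formed across chromosomes:
#' Sved's relation needs a physical distance on one chromosome.
#'
#' Missing data are handled by pairwise-complete deletion; each pair carries
#' its own observation count \code{n_obs}, used downstream by the
#' sample-size correction.  Pairs with fewer than 3 complete observations or
#' a locus monomorphic among them are skipped; skip counts are attached as
#' \code{attr(, "skipped")} and reported in a message.
#'
#' The work is partitioned by leading-marker blocks and may be spread over
#' \code{threads} worker processes; the output order (chromosome appearance
#' order, then pos_a, then pos_b) and content are identical for any thread
#' count.
#'
#' @param x a \linkS4class{SnpGenotypes} object, already MAF-filtered.
#' @param minDist,maxDist admitted distance range in bp (defaults 5e4, 4e6).
#' @param chromosomes optional character vector restricting the analysis.
#' @param estimator \code{"auto"} (from the phase of \code{x}),
#'   \code{"genotype"} or \code{"haplotype"}.
#' @param threads number of worker processes (>= 1).
#' @param blockSize leading markers per work unit.
#' @return data.frame with columns \code{chrom}, \code{pos_a}, \code{pos_b},
#'   \code{dist}, \code{r2}, \code{n_obs}.
#' @seealso \code{\link{r2Genotype}}, \code{\link{r2Haplotype}},
#'   \code{\link{runTrajectory}}
#' @export
ldPairs <- function(x, minDist = 5e4, maxDist = 4e6, chromosomes = NULL,
                    estimator = c("auto", "genotype", "haplotype"),
                    threads = 1L, blockSize = 256L) {
  stopifnot(is(x, "SnpGenotypes"))
  estimator <- match.arg(estimator)
  if (!is.numeric(minDist) || !is.numeric(maxDist) || minDist >= maxDist)
    stop("need minDist < maxDist")
  if (threads < 1L) stop("threads must be >= 1")
  phased <- isPhased(x)
  if (estimator == "haplotype" && !phased)
    stop("haplotype estimator requires phased data")
  if (estimator == "genotype" && phased)
    stop("genotype estimator requires unphased data")
  mm <- markerMap(x)
  calls <- genotypeCalls(x)
  chroms <- unique(mm$chrom)
  if (!is.null(chromosomes)) {
    chroms <- chroms[chroms %in% as.character(chromosomes)]
    if (!length(chroms)) stop("no markers on the requested chromosomes")
  }
  skipped <- c(insufficient_obs = 0L, monomorphic = 0L)
  chunks <- list()
  for (cc in chroms) {
    rows <- which(mm$chrom == cc)
    if (length(rows) < 2L) next
    pos <- mm$pos[rows]
    C <- t(calls[rows, , drop = FALSE])       # samples/haplotypes x markers
    M <- (!is.na(C)) * 1
    X0 <- C; X0[is.na(X0)] <- 0
    X2 <- if (!phased) X0 * X0 else NULL
    m <- length(pos)
    # partner index window per leading marker (positions sorted, delta > 0)
    lo <- findInterval(pos + max(minDist, 1) - 0.5, pos) + 1L
    hi <- findInterval(pos + maxDist + 0.5, pos)
    lead <- which(lo <= hi & lo <= m)
    if (!length(lead)) next
    blocks <- split(lead, ceiling(seq_along(lead) / blockSize))
    worker <- function(ii) {
      jmin <- min(lo[ii]); jmax <- max(pmin(hi[ii], m))
      jj <- jmin:jmax
      blk <- if (phased) .blockHaplotype(M, X0, ii, jj)
             else .blockGenotype(M, X0, X2, ii, jj)
      out <- vector("list", length(ii))
      for (u in seq_along(ii)) {
        i <- ii[u]
        js <- lo[i]:min(hi[i], m)
        col <- js - jmin + 1L
        r2 <- blk$r2[u, col]
        keep <- !is.na(r2)
        out[[u]] <- list(
          pos_a = rep(pos[i], sum(keep)), pos_b = pos[js][keep],
          r2 = r2[keep], n_obs = blk$n[u, col][keep],
          lown = sum(blk$lown[u, col]), mono = sum(blk$mono[u, col]))
      }
      out
    }
    res <- if (threads > 1L)
      parallel::mclapply(blocks, worker, mc.cores = threads,
                         mc.preschedule = TRUE)
    else lapply(blocks, worker)
    res <- unlist(res, recursive = FALSE, use.names = FALSE)
    skipped["insufficient_obs"] <- skipped[["insufficient_obs"]] +
      sum(vapply(res, `[[`, 0, "lown"))
    skipped["monomorphic"] <- skipped[["monomorphic"]] +
      sum(vapply(res, `[[`, 0, "mono"))
    np <- sum(lengths(lapply(res, `[[`, "r2")))
    if (np > 0L)
      chunks[[cc]] <- data.frame(
        chrom = rep(cc, np),
        pos_a = unlist(lapply(res, `[[`, "pos_a"), use.names = FALSE),
        pos_b = unlist(lapply(res, `[[`, "pos_b"), use.names = FALSE),
        r2 = unlist(lapply(res, `[[`, "r2"), use.names = FALSE),
        n_obs = unlist(lapply(res, `[[`, "n_obs"), use.names = FALSE),
        stringsAsFactors = FALSE)
  }
  if (!length(chunks)) {
    pairs <- data.frame(chrom = character(), pos_a = numeric(),
                        pos_b = numeric(), dist = numeric(), r2 = numeric(),
                        n_obs = numeric(), stringsAsFactors = FALSE)
  } else {
    pairs <- do.call(rbind, unname(chunks))
    pairs <- pairs[order(match(pairs$chrom, chroms), pairs$pos_a, pairs$pos_b), ]
    rownames(pairs) <- NULL
  }
  pairs$dist <- pairs$pos_b - pairs$pos_a
  pairs <- pairs[, c("chrom", "pos_a", "pos_b", "dist", "r2", "n_obs")]
  if (sum(skipped) > 0L)
    message(sum(skipped), " pair(s) skipped (",
            skipped[["insufficient_obs"]], " insufficient observations, ",
            skipped[["monomorphic"]], " monomorphic)")
  attr(pairs, "skipped") <- skipped
  pairs
}
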