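#' @import methods
#' @importFrom stats sd rpois runif
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<-
#'   assayNames rowRanges colData
NULL

#' SnpGenotypes: SNP calls with a physical marker map
#'
#' An S4 container for diploid SNP data together with the physical map of the
#' markers, extending \linkS4class{RangedSummarizedExperiment}.  Rows are
#' markers (with a \code{GRanges} of single-base positions), columns are
#' either individuals (unphased data; minor-allele dosage 0/1/2) or haplotypes
#' (phased data; minor-allele indicator 0/1, two consecutive columns per
#' individual).  Missing calls are \code{NA}.
#'
#' Markers are kept sorted by physical position within each chromosome;
#' chromosome labels are opaque strings compared verbatim, ordered by first
#' appearance in the input.  The original input order of the markers is
#' retained in \code{mcols(rowRanges(x))$origIndex}.
#'
#' @slot phased logical scalar; \code{TRUE} when columns are haplotypes.
#'
#' @seealso \code{\link{readPlink}}, \code{\link{simulateWrightFisher}},
#'   \code{\link{ldPairs}}
#' @aliases SnpGenotypes-class
#' @exportClass SnpGenotypes
setClass("SnpGenotypes",
  contains = "RangedSummarizedExperiment",
  representation(phased = "logical")
)

setValidity("SnpGenotypes", function(object) {
  msg <- character()
  if (length(object@phased) != 1L || is.na(object@phased))
    msg <- c(msg, "'phased' must be TRUE or FALSE")
  if (!"calls" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'calls' is missing")
  else {
    a <- SummarizedExperiment::assay(object, "calls")
    vals <- a[!is.na(a)]
    allowed <- if (isTRUE(object@phased)) c(0, 1) else c(0, 1, 2)
    if (length(vals) && !all(vals %in% allowed))
      msg <- c(msg, sprintf("call values must be in {%s} or NA",
                            paste(allowed, collapse = ",")))
    if (isTRUE(object@phased) && ncol(a) %% 2L != 0L)
      msg <- c(msg, "phased data need an even number of haplotype columns")
  }
  rn <- rownames(object)
  if (is.null(rn) || anyDuplicated(rn))
    msg <- c(msg, "marker ids must be present and unique")
  rr <- SummarizedExperiment::rowRanges(object)
  if (length(rr) > 1L) {
    chr <- as.character(GenomicRanges::seqnames(rr))
    pos <- GenomicRanges::start(rr)
    for (cc in unique(chr)) {
      p <- pos[chr == cc]
      if (is.unsorted(p))
        msg <- c(msg, sprintf("markers on chromosome '%s' not sorted by position", cc))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SnpGenotypes object
#'
#' @param calls numeric/integer matrix, markers x columns.  Unphased: one
#'   column per individual with minor-allele dosages in \{0,1,2,NA\}.  Phased:
#'   two columns per individual (haplotypes) with values in \{0,1,NA\}.
#' @param map data.frame with columns \code{chrom} (character), \code{id}
#'   (unique marker ids), \code{pos} (1-based bp, integer-valued) and
#'   optionally \code{cM} (genetic position, carried along but never used in
#'   computation); one row per marker, in the same order as \code{rows} of
#'   \code{calls}.
#' @param phased logical scalar.
#' @param sampleIds character vector of individual ids (one per individual,
#'   not per haplotype); defaults to \code{S1..Sn}.
#'
#' @details Markers are stably sorted by position within each chromosome;
#'   chromosomes keep their order of first appearance.  Duplicate positions
#'   on a chromosome are permitted but reported with a message.
#'
#' @return A \linkS4class{SnpGenotypes} object.
#' @examples
#' map <- data.frame(chrom = "1", id = c("a", "b"), pos = c(100L, 200L))
#' g <- SnpGenotypes(matrix(c(0, 1, 2, 1, 0, 2), nrow = 2), map)
#' nMarkers(g)
#' @export
SnpGenotypes <- function(calls, map, phased = FALSE, sampleIds = NULL) {
  calls <- as.matrix(calls)
  stopifnot(is.data.frame(map), nrow(map) == nrow(calls),
            all(c("chrom", "id", "pos") %in% names(map)))
  if (anyDuplicated(map$id))
    stop("duplicate marker ids: ", paste(unique(map$id[duplicated(map$id)]),
                                         collapse = ", "))
  chrom <- as.character(map$chrom)
  pos <- as.integer(round(map$pos))
  if (any(pos < 0L)) stop("marker positions must be >= 0")
  cm <- if ("cM" %in% names(map)) as.numeric(map$cM) else rep(NA_real_, nrow(map))
  # stable sort: chromosome first-appearance order, then bp
  ord <- order(match(chrom, unique(chrom)), pos)
  dup <- tapply(pos, chrom, function(p) sum(duplicated(p)))
  if (any(dup > 0))
    message("note: ", sum(dup), " duplicate marker position(s) within a chromosome")
  calls <- calls[ord, , drop = FALSE]
  rr <- GenomicRanges::GRanges(
    seqnames = factor(chrom[ord], levels = unique(chrom)),
    ranges = IRanges::IRanges(start = pos[ord], width = 1L)
  )
  names(rr) <- map$id[ord]
  S4Vectors::mcols(rr)$cM <- cm[ord]
  S4Vectors::mcols(rr)$origIndex <- ord
  nInd <- if (phased) ncol(calls) %/% 2L else ncol(calls)
  if (is.null(sampleIds)) sampleIds <- paste0("S", seq_len(nInd))
  if (length(sampleIds) != nInd)
    stop("sampleIds must have one entry per individual")
  if (phased) {
    cn <- paste0(rep(sampleIds, each = 2L), c("_1", "_2"))
    cd <- S4Vectors::DataFrame(individual = rep(sampleIds, each = 2L),
                               row.names = cn)
  } else {
    cd <- S4Vectors::DataFrame(individual = sampleIds, row.names = sampleIds)
  }
  colnames(calls) <- rownames(cd)
  rownames(calls) <- names(rr)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(calls = calls), rowRanges = rr, colData = cd)
  new("SnpGenotypes", se, phased = phased)
}

#' @describeIn SnpGenotypes-accessors number of markers
#' @export
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))

#' @describeIn SnpGenotypes-accessors number of individuals
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))

#' @describeIn SnpGenotypes-accessors TRUE for phased (haplotype) data
#' @export
setGeneric("isPhased", function(x) standardGeneric("isPhased"))

#' @describeIn SnpGenotypes-accessors the call matrix (markers x columns)
#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))

#' @describeIn SnpGenotypes-accessors the marker map as a data.frame
#' @export
setGeneric("markerMap", function(x) standardGeneric("markerMap"))

#' @describeIn SnpGenotypes-accessors individual ids
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' Accessors for SnpGenotypes
#'
#' @param x a \linkS4class{SnpGenotypes} object.
#' @name SnpGenotypes-accessors
#' @aliases nMarkers nIndividuals isPhased genotypeCalls markerMap sampleIds
NULL

#' @rdname SnpGenotypes-accessors
#' @export
setMethod("nMarkers", "SnpGenotypes", function(x) nrow(x))

#' @rdname SnpGenotypes-accessors
#' @export
setMethod("nIndividuals", "SnpGenotypes",
          function(x) if (x@phased) ncol(x) %/% 2L else ncol(x))

#' @rdname SnpGenotypes-accessors
#' @export
setMethod("isPhased", "SnpGenotypes", function(x) x@phased)

#' @rdname SnpGenotypes-accessors
#' @export
setMethod("genotypeCalls", "SnpGenotypes",
          function(x) SummarizedExperiment::assay(x, "calls"))

#' @rdname SnpGenotypes-accessors
#' @export
setMethod("markerMap", "SnpGenotypes", function(x) {
  rr <- SummarizedExperiment::rowRanges(x)
  data.frame(chrom = as.character(GenomicRanges::seqnames(rr)),
             id = names(rr),
             cM = S4Vectors::mcols(rr)$cM,
             pos = GenomicRanges::start(rr),
             origIndex = S4Vectors::mcols(rr)$origIndex,
             stringsAsFactors = FALSE)
})

#' @rdname SnpGenotypes-accessors
#' @export
setMethod("sampleIds", "SnpGenotypes",
          function(x) unique(SummarizedExperiment::colData(x)$individual))

setMethod("show", "SnpGenotypes", function(object) {
  cat(sprintf("SnpGenotypes: %d markers x %d individuals (%s)\n",
              nMarkers(object), nIndividuals(object),
              if (object@phased) "phased haplotypes" else "unphased dosages"))
  chr <- as.character(GenomicRanges::seqnames(SummarizedExperiment::rowRanges(object)))
  cat(sprintf("chromosomes (%d): %s\n", length(unique(chr)),
              paste(utils::head(unique(chr), 8), collapse = ", ")))
  nmiss <- sum(is.na(SummarizedExperiment::assay(object, "calls")))
  cat(sprintf("missing calls: %d\n", nmiss))
})

#' BinScheme: power-law distance bins
#'
#' Distance bins partition the inter-marker distance range [minD, maxD] into
#' \code{totBins} contiguous intervals whose edges follow a power law with
#' exponent \code{x}: edge_i = minD + (maxD - minD) * (i/totBins)^x for
#' i = 0..totBins.  With x = 1 all bins have equal width; with x > 1 widths
#' increase with distance so that distant (recent-generation) bins capture
#' comparable numbers of SNP pairs.  Bins are half-open [lo, hi) except the
#' last, which is closed at maxD.
#'
#' @slot minD,maxD numeric; distance range in bp.
#' @slot totBins integer; number of bins.
#' @slot x numeric; positive bin-width exponent.
#' @slot edges numeric vector of length totBins + 1.
#'
#' @seealso \code{\link{makeBins}}, \code{\link{summarizeBins}}
#' @aliases BinScheme-class
#' @exportClass BinScheme
setClass("BinScheme",
  representation(minD = "numeric", maxD = "numeric", totBins = "integer",
                 x = "numeric", edges = "numeric"))

setValidity("BinScheme", function(object) {
  msg <- character()
  if (object@minD >= object@maxD) msg <- c(msg, "minD must be < maxD")
  if (object@totBins < 1L) msg <- c(msg, "totBins must be >= 1")
  if (object@x <= 0) msg <- c(msg, "x must be > 0")
  if (length(object@edges) != object@totBins + 1L)
    msg <- c(msg, "edges must have totBins + 1 entries")
  if (is.unsorted(object@edges, strictly = TRUE))
    msg <- c(msg, "edges must be strictly increasing")
  if (length(msg)) msg else TRUE
})

setMethod("show", "BinScheme", function(object) {
  cat(sprintf("BinScheme: %d bins on [%g, %g] bp, exponent x = %g\n",
              object@totBins, object@minD, object@maxD, object@x))
  bt <- binTable(object)
  print(utils::head(bt, 4))
  if (nrow(bt) > 4) cat("...\n")
})

#' @describeIn makeBins number of bins in a scheme
#' @export
setGeneric("nBins", function(scheme) standardGeneric("nBins"))

#' @rdname makeBins
#' @export
setMethod("nBins", "BinScheme", function(scheme) scheme@totBins)

#' @describeIn makeBins bin intervals as a data.frame with columns
#'   \code{bin}, \code{lo}, \code{hi}, \code{mid}
#' @export
setGeneric("binTable", function(scheme) standardGeneric("binTable"))

#' @rdname makeBins
#' @export
setMethod("binTable", "BinScheme", function(scheme) {
  e <- scheme@edges
  n <- scheme@totBins
  data.frame(bin = seq_len(n), lo = e[-(n + 1L)], hi = e[-1L],
             mid = (e[-(n + 1L)] + e[-1L]) / 2)
})
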