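## PLINK text (.ped/.map) and LD-table I/O.

.ALLELE_CODES <- c("A", "C", "G", "T", "1", "2")

#' Read PLINK text genotype files
#'
#' Parses the standard PLINK text pair of files: a \code{.map} marker table
#' (3-column \code{chrom id bp} or 4-column \code{chrom id cM bp} dialect,
#' auto-detected) and a \code{.ped} file with six leading columns
#' (FID IID PAT MAT SEX PHENO) followed by two allele fields per marker.
#' Allele codes must come from \{A,C,G,T,1,2\}; \code{0} denotes a missing
#' allele, and a genotype with either allele missing is treated as a missing
#' call.
#'
#' Calls are recoded against the per-locus minor allele (the less frequent
#' allele over non-missing calls; frequency ties are broken by lexicographic
#' allele order, and at a monomorphic locus the unobserved allele is taken as
#' minor so all dosages are 0).  r2 is invariant to this choice; it only
#' fixes the reporting convention.
#'
#' @param ped_path,map_path paths to the .ped and .map files.
#' @param phased if \code{TRUE} the two allele fields of each marker are
#'   taken as haplotype-ordered and a phased object is returned.
#' @return A \linkS4class{SnpGenotypes} object (markers sorted by bp within
#'   chromosome).  A load report (individuals, markers, missing calls) is
#'   emitted as a message.
#' @examples
#' d <- simulateWrightFisher(popSize = 20, sampleN = 10, nMarkers = 12,
#'                           chromLengthBp = 1e6, recombRatePerBp = 1e-8,
#'                           generations = 5, seed = 1)
#' ped <- tempfile(fileext = ".ped"); map <- tempfile(fileext = ".map")
#' writePlink(d, ped, map)
#' g <- readPlink(ped, map)
#' @export
readPlink <- function(ped_path, map_path, phased = FALSE) {
  map <- .readMap(map_path)
  m <- nrow(map)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty ped file: ", ped_path)
  toks <- strsplit(trimws(lines), "[ \t]+")
  want <- 6L + 2L * m
  lens <- lengths(toks)
  if (any(lens != want)) {
    bad <- which(lens != want)[1L]
    if (length(unique(lens)) > 1L)
      stop(sprintf("ragged ped line %d: %d fields, expected %d",
                   bad, lens[bad], want))
    stop(sprintf("marker count mismatch: ped line has %d allele fields for %d map markers",
                 lens[1L] - 6L, m))
  }
  tab <- matrix(unlist(toks), nrow = length(toks), byrow = TRUE)
  ids <- tab[, 2L]
  al <- tab[, -(1:6), drop = FALSE]          # n x 2m allele codes
  okCodes <- c(.ALLELE_CODES, "0")
  if (!all(al %in% okCodes)) {
    badcode <- setdiff(unique(as.vector(al)), okCodes)
    stop("allele code(s) outside {A,C,G,T,1,2,0}: ",
         paste(utils::head(badcode, 5), collapse = ", "))
  }
  n <- nrow(al)
  a1 <- al[, 2L * seq_len(m) - 1L, drop = FALSE]
  a2 <- al[, 2L * seq_len(m), drop = FALSE]
  miss <- a1 == "0" | a2 == "0"
  calls <- matrix(NA_real_, nrow = m, ncol = if (phased) 2L * n else n)
  for (j in seq_len(m)) {
    mj <- miss[, j]
    obs <- c(a1[!mj, j], a2[!mj, j])
    alleles <- sort(unique(obs))
    if (length(alleles) > 2L)
      stop(sprintf("marker '%s' has >2 distinct alleles: %s",
                   map$id[j], paste(alleles, collapse = ",")))
    minor <- .minorAllele(obs, alleles)
    if (phased) {
      h1 <- as.numeric(a1[, j] == minor); h2 <- as.numeric(a2[, j] == minor)
      h1[mj] <- NA; h2[mj] <- NA
      calls[j, 2L * seq_len(n) - 1L] <- h1
      calls[j, 2L * seq_len(n)] <- h2
    } else {
      cj <- as.numeric(a1[, j] == minor) + as.numeric(a2[, j] == minor)
      cj[mj] <- NA
      calls[j, ] <- cj
    }
  }
  g <- SnpGenotypes(calls, map, phased = phased, sampleIds = ids)
  message(sprintf("loaded %d individuals x %d markers (%d missing calls) from %s",
                  n, m, sum(miss), ped_path))
  g
}

.readMap <- function(map_path) {
  raw <- readLines(map_path)
  raw <- raw[nzchar(trimws(raw))]
  if (!length(raw)) stop("empty map file: ", map_path)
  toks <- strsplit(trimws(raw), "[ \t]+")
  nc <- unique(lengths(toks))
  if (length(nc) != 1L || !nc %in% c(3L, 4L))
    stop("map file must have 3 (chrom id bp) or 4 (chrom id cM bp) columns")
  tab <- matrix(unlist(toks), ncol = nc, byrow = TRUE)
  if (nc == 4L)
    map <- data.frame(chrom = tab[, 1L], id = tab[, 2L],
                      cM = as.numeric(tab[, 3L]), pos = as.numeric(tab[, 4L]),
                      stringsAsFactors = FALSE)
  else
    map <- data.frame(chrom = tab[, 1L], id = tab[, 2L], cM = NA_real_,
                      pos = as.numeric(tab[, 3L]), stringsAsFactors = FALSE)
  if (anyNA(map$pos)) stop("non-numeric bp position in map file")
  map
}

# minor allele over observed codes; ties broken lexicographically; at a
# monomorphic locus the unobserved allele is "minor" (dosage 0 everywhere)
.minorAllele <- function(obs, alleles) {
  if (length(alleles) <= 1L) return("\x01none")   # matches no real code
  f <- c(sum(obs == alleles[1L]), sum(obs == alleles[2L]))
  if (f[1L] == f[2L]) alleles[1L] else alleles[which.min(f)]
}

#' Write a SnpGenotypes object as PLINK text files
#'
#' Emits a .ped/.map pair readable by \code{\link{readPlink}}.  Dosage 0 is
#' written as \code{G G}, 1 as \code{A G} (or haplotype-ordered for phased
#' data), 2 as \code{A A}; missing calls as \code{0 0}.  The map is written
#' in the 4-column dialect (cM written as 0 when unknown).
#'
#' @param x a \linkS4class{SnpGenotypes} object with at least one marker.
#' @param ped_path,map_path output paths.
#' @return invisibly, the ped path.
#' @export
writePlink <- function(x, ped_path, map_path) {
  stopifnot(is(x, "SnpGenotypes"))
  if (nMarkers(x) == 0L || nIndividuals(x) == 0L)
    stop("empty dataset: nothing to write")
  mm <- markerMap(x)
  cm <- ifelse(is.na(mm$cM), 0, mm$cM)
  writeLines(paste(mm$chrom, mm$id, cm, mm$pos), map_path)
  calls <- genotypeCalls(x)
  n <- nIndividuals(x)
  m <- nMarkers(x)
  ids <- sampleIds(x)
  if (isPhased(x)) {
    h1 <- calls[, 2L * seq_len(n) - 1L, drop = FALSE]
    h2 <- calls[, 2L * seq_len(n), drop = FALSE]
    f1 <- ifelse(is.na(h1), "0", ifelse(h1 == 1, "A", "G"))
    f2 <- ifelse(is.na(h2), "0", ifelse(h2 == 1, "A", "G"))
    f1[is.na(h2)] <- "0"; f2[is.na(h1)] <- "0"   # missing is per-genotype
  } else {
    f1 <- ifelse(is.na(calls), "0", ifelse(calls >= 1, "A", "G"))
    f2 <- ifelse(is.na(calls), "0", ifelse(calls == 2, "A", "G"))
  }
  # interleave the two allele fields: markers x 2m per individual
  out <- character(n)
  for (i in seq_len(n)) {
    gi <- as.vector(rbind(f1[, i], f2[, i]))
    out[i] <- paste(c("FAM", ids[i], "0", "0", "0", "-9", gi), collapse = " ")
  }
  writeLines(out, ped_path)
  invisible(ped_path)
}

#' Read a pre-computed pairwise-LD table
#'
#' Reads a delimited text file of pairwise LD records as produced by external
#' LD software, for use with \code{\link{runTrajectory}} in place of
#' \code{\link{ldPairs}}.  The file must provide, per pair, a chromosome
#' label, either the two bp positions or a bp distance, and r2; an optional
#' per-pair observation count column may be given, otherwise a global
#' \code{n} applies to every pair.
#'
#' Rows with r2 outside [0,1] or non-positive distance are dropped; the
#' number dropped is reported in a message.
#'
#' @param path input file path.
#' @param columns named list/vector mapping the roles \code{chrom},
#'   \code{pos_a}, \code{pos_b} (or \code{dist}), and \code{r2} (and
#'   optionally \code{n_obs}) to column names (if the file has a header) or
#'   1-based column indexes.  Default matches \code{\link{writeLDTable}}.
#' @param n global per-pair observation count used when no \code{n_obs}
#'   column is mapped.
#' @param sep field separator (default: any whitespace).
#' @param header whether the file has a header row (default \code{TRUE}
#'   when column names are given, \code{FALSE} for indexes).
#' @return data.frame with columns \code{chrom}, \code{pos_a}, \code{pos_b},
#'   \code{dist}, \code{r2}, \code{n_obs}.
#' @examples
#' tf <- tempfile()
#' writeLines(c("chrom\tpos_a\tpos_b\tr2", "1\t1000\t51000\t0.25"), tf)
#' readLDTable(tf, columns = c(chrom = "chrom", pos_a = "pos_a",
#'                             pos_b = "pos_b", r2 = "r2"), n = 50)
#' @export
readLDTable <- function(path,
                        columns = c(chrom = "chrom", pos_a = "pos_a",
                                    pos_b = "pos_b", r2 = "r2",
                                    n_obs = "n_obs"),
                        n = NULL, sep = "", header = NULL) {
  columns <- as.list(columns)
  need <- c("chrom", "r2")
  if (!all(need %in% names(columns)))
    stop("column spec must map at least 'chrom' and 'r2'")
  haveDist <- "dist" %in% names(columns)
  havePos <- all(c("pos_a", "pos_b") %in% names(columns))
  if (!haveDist && !havePos)
    stop("column spec must map either 'dist' or both 'pos_a' and 'pos_b'")
  byName <- is.character(columns[[1L]])
  if (is.null(header)) header <- byName
  tab <- tryCatch(
    utils::read.table(path, sep = sep, header = header,
                      stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("no LD records in ", path, ": ", conditionMessage(e)))
  if (nrow(tab) == 0L) stop("no LD records in ", path)
  getcol <- function(role) {
    key <- columns[[role]]
    if (is.character(key)) {
      if (!key %in% names(tab)) stop("missing mandatory column '", key, "'")
      tab[[key]]
    } else {
      if (key > ncol(tab)) stop("column index ", key, " out of range")
      tab[[key]]
    }
  }
  chrom <- as.character(getcol("chrom"))
  r2 <- as.numeric(getcol("r2"))
  if (havePos) {
    pa <- as.numeric(getcol("pos_a")); pb <- as.numeric(getcol("pos_b"))
    swap <- !is.na(pa) & !is.na(pb) & pa > pb
    tmp <- pa[swap]; pa[swap] <- pb[swap]; pb[swap] <- tmp
    dist <- pb - pa
  } else {
    dist <- as.numeric(getcol("dist"))
    pa <- rep(NA_real_, length(dist)); pb <- pa
  }
  nObs <- if ("n_obs" %in% names(columns) &&
              (is.numeric(columns$n_obs) || columns$n_obs %in% names(tab)))
    as.numeric(getcol("n_obs"))
  else if (!is.null(n)) rep(as.numeric(n), nrow(tab))
  else stop("no 'n_obs' column mapped and no global n supplied")
  ok <- !is.na(r2) & r2 >= 0 & r2 <= 1 & !is.na(dist) & dist > 0
  if (any(!ok))
    message(sum(!ok), " LD row(s) dropped (r2 outside [0,1] or distance <= 0)")
  if (!any(ok)) stop("no LD records in ", path)
  data.frame(chrom = chrom[ok], pos_a = pa[ok], pos_b = pb[ok],
             dist = dist[ok], r2 = r2[ok], n_obs = nObs[ok],
             stringsAsFactors = FALSE)
}

#' Write a pairwise-LD table
#'
#' Tab-delimited with header \code{chrom pos_a pos_b dist r2 n_obs};
#' readable back by \code{\link{readLDTable}} with the default column spec.
#'
#' @param pairs data.frame as returned by \code{\link{ldPairs}}.
#' @param path output path.
#' @export
writeLDTable <- function(pairs, path) {
  stopifnot(is.data.frame(pairs), nrow(pairs) >= 1L)
  out <- data.frame(chrom = pairs$chrom,
                    pos_a = pairs$pos_a, pos_b = pairs$pos_b,
                    dist = pairs$dist,
                    r2 = sprintf("%.10g", pairs$r2),
                    n_obs = pairs$n_obs)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an Ne trajectory file
#'
#' Writes the tab-delimited trajectory table: one row per distance bin with
#' the generations ago it represents (\code{GenAgo}), the Ne estimate
#' (\code{Ne}), the average pair distance in bp (\code{AvgDist}), the mean
#' and standard deviation of adjusted r2 (\code{AvgR2}, \code{SdR2}) and the
#' number of SNP pairs in the bin (\code{NPairs}).  GenAgo, Ne and AvgDist
#' are written with 1 decimal, the r2 statistics with 6 decimals.
#'
#' @param estimates data.frame as returned by \code{\link{runTrajectory}}.
#' @param path output path.
#' @export
writeTrajectory <- function(estimates, path) {
  if (!is.data.frame(estimates) || nrow(estimates) == 0L)
    stop("nothing to write: no Ne estimates")
  lines <- c("GenAgo\tNe\tAvgDist\tAvgR2\tSdR2\tNPairs",
             sprintf("%.1f\t%.1f\t%.1f\t%.6f\t%.6f\t%d",
                     estimates$gen_ago, estimates$ne, estimates$mean_dist,
                     estimates$mean_r2_adj, estimates$sd_r2_adj,
                     as.integer(estimates$n_pairs)))
  writeLines(lines, path)
  invisible(path)
}

#' Read back a trajectory file written by writeTrajectory
#'
#' @param path path to a trajectory TSV.
#' @return data.frame with the same columns as \code{\link{runTrajectory}}.
#' @export
readTrajectory <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE)
  data.frame(gen_ago = tab$GenAgo, ne = tab$Ne, mean_dist = tab$AvgDist,
             mean_r2_adj = tab$AvgR2, sd_r2_adj = tab$SdR2,
             n_pairs = tab$NPairs)
}
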