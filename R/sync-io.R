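#' @include AllClasses.R
NULL

#' Read a synchronized pooled pileup ("sync") file
#'
#' Parses the tab-separated sync format (as produced by PoPoolation2's
#' synchronization step): one line per site with chromosome, 1-based
#' position, reference base, then one colon-joined \code{A:T:C:G:N:del}
#' count string per pool. Malformed lines are reported with their line
#' number; the number of pools must be constant across lines.
#'
#' Sites are named by their chromosome field when chromosomes are unique
#' (the convention used by the simulator, which stores one locus per
#' contig), otherwise by \code{chrom_pos}.
#'
#' @param file path to (or connection of) a sync file.
#' @return A [PoolCounts-class].
#' @seealso [writeSync()]
#' @examples
#' f <- tempfile()
#' writeLines("chr1\t100\tA\t96:0:4:0:0:0", f)
#' readSync(f)
#' @export
readSync <- function(file) {
  lines <- readLines(file)
  nonEmpty <- which(nzchar(trimws(lines)))
  if (!length(nonEmpty))
    return(PoolCounts(character(), integer(), character(),
                      list(), poolNames = character()))
  parts <- strsplit(lines[nonEmpty], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 4L))
    stop(sprintf("sync parse error at line %d: expected at least 4 fields, found %d",
                 nonEmpty[which(nf < 4L)[1]], nf[nf < 4L][1]))
  nPools <- nf[1] - 3L
  if (any(nf != nf[1]))
    stop(sprintf("sync parse error at line %d: inconsistent number of pools (%d vs %d)",
                 nonEmpty[which(nf != nf[1])[1]], nf[nf != nf[1]][1] - 3L,
                 nPools))
  nSites <- length(parts)
  chrom <- vapply(parts, `[`, character(1), 1L)
  posStr <- vapply(parts, `[`, character(1), 2L)
  pos <- suppressWarnings(as.integer(posStr))
  if (anyNA(pos))
    stop(sprintf("sync parse error at line %d: non-integer position '%s'",
                 nonEmpty[which(is.na(pos))[1]], posStr[is.na(pos)][1]))
  ref <- vapply(parts, `[`, character(1), 3L)
  cnt <- lapply(setNames(.SYNC_CATEGORIES, .SYNC_CATEGORIES),
                function(nm) matrix(0L, nSites, nPools))
  for (i in seq_len(nSites)) {
    for (k in seq_len(nPools)) {
      fields <- strsplit(parts[[i]][3L + k], ":", fixed = TRUE)[[1]]
      if (length(fields) != 6L)
        stop(sprintf(
          "sync parse error at line %d: count string '%s' must have 6 colon-separated fields",
          nonEmpty[i], parts[[i]][3L + k]))
      vals <- suppressWarnings(as.integer(fields))
      if (anyNA(vals) || any(vals < 0))
        stop(sprintf(
          "sync parse error at line %d: non-integer count in '%s'",
          nonEmpty[i], parts[[i]][3L + k]))
      for (b in seq_along(.SYNC_CATEGORIES))
        cnt[[b]][i, k] <- vals[b]
    }
  }
  lociNames <- if (!anyDuplicated(chrom)) chrom else paste(chrom, pos, sep = "_")
  PoolCounts(chrom = chrom, pos = pos, ref = ref, counts = cnt,
             lociNames = lociNames)
}

#' Write a synchronized pooled pileup ("sync") file
#'
#' Serializes a [PoolCounts-class] in the dialect read by [readSync()]:
#' exactly six colon-separated counts (\code{A:T:C:G:N:del}) per pool,
#' tab-separated fields, sites in object order. Writing then re-reading a
#' file reproduces it byte for byte.
#'
#' @param x a [PoolCounts-class].
#' @param file output path or connection.
#' @return \code{file}, invisibly.
#' @export
writeSync <- function(x, file) {
  stopifnot(is(x, "PoolCounts"))
  nSites <- nrow(x)
  chrom <- as.character(seqnames(rowRanges(x)))
  pos <- start(rowRanges(x))
  ref <- mcols(rowRanges(x))$ref
  mats <- lapply(setNames(.SYNC_CATEGORIES, .SYNC_CATEGORIES),
                 function(nm) assay(x, nm))
  lines <- character(nSites)
  for (i in seq_len(nSites)) {
    poolStr <- vapply(seq_len(ncol(x)), function(k)
      paste(vapply(mats, function(m) as.character(m[i, k]), character(1)),
            collapse = ":"), character(1))
    lines[i] <- paste(c(chrom[i], pos[i], ref[i], poolStr), collapse = "\t")
  }
  writeLines(lines, file)
  invisible(file)
}
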