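#' @include AllClasses.R AllGenerics.R
NULL

#' Define the major and minor allele from combined counts
#'
#' The major allele is the base with the highest count summed over all pools;
#' the minor allele is the runner-up. Ties are broken by the fixed base order
#' A < C < G < T. Because the definition uses combined counts, a single
#' pool's major-allele frequency can be below 0.5.
#'
#' @param combinedCounts numeric vector of base counts named with (a subset
#'   of) A, C, G, T; unnamed vectors of length 4 are taken in that order.
#' @return Named character vector \code{c(major = ..., minor = ...)}.
#' @examples
#' defineMajorAllele(c(A = 300, T = 200))        # A, T
#' defineMajorAllele(c(A = 100, T = 100))        # tie -> A, T
#' @export
defineMajorAllele <- function(combinedCounts) {
  if (is.null(names(combinedCounts)) && length(combinedCounts) == 4L)
    names(combinedCounts) <- .BASES
  counts <- setNames(numeric(4), .BASES)
  counts[names(combinedCounts)] <- combinedCounts
  if (anyNA(counts) || all(counts == 0))
    stop("combined counts must contain at least one nonzero base count")
  ord <- order(-counts)  # stable: ties fall back to A < C < G < T
  c(major = .BASES[ord[1]], minor = .BASES[ord[2]])
}

#' Major-allele frequency within one pool
#'
#' The frequency of a given base among a pool's nucleotide reads:
#' \code{count(base) / (A + C + G + T)}. N and deletion counts never enter
#' the denominator.
#'
#' @param counts named numeric vector of this pool's base counts (names among
#'   A, C, G, T, N, del).
#' @param majorBase the base whose frequency is returned.
#' @return The frequency in \eqn{[0, 1]}.
#' @examples
#' poolFrequency(c(A = 96, C = 4), "A")  # 0.96
#' @export
poolFrequency <- function(counts, majorBase) {
  stopifnot(is.character(majorBase), length(majorBase) == 1L,
            majorBase %in% .BASES)
  base <- setNames(numeric(4), .BASES)
  known <- intersect(names(counts), .BASES)
  if (is.null(names(counts)))
    stop("'counts' must be named by base")
  base[known] <- counts[known]
  total <- sum(base)
  if (total < 1)
    stop("zero coverage: no nucleotide reads in this pool")
  unname(base[majorBase] / total)
}

#' Call SNPs from pooled counts
#'
#' Applies the SNP-identification filters to every site of a
#' [PoolCounts-class] object and computes per-pool major-allele frequencies
#' for the retained sites. A site is retained iff
#' \enumerate{
#'   \item every pool's coverage (four-nucleotide sum) lies within
#'     \code{[minCoverage, maxCoverage]}, and
#'   \item at least two bases have nonzero counts summed across pools and
#'     the second-most-frequent base reaches \code{minMinorCount}
#'     (combined across pools by default; within every pool when
#'     \code{minorScope = "per-pool"}).
#' }
#' Sites where more than two bases segregate are retained if the top-two rule
#' passes; the residual counts are reported in \code{extraCount} and excluded
#' from frequency denominators, with a warning.
#'
#' @param x a [PoolCounts-class].
#' @param params a [FilterParams-class] (defaults: minor count 4, coverage
#'   within \eqn{[20, 400]}).
#' @param ... unused.
#' @return A [SnpTable-class] of retained sites (possibly empty).
#' @examples
#' pc <- PoolCounts("chr1", 100, "A",
#'                  list(A = matrix(50, 1, 3), T = matrix(50, 1, 3)))
#' callSnps(pc)
#' @aliases callSnps
#' @export
setMethod("callSnps", "PoolCounts", function(x, params = FilterParams(), ...) {
  validObject(params)
  nSites <- nrow(x)
  nPools <- ncol(x)
  siteNames <- rownames(x)
  if (is.null(siteNames)) {
    chr <- as.character(seqnames(rowRanges(x)))
    siteNames <- if (!anyDuplicated(chr)) chr
                 else paste(chr, start(rowRanges(x)), sep = "_")
  }
  emptyTable <- function() new("SnpTable",
    info = DataFrame(chrom = character(), pos = integer(), ref = character(),
                     major = character(), minor = character(),
                     extraCount = integer(), row.names = character()),
    coverage = matrix(0L, 0, nPools), maf = matrix(0, 0, nPools),
    majorCounts = matrix(0L, 0, nPools),
    combinedCounts = matrix(0L, 0, 4, dimnames = list(NULL, .BASES)),
    poolBaseCounts = array(0L, c(0, nPools, 4)), params = params)
  if (nSites == 0L)
    return(emptyTable())
  # sites x pools x base array in tie-break base order
  arr <- array(0L, c(nSites, nPools, 4),
               dimnames = list(siteNames, colnames(x), .BASES))
  for (b in .BASES) arr[, , b] <- assay(x, b)
  cov4 <- apply(arr, c(1, 2), sum)
  dim(cov4) <- c(nSites, nPools)
  covOK <- rowSums(cov4 >= params@minCoverage &
                   cov4 <= params@maxCoverage) == nPools
  combined <- apply(arr, c(1, 3), sum)
  dim(combined) <- c(nSites, 4)
  colnames(combined) <- .BASES
  majorIdx <- minorIdx <- integer(nSites)
  minorOK <- logical(nSites)
  for (i in seq_len(nSites)) {
    ord <- order(-combined[i, ])
    majorIdx[i] <- ord[1]
    minorIdx[i] <- ord[2]
    if (sum(combined[i, ] > 0) < 2L) {
      minorOK[i] <- FALSE
    } else if (params@minorScope == "combined") {
      minorOK[i] <- combined[i, ord[2]] >= params@minMinorCount
    } else {
      minorOK[i] <- all(arr[i, , ord[2]] >= params@minMinorCount)
    }
  }
  keep <- which(covOK & minorOK)
  if (!length(keep))
    return(emptyTable())
  major <- .BASES[majorIdx[keep]]
  minor <- .BASES[minorIdx[keep]]
  nKeep <- length(keep)
  majorCounts <- minorCounts <- matrix(0L, nKeep, nPools,
                                       dimnames = list(siteNames[keep],
                                                       colnames(x)))
  for (r in seq_len(nKeep)) {
    majorCounts[r, ] <- arr[keep[r], , majorIdx[keep[r]]]
    minorCounts[r, ] <- arr[keep[r], , minorIdx[keep[r]]]
  }
  biCov <- majorCounts + minorCounts
  extra <- as.integer(rowSums(combined[keep, , drop = FALSE])) -
    as.integer(rowSums(biCov))
  if (any(extra > 0))
    warning(sprintf(
      "%d site(s) carry reads on a third/fourth base; those counts are excluded from frequencies (see 'extraCount')",
      sum(extra > 0)))
  info <- DataFrame(
    chrom = as.character(seqnames(rowRanges(x)))[keep],
    pos = start(rowRanges(x))[keep],
    ref = mcols(rowRanges(x))$ref[keep],
    major = major, minor = minor, extraCount = extra,
    row.names = siteNames[keep])
  maf <- majorCounts / biCov
  maf[biCov == 0L] <- 0  # a pool with only N/del/extra reads carries no signal
  new("SnpTable", info = info, coverage = biCov,
      maf = maf, majorCounts = majorCounts,
      combinedCounts = combined[keep, , drop = FALSE],
      poolBaseCounts = arr[keep, , , drop = FALSE], params = params)
})
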