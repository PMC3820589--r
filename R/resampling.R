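#' @include AllClasses.R
NULL

# Multivariate hypergeometric draws: sample `k` reads without replacement
# from the category counts, `nDraws` times. Categories are drawn
# sequentially, each marginal being univariate hypergeometric.
.rmvhyper <- function(counts, k, nDraws) {
  counts <- as.integer(round(counts))
  total <- sum(counts)
  k <- as.integer(k)
  if (k > total)
    stop(sprintf("cannot draw %d reads from %d available", k, total))
  nc <- length(counts)
  out <- matrix(0L, nc, nDraws)
  remK <- rep.int(k, nDraws)
  remN <- total
  for (b in seq_len(nc - 1L)) {
    remN <- remN - counts[b]
    x <- rhyper(nDraws, counts[b], remN, remK)
    out[b, ] <- x
    remK <- remK - x
  }
  out[nc, ] <- remK
  out
}

#' Downsample a pool's reads to a target coverage
#'
#' Draws \code{target} reads without replacement from the observed base
#' counts (a multivariate hypergeometric draw), emulating what the pool would
#' have looked like at lower sequencing depth. Sampling is never done with
#' replacement: requesting more reads than were observed is an error.
#'
#' @param counts named numeric vector of base counts (names among A, C, G,
#'   T).
#' @param target number of reads to keep, \eqn{\le} the total count.
#' @param seed optional seed for a reproducible draw.
#' @return Named integer vector of downsampled counts summing to
#'   \code{target}.
#' @examples
#' downsampleCounts(c(A = 96, C = 4), 10, seed = 1)
#' @export
downsampleCounts <- function(counts, target, seed = NULL) {
  if (is.null(names(counts)))
    stop("'counts' must be named by base")
  if (!is.numeric(target) || length(target) != 1L || is.na(target) ||
      target < 0 || target != round(target))
    stop("'target' must be a single non-negative integer")
  .withSeed(seed, {
    draw <- .rmvhyper(counts, target, 1L)[, 1]
    setNames(draw, names(counts))
  })
}

# Squared Pearson correlation of each column of F with q (the per-iteration
# regression R-squared); NA where a column has zero variance.
.colR2 <- function(F, q) {
  n <- nrow(F)
  qc <- q - mean(q)
  syy <- sum(qc^2)
  sx <- colSums(F)
  sxx <- colSums(F * F) - sx^2 / n
  sxy <- colSums(F * qc)
  r2 <- sxy^2 / (sxx * syy)
  r2[sxx <= 0 | syy <= 0] <- NA_real_
  r2
}

#' Accuracy of pooled frequencies as a function of coverage
#'
#' The read-resampling analysis: for each coverage level \code{c} in
#' \code{coverageRange} and each of \code{nIterations} iterations, every
#' record's reads are downsampled without replacement to \code{c}, the
#' major-allele frequencies are recomputed, and two summaries are taken
#' against the individual-based frequencies — the mean absolute frequency
#' difference over records, and the R-squared of the untransformed linear
#' regression. Per coverage level, the across-iteration average and standard
#' deviation of both quantities are reported.
#'
#' Records are processed in a fixed sorted order from one seeded random
#' stream, so a given configuration and seed always yields the identical
#' curve.
#'
#' @param records comparison records from [pairRecords()], carrying the four
#'   base-count columns; every record's total count must be at least
#'   \code{max(coverageRange)}.
#' @param coverageRange integer coverages to simulate (default
#'   \code{1:55}).
#' @param nIterations resampling iterations per coverage (default 1000).
#' @param seed seed for the resampling stream.
#' @return A \code{data.frame} with columns \code{coverage,
#'   meanAbsDiffAvg, meanAbsDiffSd, rSquaredAvg, rSquaredSd, nIterations}.
#' @seealso [coverageAtThreshold()]
#' @export
coverageCurve <- function(records, coverageRange = 1:55, nIterations = 1000,
                          seed = NULL) {
  need <- c("snp", "population", "indivMaf", "major",
            paste0("count_", .BASES))
  if (!all(need %in% names(records)))
    stop("records must carry snp, population, indivMaf, major and the four count_* columns")
  coverageRange <- sort(unique(as.integer(coverageRange)))
  if (any(coverageRange < 1L))
    stop("coverage range must start at 1 or above")
  nIterations <- .assertCount(nIterations, "nIterations")
  records <- records[is.finite(records$indivMaf), , drop = FALSE]
  records <- records[order(records$snp, records$population), , drop = FALSE]
  R <- nrow(records)
  if (R < 3L)
    stop("at least 3 records with individual frequencies are required")
  countsM <- as.matrix(records[, paste0("count_", .BASES)])
  totals <- rowSums(countsM)
  short <- totals < max(coverageRange)
  if (any(short))
    stop(sprintf(
      "record(s) with fewer reads than the requested maximum coverage (%d): %s",
      max(coverageRange),
      paste(records$snp[short], records$population[short], sep = "/",
            collapse = ", ")))
  majorIdx <- match(records$major, .BASES)
  q <- records$indivMaf
  .withSeed(seed, {
    out <- lapply(coverageRange, function(cc) {
      F <- matrix(0, R, nIterations)
      for (r in seq_len(R)) {
        draws <- .rmvhyper(countsM[r, ], cc, nIterations)
        F[r, ] <- draws[majorIdx[r], ] / cc
      }
      madIter <- colMeans(abs(F - q))
      r2Iter <- .colR2(F, q)
      data.frame(coverage = cc,
                 meanAbsDiffAvg = mean(madIter),
                 meanAbsDiffSd = sd(madIter),
                 rSquaredAvg = mean(r2Iter, na.rm = TRUE),
                 rSquaredSd = sd(r2Iter, na.rm = TRUE),
                 nIterations = nIterations)
    })
    do.call(rbind, out)
  })
}

#' Smallest coverage reaching an accuracy threshold
#'
#' Scans a coverage curve for the smallest coverage whose across-iteration
#' average crosses a threshold: below the threshold for the mean absolute
#' frequency difference, at or above it for the regression R-squared.
#'
#' @param curve a curve from [coverageCurve()].
#' @param metric \code{"mean_abs_diff"} or \code{"r_squared"}.
#' @param threshold the threshold to cross.
#' @return The smallest qualifying coverage, or \code{NA} (integer) if the
#'   threshold is never crossed.
#' @export
coverageAtThreshold <- function(curve,
                                metric = c("mean_abs_diff", "r_squared"),
                                threshold) {
  metric <- match.arg(metric)
  if (!is.data.frame(curve) || nrow(curve) == 0L)
    stop("'curve' must be a non-empty coverage curve")
  hit <- switch(metric,
                mean_abs_diff = curve$meanAbsDiffAvg < threshold,
                r_squared = curve$rSquaredAvg >= threshold)
  idx <- which(hit)
  if (!length(idx))
    return(NA_integer_)
  as.integer(curve$coverage[idx[1]])
}
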