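#' @include utils.R
NULL

# ---------------------------------------------------------------------------
# PopulationDesign
# ---------------------------------------------------------------------------

#' Design of a pooled-sequencing validation study
#'
#' Describes the sampling design a synthetic data set should emulate: how many
#' populations (one pool each), how many diploid (or higher-ploidy)
#' individuals contribute to each pool, how many biallelic SNPs are assayed,
#' and the true per-population major-allele frequency at each SNP.
#'
#' The effective pool size is \code{nIndividuals * ploidy}, the number of
#' chromosomes sampled into each pool.
#'
#' @slot nPopulations number of populations (= pools).
#' @slot nIndividuals individuals contributing to each pool.
#' @slot ploidy ploidy level of the organism.
#' @slot nSnps number of biallelic SNPs.
#' @slot trueMajorFreqs \code{nPopulations x nSnps} matrix of true
#'   major-allele frequencies in \eqn{[0,1]}.
#' @slot majorBase,minorBase length-\code{nSnps} nucleotide codes of the two
#'   alleles at each SNP; must differ per SNP.
#' @slot populationNames,lociNames identifiers used throughout the pipeline.
#'
#' @seealso [studyDesign()] for the default emulated design,
#'   [simulateGenotypes()].
#' @exportClass PopulationDesign
setClass("PopulationDesign", slots = c(
  nPopulations = "integer",
  nIndividuals = "integer",
  ploidy = "integer",
  nSnps = "integer",
  trueMajorFreqs = "matrix",
  majorBase = "character",
  minorBase = "character",
  populationNames = "character",
  lociNames = "character"))

setValidity("PopulationDesign", function(object) {
  msg <- character()
  for (s in c("nPopulations", "nIndividuals", "ploidy", "nSnps"))
    if (length(slot(object, s)) != 1L || is.na(slot(object, s)) ||
        slot(object, s) < 1L)
      msg <- c(msg, sprintf("'%s' must be a single positive integer", s))
  if (object@nIndividuals * object@ploidy < 1L)
    msg <- c(msg, "effective pool size must be strictly positive")
  f <- object@trueMajorFreqs
  if (!is.numeric(f) || nrow(f) != object@nPopulations ||
      ncol(f) != object@nSnps)
    msg <- c(msg, sprintf(
      "'trueMajorFreqs' must be a numeric %d x %d matrix (populations x SNPs)",
      object@nPopulations, object@nSnps))
  else if (anyNA(f) || any(f < 0 | f > 1))
    msg <- c(msg, "'trueMajorFreqs' must lie in [0,1]")
  if (length(object@majorBase) != object@nSnps ||
      length(object@minorBase) != object@nSnps)
    msg <- c(msg, "'majorBase' and 'minorBase' must have one entry per SNP")
  else {
    if (!all(object@majorBase %in% .BASES) ||
        !all(object@minorBase %in% .BASES))
      msg <- c(msg, "allele bases must be one of A, C, G, T")
    if (any(object@majorBase == object@minorBase))
      msg <- c(msg, "major and minor base must differ at every SNP")
  }
  if (length(object@populationNames) != object@nPopulations ||
      anyDuplicated(object@populationNames))
    msg <- c(msg, "'populationNames' must be unique, one per population")
  if (length(object@lociNames) != object@nSnps ||
      anyDuplicated(object@lociNames))
    msg <- c(msg, "'lociNames' must be unique, one per SNP")
  if (length(msg)) msg else TRUE
})

#' Create a PopulationDesign
#'
#' @param nPopulations,nIndividuals,ploidy,nSnps design counts; the defaults
#'   mirror a typical validation design of 3 populations of 20 diploid
#'   individuals at 9 SNPs.
#' @param trueMajorFreqs numeric matrix (\code{nPopulations x nSnps}) of true
#'   major-allele frequencies.
#' @param majorBase,minorBase nucleotide codes per SNP (recycled if length 1).
#' @param populationNames,lociNames optional identifiers.
#' @return A [PopulationDesign-class] object.
#' @examples
#' PopulationDesign(trueMajorFreqs = matrix(0.8, 3, 9))
#' @export
PopulationDesign <- function(nPopulations = 3, nIndividuals = 20, ploidy = 2,
                             nSnps = 9, trueMajorFreqs,
                             majorBase = "A", minorBase = "T",
                             populationNames = NULL, lociNames = NULL) {
  nPopulations <- .assertCount(nPopulations, "nPopulations")
  nIndividuals <- .assertCount(nIndividuals, "nIndividuals")
  ploidy <- .assertCount(ploidy, "ploidy")
  nSnps <- .assertCount(nSnps, "nSnps")
  trueMajorFreqs <- as.matrix(trueMajorFreqs)
  if (length(majorBase) == 1L) majorBase <- rep(majorBase, nSnps)
  if (length(minorBase) == 1L) minorBase <- rep(minorBase, nSnps)
  if (is.null(populationNames))
    populationNames <- sprintf("pop%d", seq_len(nPopulations))
  if (is.null(lociNames))
    lociNames <- sprintf("snp%02d", seq_len(nSnps))
  new("PopulationDesign", nPopulations = nPopulations,
      nIndividuals = nIndividuals, ploidy = ploidy, nSnps = nSnps,
      trueMajorFreqs = trueMajorFreqs, majorBase = majorBase,
      minorBase = minorBase, populationNames = populationNames,
      lociNames = lociNames)
}

setMethod("show", "PopulationDesign", function(object) {
  cat(sprintf(
    "PopulationDesign: %d population(s) x %d individuals (ploidy %d), %d SNP(s)\n",
    object@nPopulations, object@nIndividuals, object@ploidy, object@nSnps))
  cat(sprintf("  effective pool size: %d chromosomes\n",
              object@nIndividuals * object@ploidy))
  cat(sprintf("  true major-allele frequencies: %.3f - %.3f\n",
              min(object@trueMajorFreqs), max(object@trueMajorFreqs)))
})

# ---------------------------------------------------------------------------
# SequencingModel
# ---------------------------------------------------------------------------

#' Model of the pooled sequencing process
#'
#' Parameters governing how pooled reads are generated from a set of
#' genotypes: the per-pool, per-SNP coverage, the per-base substitution error
#' rate, and the variability of individual DNA contributions to the pool.
#'
#' @slot coverage either a single integer (fixed coverage), a length-2
#'   numeric \code{c(lo, hi)} for a uniform integer coverage sampler, or an
#'   integer matrix (pools x SNPs) of fixed coverages. All values must be
#'   \eqn{\ge 1}.
#' @slot errorRate per-base substitution probability in \eqn{[0, 0.25)};
#'   an erroneous read base is one of the three other nucleotides, uniformly.
#' @slot pipettingCV coefficient of variation of per-individual DNA
#'   contribution weights; 0 means perfectly equimolar pooling. Nonzero
#'   values draw gamma-distributed weights with mean 1.
#' @slot nRate,delRate probabilities that a read base is recorded as N or as
#'   a deletion; both default to 0 (quality-filtered pileups rarely carry
#'   them) and such reads never enter coverage or frequency denominators.
#'
#' @exportClass SequencingModel
setClass("SequencingModel", slots = c(
  coverage = "ANY",
  errorRate = "numeric",
  pipettingCV = "numeric",
  nRate = "numeric",
  delRate = "numeric"))

setValidity("SequencingModel", function(object) {
  msg <- character()
  cv <- object@coverage
  if (is.matrix(cv)) {
    if (anyNA(cv) || any(cv < 1) || any(cv != round(cv)))
      msg <- c(msg, "coverage matrix entries must be integers >= 1")
  } else if (is.numeric(cv) && length(cv) %in% 1:2) {
    if (anyNA(cv) || any(cv < 1) || any(cv != round(cv)))
      msg <- c(msg, "coverage values must be integers >= 1")
    if (length(cv) == 2L && cv[1] > cv[2])
      msg <- c(msg, "coverage range must satisfy lo <= hi")
  } else {
    msg <- c(msg, "coverage must be a scalar, a c(lo, hi) range, or a matrix")
  }
  if (object@errorRate < 0 || object@errorRate >= 0.25)
    msg <- c(msg, "'errorRate' must lie in [0, 0.25)")
  if (object@pipettingCV < 0)
    msg <- c(msg, "'pipettingCV' must be >= 0")
  if (object@nRate < 0 || object@delRate < 0 ||
      object@nRate + object@delRate >= 1)
    msg <- c(msg, "'nRate' and 'delRate' must be >= 0 and sum to < 1")
  if (length(msg)) msg else TRUE
})

#' Create a SequencingModel
#'
#' @param coverage coverage sampler; the default draws uniform integer
#'   coverages on \code{[55, 284]} per pool and SNP.
#' @param errorRate per-base substitution probability; default 0.01, a
#'   conservative bound for quality-trimmed Illumina data.
#' @param pipettingCV coefficient of variation of individual contribution
#'   weights (0 = equimolar).
#' @param nRate,delRate rates of N and deletion read categories (default 0).
#' @return A [SequencingModel-class] object.
#' @examples
#' SequencingModel(coverage = 100, errorRate = 0)
#' @export
SequencingModel <- function(coverage = c(55, 284), errorRate = 0.01,
                            pipettingCV = 0, nRate = 0, delRate = 0) {
  new("SequencingModel", coverage = coverage,
      errorRate = as.numeric(errorRate), pipettingCV = as.numeric(pipettingCV),
      nRate = as.numeric(nRate), delRate = as.numeric(delRate))
}

setMethod("show", "SequencingModel", function(object) {
  cv <- object@coverage
  desc <- if (is.matrix(cv)) sprintf("fixed matrix (%d x %d)", nrow(cv), ncol(cv))
          else if (length(cv) == 2L) sprintf("uniform on [%d, %d]", cv[1], cv[2])
          else sprintf("fixed at %dx", cv)
  cat(sprintf(
    "SequencingModel: coverage %s, error rate %.4g, pipetting CV %.3g\n",
    desc, object@errorRate, object@pipettingCV))
})

# ---------------------------------------------------------------------------
# GenotypeMatrix
# ---------------------------------------------------------------------------

#' Individual diploid genotype calls
#'
#' Per-individual, per-locus allele calls, stored as strings of \code{ploidy}
#' nucleotide characters (e.g. \code{"AT"} for a diploid heterozygote), with
#' \code{NA} marking failed calls. Individuals carry a population label that
#' partitions them into the sequencing pools.
#'
#' @slot calls character matrix, individuals x loci.
#' @slot population factor of population labels, one per individual.
#' @slot ploidy ploidy level (number of characters per non-missing call).
#' @slot majorBase,minorBase optional per-locus allele declarations; when
#'   present, every non-missing call is validated against them.
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix", slots = c(
  calls = "matrix",
  population = "factor",
  ploidy = "integer",
  majorBase = "character",
  minorBase = "character"))

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  cl <- object@calls
  if (!is.character(cl))
    msg <- c(msg, "'calls' must be a character matrix")
  if (length(object@population) != nrow(cl))
    msg <- c(msg, "'population' must have one label per individual (row)")
  if (length(object@ploidy) != 1L || is.na(object@ploidy) ||
      object@ploidy < 1L)
    msg <- c(msg, "'ploidy' must be a single positive integer")
  ok <- !is.na(cl)
  if (any(nchar(cl[ok]) != object@ploidy))
    msg <- c(msg, "every non-missing call must have 'ploidy' characters")
  declared <- length(object@majorBase) > 0L
  if (declared &&
      (length(object@majorBase) != ncol(cl) ||
       length(object@minorBase) != ncol(cl)))
    msg <- c(msg, "allele declarations must match the number of loci")
  else if (declared) {
    for (j in seq_len(ncol(cl))) {
      v <- cl[, j]
      v <- v[!is.na(v)]
      if (!length(v)) next
      chars <- unique(unlist(strsplit(v, "", fixed = TRUE)))
      if (!all(chars %in% c(object@majorBase[j], object@minorBase[j]))) {
        msg <- c(msg, sprintf(
          "calls at locus '%s' use bases outside the declared alleles",
          colnames(cl)[j]))
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Create a GenotypeMatrix
#'
#' @param calls character matrix (individuals x loci) of allele-call strings,
#'   \code{NA} for missing.
#' @param population population label per individual (coerced to factor).
#' @param ploidy ploidy level; default 2.
#' @param majorBase,minorBase optional per-locus allele declarations.
#' @return A [GenotypeMatrix-class] object.
#' @export
GenotypeMatrix <- function(calls, population, ploidy = 2,
                           majorBase = character(), minorBase = character()) {
  new("GenotypeMatrix", calls = calls,
      population = as.factor(population),
      ploidy = .assertCount(ploidy, "ploidy"),
      majorBase = majorBase, minorBase = minorBase)
}

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf(
    "GenotypeMatrix: %d individuals x %d loci (ploidy %d), %d population(s)\n",
    nrow(object@calls), ncol(object@calls), object@ploidy,
    nlevels(object@population)))
  nMiss <- sum(is.na(object@calls))
  cat(sprintf("  missing calls: %d / %d\n", nMiss, length(object@calls)))
})

# ---------------------------------------------------------------------------
# PoolCounts
# ---------------------------------------------------------------------------

#' Synchronized pooled pileup counts
#'
#' Per-site, per-pool counts of the six pileup categories (A, T, C, G, N,
#' deletion) — the unit of information the PoPoolation2-style "sync" format
#' serializes. Built on \linkS4class{RangedSummarizedExperiment}: sites are
#' rows (with chromosome, 1-based position and reference base), pools are
#' columns, and each category is one integer assay.
#'
#' A pool's coverage at a site is the sum of the four nucleotide counts; N
#' and deletion counts never enter coverage or frequency denominators.
#'
#' @seealso [readSync()], [writeSync()], [callSnps()], [poolCoverage()]
#' @exportClass PoolCounts
setClass("PoolCounts", contains = "RangedSummarizedExperiment")

setValidity("PoolCounts", function(object) {
  msg <- character()
  if (!identical(assayNames(object), .SYNC_CATEGORIES))
    msg <- c(msg, sprintf("assays must be exactly: %s",
                          paste(.SYNC_CATEGORIES, collapse = ", ")))
  else {
    for (nm in .SYNC_CATEGORIES) {
      a <- assay(object, nm)
      if (anyNA(a) || any(a < 0) || any(a != round(a))) {
        msg <- c(msg, "all counts must be non-negative integers")
        break
      }
    }
  }
  if (!"ref" %in% colnames(mcols(rowRanges(object))))
    msg <- c(msg, "rowRanges must carry a 'ref' metadata column")
  if (length(msg)) msg else TRUE
})

#' Create a PoolCounts object
#'
#' @param chrom,pos,ref per-site chromosome/contig name, 1-based position and
#'   reference base.
#' @param counts named list with elements \code{A, T, C, G, N, del}, each a
#'   sites x pools integer matrix (missing categories are filled with 0).
#' @param poolNames optional pool (column) names.
#' @param lociNames optional site (row) names.
#' @return A [PoolCounts-class] object.
#' @export
PoolCounts <- function(chrom, pos, ref, counts, poolNames = NULL,
                       lociNames = NULL) {
  counts <- lapply(counts, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "integer"
    m
  })
  nSites <- length(chrom)
  nPools <- if (length(counts)) ncol(counts[[1]]) else 0L
  full <- setNames(vector("list", length(.SYNC_CATEGORIES)), .SYNC_CATEGORIES)
  for (nm in .SYNC_CATEGORIES)
    full[[nm]] <- if (nm %in% names(counts)) counts[[nm]]
                  else matrix(0L, nSites, nPools)
  if (is.null(poolNames)) poolNames <- sprintf("pool%d", seq_len(nPools))
  full <- lapply(full, function(m) {
    dimnames(m) <- list(lociNames, poolNames)
    m
  })
  rr <- GRanges(chrom, IRanges(start = as.integer(pos), width = 1L),
                ref = as.character(ref))
  names(rr) <- lociNames
  new("PoolCounts",
      SummarizedExperiment(assays = full, rowRanges = rr,
                           colData = DataFrame(row.names = poolNames)))
}

# ---------------------------------------------------------------------------
# FilterParams
# ---------------------------------------------------------------------------

#' SNP-identification filter thresholds
#'
#' Thresholds used by [callSnps()]: a site is retained if every pool's
#' coverage (four-nucleotide sum) lies within \code{[minCoverage,
#' maxCoverage]} and the second-most-frequent base reaches
#' \code{minMinorCount}, by default counted across all pools combined.
#' The defaults (4, 20, 400) suit pooled data where a minimum minor count
#' guards against sequencing errors and a maximum coverage guards against
#' collapsed repeats.
#'
#' @slot minMinorCount minimum minor-allele count (default 4).
#' @slot minCoverage,maxCoverage per-pool coverage bounds (defaults 20, 400).
#' @slot minorScope \code{"combined"} applies \code{minMinorCount} to counts
#'   summed across pools; \code{"per-pool"} requires the threshold within
#'   every pool.
#' @exportClass FilterParams
setClass("FilterParams", slots = c(
  minMinorCount = "integer",
  minCoverage = "integer",
  maxCoverage = "integer",
  minorScope = "character"))

setValidity("FilterParams", function(object) {
  msg <- character()
  if (object@minMinorCount < 1L)
    msg <- c(msg, "'minMinorCount' must be >= 1")
  if (object@minCoverage > object@maxCoverage)
    msg <- c(msg, "'minCoverage' must be <= 'maxCoverage'")
  if (object@minCoverage < 1L)
    msg <- c(msg, "'minCoverage' must be >= 1")
  if (!object@minorScope %in% c("combined", "per-pool"))
    msg <- c(msg, "'minorScope' must be \"combined\" or \"per-pool\"")
  if (length(msg)) msg else TRUE
})

#' @rdname FilterParams-class
#' @param minMinorCount,minCoverage,maxCoverage,minorScope see slots.
#' @return A [FilterParams-class] object.
#' @examples
#' FilterParams()  # the default thresholds
#' @export
FilterParams <- function(minMinorCount = 4, minCoverage = 20,
                         maxCoverage = 400, minorScope = "combined") {
  new("FilterParams",
      minMinorCount = .assertCount(minMinorCount, "minMinorCount"),
      minCoverage = .assertCount(minCoverage, "minCoverage"),
      maxCoverage = .assertCount(maxCoverage, "maxCoverage"),
      minorScope = minorScope)
}

setMethod("show", "FilterParams", function(object) {
  cat(sprintf(
    "FilterParams: min minor count %d (%s), per-pool coverage in [%d, %d]\n",
    object@minMinorCount, object@minorScope, object@minCoverage,
    object@maxCoverage))
})

# ---------------------------------------------------------------------------
# SnpTable
# ---------------------------------------------------------------------------

#' Called SNPs with per-pool major-allele frequencies
#'
#' Result of [callSnps()]: the sites surviving the filters, the major/minor
#' allele assignment from counts combined across pools, and per-pool
#' major-allele frequencies (MAF). Because the major allele is defined on the
#' combined counts, a single pool's MAF may fall below 0.5.
#'
#' The reported per-pool \code{coverage} is the biallelic (major + minor)
#' count sum — the exact denominator of the MAF — so that
#' \code{maf * coverage} reproduces the integer major-allele count. Counts on
#' any third or fourth base are reported in the \code{extraCount} column of
#' \code{snpInfo()} and excluded from frequencies.
#'
#' @slot info \code{DataFrame} with columns chrom, pos, ref, major, minor,
#'   extraCount; row names are locus identifiers.
#' @slot coverage,maf,majorCounts sites x pools matrices.
#' @slot combinedCounts sites x 4 matrix of across-pool base counts (A,C,G,T).
#' @slot poolBaseCounts sites x pools x 4 array of per-pool base counts.
#' @slot params the [FilterParams-class] used.
#' @seealso [snpInfo()], [snpMaf()], [snpCoverage()], [pairRecords()]
#' @exportClass SnpTable
setClass("SnpTable", slots = c(
  info = "DataFrame",
  coverage = "matrix",
  maf = "matrix",
  majorCounts = "matrix",
  combinedCounts = "matrix",
  poolBaseCounts = "array",
  params = "FilterParams"))

setValidity("SnpTable", function(object) {
  msg <- character()
  n <- nrow(object@info)
  if (nrow(object@coverage) != n || nrow(object@maf) != n ||
      nrow(object@majorCounts) != n)
    msg <- c(msg, "matrix slots must have one row per SNP")
  if (n > 0 && (any(object@maf < 0) || any(object@maf > 1)))
    msg <- c(msg, "frequencies must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SnpTable", function(object) {
  cat(sprintf("SnpTable: %d SNP(s) x %d pool(s)\n",
              nrow(object@info), ncol(object@coverage)))
  show(object@params)
  if (nrow(object@info) > 0) {
    cat(sprintf("  per-pool MAF range: %.3f - %.3f\n",
                min(object@maf), max(object@maf)))
  }
})

# ---------------------------------------------------------------------------
# ValidationReport
# ---------------------------------------------------------------------------

#' Pooled-vs-individual concordance report
#'
#' Result of [buildValidationReport()]: the comparison records and, for the
#' all-records and complete-records-only variants, the concordance
#' statistics — mean absolute frequency difference with its standard error,
#' slope/intercept/R-squared of the untransformed least-squares regression,
#' the regression p-value and paired t-test on arcsine-square-root
#' transformed frequencies, and the Pearson correlation of coverage with the
#' absolute difference.
#'
#' @slot records the comparison records (one per SNP x population).
#' @slot all,completeOnly named lists of statistics; \code{available = FALSE}
#'   marks a variant that could not be computed (too few records).
#' @slot orientation regression orientation, \code{"pool~x, indiv~y"}.
#' @exportClass ValidationReport
setClass("ValidationReport", slots = c(
  records = "data.frame",
  all = "list",
  completeOnly = "list",
  orientation = "character"))

setMethod("show", "ValidationReport", function(object) {
  fmt <- function(v, label) {
    if (!isTRUE(v$available)) {
      cat(sprintf("  %s: unavailable (%s)\n", label,
                  if (!is.null(v$note)) v$note else "no records"))
      return(invisible())
    }
    cat(sprintf(
      "  %s (n = %d): mean |diff| %.4f +/- %.4f SE; y = %.3fx + %.3f, R2 = %.3f\n",
      label, v$n, v$meanAbsDiff, v$seAbsDiff, v$slope, v$intercept,
      v$rSquared))
    cat(sprintf(
      "    p(regression, transformed) = %.3g; paired t = %.3f, p = %.3g; r(coverage) = %.3f, p = %.3g\n",
      v$pRegression, v$tStatistic, v$pPaired, v$pearsonRCoverage,
      v$pCoverage))
  }
  cat("ValidationReport (pooled MAF = x, individual MAF = y)\n")
  fmt(object@all, "all records")
  fmt(object@completeOnly, "complete only")
})
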