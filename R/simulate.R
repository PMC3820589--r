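#' @include AllClasses.R
NULL

#' Default emulated validation design
#'
#' Convenience constructor for the study design the package emulates by
#' default: 3 populations of 20 diploid individuals pooled equimolarly,
#' assayed at 9 biallelic SNPs. True major-allele frequencies are drawn
#' i.i.d. Uniform(0, 1) per population and SNP — validation panels are
#' typically enriched for strongly differentiated SNPs spanning the whole
#' frequency range — and the two alleles of each SNP are a random pair of
#' distinct nucleotides.
#'
#' @param seed seed controlling the frequency and allele draws.
#' @param nPopulations,nIndividuals,ploidy,nSnps design counts.
#' @return A [PopulationDesign-class].
#' @examples
#' studyDesign(seed = 1)
#' @export
studyDesign <- function(seed = NULL, nPopulations = 3, nIndividuals = 20,
                        ploidy = 2, nSnps = 9) {
  .withSeed(seed, {
    freqs <- matrix(runif(nPopulations * nSnps), nPopulations, nSnps)
    pairs <- vapply(seq_len(nSnps), function(j) sample(.BASES, 2L),
                    character(2))
    PopulationDesign(nPopulations = nPopulations, nIndividuals = nIndividuals,
                     ploidy = ploidy, nSnps = nSnps, trueMajorFreqs = freqs,
                     majorBase = pairs[1, ], minorBase = pairs[2, ])
  })
}

#' Simulate individual genotypes under Hardy-Weinberg proportions
#'
#' For each individual and SNP, the number of major-allele copies is drawn
#' from Binomial(ploidy, p) with p the individual's population's true major
#' frequency — the neutral stand-in for sampling unrelated individuals from
#' an outcrossing population. Deviations from Hardy-Weinberg can be studied
#' by constructing a [GenotypeMatrix-class] directly.
#'
#' @param design a [PopulationDesign-class].
#' @param seed seed for reproducible draws.
#' @return A [GenotypeMatrix-class] with no missing calls.
#' @examples
#' gm <- simulateGenotypes(studyDesign(seed = 1), seed = 2)
#' @export
simulateGenotypes <- function(design, seed = NULL) {
  stopifnot(is(design, "PopulationDesign"))
  validObject(design)
  .withSeed(seed, {
    nP <- design@nPopulations
    nI <- design@nIndividuals
    pl <- design@ploidy
    nS <- design@nSnps
    calls <- matrix(NA_character_, nP * nI, nS, dimnames = list(
      paste(rep(design@populationNames, each = nI),
            sprintf("ind%02d", rep(seq_len(nI), nP)), sep = "_"),
      design@lociNames))
    for (k in seq_len(nP)) {
      rows <- (k - 1L) * nI + seq_len(nI)
      for (j in seq_len(nS)) {
        d <- rbinom(nI, pl, design@trueMajorFreqs[k, j])
        calls[rows, j] <- paste0(strrep(design@majorBase[j], d),
                                 strrep(design@minorBase[j], pl - d))
      }
    }
    GenotypeMatrix(calls,
                   population = factor(rep(design@populationNames, each = nI),
                                       levels = design@populationNames),
                   ploidy = pl, majorBase = design@majorBase,
                   minorBase = design@minorBase)
  })
}

# Major-allele dosage per individual and locus; NA where the call is missing.
.majorDosage <- function(gm) {
  cl <- gm@calls
  d <- matrix(NA_integer_, nrow(cl), ncol(cl), dimnames = dimnames(cl))
  for (j in seq_len(ncol(cl))) {
    v <- cl[, j]
    ok <- !is.na(v)
    if (any(ok))
      d[ok, j] <- vapply(strsplit(v[ok], "", fixed = TRUE),
                         function(a) sum(a == gm@majorBase[j]), integer(1))
  }
  d
}

.drawCoverage <- function(coverage, pool, snp) {
  if (is.matrix(coverage))
    as.integer(coverage[pool, snp])
  else if (length(coverage) == 2L)
    as.integer(coverage[1] + floor(runif(1) * (coverage[2] - coverage[1] + 1)))
  else
    as.integer(coverage)
}

#' Simulate pooled read counts
#'
#' Generates the pooled sequencing outcome for each population: individual
#' DNA contribution weights (gamma-distributed with mean 1 and the model's
#' CV; exactly 1 when \code{pipettingCV = 0}), the resulting true pool
#' frequency (weight-weighted mean of individual major-allele dosages divided
#' by ploidy), a drawn coverage, and read bases drawn independently — with
#' probability \code{1 - errorRate} the true base, otherwise uniformly one of
#' the three other nucleotides. Counts are accumulated into the six pileup
#' categories; N and deletion reads are only produced when the model
#' configures nonzero rates.
#'
#' @param genotypes a fully called [GenotypeMatrix-class] with declared
#'   alleles (no missing values).
#' @param model a [SequencingModel-class].
#' @param seed seed for reproducible draws.
#' @return A [PoolCounts-class] with one column per population; the true
#'   (weight-weighted) pool frequencies are stored in
#'   \code{metadata(x)$truePoolFreqs}.
#' @examples
#' gm <- simulateGenotypes(studyDesign(seed = 1), seed = 2)
#' pc <- simulatePoolCounts(gm, SequencingModel(coverage = 100), seed = 3)
#' @export
simulatePoolCounts <- function(genotypes, model, seed = NULL) {
  stopifnot(is(genotypes, "GenotypeMatrix"), is(model, "SequencingModel"))
  validObject(model)
  if (anyNA(genotypes@calls))
    stop("pooled truth requires fully genotyped individuals (no missing calls)")
  if (!length(genotypes@majorBase))
    stop("'genotypes' must declare major/minor bases per locus")
  .withSeed(seed, {
    pops <- levels(genotypes@population)
    loci <- colnames(genotypes@calls)
    nS <- length(loci)
    nP <- length(pops)
    pl <- genotypes@ploidy
    dosage <- .majorDosage(genotypes)
    cnt <- lapply(setNames(.SYNC_CATEGORIES, .SYNC_CATEGORIES),
                  function(nm) matrix(0L, nS, nP))
    trueFreqs <- matrix(NA_real_, nS, nP, dimnames = list(loci, pops))
    e <- model@errorRate
    aux <- model@nRate + model@delRate
    for (k in seq_len(nP)) {
      idx <- genotypes@population == pops[k]
      n <- sum(idx)
      w <- if (model@pipettingCV > 0)
        rgamma(n, shape = 1 / model@pipettingCV^2,
               rate = 1 / model@pipettingCV^2)
      else rep(1, n)
      for (j in seq_len(nS)) {
        p <- sum(w * dosage[idx, j]) / (sum(w) * pl)
        trueFreqs[j, k] <- p
        cvg <- .drawCoverage(model@coverage, k, j)
        if (cvg < 1L)
          stop("coverage sampler yielded a value below 1")
        pTrue <- setNames(numeric(4), .BASES)
        pTrue[genotypes@majorBase[j]] <- p
        pTrue[genotypes@minorBase[j]] <- pTrue[genotypes@minorBase[j]] + 1 - p
        pObs <- pTrue * (1 - e) + (1 - pTrue) * (e / 3)
        draw <- rmultinom(1, cvg, c(pObs * (1 - aux),
                                    N = model@nRate, del = model@delRate))
        for (b in .BASES) cnt[[b]][j, k] <- draw[b, 1]
        cnt[["N"]][j, k] <- draw["N", 1]
        cnt[["del"]][j, k] <- draw["del", 1]
      }
    }
    pc <- PoolCounts(chrom = loci, pos = rep(1L, nS),
                     ref = genotypes@majorBase, counts = cnt,
                     poolNames = pops, lociNames = loci)
    metadata(pc)$truePoolFreqs <- trueFreqs
    pc
  })
}

#' Simulate genotyping dropout
#'
#' Replaces each individual call independently by a missing value with the
#' given failure probability, emulating amplification/sequencing failures of
#' a targeted genotyping assay. Calls that succeed are left untouched (the
#' assay is treated as exact).
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param failureRate per-call failure probability in \eqn{[0, 1)}.
#' @param seed seed for reproducible draws.
#' @return A [GenotypeMatrix-class] with failed calls set to \code{NA}.
#' @export
simulateIndividualCalls <- function(genotypes, failureRate, seed = NULL) {
  stopifnot(is(genotypes, "GenotypeMatrix"))
  failureRate <- .assertProb(failureRate, "failureRate", maxExclusive = TRUE)
  .withSeed(seed, {
    cl <- genotypes@calls
    cl[runif(length(cl)) < failureRate] <- NA_character_
    initialize(genotypes, calls = cl)
  })
}

#' Frequency of a singleton allele in a pool
#'
#' A singleton — a single allele copy carried by one heterozygous individual
#' — has within-pool frequency \eqn{1 / (n \times ploidy)}, the reciprocal of
#' the effective pool size. For 20 diploid individuals this is 0.025 (2.5%);
#' singletons are reliably detectable only when the sequencing error rate
#' lies well below this value.
#'
#' @param nIndividuals,ploidy pool composition, both \eqn{\ge 1}.
#' @return The singleton frequency.
#' @examples
#' singletonFrequency(20, 2)  # 0.025
#' @export
singletonFrequency <- function(nIndividuals, ploidy) {
  nIndividuals <- .assertCount(nIndividuals, "nIndividuals")
  ploidy <- .assertCount(ploidy, "ploidy")
  1 / (nIndividuals * ploidy)
}

#' Minimum recommended sequencing coverage for a pool
#'
#' To give every chromosome in the pool a chance to be sampled at least once
#' — and hence rare variants a chance to be seen — the per-pool coverage
#' should be at least the effective pool size, the number of individuals
#' multiplied by the ploidy level.
#'
#' @param nIndividuals,ploidy pool composition, both \eqn{\ge 1}.
#' @return The effective pool size as an integer coverage.
#' @examples
#' minimumRecommendedCoverage(20, 2)  # 40
#' @export
minimumRecommendedCoverage <- function(nIndividuals, ploidy) {
  nIndividuals <- .assertCount(nIndividuals, "nIndividuals")
  ploidy <- .assertCount(ploidy, "ploidy")
  nIndividuals * ploidy
}
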