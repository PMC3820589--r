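# Shared fixtures and independent oracles. The oracles are deliberately
# written as plain, per-site / closed-form transcriptions so they share no
# code path with the package implementation.

BASES4 <- c("A", "C", "G", "T")

# Build a PoolCounts from a sites x pools x 4 array of A,C,G,T counts.
pcFromArray <- function(arr, chrom = NULL) {
  nS <- dim(arr)[1]
  nP <- dim(arr)[2]
  cnt <- setNames(lapply(1:4, function(b) matrix(arr[, , b], nS, nP)),
                  BASES4)
  PoolCounts(chrom = if (is.null(chrom)) sprintf("site%04d", seq_len(nS))
             else chrom,
             pos = seq_len(nS), ref = rep("N", nS), counts = cnt,
             lociNames = if (is.null(chrom)) sprintf("site%04d", seq_len(nS))
             else chrom)
}

# A diploid GenotypeMatrix from a matrix of major-allele dosages (0/1/2),
# one population per row-block of `perPop` individuals.
gmFromDosage <- function(dosage, perPop = nrow(dosage), major = "A",
                         minor = "T") {
  nI <- nrow(dosage)
  nL <- ncol(dosage)
  calls <- matrix(NA_character_, nI, nL,
                  dimnames = list(sprintf("ind%03d", seq_len(nI)),
                                  sprintf("snp%02d", seq_len(nL))))
  for (j in seq_len(nL))
    calls[, j] <- c("TT", "AT", "AA")[dosage[, j] + 1L]
  if (major != "A" || minor != "T")
    calls <- matrix(chartr("AT", paste0(major, minor), calls), nI, nL,
                    dimnames = dimnames(calls))
  pops <- rep(sprintf("pop%d", seq_len(nI / perPop)), each = perPop)
  GenotypeMatrix(calls, population = pops, ploidy = 2,
                 majorBase = rep(major, nL), minorBase = rep(minor, nL))
}

# Straight per-site transcription of the three SNP-identification rules.
# site: pools x 4 matrix with columns A,C,G,T.
bruteKeepSite <- function(site, minMinor = 4, minCov = 20, maxCov = 400,
                          scope = "combined") {
  for (k in seq_len(nrow(site))) {
    cv <- site[k, 1] + site[k, 2] + site[k, 3] + site[k, 4]
    if (cv < minCov || cv > maxCov) return(FALSE)
  }
  comb <- c(sum(site[, 1]), sum(site[, 2]), sum(site[, 3]), sum(site[, 4]))
  nSeg <- 0
  for (b in 1:4) if (comb[b] > 0) nSeg <- nSeg + 1
  if (nSeg < 2) return(FALSE)
  best <- 1
  for (b in 2:4) if (comb[b] > comb[best]) best <- b
  rest <- setdiff(1:4, best)
  second <- rest[1]
  for (b in rest) if (comb[b] > comb[second]) second <- b
  if (scope == "combined") comb[second] >= minMinor
  else all(site[, second] >= minMinor)
}

# Closed-form normal equations for simple OLS, incl. the slope t-test.
olsOracle <- function(x, y) {
  n <- length(x)
  sxx <- sum(x^2) - sum(x)^2 / n
  syy <- sum(y^2) - sum(y)^2 / n
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  rss <- syy - slope * sxy
  r2 <- 1 - rss / syy
  seSlope <- sqrt(rss / (n - 2) / sxx)
  t <- slope / seSlope
  list(slope = slope, intercept = intercept, r2 = r2, t = t,
       p = 2 * pt(-abs(t), n - 2))
}

# Closed-form one-sample (paired) t-test on differences.
pairedTOracle <- function(d) {
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), n - 1))
}

# Closed-form Pearson product-moment correlation with its t-based p.
pearsonOracle <- function(x, y) {
  n <- length(x)
  r <- (sum(x * y) - sum(x) * sum(y) / n) /
    sqrt((sum(x^2) - sum(x)^2 / n) * (sum(y^2) - sum(y)^2 / n))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), n - 2))
}

# Full simulated validation run under the default emulated design.
simulateValidationRun <- function(seed, errorRate = 0.01,
                                  coverage = c(55, 284), failureRate = 0,
                                  pipettingCV = 0) {
  design <- studyDesign(seed = seed)
  gm <- simulateGenotypes(design, seed = seed + 1)
  pc <- simulatePoolCounts(
    gm, SequencingModel(coverage = coverage, errorRate = errorRate,
                        pipettingCV = pipettingCV), seed = seed + 2)
  st <- suppressWarnings(callSnps(pc))
  called <- if (failureRate > 0)
    simulateIndividualCalls(gm, failureRate, seed = seed + 3) else gm
  records <- suppressWarnings(pairRecords(st, called))
  list(design = design, genotypes = gm, called = called, pools = pc,
       snpTable = st, records = records)
}
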