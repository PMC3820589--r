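#' @include AllClasses.R
NULL

#' Major-allele frequency from individual genotype calls
#'
#' Counts major-allele copies over the non-missing calls of one population at
#' one locus and divides by the number of non-missing chromosomes (pairwise
#' deletion: failed individuals drop out of numerator and denominator).
#'
#' @param calls character vector of allele-call strings (\code{NA} = failed).
#' @param majorBase the allele to count.
#' @return Frequency in \eqn{[0, 1]}.
#' @examples
#' individualMaf(c("AA", "AA", "AT"), "A")  # 5/6
#' @export
individualMaf <- function(calls, majorBase) {
  stopifnot(is.character(majorBase), length(majorBase) == 1L)
  calls <- calls[!is.na(calls)]
  if (!length(calls))
    stop("all calls are missing: individual frequency undefined")
  alleles <- unlist(strsplit(calls, "", fixed = TRUE))
  mean(alleles == majorBase)
}

#' Pair pooled and individual frequencies per SNP and population
#'
#' Builds one comparison record per retained SNP x population: the pooled
#' major-allele frequency from the [SnpTable-class], the individual-based
#' frequency from the genotype calls (pairwise deletion of failed calls), the
#' pool's coverage, a completeness flag (TRUE iff no individual call was
#' missing for that SNP x population), and the pool's four base counts (used
#' by the coverage-resampling analysis). Loci or populations present in only
#' one of the two inputs are reported with a warning, never silently dropped.
#'
#' @param snpTable a [SnpTable-class].
#' @param genotypes a [GenotypeMatrix-class] whose locus names match the
#'   SNP table's locus identifiers.
#' @return A \code{data.frame} with columns \code{snp, population, poolMaf,
#'   indivMaf, absDiff, coverage, complete, major, count_A, count_C,
#'   count_G, count_T}.
#' @export
pairRecords <- function(snpTable, genotypes) {
  stopifnot(is(snpTable, "SnpTable"), is(genotypes, "GenotypeMatrix"))
  lociS <- rownames(snpTable@info)
  lociG <- colnames(genotypes@calls)
  poolsS <- colnames(snpTable@coverage)
  popsG <- levels(genotypes@population)
  onlyS <- setdiff(lociS, lociG)
  onlyG <- setdiff(lociG, lociS)
  if (length(onlyS) || length(onlyG))
    warning(sprintf(
      "loci present in only one input: %s",
      paste(c(onlyS, onlyG), collapse = ", ")))
  if (!ncol(genotypes@calls) || !nrow(genotypes@calls))
    warning("empty genotype table: no comparison records can be formed")
  loci <- intersect(lociS, lociG)
  pops <- intersect(poolsS, popsG)
  if (!length(pops) && length(poolsS) == length(popsG) && length(popsG)) {
    # sync-derived pools carry no labels; pair pools to populations by order
    message("pool names do not match population labels; pairing by position")
    pops <- popsG
    poolFor <- setNames(seq_along(popsG), popsG)
  } else {
    if (!setequal(poolsS, popsG) && length(poolsS) && length(popsG))
      warning("pool and population labels do not fully match")
    poolFor <- setNames(match(pops, poolsS), pops)
  }
  rows <- vector("list", length(loci) * length(pops))
  i <- 0L
  for (snp in loci) {
    si <- match(snp, lociS)
    major <- snpTable@info$major[si]
    for (pop in pops) {
      pi <- poolFor[[pop]]
      calls <- genotypes@calls[genotypes@population == pop, snp]
      nMiss <- sum(is.na(calls))
      indiv <- if (nMiss == length(calls)) NA_real_
               else individualMaf(calls, major)
      pool <- snpTable@maf[si, pi]
      counts <- snpTable@poolBaseCounts[si, pi, ]
      i <- i + 1L
      rows[[i]] <- data.frame(
        snp = snp, population = pop, poolMaf = pool, indivMaf = indiv,
        absDiff = abs(pool - indiv), coverage = snpTable@coverage[si, pi],
        complete = nMiss == 0L, major = major,
        count_A = counts["A"], count_C = counts["C"],
        count_G = counts["G"], count_T = counts["T"],
        stringsAsFactors = FALSE)
    }
  }
  if (!i)
    return(data.frame(snp = character(), population = character(),
                      poolMaf = numeric(), indivMaf = numeric(),
                      absDiff = numeric(), coverage = numeric(),
                      complete = logical(), major = character(),
                      count_A = integer(), count_C = integer(),
                      count_G = integer(), count_T = integer()))
  out <- do.call(rbind, rows[seq_len(i)])
  rownames(out) <- NULL
  out
}

# Extract the (x, y) = (pooled, individual) frequency pairs of a record set.
.recordXY <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("poolMaf", "indivMaf") %in% names(records)))
  ok <- is.finite(records$poolMaf) & is.finite(records$indivMaf)
  list(x = records$poolMaf[ok], y = records$indivMaf[ok])
}

#' Untransformed least-squares concordance regression
#'
#' Ordinary least squares of individual-based frequencies (y) on pooled
#' frequencies (x), on the raw frequency scale: the slope, intercept and
#' R-squared quantify the deviation from the ideal 1:1 relationship, so the
#' data are deliberately not transformed here.
#'
#' @param records comparison records from [pairRecords()] (or any data frame
#'   with \code{poolMaf} and \code{indivMaf} columns).
#' @return List with \code{slope}, \code{intercept}, \code{rSquared},
#'   \code{n}.
#' @export
regressionUntransformed <- function(records) {
  xy <- .recordXY(records)
  .ols(xy$x, xy$y)
}

.ols <- function(x, y) {
  n <- length(x)
  if (n < 3L)
    stop("at least 3 records are required for the regression")
  if (var(x) == 0)
    stop("degenerate fit: no variance in the pooled frequencies")
  if (var(y) == 0)
    return(list(slope = 0, intercept = mean(y), rSquared = 0, n = n))
  fit <- lm(y ~ x)
  # summary.lm warns on an exactly perfect fit; that input is legitimate here
  s <- suppressWarnings(summary(fit))
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       rSquared = s$r.squared, n = n)
}

#' Arcsine square-root transform
#'
#' The variance-stabilizing transform for proportions,
#' \eqn{\arcsin(\sqrt{p})}, mapping \eqn{[0,1]} onto \eqn{[0, \pi/2]}.
#' Applied before the p-value-bearing tests ([regressionPTransformed()],
#' [pairedTTransformed()]).
#'
#' @param freq frequencies in \eqn{[0, 1]}.
#' @return Transformed values.
#' @examples
#' arcsineTransform(c(0, 0.5, 1))  # 0, pi/4, pi/2
#' @export
arcsineTransform <- function(freq) {
  if (anyNA(freq) || any(freq < 0 | freq > 1))
    stop("frequencies must lie in [0,1]")
  asin(sqrt(freq))
}

#' Regression p-value on transformed frequencies
#'
#' Fits the concordance regression on arcsine-square-root transformed pooled
#' and individual frequencies and returns the two-sided p-value of the
#' slope's t statistic (df = n - 2). The transform stabilizes the variance of
#' the proportions so the t reference distribution is defensible.
#'
#' @inheritParams regressionUntransformed
#' @return Two-sided p-value.
#' @export
regressionPTransformed <- function(records) {
  xy <- .recordXY(records)
  n <- length(xy$x)
  if (n < 3L)
    stop("at least 3 records are required for the regression")
  xt <- arcsineTransform(xy$x)
  yt <- arcsineTransform(xy$y)
  if (var(xt) == 0)
    stop("degenerate fit: no variance in the transformed pooled frequencies")
  fit <- lm(yt ~ xt)
  cf <- suppressWarnings(summary(fit))$coefficients
  p <- cf["xt", "Pr(>|t|)"]
  # exactly collinear data: residual SE is 0 and the t statistic degenerates
  if (!is.finite(p) && sum(residuals(fit)^2) < 1e-24)
    p <- 0
  unname(p)
}

#' Paired t-test on transformed frequencies
#'
#' Tests whether pooled sequencing systematically over- or underestimates
#' allele frequencies: a paired, two-sided t-test of the arcsine-square-root
#' transformed pooled vs individual frequencies (df = n - 1).
#'
#' @inheritParams regressionUntransformed
#' @return List with \code{statistic} (t) and \code{p}.
#' @export
pairedTTransformed <- function(records) {
  xy <- .recordXY(records)
  if (length(xy$x) < 2L)
    stop("at least 2 records are required for the paired t-test")
  d <- arcsineTransform(xy$x) - arcsineTransform(xy$y)
  # guard numerically constant differences (sd of order machine epsilon)
  if (sd(d) <= 1e-12 * max(1, abs(mean(d)))) {
    if (all(abs(d) <= 1e-12))
      return(list(statistic = 0, p = 1))
    warning("zero-variance nonzero differences: t statistic is unbounded")
    return(list(statistic = sign(mean(d)) * Inf, p = 0))
  }
  tt <- t.test(d)
  list(statistic = unname(tt$statistic), p = tt$p.value)
}

#' Mean absolute frequency difference
#'
#' The average of \eqn{|pooled - individual|} over the records, with its
#' standard error (sample SD over \eqn{\sqrt{n}}).
#'
#' @inheritParams regressionUntransformed
#' @return List with \code{mean}, \code{se}, \code{n}.
#' @export
meanAbsDiff <- function(records) {
  xy <- .recordXY(records)
  n <- length(xy$x)
  if (n < 1L)
    stop("at least 1 record is required")
  d <- abs(xy$x - xy$y)
  list(mean = mean(d), se = if (n > 1L) sd(d) / sqrt(n) else NA_real_, n = n)
}

#' Effect of coverage on estimation accuracy
#'
#' Pearson correlation between a record's sequencing coverage and its
#' absolute pooled-vs-individual frequency difference, with the two-sided
#' p-value from the t transform (df = n - 2). A significant positive or
#' negative r would indicate that accuracy depends on depth within the
#' observed coverage range.
#'
#' @inheritParams regressionUntransformed
#' @return List with \code{r}, \code{p}, \code{n}; \code{NA} (with a
#'   warning) when either variable has zero variance.
#' @export
coverageEffect <- function(records) {
  stopifnot(all(c("coverage", "absDiff") %in% names(records)))
  ok <- is.finite(records$coverage) & is.finite(records$absDiff)
  cv <- records$coverage[ok]
  d <- records$absDiff[ok]
  n <- length(cv)
  if (n < 3L)
    stop("at least 3 records with finite coverage are required")
  if (var(cv) == 0 || var(d) == 0) {
    warning("zero variance: coverage-effect correlation is undefined")
    return(list(r = NA_real_, p = NA_real_, n = n))
  }
  ct <- suppressWarnings(cor.test(cv, d, method = "pearson"))
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

.reportStats <- function(records) {
  n <- nrow(records)
  if (n < 3L)
    return(list(available = FALSE, n = n,
                note = "fewer than 3 records: statistics not computed"))
  tryCatch({
    mad <- meanAbsDiff(records)
    ols <- regressionUntransformed(records)
    tt <- pairedTTransformed(records)
    ce <- coverageEffect(records)
    list(available = TRUE, n = n,
         meanAbsDiff = mad$mean, seAbsDiff = mad$se,
         slope = ols$slope, intercept = ols$intercept,
         rSquared = ols$rSquared,
         pRegression = regressionPTransformed(records),
         tStatistic = tt$statistic, pPaired = tt$p,
         pearsonRCoverage = ce$r, pCoverage = ce$p)
  }, error = function(e)
    list(available = FALSE, n = n, note = conditionMessage(e)))
}

#' Build the pooled-vs-individual validation report
#'
#' Runs all concordance statistics on the comparison records, in two
#' variants: over all records (failed individual calls handled by pairwise
#' deletion inside each record) and over complete records only (records
#' untouched by genotyping failures), which together bound the influence of
#' missing values on the conclusions.
#'
#' @param records comparison records from [pairRecords()].
#' @param variant \code{"both"} (default), \code{"all"} or
#'   \code{"complete_only"}; unselected variants are reported as skipped.
#' @return A [ValidationReport-class].
#' @export
buildValidationReport <- function(records,
                                  variant = c("both", "all",
                                              "complete_only")) {
  variant <- match.arg(variant)
  skipped <- list(available = FALSE, n = NA_integer_,
                  note = "variant not requested")
  allStats <- if (variant %in% c("both", "all"))
    .reportStats(records[is.finite(records$indivMaf), , drop = FALSE])
  else skipped
  compStats <- if (variant %in% c("both", "complete_only"))
    .reportStats(records[records$complete & is.finite(records$indivMaf), ,
                         drop = FALSE])
  else skipped
  new("ValidationReport", records = records, all = allStats,
      completeOnly = compStats, orientation = "x = pooled, y = individual")
}
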