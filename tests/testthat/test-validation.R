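test_that("individual frequencies use pairwise deletion of failed calls", {
  expect_identical(individualMaf(rep("AA", 20), "A"), 1)
  expect_equal(individualMaf(c(rep("AA", 19), "AT"), "A"), 39 / 40)
  expect_equal(individualMaf(c(rep("AA", 18), "AT", NA), "A"), 37 / 38)
  expect_error(individualMaf(c(NA_character_, NA), "A"), "missing")
})

test_that("record pairing yields one record per SNP and population", {
  run <- simulateValidationRun(seed = 11, errorRate = 0)
  expect_identical(nrow(run$records), 27L)
  expect_true(all(run$records$complete))
  expect_true(all(run$records$absDiff ==
                    abs(run$records$poolMaf - run$records$indivMaf)))
  expect_true(all(run$records$poolMaf >= 0 & run$records$poolMaf <= 1))

  # dropout flags exactly the touched SNP x population pairings
  called <- simulateIndividualCalls(run$genotypes, 22 / 540, seed = 99)
  rec <- pairRecords(run$snpTable, called)
  touched <- with(expand.grid(snp = colnames(genotypeCalls(called)),
                              pop = levels(populationLabels(called)),
                              stringsAsFactors = FALSE),
                  mapply(function(s, p) anyNA(
                    genotypeCalls(called)[populationLabels(called) == p, s]),
                    snp, pop))
  expect_identical(sum(!rec$complete), sum(touched))

  # loci present in only one input are reported
  gmSub <- GenotypeMatrix(genotypeCalls(run$genotypes)[, -1],
                          populationLabels(run$genotypes), ploidy = 2)
  expect_warning(recSub <- pairRecords(run$snpTable, gmSub), "only one input")
  expect_identical(nrow(recSub), 24L)

  # empty genotype table
  gmEmpty <- GenotypeMatrix(
    matrix(character(), 0, 0), factor(character()), ploidy = 2)
  ws <- capture_warnings(recE <- pairRecords(run$snpTable, gmEmpty))
  expect_true(any(grepl("empty genotype table", ws)))
  expect_identical(nrow(recE), 0L)
})

test_that("untransformed regression matches the closed-form normal equations", {
  # perfect concordance
  recPerfect <- data.frame(poolMaf = c(0.1, 0.4, 0.9),
                           indivMaf = c(0.1, 0.4, 0.9))
  fit <- regressionUntransformed(recPerfect)
  expect_equal(fit$slope, 1)
  expect_equal(fit$intercept, 0)
  expect_equal(fit$rSquared, 1)
  # hand-computed 4-point fit
  x <- c(0.1, 0.5, 0.8, 1.0)
  y <- c(0.12, 0.48, 0.83, 0.97)
  fit4 <- regressionUntransformed(data.frame(poolMaf = x, indivMaf = y))
  oracle <- olsOracle(x, y)
  expect_equal(fit4$slope, oracle$slope, tolerance = 1e-12)
  expect_equal(fit4$intercept, oracle$intercept, tolerance = 1e-12)
  expect_equal(fit4$rSquared, oracle$r2, tolerance = 1e-12)
  # constant response
  flat <- regressionUntransformed(data.frame(poolMaf = x,
                                             indivMaf = rep(0.5, 4)))
  expect_identical(flat$slope, 0)
  expect_identical(flat$rSquared, 0)
  # degenerate predictor
  expect_error(
    regressionUntransformed(data.frame(poolMaf = rep(0.5, 4), indivMaf = y)),
    "degenerate")
})

test_that("arcsine square-root transform maps [0,1] to [0, pi/2]", {
  expect_identical(arcsineTransform(0), 0)
  expect_equal(arcsineTransform(1), pi / 2)
  expect_equal(arcsineTransform(0.5), pi / 4)
  expect_error(arcsineTransform(1.2), "\\[0,1\\]")
  expect_error(arcsineTransform(-0.1), "\\[0,1\\]")
})

test_that("transformed regression p-value matches the slope t-test", {
  x <- c(0.05, 0.3, 0.55, 0.7, 0.95)
  y <- c(0.1, 0.25, 0.6, 0.65, 0.9)
  p <- regressionPTransformed(data.frame(poolMaf = x, indivMaf = y))
  oracle <- olsOracle(asin(sqrt(x)), asin(sqrt(y)))
  expect_equal(p, oracle$p, tolerance = 1e-12)
  # collinear transformed data: p numerically zero
  same <- data.frame(poolMaf = x, indivMaf = x)
  expect_lt(regressionPTransformed(same), 1e-12)
})

test_that("transformed regression p is uniform under independence", {
  set.seed(77)
  n <- 27L
  nRep <- 500L
  p <- vapply(seq_len(nRep), function(i) {
    regressionPTransformed(data.frame(poolMaf = runif(n),
                                      indivMaf = runif(n)))
  }, numeric(1))
  rej <- mean(p < 0.05)
  se <- sqrt(0.05 * 0.95 / nRep)
  expect_lt(abs(rej - 0.05), 3 * se)
})

test_that("paired t-test on transformed frequencies matches the formula", {
  same <- data.frame(poolMaf = c(0.2, 0.5, 0.9), indivMaf = c(0.2, 0.5, 0.9))
  tt <- pairedTTransformed(same)
  expect_identical(tt$statistic, 0)
  expect_identical(tt$p, 1)
  x <- c(0.15, 0.42, 0.61, 0.8, 0.97)
  y <- c(0.1, 0.47, 0.55, 0.86, 0.92)
  tt2 <- pairedTTransformed(data.frame(poolMaf = x, indivMaf = y))
  oracle <- pairedTOracle(asin(sqrt(x)) - asin(sqrt(y)))
  expect_equal(tt2$statistic, oracle$t, tolerance = 1e-12)
  expect_equal(tt2$p, oracle$p, tolerance = 1e-12)
  # constant nonzero difference: unbounded statistic, flagged
  shifted <- data.frame(poolMaf = c(0.3, 0.5, 0.7),
                        indivMaf = sin(asin(sqrt(c(0.3, 0.5, 0.7))) - 0.1)^2)
  expect_warning(ttInf <- pairedTTransformed(shifted), "zero-variance")
  expect_identical(ttInf$statistic, Inf)
  expect_identical(ttInf$p, 0)
})

test_that("mean absolute difference and its standard error", {
  zero <- data.frame(poolMaf = c(0.2, 0.8), indivMaf = c(0.2, 0.8))
  expect_identical(meanAbsDiff(zero)$mean, 0)
  expect_identical(meanAbsDiff(zero)$se, 0)
  two <- data.frame(poolMaf = c(0.52, 0.46), indivMaf = c(0.5, 0.5))
  mad2 <- meanAbsDiff(two)
  expect_equal(mad2$mean, 0.03)
  expect_equal(mad2$se, 0.01)
  # transcription oracle on simulated records
  run <- simulateValidationRun(seed = 21)
  d <- abs(run$records$poolMaf - run$records$indivMaf)
  madR <- meanAbsDiff(run$records)
  expect_equal(madR$mean, sum(d) / length(d))
  expect_equal(madR$se, sqrt(sum((d - mean(d))^2) / (length(d) - 1)) /
                 sqrt(length(d)))
})

test_that("coverage-effect correlation matches the product-moment formula", {
  prop <- data.frame(coverage = c(10, 20, 30, 40),
                     absDiff = c(0.01, 0.02, 0.03, 0.04))
  expect_equal(coverageEffect(prop)$r, 1)
  hand <- data.frame(coverage = c(60, 120, 200, 280),
                     absDiff = c(0.06, 0.02, 0.035, 0.01))
  ce <- coverageEffect(hand)
  oracle <- pearsonOracle(hand$coverage, hand$absDiff)
  expect_equal(ce$r, oracle$r, tolerance = 1e-12)
  expect_equal(ce$p, oracle$p, tolerance = 1e-12)
  flat <- data.frame(coverage = rep(100, 5), absDiff = runif(5))
  expect_warning(ceFlat <- coverageEffect(flat), "zero variance")
  expect_true(is.na(ceFlat$r))
})

test_that("the report emits the all-records and complete-only variants", {
  run <- simulateValidationRun(seed = 41, failureRate = 22 / 540)
  rep <- buildValidationReport(run$records)
  expect_identical(rep@all$n, 27L)
  expect_identical(rep@completeOnly$n, sum(run$records$complete))
  expect_lt(rep@completeOnly$n, 27L)
  # no failures: both variants agree
  repFull <- buildValidationReport(simulateValidationRun(seed = 42)$records)
  expect_identical(repFull@all[names(repFull@all) != "n"],
                   repFull@completeOnly[names(repFull@completeOnly) != "n"])
  # all records incomplete: complete-only variant reported unavailable
  recs <- simulateValidationRun(seed = 43)$records
  recs$complete <- FALSE
  repNone <- buildValidationReport(recs)
  expect_false(repNone@completeOnly$available)
  expect_true(repNone@all$available)
})

test_that("all statistics are invariant to record order", {
  run <- simulateValidationRun(seed = 51, failureRate = 22 / 540)
  set.seed(1)
  shuffled <- run$records[sample(nrow(run$records)), ]
  a <- buildValidationReport(run$records)
  b <- buildValidationReport(shuffled)
  expect_equal(a@all, b@all)
  expect_equal(a@completeOnly, b@completeOnly)
})
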