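test_that("genotype draws respect degenerate and binomial frequencies", {
  d <- PopulationDesign(nPopulations = 1, nIndividuals = 10, nSnps = 2,
                        trueMajorFreqs = matrix(c(1, 0), 1, 2))
  gm <- simulateGenotypes(d, seed = 1)
  expect_true(all(genotypeCalls(gm)[, 1] == "AA"))
  expect_true(all(genotypeCalls(gm)[, 2] == "TT"))

  # moments at p = 0.5: the equivalent of 10,000 replicate 20-diploid pools
  nInd <- 200000L
  d2 <- PopulationDesign(nPopulations = 1, nIndividuals = nInd, nSnps = 1,
                         trueMajorFreqs = matrix(0.5))
  gm2 <- simulateGenotypes(d2, seed = 2)
  freq <- individualMaf(genotypeCalls(gm2)[, 1], "A")
  se <- sqrt(0.5 * 0.5 / (2 * nInd))
  expect_lt(abs(freq - 0.5), 3 * se)
})

test_that("design validation rejects malformed frequency matrices", {
  expect_error(PopulationDesign(nPopulations = 3, nSnps = 9,
                                trueMajorFreqs = matrix(0.5, 2, 9)),
               "matrix")
  expect_error(PopulationDesign(nPopulations = 1, nSnps = 1,
                                trueMajorFreqs = matrix(1.2)),
               "\\[0,1\\]")
  expect_error(PopulationDesign(nPopulations = 1, nSnps = 1,
                                trueMajorFreqs = matrix(0.5),
                                majorBase = "A", minorBase = "A"),
               "differ")
})

test_that("noiseless pools reproduce the genotype frequencies exactly", {
  # all homozygous major: every read is the major base
  gm <- gmFromDosage(matrix(2L, 20, 3))
  pc <- simulatePoolCounts(gm, SequencingModel(coverage = 100, errorRate = 0,
                                               pipettingCV = 0), seed = 5)
  expect_true(all(SummarizedExperiment::assay(pc, "A") == 100L))
  expect_true(all(SummarizedExperiment::assay(pc, "T") == 0L))
  # equimolar truth equals the realized genotype frequency exactly
  dosage <- matrix(c(2L, 1L, 0L, 2L, 2L, 1L), 6, 4)
  gm2 <- gmFromDosage(dosage)
  pc2 <- simulatePoolCounts(gm2, SequencingModel(coverage = 50, errorRate = 0,
                                                 pipettingCV = 0), seed = 6)
  expect_equal(unname(S4Vectors::metadata(pc2)$truePoolFreqs[, 1]),
               unname(colMeans(dosage) / 2))
})

test_that("pooled major counts follow Binomial(coverage, pool frequency)", {
  nRep <- 2000L  # loci as i.i.d. replicates: all individuals heterozygous
  gm <- gmFromDosage(matrix(1L, 20, nRep))
  pc <- simulatePoolCounts(gm, SequencingModel(coverage = 100, errorRate = 0,
                                               pipettingCV = 0), seed = 7)
  a <- SummarizedExperiment::assay(pc, "A")[, 1]
  se <- sqrt(100 * 0.5 * 0.5 / nRep)
  expect_lt(abs(mean(a) - 50), 3 * se)
  expect_true(all(a + SummarizedExperiment::assay(pc, "T")[, 1] == 100L))
})

test_that("sequencing error biases the estimate by p(1-e) + (1-p)e/3", {
  nRep <- 2000L
  # realized pool frequency exactly 0.9: 16 hom major + 4 het of 20 diploids
  gm <- gmFromDosage(matrix(rep(c(2L, 1L), c(16, 4)), 20, nRep))
  e <- 0.01
  pc <- simulatePoolCounts(gm, SequencingModel(coverage = 100, errorRate = e,
                                               pipettingCV = 0), seed = 8)
  pHat <- mean(SummarizedExperiment::assay(pc, "A")[, 1]) / 100
  expected <- 0.9 * (1 - e) + (1 - 0.9) * e / 3
  se <- sqrt(expected * (1 - expected) / 100 / nRep)
  expect_lt(abs(pHat - expected), 3 * se)
})

test_that("the six pileup categories always sum to the drawn coverage", {
  gm <- gmFromDosage(matrix(c(2L, 1L, 0L, 1L), 4, 6), perPop = 2)
  model <- SequencingModel(coverage = 80, errorRate = 0.02, pipettingCV = 0.3,
                           nRate = 0.05, delRate = 0.02)
  pc <- simulatePoolCounts(gm, model, seed = 9)
  total <- Reduce(`+`, as.list(SummarizedExperiment::assays(pc)))
  expect_true(all(total == 80L))
  expect_true(any(SummarizedExperiment::assay(pc, "N") > 0))
})

test_that("a singleton carrier gives a true pool frequency of 2.5%", {
  gm <- gmFromDosage(matrix(rep(c(2L, 1L), c(19, 1)), 20, 1))
  pc <- simulatePoolCounts(gm, SequencingModel(coverage = 1000, errorRate = 0,
                                               pipettingCV = 0), seed = 10)
  expect_equal(unname(S4Vectors::metadata(pc)$truePoolFreqs[1, 1]), 0.975)
  expect_identical(singletonFrequency(20, 2), 0.025)
})

test_that("pipetting-weight variation perturbs the true pool frequency", {
  dosage <- matrix(rep(c(2L, 1L, 0L), c(7, 6, 7)), 20, 1)
  gm <- gmFromDosage(dosage)
  equim <- simulatePoolCounts(gm, SequencingModel(coverage = 50,
                                                  errorRate = 0,
                                                  pipettingCV = 0), seed = 11)
  noisy <- simulatePoolCounts(gm, SequencingModel(coverage = 50,
                                                  errorRate = 0,
                                                  pipettingCV = 0.5), seed = 11)
  p0 <- S4Vectors::metadata(equim)$truePoolFreqs[1, 1]
  p1 <- S4Vectors::metadata(noisy)$truePoolFreqs[1, 1]
  expect_equal(unname(p0), mean(dosage) / 2)
  expect_false(isTRUE(all.equal(p0, p1)))
  expect_true(p1 >= 0 && p1 <= 1)
})

test_that("genotyping dropout hits calls at the configured rate", {
  design <- studyDesign(seed = 3)
  gm <- simulateGenotypes(design, seed = 4)  # 60 x 9 = 540 calls
  expect_identical(genotypeCalls(simulateIndividualCalls(gm, 0, seed = 1)),
                   genotypeCalls(gm))
  rate <- 22 / 540
  nRep <- 1000L
  missing <- vapply(seq_len(nRep), function(i)
    sum(is.na(genotypeCalls(simulateIndividualCalls(gm, rate, seed = i)))),
    numeric(1))
  se <- sqrt(540 * rate * (1 - rate) / nRep)
  expect_lt(abs(mean(missing) - 22), 3 * se)
  expect_error(simulateIndividualCalls(gm, 1), "failureRate")
})

test_that("identical seeds give bit-identical simulator output", {
  design <- studyDesign(seed = 5)
  expect_identical(simulateGenotypes(design, seed = 42),
                   simulateGenotypes(design, seed = 42))
  gm <- simulateGenotypes(design, seed = 42)
  model <- SequencingModel(pipettingCV = 0.2)
  expect_identical(simulatePoolCounts(gm, model, seed = 43),
                   simulatePoolCounts(gm, model, seed = 43))
  expect_identical(genotypeCalls(simulateIndividualCalls(gm, 0.1, seed = 44)),
                   genotypeCalls(simulateIndividualCalls(gm, 0.1, seed = 44)))
  # and different seeds differ
  expect_false(identical(simulateGenotypes(design, seed = 42),
                         simulateGenotypes(design, seed = 43)))
})

test_that("design helpers compute singleton frequency and minimum coverage", {
  expect_identical(singletonFrequency(20, 2), 0.025)
  expect_identical(singletonFrequency(1, 1), 1)
  expect_identical(singletonFrequency(50, 2), 0.01)
  expect_identical(minimumRecommendedCoverage(20, 2), 40L)
  expect_identical(minimumRecommendedCoverage(1, 2), 2L)
  expect_identical(minimumRecommendedCoverage(96, 2), 192L)
  expect_error(singletonFrequency(0, 2), "nIndividuals")
  expect_error(minimumRecommendedCoverage(20, -1), "ploidy")
})
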