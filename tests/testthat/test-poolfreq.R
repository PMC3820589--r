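test_that("major/minor allele assignment follows combined counts with fixed tie-break", {
  expect_identical(defineMajorAllele(c(A = 300, T = 200)),
                   c(major = "A", minor = "T"))
  expect_identical(defineMajorAllele(c(A = 100, T = 100)),
                   c(major = "A", minor = "T"))
  expect_identical(defineMajorAllele(c(G = 5, C = 7, T = 1)),
                   c(major = "C", minor = "G"))
  expect_error(defineMajorAllele(c(A = 0, C = 0, G = 0, T = 0)), "nonzero")
  # combined definition can put a single pool's MAF below 0.5
  arr <- array(0L, c(1, 3, 4), dimnames = list(NULL, NULL, BASES4))
  arr[1, , "A"] <- c(10L, 80L, 80L)
  arr[1, , "T"] <- c(90L, 20L, 20L)
  st <- callSnps(pcFromArray(arr))
  expect_identical(snpInfo(st)$major, "A")
  expect_equal(unname(snpMaf(st)[1, ]), c(0.1, 0.8, 0.8))
})

test_that("pool frequency is the count ratio over the four nucleotides", {
  expect_identical(poolFrequency(c(A = 40), "A"), 1)
  expect_identical(poolFrequency(c(A = 96, C = 4), "A"), 0.96)
  expect_identical(poolFrequency(c(A = 1, T = 39), "A"), 0.025)
  # N and deletions never enter the denominator
  expect_identical(poolFrequency(c(A = 30, T = 10, N = 60, del = 10), "A"),
                   0.75)
  expect_error(poolFrequency(c(A = 0, C = 0), "A"), "coverage")
})

test_that("the filter thresholds act exactly as specified", {
  mk <- function(...) {
    rows <- list(...)
    arr <- array(0L, c(1, length(rows), 4))
    for (k in seq_along(rows)) arr[1, k, ] <- rows[[k]]
    pcFromArray(arr)
  }
  # minor count 3 < 4 (combined): rejected
  expect_identical(nrow(snpInfo(callSnps(mk(c(96L, 3L, 0L, 0L))))), 0L)
  # at exactly 4: retained
  expect_identical(nrow(snpInfo(callSnps(mk(c(96L, 4L, 0L, 0L))))), 1L)
  # symmetric site retained with per-pool frequency 0.5
  st <- callSnps(mk(c(50L, 0L, 0L, 50L), c(50L, 0L, 0L, 50L),
                    c(50L, 0L, 0L, 50L)))
  expect_identical(nrow(snpInfo(st)), 1L)
  expect_equal(unname(snpMaf(st)[1, ]), c(0.5, 0.5, 0.5))
  # one pool below the minimum coverage: rejected
  expect_identical(
    nrow(snpInfo(callSnps(mk(c(9L, 10L, 0L, 0L), c(50L, 50L, 0L, 0L),
                             c(50L, 50L, 0L, 0L))))), 0L)
  # one pool above the maximum: rejected
  expect_identical(
    nrow(snpInfo(callSnps(mk(c(300L, 200L, 0L, 0L), c(50L, 50L, 0L, 0L))))),
    0L)
  # monomorphic site: rejected even at high coverage
  expect_identical(nrow(snpInfo(callSnps(mk(c(200L, 0L, 0L, 0L))))), 0L)
  # empty input: empty table, not an error
  empty <- callSnps(pcFromArray(array(0L, c(0, 2, 4))))
  expect_identical(nrow(snpInfo(empty)), 0L)
})

test_that("per-pool minor-count scope is stricter than combined", {
  arr <- array(0L, c(1, 3, 4))
  arr[1, , 1] <- c(98L, 95L, 97L)  # A
  arr[1, , 4] <- c(2L, 5L, 3L)     # T: combined 10 >= 4, pool minima 2 < 4
  pc <- pcFromArray(arr)
  expect_identical(nrow(snpInfo(callSnps(pc))), 1L)
  expect_identical(
    nrow(snpInfo(callSnps(pc, FilterParams(minorScope = "per-pool")))), 0L)
})

test_that("retained sites match a brute-force transcription of the rules", {
  set.seed(101)
  nSites <- 300L
  nPools <- 3L
  arr <- array(0L, c(nSites, nPools, 4))
  for (i in seq_len(nSites)) {
    # mix of depths straddling both coverage bounds, mostly biallelic
    depth <- sample(c(10:30, 100, 380:420), nPools, replace = TRUE)
    p <- runif(1)
    for (k in seq_len(nPools)) {
      major <- rbinom(1, depth[k], p)
      rest <- depth[k] - major
      third <- rbinom(1, rest, 0.05)
      arr[i, k, ] <- c(major, rest - third, third, 0L)
    }
  }
  st <- suppressWarnings(callSnps(pcFromArray(arr)))
  expected <- vapply(seq_len(nSites), function(i)
    bruteKeepSite(arr[i, , , drop = TRUE]), logical(1))
  expect_identical(sort(rownames(snpInfo(st))),
                   sort(sprintf("site%04d", which(expected))))
  expect_gt(sum(expected), 0)
  expect_lt(sum(expected), nSites)
})

test_that("filters are monotone in their thresholds", {
  set.seed(202)
  arr <- array(rpois(100 * 2 * 4, lambda = c(60, 20, 2, 0)), c(4, 100, 2))
  arr <- aperm(arr, c(2, 3, 1))
  pc <- pcFromArray(arr)
  kept <- function(params) nrow(snpInfo(suppressWarnings(callSnps(pc, params))))
  base <- kept(FilterParams())
  expect_lte(kept(FilterParams(minMinorCount = 8)), base)
  expect_lte(kept(FilterParams(minCoverage = 60)), base)
  expect_lte(kept(FilterParams(maxCoverage = 90)), base)
  expect_gte(kept(FilterParams(minMinorCount = 1, minCoverage = 1,
                               maxCoverage = 10000)), base)
})

test_that("major and minor frequencies sum to 1 at strictly biallelic sites", {
  run <- simulateValidationRun(seed = 31, errorRate = 0)
  st <- run$snpTable
  minorCounts <- snpCoverage(st) - st@majorCounts
  expect_equal(snpMaf(st) + minorCounts / snpCoverage(st),
               matrix(1, nrow(snpMaf(st)), ncol(snpMaf(st))),
               ignore_attr = TRUE)
  expect_true(all(snpInfo(st)$extraCount == 0L))
  # maf * coverage reproduces the integer major count
  expect_equal(snpMaf(st) * snpCoverage(st), st@majorCounts + 0,
               ignore_attr = TRUE)
})

test_that("third-base reads are reported and excluded from denominators", {
  arr <- array(0L, c(1, 1, 4))
  arr[1, 1, ] <- c(60L, 35L, 5L, 0L)  # A, C, G counts
  expect_warning(st <- callSnps(pcFromArray(arr)), "third")
  expect_identical(snpInfo(st)$extraCount, 5L)
  expect_identical(unname(snpCoverage(st)[1, 1]), 95L)
  expect_equal(unname(snpMaf(st)[1, 1]), 60 / 95)
})
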