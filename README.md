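# poolseqval

Validation of Pool-Seq allele frequency estimates against individual
genotyping.

## The problem

Pool-Seq sequences one library made from equimolar DNA of many individuals,
so that at a biallelic SNP the read-count ratio estimates the population
allele frequency: with major-allele count `m` among `c = n_A + n_C + n_G +
n_T` nucleotide reads, the pooled estimate is `p̂ = m / c`. Whether `p̂` can
be trusted — and at what sequencing depth it breaks down — is the question a
validation study answers by genotyping the same individuals one by one and
comparing.

`poolseqval` is for researchers planning or validating pooled sequencing
designs. It provides:

* **SNP calling from pooled counts** — the PoPoolation2-style sync format
  (per-pool `A:T:C:G:N:del` count strings), filtered by a minimum minor
  allele count (default 4) and per-pool coverage bounds (default 20–400),
  with the major allele defined on counts combined across pools.
* **Concordance statistics** — per SNP × population, the pooled major
  allele frequency `x` versus the individual-based frequency `y`
  (major-allele copies over non-missing chromosomes): mean |x − y| ± SE,
  untransformed OLS `y = a + b·x` with R², the regression p-value and a
  paired t-test on arcsine-square-root transformed frequencies
  (`arcsin √p`), and the Pearson correlation of coverage with |x − y| —
  each computed over all records and over records untouched by genotyping
  failures.
* **Coverage resampling** — reads drawn without replacement (multivariate
  hypergeometric) down to each coverage `c` in a range, with the
  across-iteration mean ± SD of the mean frequency difference and
  regression R² per coverage, and the smallest coverage crossing a given
  accuracy threshold.
* **A synthetic-data generator** — Hardy–Weinberg genotypes, binomial read
  sampling with uniform substitution errors, gamma pipetting weights and
  genotyping dropout, emulating a design of 3 populations × 20 diploid
  individuals at 9 SNPs, so the entire pipeline runs and is tested without
  any external data.

## Worked example

Simulate the default emulated design, call SNPs, and validate:

```r
library(poolseqval)

design    <- studyDesign(seed = 1)          # 3 pops x 20 diploids, 9 SNPs
genotypes <- simulateGenotypes(design, seed = 2)
pools     <- simulatePoolCounts(genotypes, SequencingModel(), seed = 3)
snps      <- callSnps(pools)                # default filters: 4 / 20 / 400
called    <- simulateIndividualCalls(genotypes, failureRate = 22/540, seed = 4)
records   <- pairRecords(snps, called)      # 27 = 9 SNPs x 3 populations
buildValidationReport(records)
```

```
ValidationReport (pooled MAF = x, individual MAF = y)
  all records (n = 27): mean |diff| 0.0279 +/- 0.0054 SE; y = 0.953x + 0.034, R2 = 0.972
    p(regression, transformed) = 2.19e-20; paired t = -0.123, p = 0.903; r(coverage) = -0.436, p = 0.0232
  complete only (n = 10): mean |diff| 0.0192 +/- 0.0039 SE; y = 0.965x + 0.023, R2 = 0.995
    p(regression, transformed) = 3.05e-09; paired t = 0.833, p = 0.426; r(coverage) = -0.793, p = 0.0062
```

Read: pooled and individual frequencies differ by 2.8% on average, the
regression is close to the ideal 1:1 line (slope 0.95, R² 0.97) and highly
significant on the transformed scale, and the paired t-test finds no
systematic over- or underestimation (p = 0.90). Seventeen of the 27 records
were touched by at least one simulated genotyping failure; restricting to
the 10 complete records changes none of the conclusions.

How does accuracy decay with depth?

```r
curve <- coverageCurve(records, coverageRange = 1:55, nIterations = 1000,
                       seed = 5)
head(curve[, 1:5], 3)
coverageAtThreshold(curve, "mean_abs_diff", 0.05)
```

```
  coverage meanAbsDiffAvg meanAbsDiffSd rSquaredAvg rSquaredSd
1        1      0.3236906    0.03436092   0.2701119  0.1446990
2        2      0.2278570    0.02894062   0.4111855  0.1421917
3        3      0.1826497    0.02623943   0.5063195  0.1294466
[1] 44
```

A single read per pool gets the frequency wrong by 32 percentage points on
average; by 44× the mean difference drops below 5%. (The absolute level
depends on the simulated design — here the true frequencies span the whole
unit interval and the reference pools are themselves finite — so the curve's
shape, not its crossings, is the transferable result.)

The same workflow is available from the shell via the thin CLI in
`inst/scripts/poolseqval` (subcommands `simulate`, `call-freqs`,
`validate`, `resample-coverage`), which reads/writes sync, TSV and JSON
files and takes a YAML config; see `vignettes/poolseq-validation.Rmd` for
the full model description.

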