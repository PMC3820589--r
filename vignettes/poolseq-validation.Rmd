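---
title: "Validating Pool-Seq allele frequencies: models and methods"
author: "poolseqval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating Pool-Seq allele frequencies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolseqval)
```

## The problem

Pool-Seq estimates population allele frequencies by sequencing a single
library made from equimolar DNA of many individuals: at a biallelic SNP the
fraction of reads carrying an allele estimates that allele's frequency among
the pooled chromosomes. The approach is attractive for population genomics —
one library per population instead of dozens — but it rests on the
assumption that read-count ratios track allele frequencies faithfully. This
package implements the full machinery needed to test that assumption against
per-individual genotyping of the same individuals, and to ask how the answer
degrades as sequencing coverage drops.

Four stages make up the pipeline:

1. **Synthetic data** (`studyDesign()`, `simulateGenotypes()`,
   `simulatePoolCounts()`, `simulateIndividualCalls()`) — generate
   individual genotypes, pooled read counts and individual genotyping calls
   with the statistical structure of a pooled validation study.
2. **SNP calling** (`callSnps()`) — identify SNPs from synchronized pooled
   pileup counts with minor-allele-count and coverage filters, and compute
   per-pool major-allele frequencies.
3. **Concordance statistics** (`pairRecords()`,
   `buildValidationReport()`) — pair pooled with individual-based
   frequencies per SNP × population and quantify their agreement.
4. **Coverage resampling** (`coverageCurve()`, `coverageAtThreshold()`) —
   downsample reads without replacement to each coverage in a range and
   summarize accuracy per coverage level.

## The generative model

### Genotypes

A `PopulationDesign` fixes the number of populations (one pool each), the
number of individuals per pool `n`, the ploidy `z`, and a matrix of true
major-allele frequencies `p[k, j]` per population `k` and SNP `j`. Genotypes
are drawn under Hardy–Weinberg proportions: the major-allele dosage of an
individual is Binomial(`z`, `p[k, j]`). Hardy–Weinberg is the natural
neutral stand-in for unrelated individuals sampled from an outcrossing
population; departures (inbreeding, structure) can be studied by passing a
hand-constructed `GenotypeMatrix` to the downstream simulators, which never
re-draw genotypes.

The *effective pool size* is `n * z`, the number of chromosomes in the pool.
Two design helpers encode its consequences: `singletonFrequency(n, z)` =
`1/(n*z)` is the within-pool frequency of an allele carried once by one
heterozygote (2.5% for 20 diploids), and `minimumRecommendedCoverage(n, z)`
= `n*z` is the depth below which some chromosomes cannot all be represented
even in the best case. Singletons are reliably detectable only when the
sequencing error rate sits well below `1/(n*z)`.

### Pooled reads

`simulatePoolCounts()` models three error processes, each switchable:

* **Pipetting/quantification error.** Individual DNA contributions are
  gamma-distributed weights with mean 1 and coefficient of variation
  `pipettingCV`; the true pool frequency is the weight-weighted mean of the
  individual dosages divided by the ploidy. The gamma family was chosen
  because contributions must be positive and the CV is the single quantity a
  lab can state; `pipettingCV = 0` bypasses sampling entirely and is the
  default, since careful fluorometric quantification makes the equimolar
  assumption reasonable and no specific magnitude can be defended a priori.
* **Coverage.** Per pool and SNP, either fixed or uniform on an integer
  range. The default `[55, 284]` spans the depth range typical of deeply
  sequenced validation pools.
* **Sequencing error.** Each read reports the true base with probability
  `1 - e` and otherwise one of the three other nucleotides uniformly
  (`e/3` each). The default `e = 0.01` is a conservative bound for
  quality-trimmed (Q20) Illumina data. Under this model the expected
  estimated frequency of an allele at true frequency `p` is
  `p(1 - e) + (1 - p) e/3`, a contraction toward intermediate frequencies
  that is negligible at `e` below 1% but visible in the simulator's moments
  (and tested there). N and deletion pileup categories are produced only
  when `nRate`/`delRate` are explicitly configured, because quality
  filtering upstream of counting removes them in practice; they never enter
  coverage or frequency denominators.

### Individual genotyping

`simulateIndividualCalls()` replaces each call independently by a missing
value with probability `failureRate` (default 22/540 ≈ 4.1%, a realistic
assay dropout rate). Calls that succeed are exact: targeted genotyping
assays are treated as ground truth, so pooled-vs-individual differences in
the simulation have exactly two sources — read sampling and sequencing
error.

### What the generator does not emulate

No read-level artifacts (FASTQ, quality scores), no mapping or reference
bias, no indels, no linkage between loci, no batch effects between pools.
Passing tests therefore demonstrate the statistical machinery under the
declared sampling model, not robustness to mapping artifacts in real data.

## SNP identification

`callSnps()` retains a site iff

* every pool's coverage — defined as the four-nucleotide count sum — lies
  within `[minCoverage, maxCoverage]` (defaults 20 and 400: a floor for
  frequency precision, a ceiling against collapsed repeats), and
* at least two bases have nonzero counts summed across pools and the
  second-most-frequent base's combined count is at least `minMinorCount`
  (default 4, guarding against sequencing errors masquerading as SNPs).

The minor-count rule is applied to counts combined across pools, matching
how pooled SNP callers accumulate evidence over populations; since the
wording of such thresholds is sometimes ambiguous, a stricter per-pool
variant is available via `FilterParams(minorScope = "per-pool")`.

The major allele is the base with the highest combined count across all
pools, ties broken by the fixed order A < C < G < T; a single pool's
major-allele frequency can therefore fall below 0.5. Sites where a third or
fourth base carries reads are retained if the top-two rule passes; the extra
counts are reported (`extraCount`) and excluded from frequency denominators,
with a warning. Consequently the `SnpTable` reports per-pool coverage as the
biallelic (major + minor) sum — the exact denominator of the reported
frequency, so `maf * coverage` reproduces the integer major count — while
the filter bounds are applied to the four-base sum. The standalone
`poolFrequency()` helper keeps the generic definition (denominator = all
four nucleotide counts).

## Concordance statistics

`pairRecords()` forms one record per retained SNP × population. The
individual-based frequency uses pairwise deletion: failed calls drop out of
numerator and denominator within a record. Each record carries a
completeness flag, and `buildValidationReport()` computes every statistic
twice — over all records and over complete records only — which brackets
the influence of missing genotype calls.

With pooled frequency `x` and individual frequency `y`:

* `regressionUntransformed()` — OLS of `y` on `x` on the raw scale. Slope,
  intercept and R² are reported untransformed because the question is the
  deviation from the ideal 1:1 line in frequency units.
* `regressionPTransformed()` — the regression p-value is computed after
  arcsine-square-root transforming *both* variables
  (`arcsineTransform()`, the variance-stabilizing transform for
  proportions), as the t reference distribution for the slope is defensible
  only with stabilized variances.
* `pairedTTransformed()` — a two-sided paired t-test on the transformed
  frequencies asks whether pooling systematically over- or underestimates.
* `meanAbsDiff()` — mean of `|x - y|` with SE = sample SD (n − 1
  denominator) over √n.
* `coverageEffect()` — Pearson correlation of coverage with `|x - y|`,
  testing for a residual depth effect within the observed coverage range.

Three genuinely open choices were settled as follows. The regression treats
the pooled frequency as predictor and the individual frequency as response;
all reported quantities (slope near 1, R², the symmetric paired t) are
robust to the orientation, and the report records it. Both variables are
transformed for the p-value-bearing tests (transforming only the response
would stabilize residual variance but leave the predictor on a different
scale). All p-values are two-sided. When a SNP table derived from a sync
file (which carries no pool labels) meets a genotype table whose populations
are named, pools are paired to populations by position, with a message.

## Coverage resampling

`coverageCurve()` downsamples each record's observed base counts to each
target coverage `c` *without replacement* — a multivariate hypergeometric
draw, implemented by sequential univariate hypergeometric draws and verified
against exact `dhyper` marginals. Without-replacement sampling is the
operation that corresponds to discarding sequenced reads, is exactly
unbiased for the observed frequency at every `c`, and collapses to zero
variance as `c` approaches the record's full depth; sampling with
replacement would have none of these properties, and requesting more reads
than were observed is an error rather than a silent fallback.

Per coverage and iteration, two summaries are taken against the
individual-based frequencies: the mean absolute frequency difference, and
the R² of the untransformed regression (computed as the squared Pearson
correlation, the identical quantity, vectorized over iterations). Per
coverage the across-iteration mean and SD of both are reported. The per-
iteration mean difference averages *absolute* differences: an accuracy curve
built from signed differences would cancel symmetric errors and go to zero
at any coverage. Records are processed in a fixed sorted order from a single
seeded stream, so a configuration plus seed reproduces the curve bit for
bit. At `c = 1` a downsampled frequency is 0 or 1, and the expected absolute
difference has the closed form `p(1-q) + (1-p)q` per record — one of the
oracle checks in the test suite. Iterations in which the downsampled
frequencies are constant across records leave the regression undefined;
such iterations are excluded from the R² average (they essentially require
`c = 1` with extreme frequencies everywhere).

`coverageAtThreshold()` reports the smallest coverage whose averaged metric
crosses a threshold (below, for the mean difference; at-or-above, for R²);
it scans the averaged curve and does not require the condition to hold for
every larger coverage.

## Numerical and testing choices

* Counts are integers end to end; frequencies become doubles only at the
  ratio. Filter decisions never involve floating-point comparisons.
* Zero-variance inputs are handled explicitly: a constant response gives
  slope 0 and R² 0; a constant predictor or zero-variance difference vector
  is an error or a flagged unbounded statistic, never a silent NaN.
* All simulators accept a `seed` and restore the caller's RNG state, so
  seeded calls compose without perturbing surrounding randomness.
* The test suite runs the full design at reduced problem sizes chosen to
  keep Monte-Carlo assertions sharp: moment checks use 2,000–200,000
  replicate draws with 3-standard-error bands; filter equivalence runs 1,000
  randomized tables against a brute-force transcription of the rules;
  parameter recovery runs the complete pipeline over 200 seeds (slope within
  [0.9, 1.1], R² at least 0.9, and a Kolmogorov–Smirnov check that the
  paired-t p-value is uniform when no systematic bias exists); the
  resampling checks use 1,000 iterations over coverages 1–55 on 27 records.
* In the resampling acceptance check the records are simulated at a fixed
  55× so that the top of the coverage range equals every record's full
  depth, making the zero-variance limit exact. With the reference pools
  themselves only 55× deep, the absolute accuracy at a given coverage is
  poorer than what deeply sequenced real pools would show; the curve's
  *shape* (monotone decline of the mean difference, monotone rise of R²) is
  what the tests assert, and threshold crossings are reported, not asserted.

## Limitations

* The individual-based reference is treated as exact; genotyping errors in
  the reference would appear as Pool-Seq inaccuracy.
* The sequencing error model is a uniform substitution with a single rate;
  real error spectra are base- and context-dependent.
* Frequencies are estimated by the plain count ratio; no model-based
  (e.g. likelihood) frequency estimator is included.
* Sites with more than two segregating bases are handled by the top-two
  rule; a true tri-allelic SNP is reported but its third allele is not
  followed.
* No population-differentiation statistics are computed; the package
  validates frequencies, it does not analyze them.
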