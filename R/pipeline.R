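#' @include AllClasses.R
NULL

#' Default run configuration
#'
#' All pipeline parameters with their defaults: the emulated design (3
#' populations x 20 diploid individuals, 9 SNPs, coverage uniform on
#' [55, 284], sequencing error rate 0.01, equimolar pooling, genotyping
#' failure rate 22/540), the SNP filters (minor count 4, coverage within
#' [20, 400]) and the resampling settings (coverages 1-55, 1000 iterations).
#'
#' @return Named list of defaults.
#' @export
defaultRunConfig <- function() {
  list(
    seed = 1L,
    out_dir = ".",
    # simulate
    n_populations = 3L,
    n_individuals = 20L,
    ploidy = 2L,
    n_snps = 9L,
    freqs = "random",
    coverage = c(55L, 284L),
    error_rate = 0.01,
    pipetting_cv = 0,
    failure_rate = 22 / 540,
    # call-freqs
    min_minor_count = 4L,
    min_coverage = 20L,
    max_coverage = 400L,
    minor_scope = "combined",
    # resample-coverage
    resample_min = 1L,
    resample_max = 55L,
    iterations = 1000L,
    # file inputs (subcommand-dependent)
    sync = NULL,
    genotypes = NULL,
    snp_table = NULL,
    records = NULL)
}

#' Resolve a run configuration
#'
#' Layered configuration: package defaults, overridden by a YAML config file
#' (if given), overridden by explicit values.
#'
#' @param configFile optional path to a YAML file with configuration keys.
#' @param overrides named list of explicit overrides (e.g. from CLI flags).
#' @return The resolved configuration list.
#' @export
loadRunConfig <- function(configFile = NULL, overrides = list()) {
  cfg <- defaultRunConfig()
  if (!is.null(configFile)) {
    if (!file.exists(configFile))
      stop(sprintf("config file not found: %s", configFile))
    fileCfg <- yaml::read_yaml(configFile)
    unknown <- setdiff(names(fileCfg), names(cfg))
    if (length(unknown))
      stop(sprintf("unknown config key(s): %s",
                   paste(unknown, collapse = ", ")))
    cfg <- modifyList(cfg, fileCfg)
  }
  overrides <- overrides[!vapply(overrides, is.null, logical(1))]
  cfg <- modifyList(cfg, overrides)
  cfg
}

.logConfig <- function(subcommand, cfg, quiet) {
  if (quiet) return(invisible())
  shown <- cfg[!vapply(cfg, is.null, logical(1))]
  message(sprintf("[poolseqval] %s with: %s", subcommand,
                  paste(sprintf("%s=%s", names(shown),
                                vapply(shown, function(v)
                                  paste(format(v), collapse = ","),
                                  character(1))),
                        collapse = " ")))
}

.designFromConfig <- function(cfg) {
  if (identical(cfg$freqs, "random"))
    studyDesign(seed = cfg$seed, nPopulations = cfg$n_populations,
                nIndividuals = cfg$n_individuals, ploidy = cfg$ploidy,
                nSnps = cfg$n_snps)
  else
    PopulationDesign(nPopulations = cfg$n_populations,
                     nIndividuals = cfg$n_individuals, ploidy = cfg$ploidy,
                     nSnps = cfg$n_snps,
                     trueMajorFreqs = matrix(unlist(cfg$freqs),
                                             cfg$n_populations, cfg$n_snps,
                                             byrow = TRUE))
}

#' Run one pipeline stage
#'
#' Drives the four stages of the validation workflow, reading and writing
#' the package's file formats:
#' \describe{
#'   \item{simulate}{emulate the study design: writes the true genotypes
#'     (\code{genotypes_true.tsv}), the genotyping calls with dropout
#'     (\code{genotypes_called.tsv}), the pooled counts (\code{pools.sync})
#'     and the simulation truth (\code{truth.json}).}
#'   \item{call-freqs}{apply the SNP filters to a sync file: writes
#'     \code{snp_table.tsv}.}
#'   \item{validate}{pair a SNP table with genotype calls and compute the
#'     concordance statistics: writes \code{validation.json} and
#'     \code{records.tsv}.}
#'   \item{resample-coverage}{downsampling accuracy analysis over a record
#'     table: writes \code{coverage_curve.tsv} and
#'     \code{coverage_curve.json}.}
#' }
#' All randomness flows from \code{config$seed}; running a stage twice with
#' the same configuration produces byte-identical outputs.
#'
#' @param subcommand one of \code{"simulate"}, \code{"call-freqs"},
#'   \code{"validate"}, \code{"resample-coverage"}.
#' @param config configuration list (see [defaultRunConfig()],
#'   [loadRunConfig()]); missing keys take their defaults.
#' @param quiet suppress the resolved-configuration log line.
#' @return Named character vector of the files written, invisibly.
#' @examples
#' out <- runPipeline("simulate",
#'                    list(out_dir = tempdir(), seed = 7, coverage = 80),
#'                    quiet = TRUE)
#' @export
runPipeline <- function(subcommand = c("simulate", "call-freqs", "validate",
                                       "resample-coverage"),
                        config = list(), quiet = FALSE) {
  subcommand <- match.arg(subcommand)
  cfg <- loadRunConfig(overrides = config)
  .logConfig(subcommand, cfg, quiet)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(cfg$out_dir, f)
  switch(subcommand,
    "simulate" = {
      design <- .designFromConfig(cfg)
      # derived sub-seeds keep the three stages independently reproducible
      gm <- simulateGenotypes(design, seed = cfg$seed)
      model <- SequencingModel(coverage = cfg$coverage,
                               errorRate = cfg$error_rate,
                               pipettingCV = cfg$pipetting_cv)
      pc <- simulatePoolCounts(gm, model, seed = cfg$seed + 1)
      called <- simulateIndividualCalls(gm, cfg$failure_rate,
                                        seed = cfg$seed + 2)
      writeGenotypes(gm, path("genotypes_true.tsv"))
      writeGenotypes(called, path("genotypes_called.tsv"))
      writeSync(pc, path("pools.sync"))
      jsonlite::write_json(
        list(schema_version = .SCHEMA_VERSION, seed = cfg$seed,
             n_populations = design@nPopulations,
             n_individuals = design@nIndividuals,
             ploidy = design@ploidy, n_snps = design@nSnps,
             effective_pool_size = design@nIndividuals * design@ploidy,
             loci = design@lociNames,
             major_base = design@majorBase, minor_base = design@minorBase,
             true_major_freqs = design@trueMajorFreqs,
             true_pool_freqs = metadata(pc)$truePoolFreqs,
             error_rate = cfg$error_rate, pipetting_cv = cfg$pipetting_cv,
             failure_rate = cfg$failure_rate),
        path("truth.json"), auto_unbox = TRUE, digits = NA)
      invisible(c(genotypes_true = path("genotypes_true.tsv"),
                  genotypes_called = path("genotypes_called.tsv"),
                  sync = path("pools.sync"), truth = path("truth.json")))
    },
    "call-freqs" = {
      if (is.null(cfg$sync))
        stop("'sync' input path is required for call-freqs")
      pc <- readSync(cfg$sync)
      params <- FilterParams(minMinorCount = cfg$min_minor_count,
                             minCoverage = cfg$min_coverage,
                             maxCoverage = cfg$max_coverage,
                             minorScope = cfg$minor_scope)
      st <- callSnps(pc, params)
      writeSnpTable(st, path("snp_table.tsv"))
      invisible(c(snp_table = path("snp_table.tsv")))
    },
    "validate" = {
      if (is.null(cfg$snp_table) || is.null(cfg$genotypes))
        stop("'snp_table' and 'genotypes' input paths are required for validate")
      st <- readSnpTable(cfg$snp_table)
      gm <- readGenotypes(cfg$genotypes)
      records <- pairRecords(st, gm)
      report <- buildValidationReport(records)
      writeComparisonRecords(records, path("records.tsv"))
      writeValidationReport(report, path("validation.json"))
      invisible(c(records = path("records.tsv"),
                  validation = path("validation.json")))
    },
    "resample-coverage" = {
      if (is.null(cfg$records))
        stop("'records' input path is required for resample-coverage")
      records <- readComparisonRecords(cfg$records)
      curve <- coverageCurve(records,
                             coverageRange = cfg$resample_min:cfg$resample_max,
                             nIterations = cfg$iterations, seed = cfg$seed)
      writeCoverageCurve(curve, path("coverage_curve.tsv"))
      writeCurveSummary(curve, path("coverage_curve.json"))
      invisible(c(curve = path("coverage_curve.tsv"),
                  summary = path("coverage_curve.json")))
    })
}
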