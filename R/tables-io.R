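#' @include AllClasses.R
NULL

.SCHEMA_VERSION <- "1"

# Commented key=value header lines make the TSV outputs self-describing.
.writeCommentedTable <- function(df, file, comments) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste0("# ", comments), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

.readCommentedTable <- function(file, ...) {
  read.table(file, sep = "\t", header = TRUE, comment.char = "#",
             check.names = FALSE, stringsAsFactors = FALSE, ...)
}

#' Read and write genotype tables
#'
#' Tab-separated genotype tables have columns \code{sample},
#' \code{population}, then one column per locus holding allele-call strings
#' (e.g. \code{"AT"}); the missing-call marker is configurable and defaults
#' to \code{"NN"}.
#'
#' @param x a [GenotypeMatrix-class].
#' @param file path to read from / write to.
#' @param missing string marking a failed call.
#' @param ploidy ploidy to assume on read; inferred from the first
#'   non-missing call when \code{NULL}.
#' @param majorBase,minorBase optional per-locus allele declarations for the
#'   object built on read.
#' @return \code{writeGenotypes} returns \code{file} invisibly;
#'   \code{readGenotypes} returns a [GenotypeMatrix-class].
#' @export
writeGenotypes <- function(x, file, missing = "NN") {
  stopifnot(is(x, "GenotypeMatrix"))
  cl <- x@calls
  cl[is.na(cl)] <- missing
  df <- data.frame(sample = rownames(cl), population = as.character(x@population),
                   cl, check.names = FALSE, stringsAsFactors = FALSE)
  .writeCommentedTable(df, file, c(
    sprintf("poolseqval genotype table v%s", .SCHEMA_VERSION),
    sprintf("ploidy=%d missing=%s", x@ploidy, missing)))
}

#' @rdname writeGenotypes
#' @export
readGenotypes <- function(file, missing = "NN", ploidy = NULL,
                          majorBase = character(), minorBase = character()) {
  df <- .readCommentedTable(file, colClasses = "character")
  if (!all(c("sample", "population") %in% names(df)))
    stop("genotype table must have 'sample' and 'population' columns")
  loci <- setdiff(names(df), c("sample", "population"))
  cl <- as.matrix(df[, loci, drop = FALSE])
  rownames(cl) <- df$sample
  cl[cl == missing] <- NA_character_
  if (is.null(ploidy)) {
    nonMiss <- cl[!is.na(cl)]
    ploidy <- if (length(nonMiss)) nchar(nonMiss[1]) else 2L
  }
  GenotypeMatrix(cl, population = df$population, ploidy = ploidy,
                 majorBase = majorBase, minorBase = minorBase)
}

#' Read and write SNP tables
#'
#' The SNP-table TSV carries one row per called SNP: locus identifier,
#' chromosome, position, reference, major and minor base, excluded
#' third/fourth-base count, then per pool its (biallelic) coverage, major
#' allele frequency and an \code{A:C:G:T} base-count string. The filter
#' parameters are recorded in commented header lines so the file is
#' self-describing, and \code{readSnpTable} restores a full
#' [SnpTable-class].
#'
#' @param x a [SnpTable-class].
#' @param file path to read from / write to.
#' @return \code{writeSnpTable} returns \code{file} invisibly;
#'   \code{readSnpTable} a [SnpTable-class].
#' @export
writeSnpTable <- function(x, file) {
  stopifnot(is(x, "SnpTable"))
  info <- as.data.frame(x@info)
  pools <- colnames(x@coverage)
  df <- data.frame(locus = rownames(x@info), info, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[names(df) == "extraCount"] <- "extra_count"
  for (k in seq_along(pools)) {
    df[[paste0("cov_", pools[k])]] <- x@coverage[, k]
    df[[paste0("maf_", pools[k])]] <- x@maf[, k]
    df[[paste0("counts_", pools[k])]] <- apply(
      x@poolBaseCounts[, k, , drop = FALSE], 1,
      function(v) paste(v, collapse = ":"))
  }
  p <- x@params
  .writeCommentedTable(df, file, c(
    sprintf("poolseqval snp table v%s", .SCHEMA_VERSION),
    sprintf("minMinorCount=%d minCoverage=%d maxCoverage=%d minorScope=%s",
            p@minMinorCount, p@minCoverage, p@maxCoverage, p@minorScope),
    "counts_* columns are A:C:G:T"))
}

#' @rdname writeSnpTable
#' @export
readSnpTable <- function(file) {
  hdr <- grep("^#", readLines(file, n = 10L), value = TRUE)
  params <- FilterParams()
  pLine <- grep("minMinorCount=", hdr, value = TRUE)
  if (length(pLine)) {
    kv <- regmatches(pLine[1],
                     gregexpr("[A-Za-z]+=[^ ]+", pLine[1]))[[1]]
    vals <- setNames(sub(".*=", "", kv), sub("=.*", "", kv))
    params <- FilterParams(
      minMinorCount = as.integer(vals["minMinorCount"]),
      minCoverage = as.integer(vals["minCoverage"]),
      maxCoverage = as.integer(vals["maxCoverage"]),
      minorScope = unname(vals["minorScope"]))
  }
  df <- .readCommentedTable(file)
  pools <- sub("^cov_", "", grep("^cov_", names(df), value = TRUE))
  n <- nrow(df)
  cov <- maf <- majorCounts <- matrix(0, n, length(pools),
                                      dimnames = list(df$locus, pools))
  arr <- array(0L, c(n, length(pools), 4),
               dimnames = list(df$locus, pools, .BASES))
  for (k in seq_along(pools)) {
    cov[, k] <- df[[paste0("cov_", pools[k])]]
    maf[, k] <- df[[paste0("maf_", pools[k])]]
    cstr <- strsplit(as.character(df[[paste0("counts_", pools[k])]]), ":",
                     fixed = TRUE)
    for (i in seq_len(n)) arr[i, k, ] <- as.integer(cstr[[i]])
    majorCounts[, k] <- vapply(seq_len(n), function(i)
      arr[i, k, match(df$major[i], .BASES)], numeric(1))
  }
  combined <- apply(arr, c(1, 3), sum)
  dim(combined) <- c(n, 4)
  colnames(combined) <- .BASES
  storage.mode(cov) <- "integer"
  storage.mode(majorCounts) <- "integer"
  new("SnpTable",
      info = DataFrame(chrom = df$chrom, pos = as.integer(df$pos),
                       ref = df$ref, major = df$major, minor = df$minor,
                       extraCount = as.integer(df$extra_count),
                       row.names = df$locus),
      coverage = cov, maf = maf, majorCounts = majorCounts,
      combinedCounts = combined, poolBaseCounts = arr, params = params)
}

#' Read and write comparison-record tables
#'
#' Flat TSV of the per-SNP, per-population comparison records, including the
#' four base-count columns needed by the coverage-resampling analysis.
#'
#' @param records comparison records from [pairRecords()].
#' @param file path to read from / write to.
#' @return \code{writeComparisonRecords} returns \code{file} invisibly;
#'   \code{readComparisonRecords} the records \code{data.frame}.
#' @export
writeComparisonRecords <- function(records, file) {
  .writeCommentedTable(records, file, c(
    sprintf("poolseqval comparison records v%s", .SCHEMA_VERSION)))
}

#' @rdname writeComparisonRecords
#' @export
readComparisonRecords <- function(file) {
  df <- .readCommentedTable(file)
  if ("complete" %in% names(df))
    df$complete <- as.logical(df$complete)
  df
}

#' Write a validation report as JSON
#'
#' @param report a [ValidationReport-class].
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
writeValidationReport <- function(report, file) {
  stopifnot(is(report, "ValidationReport"))
  out <- list(schema_version = .SCHEMA_VERSION,
              orientation = report@orientation,
              n_records = nrow(report@records),
              all = report@all,
              complete_only = report@completeOnly)
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(file)
}

#' Write a coverage curve and its threshold summary
#'
#' \code{writeCoverageCurve} writes the per-coverage averages as TSV;
#' \code{writeCurveSummary} writes a JSON summary with the smallest
#' coverages crossing the requested accuracy thresholds (by default a 5%
#' mean frequency difference and regression R-squared of 0.95 and 0.99).
#'
#' @param curve a curve from [coverageCurve()].
#' @param file output path.
#' @param diffThreshold mean-absolute-difference threshold (frequency
#'   units).
#' @param r2Thresholds R-squared thresholds.
#' @return \code{file}, invisibly.
#' @export
writeCoverageCurve <- function(curve, file) {
  .writeCommentedTable(curve, file, c(
    sprintf("poolseqval coverage curve v%s", .SCHEMA_VERSION)))
}

#' @rdname writeCoverageCurve
#' @export
writeCurveSummary <- function(curve, file, diffThreshold = 0.05,
                              r2Thresholds = c(0.95, 0.99)) {
  crossings <- c(
    setNames(list(coverageAtThreshold(curve, "mean_abs_diff", diffThreshold)),
             sprintf("mean_abs_diff_below_%g", diffThreshold)),
    setNames(lapply(r2Thresholds, function(th)
      coverageAtThreshold(curve, "r_squared", th)),
      sprintf("r_squared_at_least_%g", r2Thresholds)))
  out <- list(schema_version = .SCHEMA_VERSION,
              n_coverages = nrow(curve),
              n_iterations = curve$nIterations[1],
              threshold_crossings = crossings)
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(file)
}
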