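#' @include AllClasses.R
NULL

#' @export
setGeneric("poolCoverage", function(x, ...) standardGeneric("poolCoverage"))

#' @export
setGeneric("callSnps", function(x, params = FilterParams(), ...)
  standardGeneric("callSnps"))

#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))

#' @export
setGeneric("populationLabels", function(x) standardGeneric("populationLabels"))

#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))

#' @export
setGeneric("snpMaf", function(x) standardGeneric("snpMaf"))

#' @export
setGeneric("snpCoverage", function(x) standardGeneric("snpCoverage"))

#' Accessors
#'
#' \code{genotypeCalls} returns the individuals x loci character matrix of a
#' [GenotypeMatrix-class]; \code{populationLabels} its population factor.
#' \code{snpInfo}, \code{snpMaf} and \code{snpCoverage} return the locus
#' annotation, the per-pool major-allele frequency matrix and the per-pool
#' (biallelic) coverage matrix of a [SnpTable-class]. \code{poolCoverage}
#' returns the sites x pools four-nucleotide coverage of a
#' [PoolCounts-class].
#'
#' @param x the object.
#' @param ... unused.
#' @return See description.
#' @name accessors
#' @aliases genotypeCalls populationLabels snpInfo snpMaf snpCoverage
#'   poolCoverage
NULL

#' @rdname accessors
setMethod("genotypeCalls", "GenotypeMatrix", function(x) x@calls)

#' @rdname accessors
setMethod("populationLabels", "GenotypeMatrix", function(x) x@population)

#' @rdname accessors
setMethod("snpInfo", "SnpTable", function(x) x@info)

#' @rdname accessors
setMethod("snpMaf", "SnpTable", function(x) x@maf)

#' @rdname accessors
setMethod("snpCoverage", "SnpTable", function(x) x@coverage)

#' @rdname accessors
setMethod("poolCoverage", "PoolCounts", function(x, ...) {
  assay(x, "A") + assay(x, "T") + assay(x, "C") + assay(x, "G")
})
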