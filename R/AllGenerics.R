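#' Accessors for PhagePopulation
#'
#' @param x a [PhagePopulation-class].
#' @return \code{genomes()} returns a named [Biostrings::DNAStringSet];
#'   \code{geneAnnotations()} a [GenomicRanges::GRanges];
#'   \code{trueClusters()} a named character vector of cluster labels;
#'   \code{moduleLayout()} a data.frame of module occurrences per genome;
#'   \code{appliedEvents()} a data.frame of recorded rearrangement events;
#'   \code{gcTargets()} a named numeric vector of target G+C fractions.
#' @name PhagePopulation-accessors
#' @aliases genomes geneAnnotations trueClusters moduleLayout appliedEvents
#'   gcTargets
NULL

#' @rdname PhagePopulation-accessors
#' @export
setGeneric("genomes", function(x) standardGeneric("genomes"))
#' @rdname PhagePopulation-accessors
#' @export
setGeneric("geneAnnotations", function(x) standardGeneric("geneAnnotations"))
#' @rdname PhagePopulation-accessors
#' @export
setGeneric("trueClusters", function(x) standardGeneric("trueClusters"))
#' @rdname PhagePopulation-accessors
#' @export
setGeneric("moduleLayout", function(x) standardGeneric("moduleLayout"))
#' @rdname PhagePopulation-accessors
#' @export
setGeneric("appliedEvents", function(x) standardGeneric("appliedEvents"))
#' @rdname PhagePopulation-accessors
#' @export
setGeneric("gcTargets", function(x) standardGeneric("gcTargets"))

#' @rdname PhagePopulation-accessors
setMethod("genomes", "PhagePopulation", function(x) x@genomes)
#' @rdname PhagePopulation-accessors
setMethod("geneAnnotations", "PhagePopulation", function(x) x@genes)
#' @rdname PhagePopulation-accessors
setMethod("trueClusters", "PhagePopulation", function(x) x@clusters)
#' @rdname PhagePopulation-accessors
setMethod("moduleLayout", "PhagePopulation", function(x) x@modules)
#' @rdname PhagePopulation-accessors
setMethod("appliedEvents", "PhagePopulation", function(x) x@events)
#' @rdname PhagePopulation-accessors
setMethod("gcTargets", "PhagePopulation", function(x) x@gcTargets)
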