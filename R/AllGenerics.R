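#' @name circStrata-accessors
#' @title Accessors for circStrata classes
#' @param x A [CircExperiment], [MarkerSet], [SampleGrouping] or
#'   [ClassifierReport] as appropriate.
#' @param circId A circRNA identifier.
#' @param ... Passed to methods.
NULL

#' @describeIn circStrata-accessors BSJ read-count matrix.
#' @export
setGeneric("circCounts", function(x, ...) standardGeneric("circCounts"))

#' @describeIn circStrata-accessors gene read-count matrix.
#' @export
setGeneric("geneCounts", function(x, ...) standardGeneric("geneCounts"))

#' @describeIn circStrata-accessors circRNA (BSJ) size factors, or `NULL` if
#'   not yet estimated.
#' @export
setGeneric("circSizeFactors", function(x, ...) standardGeneric("circSizeFactors"))

#' @describeIn circStrata-accessors gene size factors, or `NULL`.
#' @export
setGeneric("geneSizeFactors", function(x, ...) standardGeneric("geneSizeFactors"))

#' @describeIn circStrata-accessors back-splice junction coordinates as a
#'   `GRanges`.
#' @export
setGeneric("backspliceRanges", function(x, ...) standardGeneric("backspliceRanges"))

#' @describeIn circStrata-accessors marker table of a [MarkerSet].
#' @export
setGeneric("markerTable", function(x, ...) standardGeneric("markerTable"))

#' @describeIn circStrata-accessors the [SampleGrouping] a given circRNA
#'   induced.
#' @export
setGeneric("groupingFor", function(x, circId, ...) standardGeneric("groupingFor"))

#' @describeIn circStrata-accessors log of circRNAs skipped during grouping.
#' @export
setGeneric("skippedCirc", function(x, ...) standardGeneric("skippedCirc"))

#' @describeIn circStrata-accessors group labels of a [SampleGrouping] as a
#'   named factor.
#' @export
setGeneric("groupLabels", function(x, ...) standardGeneric("groupLabels"))

setMethod("circCounts", "CircExperiment", function(x, ...) assay(x, "counts"))
setMethod("geneCounts", "CircExperiment", function(x, ...) assay(x@genes, "counts"))
setMethod("backspliceRanges", "CircExperiment", function(x, ...) rowRanges(x))

setMethod("circSizeFactors", "CircExperiment", function(x, ...) {
    if ("circSizeFactor" %in% colnames(colData(x)))
        setNames(colData(x)$circSizeFactor, colnames(x))
    else NULL
})

setMethod("geneSizeFactors", "CircExperiment", function(x, ...) {
    if ("geneSizeFactor" %in% colnames(colData(x)))
        setNames(colData(x)$geneSizeFactor, colnames(x))
    else NULL
})

setMethod("markerTable", "MarkerSet", function(x, ...) x@table)
setMethod("skippedCirc", "MarkerSet", function(x, ...) x@skipped)
setMethod("groupingFor", "MarkerSet", function(x, circId, ...) {
    if (!circId %in% names(x@groupings))
        stop("no grouping for circRNA ", circId,
             " (skipped or absent from the input)")
    x@groupings[[circId]]
})
setMethod("groupLabels", "SampleGrouping", function(x, ...) x@labels)

#' Estimate median-of-ratios size factors for both assays
#'
#' Computes per-sample size factors for the BSJ and the gene count matrices
#' separately (each matrix is its own normalization family) and stores them in
#' `colData` as `circSizeFactor` / `geneSizeFactor`.
#'
#' @param object A [CircExperiment].
#' @return The object with size factors filled in.
#' @seealso [sizeFactorsForCounts()] for the matrix-level estimator.
#' @export
setMethod("estimateSizeFactors", "CircExperiment", function(object, ...) {
    colData(object)$circSizeFactor <- sizeFactorsForCounts(circCounts(object))
    colData(object)$geneSizeFactor <- sizeFactorsForCounts(geneCounts(object))
    object
})
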