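#' CircExperiment: paired circRNA / gene count container
#'
#' A \linkS4class{RangedSummarizedExperiment} whose primary assay holds
#' back-splice junction (BSJ) read counts, with row ranges giving the BSJ
#' genomic coordinates, plus a companion [SummarizedExperiment] of gene read
#' counts over the same samples.  Counts must be non-negative integers and the
#' two assays must cover an identical sample set; validity enforces both.
#'
#' Size factors (median-of-ratios, see [estimateSizeFactors()]) are stored in
#' `colData` under `circSizeFactor` and `geneSizeFactor` once estimated.
#'
#' @slot genes A [SummarizedExperiment] with a `counts` assay of gene-level
#'   read counts on the same samples (possibly in a different column order).
#' @aliases CircExperiment-class
#' @export
setClass("CircExperiment",
    contains = "RangedSummarizedExperiment",
    representation(genes = "SummarizedExperiment")
)

.validCounts <- function(m, what) {
    if (!is.numeric(m))
        return(sprintf("%s counts must be numeric", what))
    if (anyNA(m))
        return(sprintf("%s counts contain missing values", what))
    if (any(m < 0))
        return(sprintf("%s counts contain negative values", what))
    if (any(m != floor(m)))
        return(sprintf("%s counts must be integers", what))
    if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
        return(sprintf("%s feature identifiers must be present and unique", what))
    if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
        return(sprintf("%s sample identifiers must be present and unique", what))
    NULL
}

setValidity("CircExperiment", function(object) {
    msgs <- character()
    if (!"counts" %in% assayNames(object))
        msgs <- c(msgs, "primary assay 'counts' (BSJ read counts) is missing")
    else {
        bad <- .validCounts(assay(object, "counts"), "circRNA")
        if (!is.null(bad)) msgs <- c(msgs, bad)
    }
    g <- object@genes
    if (!"counts" %in% assayNames(g))
        msgs <- c(msgs, "gene assay 'counts' is missing")
    else {
        bad <- .validCounts(assay(g, "counts"), "gene")
        if (!is.null(bad)) msgs <- c(msgs, bad)
    }
    extra <- setdiff(colnames(object), colnames(g))
    miss <- setdiff(colnames(g), colnames(object))
    if (length(extra) || length(miss))
        msgs <- c(msgs, sprintf(
            "circRNA and gene matrices must cover the same samples (only in circRNA: %s; only in gene: %s)",
            paste(extra, collapse = ","), paste(miss, collapse = ",")))
    if (length(msgs)) msgs else TRUE
})

#' Construct a CircExperiment
#'
#' @param circCounts Integer matrix of BSJ read counts, features x samples;
#'   row names must be back-splice identifiers of the form `"chrom:start-end"`
#'   (see [parseBacksplice()]).
#' @param geneCounts Integer matrix of gene read counts over the same samples.
#' @param sampleData Optional `DataFrame`/`data.frame` of per-sample
#'   annotation (one row per sample, rownames = sample ids).  The grouping
#'   machinery never looks at it; it is carried for the user's downstream
#'   interpretation only.
#' @param hostGenes Optional character vector of host-gene symbols parallel to
#'   the circRNA rows.
#' @return A [CircExperiment].
#' @examples
#' sim <- simulateDataset(syntheticDesign(nPerGroup = 3, nCirc = 20,
#'                                        nGenes = 50, seed = 1))
#' sim$experiment
#' @export
CircExperiment <- function(circCounts, geneCounts, sampleData = NULL,
                           hostGenes = NULL) {
    circCounts <- .asCountMatrix(circCounts, "circRNA")
    geneCounts <- .asCountMatrix(geneCounts, "gene")
    gr <- parseBacksplice(rownames(circCounts), hostGenes = hostGenes)
    common <- colnames(circCounts)
    if (!setequal(common, colnames(geneCounts)))
        stop("circRNA and gene matrices must cover the same samples; ",
             "only in circRNA: ",
             paste(setdiff(common, colnames(geneCounts)), collapse = ","),
             "; only in gene: ",
             paste(setdiff(colnames(geneCounts), common), collapse = ","))
    geneCounts <- geneCounts[, common, drop = FALSE]
    cd <- S4Vectors::DataFrame(row.names = common)
    if (!is.null(sampleData)) {
        sampleData <- as(sampleData, "DataFrame")
        if (is.null(rownames(sampleData)) && nrow(sampleData) == length(common))
            rownames(sampleData) <- common
        if (!setequal(rownames(sampleData), common))
            stop("sampleData rows do not match the sample identifiers; ",
                 "unmatched: ",
                 paste(setdiff(common, rownames(sampleData)), collapse = ","))
        cd <- sampleData[common, , drop = FALSE]
    }
    genes <- SummarizedExperiment(assays = list(counts = geneCounts))
    new("CircExperiment",
        SummarizedExperiment(assays = list(counts = circCounts),
                             rowRanges = gr, colData = cd),
        genes = genes)
}

.asCountMatrix <- function(m, what) {
    m <- as.matrix(m)
    bad <- .validCounts(m, what)
    if (!is.null(bad)) stop(bad)
    storage.mode(m) <- "integer"
    m
}

setMethod("show", "CircExperiment", function(object) {
    callNextMethod()
    cat(sprintf("genes: %d features over the same %d samples\n",
                nrow(object@genes), ncol(object@genes)))
    if (!is.null(circSizeFactors(object)))
        cat("size factors: estimated\n")
})

#' SampleGrouping: per-circRNA unsupervised sample partition
#'
#' The assignment of every sample to one of k >= 2 groups driven by a single
#' circRNA's expression profile.  Labels are canonicalized so that `g1` has
#' the lowest mean expression of the grouping circRNA.  The grouping is
#' computed from expression only and is therefore independent of any sample
#' annotation.
#'
#' @slot circId Identifier of the circRNA that produced the grouping.
#' @slot labels Factor of group labels `g1..gk`, named by sample.
#' @slot method `"median"` or `"cluster"`.
#' @slot k Number of groups.
#' @slot parameters List recording distance, algorithm, k-selection rule and
#'   seed where applicable.
#' @aliases SampleGrouping-class
#' @export
setClass("SampleGrouping",
    representation(circId = "character", labels = "factor",
                   method = "character", k = "integer", parameters = "list")
)

setValidity("SampleGrouping", function(object) {
    msgs <- character()
    if (object@k < 2L) msgs <- c(msgs, "k must be >= 2")
    if (nlevels(object@labels) != object@k)
        msgs <- c(msgs, "number of label levels must equal k")
    if (anyNA(object@labels)) msgs <- c(msgs, "every sample must be labeled")
    if (any(table(object@labels) == 0L))
        msgs <- c(msgs, "every group must be non-empty")
    if (is.null(names(object@labels)))
        msgs <- c(msgs, "labels must be named by sample")
    if (length(msgs)) msgs else TRUE
})

setMethod("show", "SampleGrouping", function(object) {
    tab <- table(object@labels)
    cat(sprintf("SampleGrouping for %s (%s, k = %d): %s\n",
                object@circId, object@method, object@k,
                paste(sprintf("%s=%d", names(tab), tab), collapse = " ")))
})

#' MarkerSet: discriminant circRNAs and the groupings they define
#'
#' Result of [selectMarkers()]: one row per retained circRNA with its
#' back-splice coordinates, effect size, significance, per-group mean
#' normalized expression and (after [rankMarkers()]) the PCA contribution;
#' plus the [SampleGrouping] of every tested circRNA and a log of skipped
#' ones.
#'
#' @slot table `DataFrame` of retained markers.
#' @slot groupings `SimpleList` of [SampleGrouping], named by circRNA id
#'   (all successfully grouped circRNAs, retained or not).
#' @slot skipped `DataFrame` with columns `circId` and `reason`.
#' @slot mode `"median"` or `"cluster"`.
#' @slot parameters List of the thresholds and options used.
#' @aliases MarkerSet-class
#' @export
setClass("MarkerSet",
    representation(table = "DataFrame", groupings = "SimpleList",
                   skipped = "DataFrame", mode = "character",
                   parameters = "list")
)

setMethod("show", "MarkerSet", function(object) {
    cat(sprintf("MarkerSet (%s mode): %d discriminant circRNAs of %d grouped (%d skipped)\n",
                object@mode, nrow(object@table), length(object@groupings),
                nrow(object@skipped)))
    if (nrow(object@table))
        print(head(as.data.frame(object@table), 5L))
})

#' ClassifierReport: random-forest RFE classification summary
#'
#' @slot selected `DataFrame` of the genes in the best subset with their
#'   (non-negative) permutation importance, ordered by importance.
#' @slot cvAccuracy Resampled accuracy of the best subset size.
#' @slot accuracyPath `DataFrame` of accuracy per candidate subset size.
#' @slot cvScheme Human-readable description of the resampling scheme.
#' @slot optSize Best subset size.
#' @slot seed Seed used for resampling and forests.
#' @aliases ClassifierReport-class
#' @export
setClass("ClassifierReport",
    representation(selected = "DataFrame", cvAccuracy = "numeric",
                   accuracyPath = "DataFrame", cvScheme = "character",
                   optSize = "integer", seed = "integer")
)

setMethod("show", "ClassifierReport", function(object) {
    cat(sprintf("ClassifierReport: %d genes selected (%s), accuracy %.3f\n",
                object@optSize, object@cvScheme, object@cvAccuracy))
    print(head(as.data.frame(object@selected), 5L))
})
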