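#' Median-of-ratios size factors for a count matrix
#'
#' Library-size/composition normalization in the DESeq style: the reference
#' profile is the per-feature geometric mean across samples, computed on the
#' features with all-positive counts, and each sample's size factor is the
#' median over those features of its counts divided by the reference.  The
#' computation is delegated to the reference implementation in
#' \pkg{DESeq2} (`estimateSizeFactorsForMatrix`).  Factors are not rescaled
#' to geometric mean one, so normalized values live on the canonical
#' median-of-ratios scale.
#'
#' @param counts Non-negative count matrix, features x samples.
#' @return Named numeric vector of strictly positive size factors.
#' @examples
#' m <- matrix(c(10, 20, 30, 20, 40, 60), nrow = 3,
#'             dimnames = list(paste0("f", 1:3), c("s1", "s2")))
#' sizeFactorsForCounts(m)  # (1/sqrt(2), sqrt(2))
#' @export
sizeFactorsForCounts <- function(counts) {
    counts <- as.matrix(counts)
    if (any(counts < 0)) stop("counts must be non-negative")
    if (!any(rowSums(counts > 0) == ncol(counts)))
        stop("no feature has positive counts in every sample; ",
             "pre-filter weakly expressed features (filterLowExpression) ",
             "before estimating size factors")
    sf <- DESeq2::estimateSizeFactorsForMatrix(counts)
    setNames(as.numeric(sf), colnames(counts))
}

#' Divide counts by per-sample size factors
#'
#' @param counts Count matrix, features x samples.
#' @param sizeFactors Positive numeric vector, one entry per sample.
#' @return Real-valued matrix of normalized counts.
#' @export
normalizeCounts <- function(counts, sizeFactors) {
    counts <- as.matrix(counts)
    if (length(sizeFactors) != ncol(counts))
        stop("length of sizeFactors (", length(sizeFactors),
             ") does not match the number of samples (", ncol(counts), ")")
    if (any(sizeFactors <= 0)) stop("size factors must be strictly positive")
    sweep(counts, 2L, sizeFactors, "/")
}

#' Shifted log2 transform
#'
#' `log2(x + pseudocount)`, the transformation used for clustering, ANOVA
#' screening, PCA ranking and classifier inputs.  Strictly monotone, so it
#' never changes orderings.
#'
#' @param x Non-negative matrix or vector (typically normalized counts).
#' @param pseudocount Positive shift, default 1 (so zero maps to zero).
#' @return Transformed object of the same shape.
#' @export
logTransform <- function(x, pseudocount = 1) {
    if (pseudocount <= 0) stop("pseudocount must be positive")
    if (any(x < 0)) stop("input must be non-negative")
    log2(x + pseudocount)
}
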