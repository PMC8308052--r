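#' Differential gene expression between circRNA-defined groups
#'
#' Tests every gene between the sample groups a circRNA defines.  With two
#' groups this is the NB Wald test ([nbWaldTest()]) on the raw gene counts
#' with gene size factors as offsets, BH-corrected within the gene family.
#' With k > 2 groups the two-group model does not apply and the function
#' falls back, with a warning, to a per-gene one-way ANOVA on
#' log2(normalized + 1) values (fold-change columns are then missing).
#'
#' @param genes Gene count matrix (raw integers), or a [CircExperiment]
#'   (its gene assay and gene size factors are used).
#' @param sizeFactors Gene size factors; estimated when `NULL`.
#' @param grouping A [SampleGrouping] (or a factor named by sample).
#' @param alpha Adjusted-p threshold recorded as the significance cut,
#'   default 0.05.
#' @return `DataFrame` in the [nbWaldTest()] schema; `metadata()` records
#'   the circRNA id, the threshold and the number of significant genes.
#' @export
geneExpressionImpact <- function(genes, sizeFactors = NULL, grouping,
                                 alpha = 0.05) {
    circId <- NA_character_
    if (is(genes, "CircExperiment")) {
        sizeFactors <- sizeFactors %||% geneSizeFactors(genes)
        genes <- geneCounts(genes)
    }
    genes <- as.matrix(genes)
    if (is.null(sizeFactors)) sizeFactors <- sizeFactorsForCounts(genes)
    if (is(grouping, "SampleGrouping")) {
        circId <- grouping@circId
        labels <- groupLabels(grouping)
    } else labels <- factor(grouping)
    if (!is.null(names(labels))) {
        miss <- setdiff(colnames(genes), names(labels))
        if (length(miss))
            stop("grouping lacks labels for sample(s): ",
                 paste(miss, collapse = ", "))
        labels <- labels[colnames(genes)]
    }
    k <- nlevels(droplevels(labels))
    if (k == 2L) {
        res <- nbWaldTest(genes, sizeFactors, labels)
    } else {
        warning("grouping has ", k,
                " groups; falling back to per-gene one-way ANOVA")
        lq <- logTransform(normalizeCounts(genes, sizeFactors))
        pv <- apply(lq, 1L, function(v) {
            if (var(v) == 0) return(NA_real_)
            oneWayAnova(v, labels)$pvalue
        })
        res <- S4Vectors::DataFrame(
            baseMean = rowMeans(normalizeCounts(genes, sizeFactors)),
            log2FoldChange = NA_real_, lfcSE = NA_real_, stat = NA_real_,
            pvalue = pv, padj = bhAdjust(pv),
            flag = ifelse(is.na(pv), "constant", "ok"),
            row.names = rownames(genes))
    }
    md <- metadata(res)
    md$circId <- circId
    md$alpha <- alpha
    md$nSignificant <- sum(!is.na(res$padj) & res$padj <= alpha)
    metadata(res) <- md
    res
}

#' Rank genes for preranked GSEA
#'
#' Sorts genes by decreasing score — the signed Wald statistic by default,
#' or the log2 fold change — breaking ties by gene identifier (lexicographic,
#' recorded in the result) so the order is deterministic.  Genes with a
#' missing score are dropped and counted.
#'
#' @param de A `DataFrame` from [geneExpressionImpact()]/[nbWaldTest()] (or
#'   any table with row names and the score column).
#' @param score `"stat"` or `"log2fc"`.
#' @return Named numeric vector sorted in decreasing order, with attributes
#'   `tieRule` and `nDropped`.
#' @export
rankGenes <- function(de, score = c("stat", "log2fc")) {
    score <- match.arg(score)
    col <- if (score == "stat") "stat" else "log2FoldChange"
    if (!col %in% colnames(de)) stop("column '", col, "' not found")
    s <- as.numeric(de[[col]])
    names(s) <- rownames(de)
    drop <- is.na(s)
    if (any(drop))
        message(sum(drop), " gene(s) dropped for missing ", score)
    s <- s[!drop]
    s <- s[order(-s, names(s), method = "radix")]
    attr(s, "tieRule") <- "lexicographic"
    attr(s, "nDropped") <- sum(drop)
    s
}

## Weighted Kolmogorov-Smirnov-like running sum.  Increments |score|^p / N_R
## at member positions, decrements 1/(N - N_hits) at non-members; the
## enrichment score is the maximum deviation from zero.  The path is
## piecewise monotone between hits, so the extrema are attained either just
## after a hit (maximum candidates) or just before one (minimum candidates).
.gseaScore <- function(hits, sabs, N) {
    nh <- length(hits)
    nm <- N - nh
    if (nm == 0L)
        stop("set covers the whole ranking; enrichment score is undefined")
    NR <- sum(sabs[hits])
    inc <- if (NR > 0) sabs[hits] / NR else rep(1 / nh, nh)
    cumHit <- cumsum(inc)
    missBefore <- (hits - seq_len(nh)) / nm
    atHit <- cumHit - missBefore
    beforeHit <- (cumHit - inc) - missBefore
    maxDev <- max(atHit, 0)
    minDev <- min(beforeHit, 0)
    if (maxDev >= -minDev) {
        iMax <- which.max(atHit)
        list(es = maxDev, leadingIdx = hits[seq_len(iMax)])
    } else {
        iMin <- which.min(beforeHit)
        list(es = minDev, leadingIdx = hits[iMin:nh])
    }
}

#' Preranked gene set enrichment analysis
#'
#' Computes, for each gene set, the weighted running-sum enrichment score
#' over the ranked list: at a member ("hit") the sum gains
#' `|score|^weight / N_R` (`N_R` normalizing the hit increments to one), at a
#' non-member it loses `1/(N - N_hits)`; the enrichment score ES is the
#' maximum deviation from zero, so `|ES| <= 1`.  The null distribution comes
#' from `nperm` random reassignments of set membership along the ranking
#' (gene-label permutation; scores stay fixed), a scheme that remains valid
#' at very small sample sizes.  The permutation p-value is smoothed,
#' `(b + 1) / (nperm + 1)` with `b` the number of same-sign permutation
#' scores at least as extreme, and NES divides ES by the mean same-sign
#' permutation |ES| (separate positive/negative normalization).  P-values
#' are BH-adjusted across the tested sets.  The leading edge holds the
#' member genes up to the score's extremum (from the extremum onward for
#' negative ES).
#'
#' @param ranking Named numeric vector sorted in decreasing order (see
#'   [rankGenes()]).
#' @param sets `CharacterList` or named list of member identifier vectors;
#'   members absent from the ranking are ignored, and sets with fewer than
#'   `minSize` or more than `maxSize` remaining members are skipped.
#' @param weight Exponent on |score| for the hit increments, default 1
#'   (0 gives the unweighted Kolmogorov-Smirnov statistic).
#' @param nperm Number of membership permutations, default 1000.
#' @param minSize,maxSize Post-restriction set size window, defaults 10/500.
#' @param seed Seed for the permutations; with the same seed the result is
#'   fully reproducible.
#' @return `DataFrame` with one row per tested set: `set`, `size`, `es`,
#'   `nes`, `pvalue`, `padj` and the `leadingEdge` (`CharacterList`).
#'   Empty (with a warning) if no set survives the size filters.
#' @export
gseaPreranked <- function(ranking, sets, weight = 1, nperm = 1000L,
                          minSize = 10L, maxSize = 500L, seed = 1L) {
    if (is.unsorted(-ranking))
        stop("ranking must be sorted in decreasing order")
    N <- length(ranking)
    genes <- names(ranking)
    if (is.null(genes) || anyDuplicated(genes))
        stop("ranking must be named by unique gene identifiers")
    sabs <- abs(ranking)^weight
    setsL <- as.list(sets)
    restricted <- lapply(setsL, function(m) {
        idx <- sort(match(unique(m), genes))
        idx[!is.na(idx)]
    })
    sizes <- lengths(restricted)
    keep <- sizes >= minSize & sizes <= maxSize & sizes < N
    dropWhole <- sizes >= N
    if (any(dropWhole))
        warning("set(s) covering the whole ranking skipped: ",
                paste(names(restricted)[dropWhole], collapse = ", "))
    if (!any(keep)) {
        warning("no gene set survives the size filters")
        out <- S4Vectors::DataFrame(set = character(), size = integer(),
                                    es = numeric(), nes = numeric(),
                                    pvalue = numeric(), padj = numeric())
        out$leadingEdge <- CharacterList()
        return(out)
    }
    restricted <- restricted[keep]
    set.seed(seed)
    res <- lapply(names(restricted), function(nm) {
        hits <- restricted[[nm]]
        obs <- .gseaScore(hits, sabs, N)
        permES <- vapply(seq_len(nperm), function(i) {
            .gseaScore(sort(sample.int(N, length(hits))), sabs, N)$es
        }, 1)
        same <- permES[sign(permES) == sign(obs$es)]
        b <- sum(abs(same) >= abs(obs$es))
        p <- (b + 1) / (nperm + 1)
        nes <- if (length(same)) obs$es / mean(abs(same)) else NA_real_
        list(es = obs$es, nes = nes, p = p,
             leading = genes[obs$leadingIdx], size = length(hits))
    })
    pv <- vapply(res, `[[`, 1, "p")
    out <- S4Vectors::DataFrame(
        set = names(restricted),
        size = vapply(res, `[[`, 1L, "size"),
        es = vapply(res, `[[`, 1, "es"),
        nes = vapply(res, `[[`, 1, "nes"),
        pvalue = pv, padj = bhAdjust(pv),
        row.names = names(restricted))
    out$leadingEdge <- CharacterList(lapply(res, `[[`, "leading"))
    metadata(out) <- list(nperm = nperm, weight = weight, seed = seed,
                          minSize = minSize, maxSize = maxSize)
    out
}

#' Classify circRNA-defined groups from gene expression
#'
#' Recursive feature elimination with a random-forest estimator
#' (\pkg{caret}'s `rfe` with `rfFuncs`): genes are pre-filtered to the
#' `topVar` most variable, candidate subset sizes decrease by powers of two,
#' resampled accuracy is estimated per size by k-fold cross-validation
#' (leave-one-out when a group is smaller than the fold count), and the
#' final forest at the best size yields a permutation-based variable
#' importance ranking (clamped at zero).
#'
#' @param genesLog log2-normalized gene expression matrix, genes x samples.
#' @param grouping A [SampleGrouping] or factor named by sample.
#' @param sizes Integer vector of candidate subset sizes; default powers of
#'   two from 2 up to the number of candidate genes.
#' @param folds Cross-validation folds, default 5.
#' @param topVar Variance pre-filter size, default 1000.
#' @param seed Seed controlling resampling and forests; equal seeds give
#'   identical reports.
#' @param ntree Trees per forest, default 500.
#' @return A [ClassifierReport].
#' @export
classifyGroups <- function(genesLog, grouping, sizes = NULL, folds = 5L,
                           topVar = 1000L, seed = 1L, ntree = 500L) {
    genesLog <- as.matrix(genesLog)
    if (is(grouping, "SampleGrouping")) labels <- groupLabels(grouping)
    else labels <- factor(grouping)
    if (!is.null(names(labels))) labels <- labels[colnames(genesLog)]
    y <- droplevels(factor(labels))
    if (nlevels(y) < 2L) stop("need at least 2 groups to classify")
    v <- apply(genesLog, 1L, var)
    top <- head(order(v, decreasing = TRUE), topVar)
    x <- as.data.frame(t(genesLog[top, , drop = FALSE]))
    p <- ncol(x)
    if (is.null(sizes)) {
        sizes <- 2^seq(1L, max(1L, floor(log2(max(p - 1L, 2L)))))
        sizes <- unique(pmin(sizes, p))
    }
    minGroup <- min(table(y))
    if (minGroup < folds) {
        warning("smallest group (", minGroup, ") is below the fold count (",
                folds, "); using leave-one-out cross-validation")
        ctrl <- caret::rfeControl(functions = caret::rfFuncs,
                                  method = "LOOCV")
        scheme <- "leave-one-out CV"
    } else {
        ctrl <- caret::rfeControl(functions = caret::rfFuncs, method = "cv",
                                  number = folds)
        scheme <- sprintf("%d-fold CV", folds)
    }
    set.seed(seed)
    fit <- caret::rfe(x, y, sizes = sizes, rfeControl = ctrl, ntree = ntree)
    sel <- caret::predictors(fit)
    imp <- caret::varImp(fit, scale = FALSE)
    impSel <- pmax(imp[sel, 1L], 0)
    ord <- order(impSel, decreasing = TRUE)
    acc <- fit$results[, c("Variables", "Accuracy")]
    new("ClassifierReport",
        selected = S4Vectors::DataFrame(gene = sel[ord],
                                        importance = impSel[ord],
                                        row.names = sel[ord]),
        cvAccuracy = fit$results$Accuracy[match(fit$optsize,
                                                fit$results$Variables)],
        accuracyPath = S4Vectors::DataFrame(size = acc$Variables,
                                            accuracy = acc$Accuracy),
        cvScheme = scheme, optSize = as.integer(fit$optsize),
        seed = as.integer(seed))
}
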