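#' Split samples at a circRNA's median expression
#'
#' Samples at or below the median go to `g1` (ties go to the low group, so
#' `g1` keeps the "low expression" reading), the rest to `g2`.  Both groups
#' must end up non-empty; an all-equal profile cannot be split and raises a
#' degenerate-grouping error (callers skip the circRNA and log it).
#'
#' @param values Named numeric vector of one circRNA's normalized expression,
#'   one entry per sample (>= 4 samples).
#' @param circId Identifier recorded in the result.
#' @return A [SampleGrouping] with `method = "median"`, k = 2.
#' @examples
#' groupLabels(medianSplit(c(s1 = 1, s2 = 2, s3 = 3, s4 = 4)))
#' @export
medianSplit <- function(values, circId = NA_character_) {
    if (length(values) < 4L)
        stop("median split needs at least 4 samples")
    if (is.null(names(values)))
        names(values) <- paste0("sample", seq_along(values))
    med <- median(values)
    low <- values <= med
    if (all(low) || !any(low))
        stop("degenerate grouping for ", circId,
             ": all samples fall on one side of the median")
    labels <- factor(ifelse(low, "g1", "g2"), levels = c("g1", "g2"))
    names(labels) <- names(values)
    new("SampleGrouping", circId = as.character(circId), labels = labels,
        method = "median", k = 2L,
        parameters = list(median = med, ties = "low"))
}

#' Cluster samples on a circRNA's expression profile
#'
#' Partitions the samples by k-means (default) or hierarchical clustering of
#' the (log-scale) expression values of one circRNA.  With `k = "auto"` the
#' number of clusters maximizing the mean silhouette width over
#' `k = 2..min(8, n - 1)` is chosen; if the silhouette is undefined for every
#' candidate the split falls back to k = 2.  Group labels are canonicalized
#' so `g1` has the lowest mean expression.
#'
#' @param values Named numeric vector (one circRNA, log2-normalized
#'   expression recommended).
#' @param distance `"euclidean"`, `"manhattan"` or `"correlation"`
#'   (correlation requires multivariate profiles and is rejected for scalar
#'   values).
#' @param algorithm `"kmeans"` or `"hierarchical"`.
#' @param k Fixed integer number of groups, or `"auto"` for the
#'   silhouette-guided choice.
#' @param linkage Agglomeration method for hierarchical clustering.
#' @param seed Seed for the k-means restarts (25 restarts).
#' @param circId Identifier recorded in the result.
#' @return A [SampleGrouping] with `method = "cluster"`.
#' @export
clusterSplit <- function(values, distance = c("euclidean", "manhattan",
                                              "correlation"),
                         algorithm = c("kmeans", "hierarchical"),
                         k = "auto", linkage = "complete", seed = 1L,
                         circId = NA_character_) {
    distance <- match.arg(distance)
    algorithm <- match.arg(algorithm)
    if (is.null(names(values)))
        names(values) <- paste0("sample", seq_along(values))
    n <- length(values)
    if (var(values) == 0)
        stop("degenerate grouping for ", circId, ": all values are equal")
    if (distance == "correlation")
        stop("correlation distance needs multivariate profiles; ",
             "per-circRNA values are scalar")
    d <- dist(values, method = distance)
    assign1 <- function(kk) {
        if (algorithm == "kmeans") {
            set.seed(seed)
            kmeans(values, centers = kk, nstart = 25L)$cluster
        } else cutree(hclust(d, method = linkage), k = kk)
    }
    auto <- identical(k, "auto")
    if (auto) {
        ks <- 2:min(8L, n - 1L)
        sil <- vapply(ks, function(kk) {
            cl <- tryCatch(assign1(kk), error = function(e) NULL)
            if (is.null(cl) || length(unique(cl)) < 2L) return(NA_real_)
            mean(cluster::silhouette(cl, d)[, "sil_width"])
        }, 1)
        k <- if (all(is.na(sil))) 2L else ks[which.max(sil)]
    }
    k <- as.integer(k)
    if (k < 2L || k > n - 1L) stop("k must lie in [2, n - 1]")
    cl <- assign1(k)
    # canonical order: g1 = lowest mean expression
    ord <- order(tapply(values, cl, mean))
    labels <- factor(paste0("g", match(cl, ord)),
                     levels = paste0("g", seq_len(k)))
    names(labels) <- names(values)
    new("SampleGrouping", circId = as.character(circId), labels = labels,
        method = "cluster", k = k,
        parameters = list(distance = distance, algorithm = algorithm,
                          linkage = linkage, seed = seed,
                          kSelection = if (auto) "silhouette" else "fixed"))
}

#' Select discriminant circRNAs
#'
#' For each circRNA, the samples are grouped by that circRNA's own expression
#' (median split by default, or clustering), and the circRNA's counts are
#' tested between the groups it defines.  In median mode the test is the
#' two-group NB Wald test, with p-values BH-corrected jointly across all
#' circRNAs, and a circRNA is retained when `padj <= alpha` and
#' `|log2FoldChange| >= minLog2FC`.  In cluster mode the screen is a one-way
#' ANOVA on log2(normalized + 1) values retained at raw `p <= alpha`
#' (set `adjustAnova = TRUE` to BH-correct this branch too).  Per-group mean
#' normalized expression is reported; labels are oriented so g1 is the
#' low-expression group, hence positive fold changes.
#'
#' Dispersions for the per-circRNA Wald tests are method-of-moments values
#' computed under each circRNA's own grouping, shrunk toward a common
#' mean-dispersion trend fitted across all circRNAs.
#'
#' @param x A [CircExperiment]; size factors are estimated on the fly if
#'   absent.
#' @param mode `"median"` or `"cluster"`.
#' @param alpha Significance threshold (adjusted p in median mode, raw
#'   ANOVA p in cluster mode), default 0.05.
#' @param minLog2FC Minimum absolute log2 fold change (median mode only),
#'   default 1.
#' @param adjustAnova Apply BH to the ANOVA branch as well (default FALSE,
#'   the screen as printed).
#' @param clusterOptions List of arguments passed to [clusterSplit()].
#' @param seed Seed forwarded to the clustering.
#' @return A [MarkerSet].
#' @export
selectMarkers <- function(x, mode = c("median", "cluster"), alpha = 0.05,
                          minLog2FC = 1, adjustAnova = FALSE,
                          clusterOptions = list(), seed = 1L) {
    mode <- match.arg(mode)
    stopifnot(is(x, "CircExperiment"))
    sf <- circSizeFactors(x)
    if (is.null(sf)) {
        x <- estimateSizeFactors(x)
        sf <- circSizeFactors(x)
    }
    counts <- circCounts(x)
    q <- normalizeCounts(counts, sf)
    lq <- logTransform(q)
    ids <- rownames(counts)
    gr <- rowRanges(x)

    groupings <- list()
    skipped <- list()
    for (id in ids) {
        g <- tryCatch({
            if (var(counts[id, ]) == 0)
                stop("degenerate grouping for ", id, ": constant counts")
            if (mode == "median") medianSplit(q[id, ], circId = id)
            else do.call(clusterSplit,
                         c(list(values = lq[id, ], circId = id, seed = seed),
                           clusterOptions))
        }, error = function(e) conditionMessage(e))
        if (is.character(g)) skipped[[id]] <- g else groupings[[id]] <- g
    }
    skippedDF <- S4Vectors::DataFrame(
        circId = as.character(names(skipped)),
        reason = as.character(unlist(skipped, use.names = FALSE)))

    gids <- names(groupings)
    if (!length(gids)) {
        warning("no circRNA produced a valid grouping")
        return(new("MarkerSet", table = S4Vectors::DataFrame(),
                   groupings = SimpleList(), skipped = skippedDF,
                   mode = mode,
                   parameters = list(alpha = alpha, minLog2FC = minLog2FC,
                                     seed = seed)))
    }

    if (mode == "median") {
        stats <- .medianModeTests(counts[gids, , drop = FALSE], sf, q,
                                  groupings)
        padj <- bhAdjust(stats$pvalue)
        keep <- !is.na(padj) & padj <= alpha &
            abs(stats$log2FoldChange) >= minLog2FC
        tab <- S4Vectors::DataFrame(
            circId = gids,
            hostGene = mcols(gr[gids])$hostGene,
            chrom = as.character(seqnames(gr[gids])),
            start = start(gr[gids]), end = end(gr[gids]),
            log2FoldChange = stats$log2FoldChange,
            lfcSE = stats$lfcSE, stat = stats$stat,
            pvalue = stats$pvalue, padj = padj,
            meanG1 = stats$meanG1, meanG2 = stats$meanG2,
            k = 2L, contribution = NA_real_,
            row.names = gids)[keep, , drop = FALSE]
    } else {
        res <- lapply(gids, function(id) {
            g <- groupings[[id]]
            a <- oneWayAnova(lq[id, ], groupLabels(g))
            gm <- tapply(q[id, ], groupLabels(g), mean)
            lfc <- if (g@k == 2L)
                log2(max(gm[2L], 0.5) / max(gm[1L], 0.5)) else NA_real_
            list(p = a$pvalue, f = a$statistic, gm = gm, lfc = lfc, k = g@k)
        })
        pv <- vapply(res, `[[`, 1, "p")
        pUsed <- if (adjustAnova) bhAdjust(pv) else pv
        keep <- !is.na(pUsed) & pUsed <= alpha
        tab <- S4Vectors::DataFrame(
            circId = gids,
            hostGene = mcols(gr[gids])$hostGene,
            chrom = as.character(seqnames(gr[gids])),
            start = start(gr[gids]), end = end(gr[gids]),
            log2FoldChange = vapply(res, `[[`, 1, "lfc"),
            statistic = vapply(res, `[[`, 1, "f"),
            pvalue = pv,
            padj = if (adjustAnova) pUsed else NA_real_,
            groupMeans = NumericList(lapply(res, `[[`, "gm")),
            k = vapply(res, `[[`, 1L, "k"),
            contribution = NA_real_,
            row.names = gids)[keep, , drop = FALSE]
    }
    new("MarkerSet", table = tab,
        groupings = SimpleList(groupings), skipped = skippedDF, mode = mode,
        parameters = list(alpha = alpha, minLog2FC = minLog2FC,
                          adjustAnova = adjustAnova, seed = seed,
                          clusterOptions = clusterOptions))
}

## Wald tests where every circRNA has its own two-group design: raw MoM
## dispersion under each circRNA's own grouping, a trend fitted across
## circRNAs, then one single-feature GLM fit per circRNA.
.medianModeTests <- function(counts, sf, q, groupings) {
    gids <- rownames(counts)
    qg <- q[gids, , drop = FALSE]
    mu <- rowMeans(qg)
    rawA <- vapply(gids, function(id) {
        lab <- groupLabels(groupings[[id]])
        v <- .pooledWithinVar(qg[id, , drop = FALSE], lab)
        .momAlpha(v, mu[id], 1e-8)
    }, 1)
    disp <- .shrinkDispersions(rawA, mu, weight = 0.5, alphaMin = 1e-8)
    out <- lapply(gids, function(id) {
        lab <- groupLabels(groupings[[id]])
        fit <- .nbGlmTwoGroup(counts[id, , drop = FALSE], sf, lab,
                              disp[id])
        gm <- tapply(qg[id, ], lab, mean)
        p <- if (fit$flag %in% c("all_zero", "no_converge")) NA_real_
             else 2 * pnorm(-abs(fit$stat))
        c(lfc = unname(fit$beta1) / log(2), se = unname(fit$se) / log(2),
          stat = unname(fit$stat), p = unname(p),
          m1 = gm[[1L]], m2 = gm[[2L]])
    })
    m <- do.call(rbind, out)
    list(log2FoldChange = m[, "lfc"], lfcSE = m[, "se"], stat = m[, "stat"],
         pvalue = m[, "p"], meanG1 = m[, "m1"], meanG2 = m[, "m2"])
}

#' Rank variables by PCA contribution
#'
#' Columns (circRNAs) are standardized to zero mean and unit variance and the
#' matrix is decomposed by SVD.  For unit right-singular vector `v_k` with
#' eigenvalue `lambda_k`, the contribution of variable j to axis k is
#' `100 * v_jk^2` (so each axis's contributions sum to 100), and the total
#' contribution over the first `axes` components is the eigenvalue-weighted
#' combination `100 * sum_k v_jk^2 lambda_k / sum_k lambda_k`.  Variables are
#' returned sorted by decreasing total contribution, truncated to `topN`.
#'
#' @param mat Numeric matrix, samples x variables (>= 2 of each).
#' @param axes Number of leading components to combine, default 2.
#' @param topN Number of variables to keep, default 25.
#' @return `DataFrame` with columns `variable` and `contribution`;
#'   `metadata()` carries `eigenvalues`, the full per-axis contribution
#'   matrix, `axes`, and any dropped zero-variance variables.
#' @export
pcaRank <- function(mat, axes = 2L, topN = 25L) {
    mat <- as.matrix(mat)
    if (nrow(mat) < 2L || ncol(mat) < 2L)
        stop("pcaRank needs at least 2 samples and 2 variables")
    if (is.null(colnames(mat)))
        colnames(mat) <- paste0("V", seq_len(ncol(mat)))
    sds <- apply(mat, 2L, sd)
    dropped <- colnames(mat)[sds == 0]
    if (length(dropped)) {
        warning("dropping zero-variance variable(s): ",
                paste(dropped, collapse = ", "))
        mat <- mat[, sds > 0, drop = FALSE]
        if (ncol(mat) < 2L) stop("fewer than 2 variables with variance left")
    }
    z <- scale(mat)
    sv <- svd(z)
    lambda <- sv$d^2 / (nrow(mat) - 1L)
    contribAxis <- 100 * sv$v^2
    rownames(contribAxis) <- colnames(mat)
    colnames(contribAxis) <- paste0("PC", seq_along(lambda))
    axes <- min(as.integer(axes), length(lambda))
    total <- as.numeric(
        contribAxis[, seq_len(axes), drop = FALSE] %*% lambda[seq_len(axes)] /
        sum(lambda[seq_len(axes)]))
    ord <- order(total, decreasing = TRUE)
    keep <- head(ord, topN)
    out <- S4Vectors::DataFrame(variable = colnames(mat)[keep],
                                contribution = total[keep],
                                row.names = colnames(mat)[keep])
    metadata(out) <- list(eigenvalues = lambda, perAxis = contribAxis,
                          axes = axes, dropped = dropped)
    out
}

#' Rank a MarkerSet's circRNAs by PCA contribution
#'
#' Builds the samples x markers matrix of log2(normalized + 1) expression for
#' the retained circRNAs, runs [pcaRank()], fills the `contribution` column
#' of the marker table and reorders it by decreasing contribution (markers
#' outside the top `topN` are dropped from the table but keep their
#' groupings).
#'
#' @param x The [CircExperiment] the markers came from.
#' @param markers A [MarkerSet] from [selectMarkers()].
#' @inheritParams pcaRank
#' @return The updated [MarkerSet]; `metadata(markerTable(...))` carries the
#'   PCA eigenvalues.
#' @export
rankMarkers <- function(x, markers, axes = 2L, topN = 25L) {
    tab <- markerTable(markers)
    if (nrow(tab) < 2L) {
        # nothing to rank against; single markers keep contribution NA
        return(markers)
    }
    sf <- circSizeFactors(x)
    if (is.null(sf)) sf <- sizeFactorsForCounts(circCounts(x))
    q <- normalizeCounts(circCounts(x)[rownames(tab), , drop = FALSE], sf)
    ranking <- pcaRank(t(logTransform(q)), axes = axes, topN = topN)
    tab <- tab[ranking$variable, , drop = FALSE]
    tab$contribution <- ranking$contribution
    metadata(tab) <- metadata(ranking)
    markers@table <- tab
    markers@parameters$axes <- axes
    markers@parameters$topN <- topN
    markers
}
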