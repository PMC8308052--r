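#' Describe a synthetic two-group circRNA/gene dataset
#'
#' The generator emulates a bladder-carcinoma-like two-condition RNA-seq
#' design at desk scale: two equal sample groups; NB counts with mean
#' `q_f * s_j * 2^(effect_f * [j in group 2])` and common dispersion
#' `alpha` (variance `mu + alpha mu^2`); baseline abundances `q_f` drawn
#' log-normal(log 50, 1) so both weak and strong expressors exist (the kind
#' of 0.5-900 normalized-mean range seen in real BSJ data); per-sample
#' library factors `s_j` uniform on `libFactorRange`.  A few "marker"
#' circRNAs carry a planted log2 effect between the groups, and each marker
#' drags a signature of linked genes with signed effects — `negativeFraction`
#' of them negative, supporting inverse circRNA-gene links such as a sponge
#' circRNA repressing its axis target.  Planted gene sets (one up- and one
#' down-signature per marker, plus null sets) make enrichment testable.
#'
#' @param nPerGroup Samples per group (default 10).
#' @param nCirc,nGenes Numbers of circRNAs and genes (defaults 300, 2000).
#' @param nMarkerCirc Number of marker circRNAs (default 2).
#' @param markerEffect Planted circRNA log2 effect, group 2 over group 1
#'   (default 2, i.e. 4-fold).
#' @param nLinkedGenes Genes linked to each marker (default 30).
#' @param linkedEffect Absolute log2 effect of linked genes (default 2).
#' @param negativeFraction Fraction of linked genes with a negative effect
#'   (default 0.5).
#' @param baselineMeanlog,baselineSdlog Log-normal parameters of baseline
#'   means (defaults log 50 and 1).
#' @param dispersion NB dispersion alpha (default 0.1; 0 gives Poisson).
#' @param libFactorRange Range of library-size factors (default 0.7-1.4).
#' @param nNullSets,nullSetSize Unenriched decoy gene sets (defaults 5 of 30).
#' @param seed Seed; the same design simulates bit-identical data.
#' @return A validated list of class `SyntheticDesign`.
#' @export
syntheticDesign <- function(nPerGroup = 10L, nCirc = 300L, nGenes = 2000L,
                            nMarkerCirc = 2L, markerEffect = 2,
                            nLinkedGenes = 30L, linkedEffect = 2,
                            negativeFraction = 0.5,
                            baselineMeanlog = log(50), baselineSdlog = 1,
                            dispersion = 0.1, libFactorRange = c(0.7, 1.4),
                            nNullSets = 5L, nullSetSize = 30L, seed = 1L) {
    d <- list(nPerGroup = as.integer(nPerGroup), nCirc = as.integer(nCirc),
              nGenes = as.integer(nGenes),
              nMarkerCirc = as.integer(nMarkerCirc),
              markerEffect = markerEffect,
              nLinkedGenes = as.integer(nLinkedGenes),
              linkedEffect = linkedEffect,
              negativeFraction = negativeFraction,
              baselineMeanlog = baselineMeanlog,
              baselineSdlog = baselineSdlog,
              dispersion = dispersion, libFactorRange = libFactorRange,
              nNullSets = as.integer(nNullSets),
              nullSetSize = as.integer(nullSetSize), seed = as.integer(seed))
    stopifnot(d$nPerGroup >= 2L, d$nCirc >= 1L, d$nGenes >= 1L,
              d$nMarkerCirc >= 0L, d$nMarkerCirc <= d$nCirc,
              is.finite(d$markerEffect), is.finite(d$linkedEffect),
              d$negativeFraction >= 0, d$negativeFraction <= 1,
              d$dispersion >= 0, all(d$libFactorRange > 0),
              length(d$libFactorRange) == 2L,
              d$nMarkerCirc * d$nLinkedGenes <= d$nGenes)
    class(d) <- "SyntheticDesign"
    d
}

#' Simulate a dataset with planted circRNA-driven structure
#'
#' Draws the circRNA and gene count matrices described by a
#' [syntheticDesign()], fully seeded (the same design yields bit-identical
#' output), and returns them with the ground truth needed to score recovery.
#'
#' @param design A `SyntheticDesign`.
#' @return List with components:
#'   \describe{
#'     \item{experiment}{[CircExperiment] with the sample condition in
#'       `colData` and the true library factors in `metadata`.}
#'     \item{geneSets}{`CharacterList` of planted and null gene sets.}
#'     \item{truth}{List of `DataFrame`s `circ` (`isMarker`, `effect`),
#'       `genes` (`isLinked`, `effect`, `marker`) and `sets` (`enriched`,
#'       `direction`, `marker`).}
#'     \item{design}{The input design.}
#'   }
#' @export
simulateDataset <- function(design) {
    stopifnot(inherits(design, "SyntheticDesign"))
    d <- design
    set.seed(d$seed)
    n <- 2L * d$nPerGroup
    inG2 <- rep(c(FALSE, TRUE), each = d$nPerGroup)
    sampleIds <- sprintf("S%03d", seq_len(n))
    sf <- runif(n, d$libFactorRange[1L], d$libFactorRange[2L])

    circIds <- .randomBsjIds(d$nCirc)
    geneIds <- sprintf("G%05d", seq_len(d$nGenes))

    circEffect <- rep(0, d$nCirc)
    markerIdx <- if (d$nMarkerCirc > 0L) sample.int(d$nCirc, d$nMarkerCirc)
                 else integer()
    circEffect[markerIdx] <- d$markerEffect

    geneEffect <- rep(0, d$nGenes)
    linkedMarker <- rep(NA_character_, d$nGenes)
    setList <- list()
    setTruth <- list()
    freeGenes <- seq_len(d$nGenes)
    for (m in seq_along(markerIdx)) {
        pick <- sample(freeGenes, d$nLinkedGenes)
        freeGenes <- setdiff(freeGenes, pick)
        nNeg <- round(d$negativeFraction * d$nLinkedGenes)
        signs <- c(rep(-1, nNeg), rep(1, d$nLinkedGenes - nNeg))
        geneEffect[pick] <- signs * d$linkedEffect
        linkedMarker[pick] <- circIds[markerIdx[m]]
        up <- geneIds[pick[signs > 0]]; dn <- geneIds[pick[signs < 0]]
        if (length(up)) {
            setList[[sprintf("planted_up_m%d", m)]] <- up
            setTruth[[sprintf("planted_up_m%d", m)]] <-
                list(TRUE, "up", circIds[markerIdx[m]])
        }
        if (length(dn)) {
            setList[[sprintf("planted_down_m%d", m)]] <- dn
            setTruth[[sprintf("planted_down_m%d", m)]] <-
                list(TRUE, "down", circIds[markerIdx[m]])
        }
    }
    for (s in seq_len(d$nNullSets)) {
        nm <- sprintf("null_set_%d", s)
        setList[[nm]] <- geneIds[sample(freeGenes,
                                        min(d$nullSetSize, length(freeGenes)))]
        setTruth[[nm]] <- list(FALSE, "none", NA_character_)
    }

    qc <- rlnorm(d$nCirc, d$baselineMeanlog, d$baselineSdlog)
    qg <- rlnorm(d$nGenes, d$baselineMeanlog, d$baselineSdlog)
    circCounts <- .drawNB(qc, circEffect, sf, inG2, d$dispersion)
    geneCounts <- .drawNB(qg, geneEffect, sf, inG2, d$dispersion)
    dimnames(circCounts) <- list(circIds, sampleIds)
    dimnames(geneCounts) <- list(geneIds, sampleIds)

    meta <- S4Vectors::DataFrame(
        condition = factor(ifelse(inG2, "B", "A")), row.names = sampleIds)
    exp <- CircExperiment(circCounts, geneCounts, sampleData = meta,
                          hostGenes = sprintf("HG%04d", seq_len(d$nCirc)))
    metadata(exp) <- list(trueSizeFactors = setNames(sf, sampleIds),
                          seed = d$seed)

    sets <- CharacterList(setList)
    mcols(sets) <- S4Vectors::DataFrame(
        description = names(setList),
        enriched = vapply(setTruth, `[[`, TRUE, 1L),
        direction = vapply(setTruth, `[[`, "", 2L),
        marker = vapply(setTruth, `[[`, "", 3L))

    truth <- list(
        circ = S4Vectors::DataFrame(
            circId = circIds, isMarker = circEffect != 0,
            effect = circEffect, row.names = circIds),
        genes = S4Vectors::DataFrame(
            geneId = geneIds, isLinked = geneEffect != 0,
            effect = geneEffect, marker = linkedMarker,
            row.names = geneIds),
        sets = S4Vectors::DataFrame(
            set = names(setList),
            enriched = vapply(setTruth, `[[`, TRUE, 1L),
            direction = vapply(setTruth, `[[`, "", 2L),
            marker = vapply(setTruth, `[[`, "", 3L),
            row.names = names(setList)))

    list(experiment = exp, geneSets = sets, truth = truth, design = design)
}

.randomBsjIds <- function(n) {
    repeat {
        chrom <- sample(c(as.character(1:22), "X"), n, replace = TRUE)
        start <- sample.int(2e8L, n)
        width <- sample(200:20000, n, replace = TRUE)
        ids <- sprintf("%s:%d-%d", chrom, start, start + width)
        if (!anyDuplicated(ids)) return(ids)
    }
}

.drawNB <- function(baseline, effect, sf, inG2, alpha) {
    nf <- length(baseline); n <- length(sf)
    mu <- outer(baseline, sf) * 2^(outer(effect, as.numeric(inG2)))
    if (any(mu <= 0) || anyNA(mu)) stop("infeasible design: means must be positive")
    counts <- if (alpha == 0) rpois(nf * n, lambda = mu)
              else rnbinom(nf * n, mu = mu, size = 1 / alpha)
    matrix(as.integer(counts), nf, n)
}
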