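test_that("median split sends ties to the low group and rejects degenerates", {
    g <- medianSplit(c(s1 = 1, s2 = 2, s3 = 3, s4 = 4))
    expect_identical(as.character(groupLabels(g)), c("g1", "g1", "g2", "g2"))
    # median 2 with a tie: the tied sample stays in g1
    g2 <- medianSplit(c(s1 = 1, s2 = 2, s3 = 2, s4 = 9))
    expect_identical(as.character(groupLabels(g2)), c("g1", "g1", "g1", "g2"))
    expect_error(medianSplit(c(s1 = 5, s2 = 5, s3 = 5, s4 = 5)), "degenerate")
    expect_error(medianSplit(c(a = 1, b = 2)), "at least 4 samples")
    # without ties and even n the split is balanced; g1 never smaller
    set.seed(2)
    for (i in 1:20) {
        v <- sample(seq(1, 100, by = 1), 10)
        names(v) <- paste0("s", 1:10)
        tab <- table(groupLabels(medianSplit(v)))
        expect_true(all(tab > 0))
        expect_gte(tab[["g1"]], tab[["g2"]])
    }
})

test_that("cluster split finds the obvious partition with silhouette-guided k", {
    v <- c(a = 0, b = 0.1, c = 0.2, d = 10, e = 10.1, f = 10.2)
    g <- clusterSplit(v, k = "auto", seed = 1)
    expect_equal(g@k, 2L)
    expect_equal(g@k, bruteBestK(v, 2:5))  # brute-force silhouette oracle
    expect_identical(as.character(groupLabels(g)),
                     c("g1", "g1", "g1", "g2", "g2", "g2"))
    # fixed k is seed-stable
    parts <- vapply(1:10, function(s) {
        paste(groupLabels(clusterSplit(v, k = 2, seed = s)), collapse = "")
    }, "")
    expect_length(unique(parts), 1L)
    # hierarchical route produces the same obvious partition
    gh <- clusterSplit(v, algorithm = "hierarchical", k = 2)
    expect_identical(groupLabels(gh), groupLabels(g))
    expect_error(clusterSplit(rep(1, 6) + numeric(6)), "degenerate")
    expect_error(clusterSplit(v, distance = "correlation"), "multivariate")
})

test_that("marker selection retains the planted circRNA and logs skips", {
    sim <- simulateDataset(syntheticDesign(
        nPerGroup = 10, nCirc = 201, nGenes = 1, nMarkerCirc = 1,
        nLinkedGenes = 0, baselineMeanlog = log(100), baselineSdlog = 0,
        dispersion = 0.1, seed = 101))
    x <- estimateSizeFactors(sim$experiment)
    # plant a constant circRNA to exercise the skip log
    cc <- circCounts(x)
    cc[1, ] <- 7L
    x2 <- estimateSizeFactors(CircExperiment(cc, geneCounts(x)))
    ms <- selectMarkers(x2)
    expect_true(trueMarkerIds(sim) %in% markerTable(ms)$circId)
    expect_true(rownames(cc)[1] %in% skippedCirc(ms)$circId)
    expect_false(rownames(cc)[1] %in% markerTable(ms)$circId)
    expect_match(skippedCirc(ms)$reason[1], "degenerate")
})

test_that("null circRNAs pass the marker filters at a low rate", {
    fp <- vapply(1:5, function(s) {
        sim <- simulateDataset(syntheticDesign(
            nPerGroup = 10, nCirc = 201, nGenes = 1, nMarkerCirc = 1,
            nLinkedGenes = 0, baselineMeanlog = log(100), baselineSdlog = 0,
            dispersion = 0.1, seed = 300 + s))
        x <- estimateSizeFactors(sim$experiment)
        tab <- markerTable(selectMarkers(x))
        sum(!tab$circId %in% trueMarkerIds(sim)) / 200
    }, 1)
    expect_lte(mean(fp), 0.05)
})

test_that("cluster-mode selection screens circRNAs by ANOVA", {
    sim <- simulateDataset(syntheticDesign(
        nPerGroup = 10, nCirc = 60, nGenes = 1, nMarkerCirc = 1,
        nLinkedGenes = 0, baselineMeanlog = log(100), baselineSdlog = 0,
        dispersion = 0.1, seed = 77))
    x <- estimateSizeFactors(sim$experiment)
    ms <- selectMarkers(x, mode = "cluster", seed = 7)
    tab <- markerTable(ms)
    expect_true(trueMarkerIds(sim) %in% tab$circId)
    expect_true(all(tab$pvalue <= 0.05))
    expect_s4_class(groupingFor(ms, trueMarkerIds(sim)), "SampleGrouping")
})

test_that("groupings ignore sample annotation entirely", {
    sim <- simulateDataset(syntheticDesign(
        nPerGroup = 5, nCirc = 30, nGenes = 80, nLinkedGenes = 10,
        seed = 15))
    x <- estimateSizeFactors(sim$experiment)
    shuffled <- x
    set.seed(1)
    SummarizedExperiment::colData(shuffled)$condition <-
        sample(SummarizedExperiment::colData(x)$condition)
    msA <- selectMarkers(x)
    msB <- selectMarkers(shuffled)
    expect_identical(lapply(msA@groupings, groupLabels),
                     lapply(msB@groupings, groupLabels))
})

test_that("PCA contributions obey symmetry and match an eigen oracle", {
    # two perfectly correlated variables split an axis evenly
    set.seed(4)
    v <- rnorm(10)
    m <- cbind(c1 = v, c2 = 2 * v + 3)
    r <- pcaRank(m, axes = 1, topN = 2)
    expect_equal(unname(r$contribution), c(50, 50), tolerance = 1e-9)
    # random matrices: per-axis sums of 100 and eigen agreement
    for (i in 1:10) {
        m <- matrix(rnorm(30), 6, 5,
                    dimnames = list(NULL, paste0("c", 1:5)))
        r <- pcaRank(m, axes = 2, topN = 5)
        perAxis <- S4Vectors::metadata(r)$perAxis
        expect_equal(unname(colSums(perAxis)), rep(100, ncol(perAxis)),
                     tolerance = 1e-6)
        # oracle: eigendecomposition of the correlation matrix
        eig <- eigen(cor(m))
        expect_equal(S4Vectors::metadata(r)$eigenvalues, eig$values,
                     tolerance = 1e-9)
        oracleTotal <- 100 *
            (eig$vectors[, 1:2]^2 %*% eig$values[1:2]) / sum(eig$values[1:2])
        expect_equal(r[colnames(m), "contribution"],
                     as.numeric(oracleTotal), tolerance = 1e-9)
    }
})

test_that("PCA ranking is invariant to sample and variable order", {
    set.seed(6)
    m <- matrix(rnorm(48), 8, 6, dimnames = list(NULL, paste0("c", 1:6)))
    r <- pcaRank(m, topN = 6)
    rShuffled <- pcaRank(m[sample(8), sample(6)], topN = 6)
    expect_equal(r[sort(rownames(r)), "contribution"],
                 rShuffled[sort(rownames(rShuffled)), "contribution"],
                 tolerance = 1e-9)
    # zero-variance variables are dropped with a warning
    m2 <- cbind(m, flat = rep(1, 8))
    expect_warning(r2 <- pcaRank(m2, topN = 10), "zero-variance")
    expect_false("flat" %in% rownames(r2))
})
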