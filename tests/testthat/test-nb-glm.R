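test_that("BH adjustment reproduces hand-computed step-up values", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhAdjust(c(0.005, 0.1, 0.9)), c(0.015, 0.15, 0.9))
    expect_equal(bhAdjust(0.37), 0.37)  # m = 1 leaves the value unchanged
    expect_equal(bhAdjust(c(0.5, NA, 0.01)), c(0.5, NA, 0.02))
    expect_error(bhAdjust(c(0.1, 1.2)), "\\[0, 1\\]")
    # sorted input gives monotone non-decreasing output
    set.seed(3)
    p <- sort(runif(100))
    expect_true(!is.unsorted(bhAdjust(p)))
})

test_that("dispersion estimates track simulated truth", {
    cd <- SummarizedExperiment::colData
    # Poisson data: estimates collapse toward zero
    simP <- simulateDataset(syntheticDesign(
        nPerGroup = 20, nCirc = 1, nGenes = 500, nMarkerCirc = 0,
        baselineMeanlog = log(100), baselineSdlog = 0, dispersion = 0,
        seed = 3))
    gp <- geneCounts(simP$experiment)
    dP <- estimateDispersionsNB(gp, sizeFactorsForCounts(gp),
                                cd(simP$experiment)$condition)
    expect_lte(median(dP), 0.05)
    # overdispersed data: median lands near the simulated alpha
    simN <- simulateDataset(syntheticDesign(
        nPerGroup = 50, nCirc = 1, nGenes = 500, nMarkerCirc = 0,
        baselineMeanlog = log(100), baselineSdlog = 0, dispersion = 0.2,
        seed = 4))
    gn <- geneCounts(simN$experiment)
    dN <- estimateDispersionsNB(gn, sizeFactorsForCounts(gn),
                                cd(simN$experiment)$condition)
    expect_gte(median(dN), 0.1)
    expect_lte(median(dN), 0.4)
    # a constant feature has no variance information: floored
    m <- rbind(flat = rep(10L, 10), ok = rpois(10, 50) + 1L)
    colnames(m) <- paste0("s", 1:10)
    dC <- estimateDispersionsNB(m, rep(1, 10),
                                factor(rep(c("a", "b"), each = 5)))
    expect_equal(unname(dC["flat"]), 1e-8)
    # all-zero feature flagged and floored
    m2 <- rbind(m, none = rep(0L, 10))
    dZ <- estimateDispersionsNB(m2, rep(1, 10))
    expect_equal(unname(dZ["none"]), 1e-8)
    expect_equal(unname(attr(dZ, "flag")["none"] == "all_zero"), TRUE)
})

test_that("Wald fit reproduces saturated two-group means and symmetries", {
    m <- rbind(f1 = c(4L, 4L, 4L, 16L, 16L, 16L))
    colnames(m) <- paste0("s", 1:6)
    g <- factor(rep(c("g1", "g2"), each = 3))
    res <- nbWaldTest(m, rep(1, 6), g, dispersions = 0.05)
    expect_equal(res$log2FoldChange, 2, tolerance = 1e-6)
    expect_equal(res$stat, res$log2FoldChange / res$lfcSE, tolerance = 1e-9)
    # identical groups: no effect, p-value one
    m0 <- rbind(f1 = c(5L, 9L, 7L, 5L, 9L, 7L))
    colnames(m0) <- paste0("s", 1:6)
    res0 <- nbWaldTest(m0, rep(1, 6), g, dispersions = 0.05)
    expect_equal(res0$log2FoldChange, 0, tolerance = 1e-6)
    expect_equal(res0$stat, 0, tolerance = 1e-6)
    expect_equal(res0$pvalue, 1, tolerance = 1e-6)
})

test_that("Wald results are antisymmetric under label swap and scale-consistent", {
    set.seed(8)
    m <- matrix(rpois(200, 80) + 1L, 10, 20,
                dimnames = list(paste0("f", 1:10), paste0("s", 1:20)))
    sf <- runif(20, 0.8, 1.2)
    g <- factor(rep(c("g1", "g2"), each = 10))
    gSwap <- factor(g, levels = c("g2", "g1"))
    a <- nbWaldTest(m, sf, g, dispersions = 0.1)
    b <- nbWaldTest(m, sf, gSwap, dispersions = 0.1)
    expect_equal(a$log2FoldChange, -b$log2FoldChange, tolerance = 1e-6)
    expect_equal(a$stat, -b$stat, tolerance = 1e-6)
    expect_equal(a$pvalue, b$pvalue, tolerance = 1e-6)
    # scaling every sample's counts and size factors together changes
    # nothing; exact in the Poisson limit, where the estimating equations
    # are scale-free (a fixed NB dispersion re-weights scaled counts)
    k <- 3L
    a0 <- nbWaldTest(m, sf, g, dispersions = 1e-8)
    sc <- nbWaldTest(m * k, sf * k, g, dispersions = 1e-8)
    expect_equal(sc$log2FoldChange, a0$log2FoldChange, tolerance = 1e-6)
})

test_that("Wald p-values match a Poisson GLM when dispersion vanishes", {
    set.seed(9)
    g <- factor(rep(c("g1", "g2"), each = 10))
    for (i in 1:5) {
        y <- rpois(20, rep(c(200, 230 + 20 * i), each = 10))
        m <- matrix(as.integer(y), 1,
                    dimnames = list("f1", paste0("s", 1:20)))
        w <- nbWaldTest(m, rep(1, 20), g, dispersions = 1e-8)
        pg <- summary(glm(y ~ g, family = poisson))$coefficients[2, 4]
        expect_lt(abs(w$pvalue - pg) / pg, 0.1)
    }
})

test_that("Wald fold changes agree with an independent NB reference", {
    sim <- simulateDataset(syntheticDesign(
        nPerGroup = 10, nCirc = 1, nGenes = 300, nMarkerCirc = 1,
        nLinkedGenes = 50, seed = 21))
    gc <- geneCounts(sim$experiment)
    grp <- sampleCondition(sim)
    sf <- sizeFactorsForCounts(gc)
    mine <- nbWaldTest(gc, sf, grp)
    dds <- DESeq2::DESeqDataSetFromMatrix(
        gc, S4Vectors::DataFrame(g = grp), ~g)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    ref <- DESeq2::results(dds)
    hi <- mine$baseMean > 50
    expect_gt(cor(mine$log2FoldChange[hi], ref$log2FoldChange[hi],
                  use = "complete.obs"), 0.999)
    expect_lt(median(abs(mine$log2FoldChange[hi] - ref$log2FoldChange[hi]),
                     na.rm = TRUE), 0.05)
})

test_that("planted log2 effects are recovered without bias at n = 50 per group", {
    # balanced up/down effects so library composition stays comparable
    sim <- simulateDataset(syntheticDesign(
        nPerGroup = 50, nCirc = 1, nGenes = 400, nMarkerCirc = 1,
        nLinkedGenes = 100, linkedEffect = 2, negativeFraction = 0.5,
        baselineMeanlog = log(80), baselineSdlog = 0.3, dispersion = 0.1,
        seed = 13))
    gc <- geneCounts(sim$experiment)
    de <- nbWaldTest(gc, sizeFactorsForCounts(gc), sampleCondition(sim))
    eff <- sim$truth$genes$effect
    up <- sim$truth$genes$geneId[eff > 0]
    dn <- sim$truth$genes$geneId[eff < 0]
    expect_lt(abs(mean(de[up, "log2FoldChange"]) - 2), 0.1)
    expect_lt(abs(mean(de[dn, "log2FoldChange"]) + 2), 0.1)
})

test_that("one-way ANOVA matches hand computation and the t-test identity", {
    a <- oneWayAnova(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
    expect_equal(a$statistic, 13.5)
    expect_equal(a$dfBetween, 1)
    expect_equal(a$dfWithin, 4)
    # no between-group variance
    flat <- oneWayAnova(rep(2, 6), rep(c("a", "b"), each = 3))
    expect_equal(flat$statistic, 0)
    expect_equal(flat$pvalue, 1)
    # two groups: F equals the squared equal-variance t statistic
    set.seed(5)
    v <- rnorm(12)
    lab <- rep(c("a", "b"), each = 6)
    tt <- t.test(v ~ lab, var.equal = TRUE)
    expect_equal(oneWayAnova(v, lab)$statistic, unname(tt$statistic)^2,
                 tolerance = 1e-10)
    expect_error(oneWayAnova(1:4, rep("a", 4)), "2 non-empty groups")
})
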