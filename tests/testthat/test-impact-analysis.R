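test_that("gene impact is null for duplicated groups and under label permutation", {
    set.seed(30)
    half <- matrix(rpois(300, 60) + 1L, 30, 10)
    m <- cbind(half, half)
    dimnames(m) <- list(paste0("G", 1:30), paste0("s", 1:20))
    g <- factor(rep(c("g1", "g2"), each = 10))
    names(g) <- colnames(m)
    de <- geneExpressionImpact(m, rep(1, 20), grouping = g)
    expect_equal(de$log2FoldChange, rep(0, 30), tolerance = 1e-6)
    # permuted labels on planted data: essentially nothing is significant
    sim <- simulateDataset(syntheticDesign(seed = 31))
    gc <- geneCounts(sim$experiment)
    sf <- sizeFactorsForCounts(gc)
    set.seed(5)
    nSig <- replicate(20, {
        gperm <- sample(sampleCondition(sim))
        names(gperm) <- colnames(gc)
        de <- nbWaldTest(gc, sf, gperm)
        sum(!is.na(de$padj) & de$padj <= 0.05)
    })
    expect_equal(median(nSig), 0)
})

test_that("gene impact falls back to ANOVA for more than two groups", {
    sim <- simulateDataset(syntheticDesign(
        nPerGroup = 6, nCirc = 5, nGenes = 40, nMarkerCirc = 0, seed = 32))
    x <- estimateSizeFactors(sim$experiment)
    lab <- factor(rep(c("g1", "g2", "g3"), each = 4))
    names(lab) <- colnames(geneCounts(x))
    expect_warning(de <- geneExpressionImpact(x, grouping = lab), "ANOVA")
    expect_true(all(is.na(de$log2FoldChange)))
    expect_true(all(de$pvalue >= 0 & de$pvalue <= 1, na.rm = TRUE))
})

test_that("gene ranking is deterministic with lexicographic tie-breaking", {
    de <- S4Vectors::DataFrame(stat = c(2, -1, 0.5),
                               log2FoldChange = c(1, -2, 3),
                               row.names = c("g1", "g2", "g3"))
    r <- rankGenes(de)
    expect_identical(names(r), c("g1", "g3", "g2"))
    # ties resolve by identifier, identically across calls
    deT <- S4Vectors::DataFrame(stat = c(1, 1, 2),
                                row.names = c("bbb", "aaa", "ccc"))
    expect_identical(names(rankGenes(deT)), c("ccc", "aaa", "bbb"))
    expect_identical(names(rankGenes(deT)), names(rankGenes(deT)))
    # flipping the score sign reverses the order exactly
    deF <- S4Vectors::DataFrame(stat = c(3, -2, 0.5, 1.7),
                                row.names = paste0("g", 1:4))
    deR <- deF; deR$stat <- -deR$stat
    expect_identical(names(rankGenes(deF)), rev(names(rankGenes(deR))))
    # missing scores are dropped, with a message
    deN <- S4Vectors::DataFrame(stat = c(1, NA, 2), row.names = paste0("g", 1:3))
    expect_message(rN <- rankGenes(deN), "dropped")
    expect_length(rN, 2)
})

test_that("enrichment scores reproduce hand-computed running sums", {
    scores <- c(a = 5, b = 4, c = 3, d = 2, e = 1)
    # both hits at the top: the sum reaches 5/9 + 4/9 = 1 before any miss
    r1 <- gseaPreranked(scores, list(S = c("a", "b")), minSize = 2,
                        nperm = 50, seed = 1)
    expect_equal(r1$es, 1)
    # hits at ranks 1 and 5: peak 5/6 after the first hit
    r2 <- gseaPreranked(scores, list(S = c("a", "e")), minSize = 2,
                        nperm = 50, seed = 1)
    expect_equal(r2$es, 5 / 6)
    expect_identical(r2$leadingEdge[[1]], "a")
    # unweighted statistic with a contiguous top block reaches exactly 1
    r3 <- gseaPreranked(scores, list(S = c("a", "b", "c")), weight = 0,
                        minSize = 2, nperm = 50, seed = 1)
    expect_equal(r3$es, 1)
    # a set equal to the whole ranking is skipped with a warning
    expect_warning(
        expect_warning(gseaPreranked(scores, list(S = names(scores)),
                                     minSize = 2, nperm = 10, seed = 1),
                       "whole ranking"),
        "size filters")
})

test_that("enrichment scores match brute-force and fgsea oracles", {
    set.seed(77)
    for (i in 1:50) {
        N <- sample(10:50, 1)
        scores <- sort(rnorm(N), decreasing = TRUE)
        names(scores) <- sprintf("g%03d", seq_len(N))
        nh <- sample(2:(N - 1), 1)
        members <- sort(sample.int(N, nh))
        mine <- gseaPreranked(scores, list(S = names(scores)[members]),
                              minSize = 2, maxSize = N, nperm = 2, seed = 1)
        expect_equal(mine$es, bruteES(scores, members), tolerance = 1e-12)
        refES <- fgsea::calcGseaStat(scores, selectedStats = members,
                                     gseaParam = 1)
        expect_equal(mine$es, refES, tolerance = 1e-12)
    }
})

test_that("permutation GSEA is seeded, bounded, and reproducible", {
    set.seed(12)
    scores <- sort(rnorm(200), decreasing = TRUE)
    names(scores) <- sprintf("g%03d", 1:200)
    sets <- list(top = names(scores)[1:15],
                 rand = sample(names(scores), 20))
    a <- gseaPreranked(scores, sets, nperm = 200, seed = 99)
    b <- gseaPreranked(scores, sets, nperm = 200, seed = 99)
    expect_identical(as.data.frame(a[, c("es", "nes", "pvalue", "padj")]),
                     as.data.frame(b[, c("es", "nes", "pvalue", "padj")]))
    expect_true(all(a$pvalue >= 1 / 201 & a$pvalue <= 1))
    expect_true(all(abs(a$es) <= 1))
    expect_lt(a["top", "pvalue"], 0.05)
    expect_true(all(a[["leadingEdge"]][[1]] %in% sets$top))
})

test_that("a perfectly separating gene dominates the classifier", {
    set.seed(41)
    n <- 20
    g <- factor(rep(c("g1", "g2"), each = n / 2))
    m <- matrix(rnorm(50 * n), 50, n,
                dimnames = list(paste0("G", 1:50), paste0("s", 1:n)))
    m["G10", ] <- ifelse(g == "g1", rnorm(n, 0, 0.1), rnorm(n, 8, 0.1))
    names(g) <- colnames(m)
    cls <- classifyGroups(m, g, topVar = 50, sizes = c(2, 4, 8), seed = 3,
                          ntree = 200)
    expect_identical(cls@selected$gene[1], "G10")
    expect_equal(cls@cvAccuracy, 1.0)
    expect_true(all(cls@selected$importance >= 0))
    # same seed, same report
    cls2 <- classifyGroups(m, g, topVar = 50, sizes = c(2, 4, 8), seed = 3,
                           ntree = 200)
    expect_identical(as.data.frame(cls@selected), as.data.frame(cls2@selected))
    expect_identical(cls@cvAccuracy, cls2@cvAccuracy)
})

test_that("pure-noise classification shows no systematic optimism", {
    set.seed(7)
    noise <- matrix(rnorm(100 * 20), 100,
                    dimnames = list(paste0("G", 1:100), paste0("s", 1:20)))
    ylab <- factor(rep(c("g1", "g2"), 10))
    names(ylab) <- colnames(noise)
    cls <- classifyGroups(noise, ylab, topVar = 50, sizes = c(2, 8, 32),
                          seed = 7, ntree = 200)
    expect_gte(cls@cvAccuracy, 0.2)
    expect_lte(cls@cvAccuracy, 0.8)
    # tiny groups trigger the leave-one-out fallback
    small <- noise[, 1:6]
    ys <- factor(rep(c("g1", "g2"), each = 3))
    names(ys) <- colnames(small)
    expect_warning(clsS <- classifyGroups(small, ys, topVar = 20,
                                          sizes = c(2, 4), seed = 1,
                                          ntree = 100),
                   "leave-one-out")
    expect_match(clsS@cvScheme, "leave-one-out")
})

test_that("the selected subset captures planted informative genes", {
    caps <- vapply(1:10, function(s) {
        sim <- simulateDataset(syntheticDesign(
            nPerGroup = 15, nCirc = 5, nGenes = 500, nMarkerCirc = 1,
            nLinkedGenes = 20, linkedEffect = 1, seed = 200 + s))
        x <- estimateSizeFactors(sim$experiment)
        g <- sampleCondition(sim)
        glog <- logTransform(normalizeCounts(geneCounts(x),
                                             geneSizeFactors(x)))
        cls <- classifyGroups(glog, g, topVar = 200,
                              sizes = c(2, 4, 8, 16, 32, 64), seed = s,
                              ntree = 300)
        mean(linkedGeneIds(sim) %in% cls@selected$gene)
    }, 1)
    expect_gte(mean(caps), 0.5)
})
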