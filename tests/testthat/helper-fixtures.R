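# Shared builders and independent oracles for the test suite.

sampleCondition <- function(sim) {
    g <- SummarizedExperiment::colData(sim$experiment)$condition
    g <- factor(g)
    names(g) <- colnames(circCounts(sim$experiment))
    g
}

trueMarkerIds <- function(sim) {
    sim$truth$circ$circId[sim$truth$circ$isMarker]
}

linkedGeneIds <- function(sim) {
    sim$truth$genes$geneId[sim$truth$genes$isLinked]
}

# small deterministic CircExperiment without simulation machinery
toyExperiment <- function(n = 6L, nCirc = 5L, nGenes = 8L, seed = 1L) {
    set.seed(seed)
    circ <- matrix(rpois(nCirc * n, 50), nCirc, n,
                   dimnames = list(sprintf("%d:%d-%d", 1:nCirc,
                                           1000 * (1:nCirc),
                                           1000 * (1:nCirc) + 500),
                                   paste0("s", seq_len(n))))
    genes <- matrix(rpois(nGenes * n, 100), nGenes, n,
                    dimnames = list(paste0("G", seq_len(nGenes)),
                                    paste0("s", seq_len(n))))
    CircExperiment(circ, genes)
}

# brute-force Benjamini-Hochberg step-up: explicit minimum over the tail
bruteBH <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- numeric(m)
    for (i in seq_len(m)) {
        tail <- i:m
        adj[o[i]] <- min(1, min(p[o[tail]] * m / tail))
    }
    adj
}

# brute-force GSEA running sum: literal walk over every rank position
bruteES <- function(scores, memberIdx, p = 1) {
    N <- length(scores)
    hits <- seq_len(N) %in% memberIdx
    sabs <- abs(scores)^p
    NR <- sum(sabs[hits])
    inc <- if (NR > 0) sabs / NR else rep(1 / sum(hits), N)
    dec <- 1 / (N - sum(hits))
    run <- 0
    best <- 0
    for (i in seq_len(N)) {
        run <- run + if (hits[i]) inc[i] else -dec
        if (abs(run) > abs(best) ||
            (abs(run) == abs(best) && run > best)) best <- run
    }
    unname(best)
}

# brute-force mean-silhouette over candidate k for 1-d values
bruteBestK <- function(values, ks = 2:5) {
    d <- dist(values)
    width <- vapply(ks, function(k) {
        set.seed(1)
        cl <- kmeans(values, k, nstart = 25)$cluster
        mean(cluster::silhouette(cl, d)[, "sil_width"])
    }, 1)
    ks[which.max(width)]
}
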