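#' Benjamini-Hochberg adjustment with missing-value passthrough
#'
#' Step-up FDR adjustment (via [stats::p.adjust()]) over the non-missing
#' entries; `NA`s are passed through unchanged and do not count toward the
#' family size.  Values are validated to lie in [0, 1].
#'
#' @param pvalues Numeric vector of p-values (may contain `NA`).
#' @return Adjusted p-values in the original order.
#' @export
bhAdjust <- function(pvalues) {
    ok <- !is.na(pvalues)
    if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
        stop("p-values must lie in [0, 1]")
    out <- rep(NA_real_, length(pvalues))
    out[ok] <- p.adjust(pvalues[ok], method = "BH")
    names(out) <- names(pvalues)
    out
}

#' Classical one-way ANOVA
#'
#' F = (SSB/df_B) / (SSW/df_W) with the p-value from the F distribution,
#' computed through [stats::lm()]/[stats::anova()].  The completely
#' degenerate case (zero between- and within-group variance) returns F = 0,
#' p = 1.
#'
#' @param values Numeric vector, one value per sample.
#' @param labels Group labels (>= 2 non-empty groups; total within df >= 1).
#' @return List with `statistic` (F), `pvalue`, `dfBetween`, `dfWithin`.
#' @examples
#' oneWayAnova(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))$statistic  # 13.5
#' @export
oneWayAnova <- function(values, labels) {
    g <- factor(labels)
    g <- droplevels(g)
    if (nlevels(g) < 2L) stop("at least 2 non-empty groups are required")
    if (length(values) != length(g)) stop("values and labels differ in length")
    dfW <- length(values) - nlevels(g)
    if (dfW < 1L) stop("no within-group degrees of freedom")
    if (var(values) == 0)
        return(list(statistic = 0, pvalue = 1,
                    dfBetween = nlevels(g) - 1L, dfWithin = dfW))
    tab <- anova(lm(values ~ g))
    f <- tab[["F value"]][1L]
    p <- tab[["Pr(>F)"]][1L]
    if (is.na(f)) { f <- 0; p <- 1 }  # zero within-variance, non-zero between
    if (is.na(p)) p <- 1
    list(statistic = f, pvalue = p,
         dfBetween = tab$Df[1L], dfWithin = tab$Df[2L])
}

#' Estimate negative-binomial dispersions (moments + trend shrinkage)
#'
#' Per-feature dispersion of the NB variance function `mu + alpha * mu^2`.
#' The gene-wise estimate is method-of-moments on normalized counts,
#' `alpha_raw = max(alphaMin, (v - mu) / mu^2)` with `v` the pooled
#' within-group sample variance (falling back to the overall variance when a
#' group has fewer than 2 samples).  A mean-dispersion trend
#' `alpha_tr(mu) = a0 + a1/mu` is then fitted by robust regression over the
#' features, and the returned value is the geometric combination
#' `exp((1 - weight) * log(alpha_raw) + weight * log(alpha_tr))`, an
#' empirical-Bayes style shrinkage toward the trend.  All-zero features get
#' `alphaMin` and are flagged.
#'
#' @param counts Integer count matrix, features x samples.
#' @param sizeFactors Per-sample size factors.
#' @param group Factor of group labels used for the within-group variance
#'   (or `NULL` for a single pooled group).
#' @param weight Shrinkage weight toward the trend in log space, default 0.5.
#' @param alphaMin Dispersion floor, default 1e-8.
#' @return Numeric vector of dispersions with attributes `raw`, `trend` and
#'   `flag` (`"ok"` or `"all_zero"`).
#' @export
estimateDispersionsNB <- function(counts, sizeFactors, group = NULL,
                                  weight = 0.5, alphaMin = 1e-8) {
    counts <- as.matrix(counts)
    q <- normalizeCounts(counts, sizeFactors)
    if (is.null(group)) group <- factor(rep("all", ncol(counts)))
    group <- droplevels(factor(group))
    v <- .pooledWithinVar(q, group)
    mu <- rowMeans(q)
    out <- .shrinkDispersions(rawAlpha = .momAlpha(v, mu, alphaMin), mu = mu,
                              weight = weight, alphaMin = alphaMin)
    # a zero-variance feature carries no dispersion information: floor it
    flat <- v == 0 & mu > 0
    if (any(flat)) {
        out[flat] <- alphaMin
        flag <- attr(out, "flag")
        flag[flat] <- "constant"
        attr(out, "flag") <- flag
    }
    out
}

## pooled within-group variance; overall variance when groups are too small
.pooledWithinVar <- function(q, group) {
    sizes <- table(group)
    if (any(sizes < 2L) || ncol(q) - nlevels(group) < 1L)
        return(apply(q, 1L, var))
    ss <- 0
    for (lev in levels(group)) {
        cols <- group == lev
        gm <- rowMeans(q[, cols, drop = FALSE])
        ss <- ss + rowSums((q[, cols, drop = FALSE] - gm)^2)
    }
    ss / (ncol(q) - nlevels(group))
}

.momAlpha <- function(v, mu, alphaMin) {
    raw <- ifelse(mu > 0, (v - mu) / mu^2, NA_real_)
    pmax(raw, alphaMin)
}

.shrinkDispersions <- function(rawAlpha, mu, weight, alphaMin) {
    allZero <- is.na(rawAlpha) | mu <= 0
    use <- !allZero & rawAlpha > alphaMin & is.finite(rawAlpha)
    trend <- rep(NA_real_, length(mu))
    if (sum(use) >= 10L) {
        fit <- tryCatch(
            MASS::rlm(rawAlpha[use] ~ I(1 / mu[use]), maxit = 50),
            error = function(e) NULL, warning = function(w) {
                suppressWarnings(MASS::rlm(rawAlpha[use] ~ I(1 / mu[use]),
                                           maxit = 50))
            })
        if (!is.null(fit)) {
            a0 <- max(coef(fit)[1L], 0)
            a1 <- max(coef(fit)[2L], 0)
            trend <- a0 + a1 / pmax(mu, .Machine$double.eps)
        }
    }
    if (anyNA(trend)) {
        med <- if (any(use)) median(rawAlpha[use]) else alphaMin
        trend[is.na(trend)] <- med
    }
    trend <- pmax(trend, alphaMin)
    out <- exp((1 - weight) * log(pmax(rawAlpha, alphaMin)) +
               weight * log(trend))
    out[allZero] <- alphaMin
    flag <- ifelse(allZero, "all_zero", "ok")
    structure(pmax(out, alphaMin), raw = rawAlpha, trend = trend, flag = flag,
              names = names(mu))
}

#' Two-group negative-binomial Wald test
#'
#' Fits, per feature, the NB GLM `log mu_j = beta0 + beta1 * [j in g2] +
#' log s_j` with fixed dispersion, by Fisher scoring (IRLS).  The standard
#' error of `beta1` comes from the Fisher information at the fit, the Wald
#' statistic is `beta1 / SE`, the two-sided p-value from the standard normal,
#' and the reported fold change is `log2FoldChange = beta1 / ln 2` (second
#' group level relative to the first).  P-values are BH-adjusted within the
#' call.
#'
#' Features with an all-zero group cannot support a finite MLE; their fold
#' change is computed against a half-count floor on the normalized group
#' means and they are flagged `"zero_group"` (`"all_zero"` when both groups
#' are empty, with a missing p-value).  Non-convergence after `maxit`
#' iterations flags the feature and sets its p-value to missing.
#'
#' @param counts Integer count matrix.
#' @param sizeFactors Per-sample size factors.
#' @param group Factor with exactly two non-empty levels; the first level is
#'   the reference (g1).
#' @param dispersions Optional per-feature dispersions; estimated with
#'   [estimateDispersionsNB()] when `NULL`.
#' @param maxit,tol IRLS iteration cap and convergence tolerance on the step.
#' @return `DataFrame` with columns `baseMean` (mean normalized counts over
#'   all samples), `log2FoldChange`, `lfcSE`, `stat`, `pvalue`, `padj`,
#'   `flag`.
#' @examples
#' m <- rbind(f1 = c(4L, 4L, 4L, 16L, 16L, 16L))
#' colnames(m) <- paste0("s", 1:6)
#' nbWaldTest(m, rep(1, 6), factor(rep(c("g1", "g2"), each = 3)),
#'            dispersions = 0.01)$log2FoldChange  # 2
#' @export
nbWaldTest <- function(counts, sizeFactors, group, dispersions = NULL,
                       maxit = 100L, tol = 1e-8) {
    counts <- as.matrix(counts)
    group <- droplevels(factor(group))
    if (nlevels(group) != 2L)
        stop("the Wald test requires exactly 2 non-empty groups (got ",
             nlevels(group), ")")
    if (length(group) != ncol(counts))
        stop("group length does not match the number of samples")
    if (is.null(dispersions))
        dispersions <- estimateDispersionsNB(counts, sizeFactors, group)
    alpha <- rep_len(as.numeric(dispersions), nrow(counts))

    fit <- .nbGlmTwoGroup(counts, sizeFactors, group, alpha, maxit, tol)
    pvalue <- ifelse(is.na(fit$stat), NA_real_, 2 * pnorm(-abs(fit$stat)))
    pvalue[fit$flag == "all_zero" | fit$flag == "no_converge"] <- NA_real_
    res <- S4Vectors::DataFrame(
        baseMean = fit$baseMean,
        log2FoldChange = fit$beta1 / log(2),
        lfcSE = fit$se / log(2),
        stat = fit$stat,
        pvalue = pvalue,
        padj = bhAdjust(pvalue),
        flag = fit$flag,
        row.names = rownames(counts))
    metadata(res) <- list(levels = levels(group), dispersions = alpha)
    res
}

## Vectorized Fisher scoring across features for the 2-group NB GLM.
## The 2x2 normal equations reduce to row sums over all samples (a, u1)
## and over the g2 samples (b, u2), so every feature is updated at once.
.nbGlmTwoGroup <- function(counts, sizeFactors, group, alpha,
                           maxit = 100L, tol = 1e-8) {
    g2 <- group == levels(group)[2L]
    nf <- nrow(counts); n <- ncol(counts)
    off <- matrix(log(sizeFactors), nf, n, byrow = TRUE)
    g2row <- matrix(as.numeric(g2), nf, n, byrow = TRUE)
    q <- normalizeCounts(counts, sizeFactors)
    m1 <- rowMeans(q[, !g2, drop = FALSE])
    m2 <- rowMeans(q[, g2, drop = FALSE])
    zero1 <- m1 == 0; zero2 <- m2 == 0
    flag <- rep("ok", nf)
    flag[zero1 | zero2] <- "zero_group"
    flag[zero1 & zero2] <- "all_zero"
    # half-count floor on the normalized scale for degenerate groups
    m1f <- pmax(m1, 0.5); m2f <- pmax(m2, 0.5)
    beta0 <- log(m1f)
    beta1 <- log(m2f) - log(m1f)
    active <- !(zero1 | zero2)
    converged <- !active
    for (it in seq_len(maxit)) {
        idx <- which(active & !converged)
        if (!length(idx)) break
        mu <- exp(beta0[idx] + beta1[idx] * g2row[idx, , drop = FALSE] +
                  off[idx, , drop = FALSE])
        den <- 1 + alpha[idx] * mu
        w <- mu / den
        r <- (counts[idx, , drop = FALSE] - mu) / den
        a <- rowSums(w); b <- rowSums(w * g2row[idx, , drop = FALSE])
        u1 <- rowSums(r); u2 <- rowSums(r * g2row[idx, , drop = FALSE])
        d0 <- (u1 - u2) / (a - b)
        d1 <- (a * u2 - b * u1) / (b * (a - b))
        d0 <- pmin(pmax(d0, -5), 5); d1 <- pmin(pmax(d1, -5), 5)
        beta0[idx] <- pmin(pmax(beta0[idx] + d0, -50), 50)
        beta1[idx] <- pmin(pmax(beta1[idx] + d1, -50), 50)
        converged[idx] <- pmax(abs(d0), abs(d1)) < tol
    }
    flag[active & !converged] <- "no_converge"
    # Fisher information at the final fit (floored fit for degenerate groups)
    mu <- exp(beta0 + beta1 * g2row + off)
    w <- mu / (1 + alpha * mu)
    a <- rowSums(w); b <- rowSums(w * g2row)
    se <- sqrt(a / (b * (a - b)))
    stat <- ifelse(se > 0, beta1 / se, 0)
    stat[flag == "all_zero"] <- 0
    beta1[flag == "all_zero"] <- 0
    stat[flag == "no_converge"] <- NA_real_
    list(baseMean = unname(rowMeans(q)), beta1 = unname(beta1),
         se = unname(se), stat = unname(stat), flag = flag,
         converged = converged)
}
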