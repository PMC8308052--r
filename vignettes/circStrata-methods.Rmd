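---
title: "Stratifying samples by circRNA expression: models and design choices"
author: "circStrata maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratifying samples by circRNA expression: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circStrata)
```

## The question the package answers

Circular RNAs are quantified by the reads spanning their back-splice
junction (BSJ).  When a circRNA's expression differs strongly across the
samples of an RNA-seq experiment, the samples can be split by that circRNA
alone — without looking at any annotation — and the linear transcriptome can
then be interrogated for genes whose expression follows the split.  A
circRNA whose self-defined grouping is both statistically solid and
accompanied by a coherent gene-expression footprint is a candidate regulator
(for example a miRNA sponge whose target shows an inverse expression
relationship), worth prioritizing for bench work.

`circStrata` implements this end to end: per-circRNA unsupervised sample
grouping, discriminant-circRNA selection, PCA-based ranking, and a
per-circRNA impact analysis combining negative-binomial differential
expression, random-forest classification, and preranked gene set enrichment.

## Input model and normalization

Counts enter as two non-negative integer matrices over one shared sample
set — BSJ counts (rows identified as `chrom:start-end`, kept verbatim with
no coordinate-convention conversion, since upstream quantifiers differ) and
gene counts — held together in the `CircExperiment` container.  Features
supported by fewer than 5 (circRNA) or 20 (gene) reads in at least
`ceiling(n/2)` samples are removed before analysis; both thresholds and the
sample fraction are arguments of `filterLowExpression()`.

Library scaling uses the median-of-ratios estimator (`sizeFactorsForCounts()`,
delegated to the reference implementation in DESeq2): the reference profile
is the per-feature geometric mean over samples, computed on features with
all-positive counts, and a sample's factor is the median ratio of its counts
to the reference.  Two consequences are worth knowing.  Factors are *not*
rescaled to geometric mean one, so normalized values sit on the canonical
median-of-ratios scale; and because the reference is recomputed from the
data, only factor *ratios* between samples are identified — multiplying one
sample's column by $c$ moves its factor by $c^{(n-1)/n}$ and everyone
else's by $c^{-1/n}$, preserving ratios.  Each matrix (circRNA, gene) is
its own normalization family.  Wherever a statistic wants roughly
variance-stable input — clustering, the ANOVA screen, PCA, the classifier —
the package uses $\log_2(\text{normalized}+1)$; the pseudocount is an
argument of `logTransform()`.

## Grouping samples by one circRNA

Two strategies are available, per circRNA:

* **Median split** (default): samples at or below the median normalized
  expression form `g1`, the rest `g2`.  Ties go to `g1`, which keeps the
  reading "`g1` is the low-expression group" deterministic; positive fold
  changes then mean "higher in `g2`".  An all-equal profile cannot be split
  and the circRNA is skipped with a logged reason, as is any circRNA with
  constant raw counts (its normalized profile merely mirrors library size).
* **Clustering**: k-means (25 restarts, seeded) or hierarchical clustering
  of the log-scale values, with `k` fixed or chosen to maximize the mean
  silhouette width over `k = 2..min(8, n-1)`; if no candidate yields a
  defined silhouette the split falls back to `k = 2`.  Group labels are
  re-ordered so `g1` has the lowest mean.

The grouping functions take expression values only; sample annotation never
enters, which is the point — groupings may cut across the known design and
reveal structure the annotation does not capture.

## The negative-binomial engine

Counts are modeled as NB with variance $\mu + \alpha\mu^2$.  The per-feature
dispersion $\alpha$ is estimated by method of moments on normalized counts,
$\hat\alpha = \max(\alpha_{\min}, (v - \mu)/\mu^2)$ with $v$ the pooled
within-group variance, then shrunk toward a robust mean-dispersion trend
$\alpha_{tr}(\mu) = a_0 + a_1/\mu$ by a geometric-mean combination in log
space with weight $w = 0.5$.  The floor is $\alpha_{\min} = 10^{-8}$;
zero-variance and all-zero features sit at the floor and are flagged, since
they carry no dispersion information.  This is deliberately *not* a
re-implementation of any particular tool's internals (no Cox–Reid
adjustment, no outlier bins); the contract it is tested against is
calibration — on seeded null NB data (2000 features, 10 + 10 samples,
$\alpha = 0.1$) the raw $p \le 0.05$ fraction stays within [0.03, 0.07] —
and unbiased effect recovery.

The two-group test fits $\log\mu_{fj} = \beta_0 + \beta_1\,[j \in g2] +
\log s_j$ per feature by Fisher scoring with the dispersion held fixed
(vectorized across features; convergence when the step falls below
$10^{-8}$, cap 100 iterations).  `stat = beta1/SE` with the SE from the
Fisher information, two-sided normal $p$-values, `log2FoldChange =
beta1/ln 2`, and Benjamini–Hochberg adjustment within the call.  A group
with all-zero counts admits no finite MLE; the fold change is then computed
against a half-count floor on the normalized group means and the feature is
flagged rather than silently reported.  No fold-change shrinkage is applied.
A fixed $\alpha > 0$ makes the weights scale-dependent, so exact invariance
under jointly scaling counts and size factors holds only in the Poisson
limit — the test suite checks it there.

Marker selection in median mode tests each circRNA between its own groups,
with gene-wise dispersions computed under each circRNA's own grouping and
shrunk toward one trend fitted across all circRNAs; $p$-values are
BH-corrected jointly across circRNAs (one family — the tightest defensible
reading of "corrected for multiple tests" here) and circRNAs pass at
`padj <= 0.05` and `|log2FoldChange| >= 1`.  Note the screen is
deliberately circular — the groups were chosen by the same circRNA's
expression — so the fold-change condition, not the $p$-value, does most of
the false-positive control.  Cluster mode screens with a one-way ANOVA on
log values at raw `p <= 0.05`, exactly as the screen is usually printed;
because that omits multiplicity control it is flagged in the output and a
`adjustAnova = TRUE` switch applies BH instead.

## Ranking and the impact analyses

Selected circRNAs are ranked by their contribution to the leading principal
components: columns (circRNAs, log scale) are standardized, the matrix is
decomposed by SVD, the contribution of circRNA $j$ to axis $k$ is
$100\,v_{jk}^2$, and the total over the first two axes (configurable) is the
eigenvalue-weighted combination.  Per-axis contributions sum to 100 by
construction; the default keeps the top 25 circRNAs.  Zero-variance columns
are dropped with a warning before standardization.

For each ranked circRNA, three analyses run against its grouping:

* **Differential gene expression** — the NB Wald test over the raw gene
  counts, BH within the gene family.  For `k > 2` clusters the two-group
  model does not apply; the fallback is a per-gene one-way ANOVA with a
  warning.
* **Classification** — recursive feature elimination with a random forest
  (via caret's `rfe`), after a variance pre-filter to the 1000 most variable
  genes, over subset sizes decreasing by powers of two, with k-fold
  cross-validated accuracy (leave-one-out when a group is smaller than the
  fold count).  Importances are permutation-based and clamped at zero.  The
  named backward-elimination step is realized by the RF-RFE itself with the
  variance pre-filter in front; a partial-least-squares eliminator is not
  used, since the operative calls are `rfe`/`varImp` with a forest.
* **Preranked GSEA** — genes ranked by the signed Wald statistic (fold
  change by flag; ties broken lexicographically so the ranking is
  deterministic).  The enrichment score is the classical weighted running
  sum: $|s|^p/N_R$ at members, $-1/(N - N_{hits})$ elsewhere, ES the maximum
  deviation from zero.  The null permutes set *membership* along the ranking
  (`nperm = 1000`), which remains valid at the very small sample sizes
  typical of circRNA case studies, where sample permutation would be
  hopeless.  $p = (b+1)/(nperm+1)$ against same-sign permutations, NES
  divides by the same-sign mean $|ES|$, BH across tested sets.  The leading
  edge holds members up to the maximum for positive ES and from the minimum
  onward for negative ES — the standard convention; a "before the extremum"
  reading is only meaningful for the positive case.  Sets are restricted to
  genes present in the ranking and kept when 10–500 members remain.

## The synthetic-data generator

`syntheticDesign()`/`simulateDataset()` emulate a two-condition bulk RNA-seq
experiment at desk scale: by default 10 + 10 samples, 300 circRNAs, 2000
genes; NB counts with dispersion 0.1; baseline abundances
log-normal($\log 50$, 1) so both weak and strong expressors exist,
mimicking the 0.5–900 normalized-mean span seen in published BSJ tables;
library factors uniform on [0.7, 1.4].  Two marker circRNAs carry a +2
log2 effect, each dragging 30 linked genes at $|\text{log2FC}| = 2$, half
negative — inverse circRNA–gene links of the kind a sponge axis produces.
Planted up/down gene sets and decoy sets make enrichment scoreable, and a
truth table records every planted effect.  The same design simulates
bit-identical data.

What the generator does *not* emulate: read-level noise, splicing structure,
correlated gene modules, batch effects, library-preparation biases, or any
dependence between a circRNA and its host gene's counts (the two matrices
are drawn independently, matching the analysis assumption that host genes
receive no special treatment).  Passing tests therefore demonstrate correct
statistics under the stated NB model, not robustness to everything real
data can do.

Two benchmark fixtures depart deliberately from the defaults.  The
planted-marker benchmark (one 4-fold marker among 200 nulls) fixes all
baselines at 100: the false-positive rate of a median-split screen depends
strongly on abundance (at low counts a median split alone clears
$|\text{log2FC}| \ge 1$), and pinning the abundance makes the benchmark
measure the screen, not the abundance spread — under it the marker survives
selection and the top-25 ranking in 50/50 seeded runs with ~3% null FPs.
The GLM recovery benchmark plants *balanced* up/down effects, because
one-directional composition shifts what median-of-ratios normalization can
identify and would confound the estimator's bias with the normalizer's.

## Numerical and reproducibility notes

* Every stochastic step (k-means restarts, GSEA permutations, forests,
  resampling, simulation) takes a seed; the pipeline derives per-circRNA
  seeds from its master seed, and two runs with the same configuration
  produce byte-identical tables.
* BH adjustment passes missing values through without counting them in the
  family; ANOVA on a completely degenerate profile returns $F = 0, p = 1$.
* Problem sizes used in the validation suite — 2000-feature calibration and
  recovery runs, 50 seeded marker-recovery replicates, 500 randomized
  enrichment-score oracle instances — were chosen as the smallest designs
  at which the Monte-Carlo bounds above are stable.
* The pipeline writes a manifest (versions, seed, parameters, per-stage
  counts, MD5 checksums) so a run can be audited without re-execution.

## Known limitations

Single-factor two-group contrasts only (no covariates, no likelihood-ratio
tests); no fold-change shrinkage; no GO-graph-aware enrichment — gene sets
arrive as plain GMT and their biological identity is the user's
responsibility; no miRNA expression layer, by design, since a sponged miRNA
need not change in abundance; quantification is upstream and out of scope.
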