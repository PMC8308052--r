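#' Assemble a pipeline configuration
#'
#' Collects inputs, thresholds and options for [runPipeline()].  Matrices may
#' be given as file paths (TSV/CSV, see [readCountMatrix()]) or in-memory
#' objects; a whole [CircExperiment] can be passed as `circCounts`.
#'
#' @param circCounts BSJ count matrix, path to one, or a [CircExperiment].
#' @param geneCounts Gene count matrix or path (ignored when `circCounts` is
#'   a [CircExperiment]).
#' @param sampleData Optional sample annotation table or path.
#' @param geneSets Optional gene sets: `CharacterList`, named list, or path
#'   to a GMT file.  GSEA is skipped when absent.
#' @param outDir Output directory (created if needed).
#' @param circMinCount,geneMinCount,minSampleFraction Expression filter:
#'   defaults 5 reads (circRNA) / 20 reads (gene) in at least half of the
#'   samples.
#' @param markerMode,alpha,minLog2FC Marker selection options (see
#'   [selectMarkers()]).
#' @param clusterOptions Options for [clusterSplit()] in cluster mode.
#' @param axes,topN PCA ranking options (defaults 2 axes, top 25).
#' @param gseaNperm,gseaMinSize,gseaMaxSize,gseaWeight GSEA options.
#' @param classifier List of [classifyGroups()] options
#'   (`topVar`, `folds`, `sizes`, `ntree`).
#' @param runClassifier,runGsea Toggle the per-circRNA stages.
#' @param impactCirc Optional character vector restricting the per-circRNA
#'   impact stage to given markers (default: all ranked markers).
#' @param delimiter Forwarded to the readers.
#' @param seed Master seed; per-circRNA stages derive their seeds from it.
#' @return A list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(circCounts, geneCounts = NULL, sampleData = NULL,
                           geneSets = NULL, outDir = tempfile("circstrata_"),
                           circMinCount = 5, geneMinCount = 20,
                           minSampleFraction = 0.5,
                           markerMode = c("median", "cluster"),
                           alpha = 0.05, minLog2FC = 1,
                           clusterOptions = list(),
                           axes = 2L, topN = 25L,
                           gseaNperm = 1000L, gseaMinSize = 10L,
                           gseaMaxSize = 500L, gseaWeight = 1,
                           classifier = list(), runClassifier = TRUE,
                           runGsea = TRUE, impactCirc = NULL,
                           delimiter = NULL, seed = 1L) {
    cfg <- list(circCounts = circCounts, geneCounts = geneCounts,
                sampleData = sampleData, geneSets = geneSets,
                outDir = outDir, circMinCount = circMinCount,
                geneMinCount = geneMinCount,
                minSampleFraction = minSampleFraction,
                markerMode = match.arg(markerMode), alpha = alpha,
                minLog2FC = minLog2FC, clusterOptions = clusterOptions,
                axes = as.integer(axes), topN = as.integer(topN),
                gseaNperm = as.integer(gseaNperm),
                gseaMinSize = as.integer(gseaMinSize),
                gseaMaxSize = as.integer(gseaMaxSize),
                gseaWeight = gseaWeight,
                classifier = modifyList(
                    list(topVar = 1000L, folds = 5L, sizes = NULL,
                         ntree = 500L), classifier),
                runClassifier = isTRUE(runClassifier),
                runGsea = isTRUE(runGsea), impactCirc = impactCirc,
                delimiter = delimiter, seed = as.integer(seed))
    stopifnot(cfg$alpha > 0, cfg$alpha <= 1, cfg$minSampleFraction > 0,
              cfg$minSampleFraction <= 1, cfg$topN >= 1L, cfg$axes >= 1L,
              cfg$gseaNperm >= 1L)
    class(cfg) <- "PipelineConfig"
    cfg
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the [pipelineConfig()] arguments; matrix/metadata/GMT entries
#' are file paths.  Unknown keys raise an error.
#'
#' @param path Path to a YAML file.
#' @return A `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
    vals <- yaml::read_yaml(path)
    known <- names(formals(pipelineConfig))
    bad <- setdiff(names(vals), known)
    if (length(bad))
        stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
    do.call(pipelineConfig, vals)
}

.loadInputs <- function(cfg) {
    if (is(cfg$circCounts, "CircExperiment")) return(list(
        exp = cfg$circCounts, sets = .loadSets(cfg$geneSets)))
    circ <- if (is.character(cfg$circCounts))
        readCountMatrix(cfg$circCounts, cfg$delimiter) else
        as.matrix(cfg$circCounts)
    genes <- if (is.character(cfg$geneCounts))
        readCountMatrix(cfg$geneCounts, cfg$delimiter) else
        as.matrix(cfg$geneCounts)
    meta <- cfg$sampleData
    if (is.character(meta)) meta <- readSampleTable(meta, cfg$delimiter)
    list(exp = CircExperiment(circ, genes, sampleData = meta),
         sets = .loadSets(cfg$geneSets))
}

.loadSets <- function(sets) {
    if (is.null(sets)) return(NULL)
    if (is.character(sets) && length(sets) == 1L) readGeneSets(sets)
    else if (is(sets, "CharacterList")) sets
    else CharacterList(sets)
}

.safeName <- function(id) gsub("[^A-Za-z0-9._]", "_", id)

#' Run the full workflow
#'
#' Filter weakly expressed features, estimate size factors, select and rank
#' discriminant circRNAs, and, for each ranked circRNA, test the genes
#' between its groups, classify the groups from gene expression, and run
#' preranked GSEA.  All tables are written as CSV under `cfg$outDir`
#' together with a structured log and a machine-readable `manifest.json`
#' recording the package version, seed, parameters, per-stage feature
#' counts, per-circRNA outcomes and MD5 checksums of every table.  Stage
#' failures are recorded in the manifest (partial outputs are kept) before
#' the error is re-raised; per-circRNA failures are recorded and skipped.
#'
#' @param cfg A `PipelineConfig` from [pipelineConfig()] /
#'   [readPipelineConfig()].
#' @return The manifest, invisibly.
#' @export
runPipeline <- function(cfg) {
    stopifnot(inherits(cfg, "PipelineConfig"))
    dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
    logPath <- file.path(cfg$outDir, "pipeline.log")
    logCon <- file(logPath, open = "wt")
    on.exit(close(logCon), add = TRUE)
    logLine <- function(...) {
        msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " INFO ", ...)
        writeLines(msg, logCon); message(msg)
    }
    manifest <- list(package = "circStrata",
                     version = as.character(packageVersion("circStrata")),
                     seed = cfg$seed,
                     parameters = cfg[setdiff(names(cfg),
                         c("circCounts", "geneCounts", "sampleData",
                           "geneSets", "classifier"))],
                     classifier = cfg$classifier,
                     stages = list(), perCirc = list(), errors = list(),
                     files = list())
    manifest$parameters$outDir <- NULL
    finish <- function() {
        paths <- list.files(cfg$outDir, pattern = "\\.csv$",
                            full.names = TRUE)
        sums <- md5sum(paths)
        manifest$files <<- as.list(setNames(unname(sums), basename(paths)))
        write_json(manifest, file.path(cfg$outDir, "manifest.json"),
                   auto_unbox = TRUE, pretty = TRUE, digits = NA,
                   null = "null")
    }
    runStage <- function(name, expr) {
        tryCatch(expr, error = function(e) {
            manifest$errors[[name]] <<- conditionMessage(e)
            finish()
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE)
        })
    }

    inputs <- runStage("load", .loadInputs(cfg))
    exp <- inputs$exp
    manifest$stages$input <- list(nCirc = nrow(exp), nGenes = nrow(exp@genes),
                                  nSamples = ncol(exp))
    logLine("loaded ", nrow(exp), " circRNAs, ", nrow(exp@genes),
            " genes, ", ncol(exp), " samples")

    exp <- runStage("filter", filterLowExpression(
        exp, circMinCount = cfg$circMinCount, geneMinCount = cfg$geneMinCount,
        minSampleFraction = cfg$minSampleFraction))
    manifest$stages$filter <- list(nCirc = nrow(exp),
                                   nGenes = nrow(exp@genes),
                                   circMinCount = cfg$circMinCount,
                                   geneMinCount = cfg$geneMinCount,
                                   minSampleFraction = cfg$minSampleFraction)
    logLine("after filtering: ", nrow(exp), " circRNAs, ",
            nrow(exp@genes), " genes")

    exp <- runStage("sizeFactors", estimateSizeFactors(exp))

    markers <- runStage("selectMarkers", selectMarkers(
        exp, mode = cfg$markerMode, alpha = cfg$alpha,
        minLog2FC = cfg$minLog2FC, clusterOptions = cfg$clusterOptions,
        seed = cfg$seed))
    for (i in seq_len(nrow(skippedCirc(markers))))
        logLine("skipped ", skippedCirc(markers)$circId[i], ": ",
                skippedCirc(markers)$reason[i])
    logLine(nrow(markerTable(markers)), " discriminant circRNAs of ",
            manifest$stages$filter$nCirc, " tested")
    manifest$stages$markers <- list(
        tested = length(markers@groupings),
        skipped = nrow(skippedCirc(markers)),
        selected = nrow(markerTable(markers)))

    markers <- runStage("rankMarkers",
                        rankMarkers(exp, markers, axes = cfg$axes,
                                    topN = cfg$topN))
    tab <- markerTable(markers)
    manifest$stages$ranking <- list(input = manifest$stages$markers$selected,
                                    ranked = nrow(tab), topN = cfg$topN)
    writeResultTable(tab, file.path(cfg$outDir, "markers.csv"))
    writeResultTable(skippedCirc(markers),
                     file.path(cfg$outDir, "skipped_circ.csv"))

    todo <- tab$circId
    if (!is.null(cfg$impactCirc)) todo <- intersect(todo, cfg$impactCirc)
    glog <- logTransform(normalizeCounts(geneCounts(exp),
                                         geneSizeFactors(exp)))
    for (i in seq_along(todo)) {
        id <- todo[i]
        stem <- .safeName(id)
        circSeed <- cfg$seed + i
        rec <- list(circId = id)
        ok <- tryCatch({
            grouping <- groupingFor(markers, id)
            de <- geneExpressionImpact(exp, grouping = grouping,
                                       alpha = cfg$alpha)
            writeResultTable(de, file.path(cfg$outDir,
                                           paste0(stem, ".de_genes.csv")))
            rec$nDEGenes <- metadata(de)$nSignificant
            logLine(id, ": ", rec$nDEGenes, " genes at padj <= ", cfg$alpha)
            if (cfg$runGsea && !is.null(inputs$sets) &&
                grouping@k == 2L) {
                ranking <- rankGenes(de)
                gs <- gseaPreranked(ranking, inputs$sets,
                                    weight = cfg$gseaWeight,
                                    nperm = cfg$gseaNperm,
                                    minSize = cfg$gseaMinSize,
                                    maxSize = cfg$gseaMaxSize,
                                    seed = circSeed)
                writeResultTable(gs, file.path(cfg$outDir,
                                               paste0(stem, ".gsea.csv")))
                rec$nSets <- nrow(gs)
                rec$nEnriched <- sum(!is.na(gs$padj) & gs$padj <= cfg$alpha)
            }
            if (cfg$runClassifier) {
                cls <- classifyGroups(glog, grouping,
                                      sizes = cfg$classifier$sizes,
                                      folds = cfg$classifier$folds,
                                      topVar = cfg$classifier$topVar,
                                      ntree = cfg$classifier$ntree,
                                      seed = circSeed)
                writeResultTable(cls@selected,
                                 file.path(cfg$outDir,
                                           paste0(stem, ".classifier.csv")))
                writeResultTable(cls@accuracyPath,
                                 file.path(cfg$outDir,
                                           paste0(stem,
                                                  ".classifier_path.csv")))
                rec$classifierAccuracy <- cls@cvAccuracy
                rec$classifierSize <- cls@optSize
            }
            TRUE
        }, error = function(e) {
            manifest$errors[[id]] <<- conditionMessage(e)
            logLine("ERROR for ", id, ": ", conditionMessage(e))
            FALSE
        })
        rec$ok <- ok
        manifest$perCirc[[id]] <- rec
    }
    finish()
    logLine("pipeline complete; outputs in ", cfg$outDir)
    invisible(manifest)
}
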