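#' Read a count matrix from TSV/CSV
#'
#' The expected layout is one feature per row, one sample per column, a
#' header row of sample names, and feature identifiers in the first column.
#' Values are validated (numeric, non-negative, integral after rounding
#' tolerance 0) and coerced to integers; row and column order are preserved.
#'
#' @param path Path to the file.
#' @param delimiter Field separator.  `NULL` (default) auto-detects: tab if
#'   the header contains a tab, comma otherwise.
#' @return Integer matrix with feature row names and sample column names.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeCountMatrix(matrix(1:4, 2, dimnames = list(c("a", "b"), c("s1", "s2"))), tf)
#' readCountMatrix(tf)
#' @export
readCountMatrix <- function(path, delimiter = NULL) {
    if (!file.exists(path)) stop("file not found: ", path)
    delimiter <- delimiter %||% .detectDelimiter(path)
    df <- read.table(path, sep = delimiter, header = TRUE,
                     check.names = FALSE, colClasses = "character",
                     quote = "\"", comment.char = "")
    if (ncol(df) < 2L)
        stop("expected a feature-identifier column plus at least one sample column")
    ids <- df[[1L]]
    if (anyDuplicated(ids))
        stop("duplicated feature identifier(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    samples <- colnames(df)[-1L]
    if (anyDuplicated(samples))
        stop("duplicated sample name(s) in header: ",
             paste(unique(samples[duplicated(samples)]), collapse = ", "))
    raw <- as.matrix(df[, -1L, drop = FALSE])
    vals <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
    bad <- which(is.na(vals) & !is.na(raw), arr.ind = TRUE)
    if (nrow(bad))
        stop(sprintf("non-numeric value '%s' at feature '%s', sample '%s'",
                     raw[bad[1L, 1L], bad[1L, 2L]], ids[bad[1L, 1L]],
                     samples[bad[1L, 2L]]))
    if (anyNA(vals)) {
        bad <- which(is.na(vals), arr.ind = TRUE)
        stop(sprintf("missing value at feature '%s', sample '%s'",
                     ids[bad[1L, 1L]], samples[bad[1L, 2L]]))
    }
    if (any(vals < 0)) {
        bad <- which(vals < 0, arr.ind = TRUE)
        stop(sprintf("negative count at feature '%s', sample '%s'",
                     ids[bad[1L, 1L]], samples[bad[1L, 2L]]))
    }
    m <- round(vals)
    dimnames(m) <- list(ids, samples)
    storage.mode(m) <- "integer"
    m
}

.detectDelimiter <- function(path) {
    header <- readLines(path, n = 1L)
    if (length(header) && grepl("\t", header)) "\t" else ","
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a count matrix as delimited text
#'
#' Inverse of [readCountMatrix()]: feature identifiers in the first column
#' (named `feature_id`), sample names as header.  `readCountMatrix()` on the
#' written file reproduces the matrix exactly.
#'
#' @param m Matrix with dimnames.
#' @param path Output path.
#' @param delimiter Field separator (default tab).
#' @return `path`, invisibly.
#' @export
writeCountMatrix <- function(m, path, delimiter = "\t") {
    df <- data.frame(feature_id = rownames(m), m, check.names = FALSE)
    write.table(df, path, sep = delimiter, quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a sample annotation table
#'
#' One row per sample, first column = sample identifier, remaining columns
#' arbitrary annotation.  Sample identifiers must be unique.
#'
#' @inheritParams readCountMatrix
#' @return A `DataFrame` with sample ids as row names.
#' @export
readSampleTable <- function(path, delimiter = NULL) {
    if (!file.exists(path)) stop("file not found: ", path)
    delimiter <- delimiter %||% .detectDelimiter(path)
    df <- read.table(path, sep = delimiter, header = TRUE,
                     check.names = FALSE, quote = "\"", comment.char = "")
    ids <- as.character(df[[1L]])
    if (anyDuplicated(ids))
        stop("duplicated sample identifier(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    out <- S4Vectors::DataFrame(df[, -1L, drop = FALSE], row.names = ids)
    out
}

#' Parse back-splice junction identifiers
#'
#' BSJ identifiers have the form `"chrom:start-end"` (coordinates as printed
#' by the upstream quantifier; no 0/1-based conversion is attempted).  The
#' original string is retained verbatim in the `raw` metadata column and as
#' the element names, so identifiers round-trip exactly.
#'
#' @param ids Character vector of identifiers.
#' @param hostGenes Optional parallel character vector of host-gene symbols.
#' @return A `GRanges` with metadata columns `raw` and `hostGene`.
#' @examples
#' parseBacksplice("11:33286412-33287511")
#' @export
parseBacksplice <- function(ids, hostGenes = NULL) {
    ids <- as.character(ids)
    m <- regmatches(ids, regexec("^(.+):([0-9]+)-([0-9]+)$", ids))
    bad <- vapply(m, length, 1L) != 4L
    if (any(bad))
        stop("malformed back-splice identifier(s): ",
             paste(head(ids[bad], 5L), collapse = ", "),
             " (expected 'chrom:start-end')")
    chrom <- vapply(m, `[[`, "", 2L)
    s <- as.numeric(vapply(m, `[[`, "", 3L))
    e <- as.numeric(vapply(m, `[[`, "", 4L))
    if (any(s >= e))
        stop("start must be less than end for: ",
             paste(head(ids[s >= e], 5L), collapse = ", "))
    if (is.null(hostGenes)) hostGenes <- rep(NA_character_, length(ids))
    gr <- GRanges(chrom, IRanges(start = s, end = e),
                  raw = ids, hostGene = as.character(hostGenes))
    names(gr) <- ids
    gr
}

#' Format a GRanges back to `"chrom:start-end"` identifiers
#' @param gr A `GRanges`, e.g. from [parseBacksplice()].
#' @return Character vector of identifiers.
#' @export
backspliceId <- function(gr) {
    sprintf("%s:%d-%d", as.character(seqnames(gr)), start(gr), end(gr))
}

#' Filter weakly expressed features
#'
#' Keeps the features supported by at least `minCount` reads in at least
#' `ceiling(minSampleFraction * n_samples)` samples; the default fraction 1/2
#' reads "half of the samples" as ceil(n/2).  Counts of surviving features
#' are untouched and the sample set is unchanged.  Recommended thresholds:
#' 5 reads for circRNAs and 20 for genes.
#'
#' @param x Count matrix, or a [CircExperiment] (then both assays are
#'   filtered, each with its own threshold).
#' @param minCount Minimum read count (matrix method).
#' @param minSampleFraction Fraction of samples, in (0, 1].
#' @param ... Passed to methods.
#' @return Object of the same class with the failing features dropped; a
#'   warning (not an error) if nothing survives.
#' @export
setGeneric("filterLowExpression",
    function(x, ...) standardGeneric("filterLowExpression"))

#' @rdname filterLowExpression
#' @export
setMethod("filterLowExpression", "matrix",
    function(x, minCount, minSampleFraction = 0.5, ...) {
        stopifnot(minCount >= 0, minSampleFraction > 0, minSampleFraction <= 1)
        need <- ceiling(minSampleFraction * ncol(x))
        keep <- rowSums(x >= minCount) >= need
        if (!any(keep))
            warning("no feature passes the expression filter (minCount = ",
                    minCount, ")")
        x[keep, , drop = FALSE]
    })

#' @rdname filterLowExpression
#' @param circMinCount,geneMinCount Thresholds for the two assays
#'   (CircExperiment method).
#' @export
setMethod("filterLowExpression", "CircExperiment",
    function(x, circMinCount = 5, geneMinCount = 20,
             minSampleFraction = 0.5, ...) {
        circ <- filterLowExpression(circCounts(x), circMinCount,
                                    minSampleFraction)
        genes <- filterLowExpression(geneCounts(x), geneMinCount,
                                     minSampleFraction)
        hg <- mcols(rowRanges(x))$hostGene[match(rownames(circ), rownames(x))]
        CircExperiment(circ, genes,
                       sampleData = colData(x)[colnames(circ), , drop = FALSE],
                       hostGenes = hg)
    })

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member identifiers, all
#' tab-separated.  Duplicate members within a line are collapsed.
#'
#' @param path Path to a GMT file.
#' @return A `CharacterList` of member identifiers named by set, with the
#'   descriptions in `mcols(x)$description`.  An empty file yields an empty
#'   collection.
#' @export
readGeneSets <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) {
        out <- CharacterList()
        mcols(out) <- S4Vectors::DataFrame(description = character())
        return(out)
    }
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- vapply(parts, length, 1L)
    if (any(nf < 3L))
        stop("GMT line ", which(nf < 3L)[1L],
             " has fewer than 3 fields (name, description, members...)")
    nms <- vapply(parts, `[[`, "", 1L)
    if (anyDuplicated(nms)) {
        warning("duplicated gene-set name(s) made unique: ",
                paste(unique(nms[duplicated(nms)]), collapse = ", "))
        nms <- make.unique(nms)
    }
    members <- lapply(parts, function(p) unique(p[-(1:2)]))
    out <- CharacterList(setNames(members, nms))
    mcols(out) <- S4Vectors::DataFrame(
        description = vapply(parts, `[[`, "", 2L))
    out
}

#' Write gene sets to GMT
#' @param sets Named `CharacterList` or list of character vectors; set
#'   descriptions may be supplied in `mcols(sets)$description`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGeneSets <- function(sets, path) {
    desc <- NULL
    if (is(sets, "CharacterList") && !is.null(mcols(sets)$description))
        desc <- mcols(sets)$description
    desc <- desc %||% rep("na", length(sets))
    lines <- vapply(seq_along(sets), function(i) {
        paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t")
    }, "")
    writeLines(lines, path)
    invisible(path)
}

#' Write a result table as CSV
#'
#' Feature identifiers (row names) become the first column `feature_id`;
#' list-columns are collapsed with `";"`.
#'
#' @param x `DataFrame` or data.frame with row names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeResultTable <- function(x, path) {
    df <- as.data.frame(lapply(x, function(col) {
        if (is.list(col) || is(col, "List"))
            vapply(col, paste, "", collapse = ";")
        else col
    }), optional = TRUE, check.names = FALSE)
    if (!is.null(rownames(x)))
        df <- data.frame(feature_id = rownames(x), df, check.names = FALSE)
    write.csv(df, path, row.names = FALSE, quote = TRUE)
    invisible(path)
}
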