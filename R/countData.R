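#' Construct a CountDataSet
#'
#' Bundles a matrix of read counts with the experimental condition of each
#' sample. Counts must be non-negative integers; gene IDs and sample names
#' must be unique. Tables with zero genes or a single gene are accepted here
#' (statistical operations enforce their own minima).
#'
#' @param countData integer matrix (genes x samples) or data.frame coercible
#'   to one; rownames are gene IDs, colnames are sample names.
#' @param conditions vector of condition labels, one per sample (named or in
#'   column order), or a factor.
#' @param sizeFactors optional numeric vector of per-sample size factors.
#' @return a \linkS4class{CountDataSet}.
#' @examples
#' k <- matrix(c(1L, 4L, 9L, 2L, 8L, 18L), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' cds <- newCountDataSet(k, c("A", "B"))
#' @export
newCountDataSet <- function(countData, conditions, sizeFactors = NULL) {
    countData <- as.matrix(countData)
    if (is.null(rownames(countData)))
        rownames(countData) <- paste0("gene", seq_len(nrow(countData)))
    if (is.null(colnames(countData)))
        colnames(countData) <- paste0("sample", seq_len(ncol(countData)))
    storage.mode(countData) <- "numeric"
    conditions <- validateConditions(colnames(countData), conditions)
    cd <- S4Vectors::DataFrame(
        condition = factor(conditions),
        sizeFactor = if (is.null(sizeFactors)) NA_real_ else {
            stopifnot(length(sizeFactors) == ncol(countData))
            as.numeric(sizeFactors)
        },
        row.names = colnames(countData))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = countData), colData = cd)
    new("CountDataSet", se)
}

# Resolve a condition assignment against the table's sample names; errors
# name the first offending sample.
validateConditions <- function(sampleNames, conditions) {
    if (!is.null(names(conditions))) {
        missing <- setdiff(sampleNames, names(conditions))
        if (length(missing) > 0)
            stop("no condition assigned to sample '", missing[1], "'")
        unknown <- setdiff(names(conditions), sampleNames)
        if (length(unknown) > 0)
            stop("design references unknown sample '", unknown[1], "'")
        conditions <- conditions[sampleNames]
    }
    if (length(conditions) != length(sampleNames))
        stop("need exactly one condition per sample (got ",
             length(conditions), " for ", length(sampleNames), " samples)")
    as.character(conditions)
}

#' Read a tab-separated count table
#'
#' Expects a header row of sample names (first cell ignored, conventionally
#' "gene_id"), gene IDs in the first column, and non-negative integer counts
#' in the remaining cells. No quoting; UTF-8.
#'
#' @param path path to the TSV file.
#' @return numeric matrix of counts with gene IDs as rownames and sample
#'   names as colnames, row and column order preserved.
#' @export
readCountTable <- function(path) {
    if (!file.exists(path))
        stop("count table file not found: ", path)
    df <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                     check.names = FALSE, colClasses = "character",
                     stringsAsFactors = FALSE)
    ids <- df[[1]]
    if (anyDuplicated(ids))
        stop("duplicate gene ID: '", ids[duplicated(ids)][1], "'")
    samples <- colnames(df)[-1]
    if (anyDuplicated(samples))
        stop("duplicate sample name: '", samples[duplicated(samples)][1], "'")
    m <- matrix(NA_real_, nrow = nrow(df), ncol = length(samples),
                dimnames = list(ids, samples))
    for (j in seq_along(samples)) {
        cell <- df[[j + 1]]
        num <- suppressWarnings(as.numeric(cell))
        bad <- which(is.na(num) | num < 0 | num != round(num))
        if (length(bad) > 0)
            stop(sprintf(
                "invalid count '%s' at row %d (gene '%s'), column '%s': cells must be non-negative integers",
                cell[bad[1]], bad[1], ids[bad[1]], samples[j]))
        m[, j] <- num
    }
    m
}

#' Write a count table as TSV
#'
#' Inverse of \code{\link{readCountTable}}: write-then-read round trips a
#' count matrix exactly.
#'
#' @param counts count matrix (or a \linkS4class{CountDataSet}).
#' @param path output path.
#' @export
writeCountTable <- function(counts, path) {
    if (is(counts, "CountDataSet"))
        counts <- counts(counts)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(c("gene_id", colnames(counts)), collapse = "\t"), con)
    if (nrow(counts) > 0) {
        body <- cbind(rownames(counts),
                      format(counts, scientific = FALSE, trim = TRUE))
        writeLines(apply(body, 1, paste, collapse = "\t"), con)
    }
}

#' Read a two-column design table (sample, condition)
#'
#' @param path path to a TSV with columns sample and condition (header
#'   optional as long as the columns are in that order).
#' @return named character vector mapping sample name to condition.
#' @export
readDesign <- function(path) {
    if (!file.exists(path))
        stop("design file not found: ", path)
    df <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                     colClasses = "character", check.names = FALSE)
    if (ncol(df) < 2)
        stop("design file must have two columns: sample, condition")
    setNames(df[[2]], df[[1]])
}

#' @describeIn newCountDataSet the raw count matrix.
#' @param object a \code{CountDataSet}.
#' @export
setMethod("counts", "CountDataSet", function(object)
    SummarizedExperiment::assay(object, "counts"))

#' Condition labels of a CountDataSet
#'
#' @param object a \linkS4class{CountDataSet}.
#' @param ... ignored.
#' @return factor of condition labels, named by sample.
#' @export
setMethod("conditions", "CountDataSet", function(object, ...)
    setNames(object$condition, colnames(object)))

#' Per-sample size factors of a CountDataSet
#'
#' @param object a \linkS4class{CountDataSet}.
#' @return named numeric vector, or NULL if not yet estimated.
#' @export
setMethod("sizeFactors", "CountDataSet", function(object) {
    sf <- object$sizeFactor
    if (is.null(sf) || all(is.na(sf))) return(NULL)
    setNames(sf, colnames(object))
})

#' @rdname sizeFactors-CountDataSet-method
#' @param value numeric vector of strictly positive factors, one per sample.
#' @export
setReplaceMethod("sizeFactors", "CountDataSet", function(object, value) {
    if (length(value) != ncol(object))
        stop("need one size factor per sample")
    if (any(!is.finite(value) | value <= 0))
        stop("size factors must be strictly positive and finite")
    object$sizeFactor <- as.numeric(value)
    validObject(object)
    object
})

#' @rdname varianceFunctions
#' @export
setMethod("varianceFunctions", "CountDataSet", function(object)
    object@fitInfo)

#' Replicate counts per condition
#'
#' @param object a \linkS4class{CountDataSet}.
#' @return named integer vector m_rho: number of samples per condition.
#' @export
replicateCounts <- function(object) {
    tab <- table(conditions(object))
    setNames(as.integer(tab), names(tab))
}
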