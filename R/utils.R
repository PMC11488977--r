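#' Normalize gene identifiers to a canonical case
#'
#' Marker catalogs, GMT files and expression matrices frequently disagree
#' on symbol case (e.g. "Ins1" vs "INS1"). All readers in this package
#' funnel identifiers through this one function so matching is consistent
#' everywhere; it is idempotent.
#'
#' @param ids Character vector of gene identifiers.
#' @return Character vector, uppercased and whitespace-trimmed.
#' @examples
#' normalizeGeneIds(c(" Ins1", "GCG "))
#' @export
normalizeGeneIds <- function(ids) {
    toupper(trimws(as.character(ids)))
}

#' Library-size log-normalization of a count matrix
#'
#' Scales each cell to a common target total and applies log1p — the
#' standard single-cell normalization. By default the target is the
#' median library size of the data (the scanpy convention), which keeps
#' normalized values on the scale of the observed counts whatever the
#' size of the gene panel; a fixed target such as 1e4 can be requested
#' instead. Accepts a \linkS4class{SingleCellExperiment} (genes x cells;
#' adds/uses the "logcounts" assay) or a plain matrix in the same
#' orientation.
#'
#' @param x SingleCellExperiment with a "counts" assay, or genes x cells
#'   matrix of nonnegative counts.
#' @param scale Target library size; NULL (default) uses the median
#'   library size.
#' @return Same class as the input, with log-normalized values (for an
#'   SCE, in assay "logcounts").
#' @export
logNormalize <- function(x, scale = NULL) {
    if (is(x, "SingleCellExperiment")) {
        cts <- SummarizedExperiment::assay(x, "counts")
        SummarizedExperiment::assay(x, "logcounts") <-
            .logNormalizeMatrix(cts, scale)
        return(x)
    }
    .logNormalizeMatrix(x, scale)
}

.logNormalizeMatrix <- function(cts, scale = NULL) {
    libs <- Matrix::colSums(cts)
    if (is.null(scale)) scale <- max(stats::median(libs), 1)
    libs[libs == 0] <- 1      # all-zero cells stay all-zero
    out <- log1p(sweep(as.matrix(cts), 2L, libs / scale, "/"))
    dimnames(out) <- dimnames(cts)
    out
}

# Library-size-normalized counts (no log), scaled to the median library;
# genes x cells.
.normcountsOf <- function(sce) {
    cts <- as.matrix(SummarizedExperiment::assay(sce, "counts"))
    libs <- colSums(cts)
    scale <- max(stats::median(libs), 1)
    libs[libs == 0] <- 1
    sweep(cts, 2L, libs / scale, "/")
}

# Log-normalized matrix of an SCE, computing it if absent; genes x cells.
.logcountsOf <- function(sce) {
    if ("logcounts" %in% SummarizedExperiment::assayNames(sce))
        return(as.matrix(SummarizedExperiment::assay(sce, "logcounts")))
    .logNormalizeMatrix(SummarizedExperiment::assay(sce, "counts"))
}

# Counts assay as a dense matrix; genes x cells.
.countsOf <- function(sce) {
    as.matrix(SummarizedExperiment::assay(sce, "counts"))
}

# Row-wise softmax with max subtraction for stability.
.rowSoftmax <- function(m) {
    m <- m - apply(m, 1L, max)
    e <- exp(m)
    e / rowSums(e)
}

# Argmax per row with ties broken toward the lowest column index.
.rowArgmax <- function(m) {
    apply(m, 1L, which.max)
}

# Restrict a marker catalog to genes present in `genes`; warns about and
# drops absent markers; types losing all markers are kept with an empty
# list (callers decide how to handle them).
.intersectCatalog <- function(cat, genes) {
    mk <- lapply(cat@markers, function(m) intersect(m, genes))
    missing <- sum(lengths(cat@markers)) - sum(lengths(mk))
    if (missing > 0)
        warning(missing, " marker(s) absent from the expression matrix ",
                "were dropped")
    mk
}

.checkSeed <- function(seed) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    as.integer(seed)
}
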