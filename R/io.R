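#' Read a cells-by-genes expression matrix
#'
#' Reads raw counts from one of three on-disk layouts into a
#' \linkS4class{SingleCellExperiment} (genes in rows, cells in columns,
#' assay "counts" — the Bioconductor orientation, regardless of how the
#' file stores it):
#' \describe{
#'   \item{mtx_dir}{a directory with \code{matrix.mtx} plus
#'     \code{genes.tsv} (or \code{features.tsv}) and \code{barcodes.tsv}.
#'     Orientation is auto-detected by matching matrix dimensions against
#'     the companion file lengths; a square matrix whose companions have
#'     equal lengths is ambiguous and requires \code{orientation}.}
#'   \item{csv}{dense CSV, cells in rows: first column cell ids, header
#'     gene ids.}
#'   \item{h5ad}{not supported by this installation; a clear error points
#'     to the supported formats.}
#' }
#'
#' @param path File or directory path.
#' @param fmt One of "mtx_dir", "csv", "h5ad".
#' @param orientation For ambiguous square mtx matrices only:
#'   "genes_x_cells" or "cells_x_genes".
#' @param caseNormalize Uppercase gene identifiers (default TRUE).
#' @return A \linkS4class{SingleCellExperiment} with assay "counts".
#' @export
readExpression <- function(path, fmt = c("mtx_dir", "csv", "h5ad"),
                           orientation = NULL, caseNormalize = TRUE) {
    fmt <- match.arg(fmt)
    if (!file.exists(path))
        stop("path does not exist: ", path)
    counts <- switch(fmt,
        mtx_dir = .readMtxDir(path, orientation),
        csv     = .readExprCsv(path),
        h5ad    = stop("h5ad input is not supported by this installation; ",
                       "export to Matrix Market (mtx_dir) or dense CSV"))
    if (caseNormalize) rownames(counts) <- normalizeGeneIds(rownames(counts))
    dup <- unique(rownames(counts)[duplicated(rownames(counts))])
    if (length(dup))
        stop("duplicate gene ids after case normalization: ",
             paste(utils::head(dup, 5), collapse = ", "))
    if (anyDuplicated(colnames(counts)))
        stop("duplicate cell ids")
    if (any(counts < 0))
        stop("negative values in count matrix")
    SingleCellExperiment::SingleCellExperiment(assays = list(counts = counts))
}

.readMtxDir <- function(dir, orientation = NULL) {
    if (!dir.exists(dir))
        stop("mtx_dir must be a directory: ", dir)
    mtx <- file.path(dir, "matrix.mtx")
    genef <- file.path(dir, "genes.tsv")
    if (!file.exists(genef)) genef <- file.path(dir, "features.tsv")
    barf <- file.path(dir, "barcodes.tsv")
    for (f in c(mtx, genef, barf))
        if (!file.exists(f))
            stop("missing companion file: ", basename(f))
    if (file.size(mtx) == 0L)
        stop("format error: empty matrix.mtx")
    m <- tryCatch(Matrix::readMM(mtx),
                  error = function(e) stop("format error in matrix.mtx: ",
                                           conditionMessage(e)))
    genes <- utils::read.table(genef, sep = "\t", header = FALSE,
                               stringsAsFactors = FALSE)[[1L]]
    cells <- utils::read.table(barf, sep = "\t", header = FALSE,
                               stringsAsFactors = FALSE)[[1L]]
    gxc <- nrow(m) == length(genes) && ncol(m) == length(cells)
    cxg <- nrow(m) == length(cells) && ncol(m) == length(genes)
    if (gxc && cxg) {           # square with equally long companions
        if (is.null(orientation))
            stop("ambiguous square matrix; pass orientation=")
        gxc <- orientation == "genes_x_cells"
    } else if (!gxc && !cxg) {
        stop("matrix dimensions match neither companion file ",
             "(genes: ", length(genes), ", barcodes: ", length(cells),
             ", matrix: ", nrow(m), " x ", ncol(m), ")")
    }
    m <- as.matrix(m)
    if (!gxc) m <- t(m)
    dimnames(m) <- list(genes, cells)
    m
}

.readExprCsv <- function(path) {
    if (file.size(path) == 0L)
        stop("format error: empty CSV file")
    df <- tryCatch(utils::read.csv(path, row.names = 1L, check.names = FALSE),
                   error = function(e) stop("format error in expression CSV: ",
                                            conditionMessage(e)))
    if (ncol(df) == 0L)
        stop("format error: expression CSV has no gene columns")
    t(as.matrix(df))            # file is cells x genes
}

#' Read a marker catalog
#'
#' Two dialects: a two-column CSV with columns \code{cell_type} and
#' \code{gene} (one marker per row, catalog order = first-appearance
#' order), or GMT where each row is \code{type, description, genes...}.
#'
#' @param path File path.
#' @param fmt "csv" or "gmt".
#' @param caseNormalize Uppercase gene identifiers (default TRUE).
#' @return A \linkS4class{MarkerCatalog}.
#' @export
readMarkers <- function(path, fmt = c("csv", "gmt"), caseNormalize = TRUE) {
    fmt <- match.arg(fmt)
    if (!file.exists(path)) stop("path does not exist: ", path)
    if (fmt == "csv") {
        df <- utils::read.csv(path, stringsAsFactors = FALSE)
        if (!all(c("cell_type", "gene") %in% names(df)))
            stop("marker CSV must have columns cell_type and gene")
        types <- unique(df$cell_type)
        markers <- lapply(types,
                          function(ty) df$gene[df$cell_type == ty])
        names(markers) <- types
    } else {
        pc <- readGMT(path, caseNormalize = FALSE)
        markers <- pathwayGenes(pc)
    }
    if (any(lengths(markers) == 0L))
        stop("empty marker list for a declared cell type")
    MarkerCatalog(markers, caseNormalize = caseNormalize)
}

#' Read gene sets from a GMT file
#'
#' Tab-separated GMT: set name, description (discarded), then member
#' genes. Rows with fewer than three fields are a format error reported
#' with their line number. Parsing delegates to
#' \code{fgsea::gmtPathways()} after validation.
#'
#' @param path File path.
#' @param caseNormalize Uppercase gene identifiers (default TRUE).
#' @return A \linkS4class{PathwayCollection}.
#' @export
readGMT <- function(path, caseNormalize = TRUE) {
    if (!file.exists(path)) stop("path does not exist: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) stop("format error: empty GMT file")
    nf <- lengths(strsplit(lines, "\t", fixed = TRUE))
    if (any(nf < 3L))
        stop("format error: GMT line ", which(nf < 3L)[1L],
             " has fewer than 3 tab-separated fields")
    sets <- fgsea::gmtPathways(path)
    if (anyDuplicated(names(sets)))
        stop("duplicate gene set names in GMT")
    PathwayCollection(sets, caseNormalize = caseNormalize)
}

#' Build the binary pathway-membership mask for a model gene list
#'
#' Intersects every pathway with \code{genes}. Pathways with no member in
#' the gene list are dropped with a warning. Genes belonging to no
#' retained pathway are, by default, removed from the model gene list
#' (they could never influence any token); alternatively they are pooled
#' into one synthetic "UNASSIGNED" pathway row.
#'
#' @param pc A \linkS4class{PathwayCollection}.
#' @param genes Character vector of candidate model genes.
#' @param keepUnassigned If TRUE, collect uncovered genes into an
#'   "UNASSIGNED" row instead of dropping them (default FALSE).
#' @return A \linkS4class{PathwayMask} whose column order fixes the model
#'   gene order.
#' @export
buildPathwayMask <- function(pc, genes, keepUnassigned = FALSE) {
    stopifnot(is(pc, "PathwayCollection"), length(genes) > 0L)
    genes <- unique(genes)
    sets <- lapply(pathwayGenes(pc), intersect, genes)
    empty <- lengths(sets) == 0L
    if (all(empty))
        stop("no pathway overlaps the gene list")
    if (any(empty)) {
        warning(sum(empty), " pathway(s) with no gene in the expression ",
                "matrix were dropped: ",
                paste(utils::head(names(sets)[empty], 5), collapse = ", "))
        sets <- sets[!empty]
    }
    covered <- unique(unlist(sets, use.names = FALSE))
    uncovered <- setdiff(genes, covered)
    if (length(uncovered)) {
        if (keepUnassigned) {
            sets <- c(sets, list(UNASSIGNED = uncovered))
        } else {
            genes <- setdiff(genes, uncovered)
        }
    }
    mask <- matrix(0, nrow = length(sets), ncol = length(genes),
                   dimnames = list(names(sets), genes))
    for (p in names(sets))
        mask[p, sets[[p]]] <- 1
    new("PathwayMask", mask = mask)
}

#' Read a gene embedding table
#'
#' TSV without header: gene id followed by d numeric coordinates. Ragged
#' rows are a format error.
#'
#' @param path File path.
#' @param caseNormalize Uppercase gene identifiers (default TRUE).
#' @return A \linkS4class{GeneEmbedding}.
#' @export
readGeneEmbedding <- function(path, caseNormalize = TRUE) {
    if (!file.exists(path)) stop("path does not exist: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) stop("format error: empty embedding file")
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (length(unique(nf)) != 1L)
        stop("format error: ragged vector lengths in embedding table ",
             "(line ", which(nf != nf[1L])[1L], ")")
    ids <- vapply(parts, `[[`, "", 1L)
    vec <- t(vapply(parts, function(p) as.numeric(p[-1L]),
                    numeric(nf[1L] - 1L)))
    if (anyNA(vec))
        stop("format error: non-numeric embedding coordinates")
    rownames(vec) <- ids
    GeneEmbedding(vec, caseNormalize = caseNormalize)
}

#' Write annotation predictions to CSV
#'
#' Columns: \code{cell_id}, \code{predicted_type}, then one probability
#' column per cell type.
#'
#' @param result An \linkS4class{AnnotationResult}.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
writePredictions <- function(result, path) {
    stopifnot(is(result, "AnnotationResult"))
    pr <- typeProbabilities(result)
    df <- data.frame(cell_id = rownames(pr),
                     predicted_type = predictedTypes(result),
                     pr, check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE)
    invisible(path)
}

#' Write an attention-profile matrix to CSV
#'
#' Cells in rows (first column \code{cell_id}), pathways in columns.
#'
#' @param attention Numeric cells x pathways matrix with dimnames.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
writeAttention <- function(attention, path) {
    stopifnot(is.matrix(attention), !is.null(rownames(attention)))
    df <- data.frame(cell_id = rownames(attention), attention,
                     check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE)
    invisible(path)
}

#' Read an attention-profile CSV written by [writeAttention()]
#'
#' @param path CSV path.
#' @return Numeric cells x pathways matrix.
#' @export
readAttention <- function(path) {
    df <- utils::read.csv(path, check.names = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df[[1L]]
    m
}
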