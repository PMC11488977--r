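#' @importFrom S4Vectors isSingleString
NULL

# ---------------------------------------------------------------------------
# MarkerCatalog
# ---------------------------------------------------------------------------

#' Catalog of marker genes per cell type
#'
#' Ordered set of candidate cell types, each with a non-empty,
#' duplicate-free list of marker gene identifiers. This is the only prior
#' knowledge the annotation pipeline requires.
#'
#' @slot typeNames character vector of T >= 2 unique cell type names.
#' @slot markers named list (one element per type, catalog order) of
#'   character vectors of marker gene identifiers.
#'
#' @seealso [readMarkers()], [computeSpecificity()]
#' @export
setClass("MarkerCatalog",
    representation(typeNames = "character", markers = "list"))

setValidity("MarkerCatalog", function(object) {
    msg <- NULL
    if (length(object@typeNames) < 2L)
        msg <- c(msg, "at least 2 cell types are required")
    if (anyDuplicated(object@typeNames))
        msg <- c(msg, "cell type names must be unique")
    if (length(object@markers) != length(object@typeNames))
        msg <- c(msg, "one marker list per type is required")
    if (!identical(names(object@markers), object@typeNames))
        msg <- c(msg, "marker list names must equal typeNames")
    for (ty in names(object@markers)) {
        m <- object@markers[[ty]]
        if (length(m) == 0L)
            msg <- c(msg, sprintf("type '%s' has an empty marker list", ty))
        if (anyDuplicated(m))
            msg <- c(msg, sprintf("type '%s' has duplicate markers", ty))
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a MarkerCatalog
#'
#' @param markers Named list of character vectors: names are cell types,
#'   elements are marker gene identifiers. Duplicate markers within a type
#'   are removed with a warning.
#' @param caseNormalize Uppercase all gene identifiers (default TRUE), so
#'   catalogs and expression matrices that differ only in case still match.
#' @return A \linkS4class{MarkerCatalog}.
#' @examples
#' MarkerCatalog(list(Alpha = c("GCG", "TTR"), Beta = c("INS", "IAPP")))
#' @export
MarkerCatalog <- function(markers, caseNormalize = TRUE) {
    stopifnot(is.list(markers), !is.null(names(markers)))
    markers <- lapply(markers, function(m) {
        m <- as.character(m)
        if (caseNormalize) m <- normalizeGeneIds(m)
        if (anyDuplicated(m)) {
            warning("duplicate markers within a type were removed")
            m <- unique(m)
        }
        m
    })
    new("MarkerCatalog", typeNames = names(markers), markers = markers)
}

#' @rdname typeNames
#' @export
setMethod("typeNames", "MarkerCatalog", function(x) x@typeNames)

#' @rdname markerGenes
#' @export
setMethod("markerGenes", "MarkerCatalog", function(x, type = NULL) {
    if (is.null(type)) return(x@markers)
    if (!type %in% x@typeNames)
        stop("unknown cell type: ", type)
    x@markers[[type]]
})

setMethod("show", "MarkerCatalog", function(object) {
    n <- lengths(object@markers)
    cat("MarkerCatalog with", length(object@typeNames), "cell types\n")
    cat("  markers per type:", paste0(object@typeNames, " (", n, ")",
        collapse = ", "), "\n")
})

# ---------------------------------------------------------------------------
# PathwayCollection
# ---------------------------------------------------------------------------

#' Collection of gene sets (pathways)
#'
#' Named gene sets, typically read from a GMT file, used to constrain the
#' classifier's token embedding so each token corresponds to one pathway.
#'
#' @slot pathwayNames character vector of unique set names.
#' @slot genes named list of character vectors (members, duplicate-free).
#'
#' @seealso [readGMT()], [buildPathwayMask()]
#' @export
setClass("PathwayCollection",
    representation(pathwayNames = "character", genes = "list"))

setValidity("PathwayCollection", function(object) {
    msg <- NULL
    if (length(object@pathwayNames) < 1L)
        msg <- c(msg, "at least one pathway is required")
    if (anyDuplicated(object@pathwayNames))
        msg <- c(msg, "pathway names must be unique")
    if (!identical(names(object@genes), object@pathwayNames))
        msg <- c(msg, "gene list names must equal pathwayNames")
    if (any(vapply(object@genes, anyDuplicated, 1L) > 0L))
        msg <- c(msg, "pathway gene sets must be duplicate-free")
    if (is.null(msg)) TRUE else msg
})

#' Construct a PathwayCollection
#'
#' @param genes Named list of character vectors (set name -> member genes).
#'   Duplicate genes within a set are collapsed.
#' @param caseNormalize Uppercase gene identifiers (default TRUE).
#' @return A \linkS4class{PathwayCollection}.
#' @examples
#' PathwayCollection(list(GLYCOLYSIS = c("HK1", "PFKL"), TCA = c("CS", "IDH1")))
#' @export
PathwayCollection <- function(genes, caseNormalize = TRUE) {
    stopifnot(is.list(genes), !is.null(names(genes)))
    genes <- lapply(genes, function(g) {
        g <- as.character(g)
        if (caseNormalize) g <- normalizeGeneIds(g)
        unique(g)
    })
    new("PathwayCollection", pathwayNames = names(genes), genes = genes)
}

#' @rdname pathwayNames
#' @export
setMethod("pathwayNames", "PathwayCollection", function(x) x@pathwayNames)

#' Member genes of each pathway
#'
#' @param x A \linkS4class{PathwayCollection}.
#' @return Named list of character vectors.
#' @export
pathwayGenes <- function(x) {
    stopifnot(is(x, "PathwayCollection"))
    x@genes
}

setMethod("show", "PathwayCollection", function(object) {
    sz <- lengths(object@genes)
    cat("PathwayCollection with", length(object@pathwayNames),
        "gene sets (sizes", min(sz), "-", max(sz), ")\n")
})

# ---------------------------------------------------------------------------
# GeneEmbedding
# ---------------------------------------------------------------------------

#' Dense gene embedding table
#'
#' External low-dimensional gene representations used by the cosine,
#' logistic-regression and pseudo-cell relevance strategies.
#'
#' @slot vectors numeric matrix, genes in rows (rownames are gene ids),
#'   embedding dimensions in columns; all entries finite, >= 2 columns.
#'
#' @seealso [readGeneEmbedding()], [embedCellsAndTypes()]
#' @export
setClass("GeneEmbedding", representation(vectors = "matrix"))

setValidity("GeneEmbedding", function(object) {
    v <- object@vectors
    msg <- NULL
    if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
        msg <- c(msg, "vectors must have unique gene-id rownames")
    if (ncol(v) < 2L)
        msg <- c(msg, "embedding dimension must be >= 2")
    if (!all(is.finite(v)))
        msg <- c(msg, "embedding vectors must be finite")
    if (is.null(msg)) TRUE else msg
})

#' Construct a GeneEmbedding
#'
#' @param vectors Numeric matrix with gene ids as rownames.
#' @param caseNormalize Uppercase gene identifiers (default TRUE).
#' @return A \linkS4class{GeneEmbedding}.
#' @export
GeneEmbedding <- function(vectors, caseNormalize = TRUE) {
    vectors <- as.matrix(vectors)
    if (caseNormalize) rownames(vectors) <- normalizeGeneIds(rownames(vectors))
    new("GeneEmbedding", vectors = vectors)
}

#' @rdname geneIds
#' @export
setMethod("geneIds", "GeneEmbedding", function(x) rownames(x@vectors))

#' Embedding matrix of a GeneEmbedding
#'
#' @param x A \linkS4class{GeneEmbedding}.
#' @return Numeric matrix, genes in rows.
#' @export
embeddingMatrix <- function(x) {
    stopifnot(is(x, "GeneEmbedding"))
    x@vectors
}

setMethod("show", "GeneEmbedding", function(object) {
    cat("GeneEmbedding:", nrow(object@vectors), "genes x",
        ncol(object@vectors), "dimensions\n")
})

# ---------------------------------------------------------------------------
# Cells-by-types score matrices
# ---------------------------------------------------------------------------

#' Virtual parent of cells-by-types score matrices
#'
#' @slot values numeric matrix, cells in rows, types in columns, with
#'   cell ids and type names as dimnames; all entries finite.
#' @slot strategy character tag recording which relevance strategy (or
#'   normalization) produced the matrix.
#' @export
setClass("CellTypeScores",
    representation("VIRTUAL", values = "matrix", strategy = "character"))

setValidity("CellTypeScores", function(object) {
    v <- object@values
    msg <- NULL
    if (is.null(rownames(v)) || is.null(colnames(v)))
        msg <- c(msg, "values must carry cell ids and type names as dimnames")
    if (!all(is.finite(v)))
        msg <- c(msg, "all score entries must be finite")
    if (is.null(msg)) TRUE else msg
})

#' Raw cell-type relevance scores
#'
#' Unnormalized association scores R between each cell and each candidate
#' type, as produced by one of the six relevance strategies. Scores may be
#' negative (cosine, specificity-weighted z-scores) and rows need not sum
#' to one.
#'
#' @seealso [scoreRelevance()], [normalizeToSimplex()]
#' @export
setClass("RelevanceMatrix", contains = "CellTypeScores")

#' Per-cell probability simplex over cell types (soft pseudo-labels)
#'
#' Row-stochastic cells-by-types matrix used as the soft training target
#' of the classifier's pretraining phase.
#'
#' @seealso [normalizeToSimplex()], [pretrain()]
#' @export
setClass("PseudoLabelMatrix", contains = "CellTypeScores")

setValidity("PseudoLabelMatrix", function(object) {
    v <- object@values
    msg <- NULL
    if (any(v < -1e-9) || any(v > 1 + 1e-9))
        msg <- c(msg, "pseudo-label entries must lie in [0, 1]")
    if (any(abs(rowSums(v) - 1) > 1e-6))
        msg <- c(msg, "every pseudo-label row must sum to 1 (tol 1e-6)")
    if (is.null(msg)) TRUE else msg
})

.newScores <- function(class, values, strategy) {
    new(class, values = values, strategy = strategy)
}

#' @rdname scoreMatrix
#' @export
setMethod("scoreMatrix", "CellTypeScores", function(x) x@values)

#' @rdname typeNames
#' @export
setMethod("typeNames", "CellTypeScores", function(x) colnames(x@values))

#' Strategy tag of a score matrix
#'
#' @param x A \linkS4class{CellTypeScores} derivative.
#' @return Single string.
#' @export
scoreStrategy <- function(x) {
    stopifnot(is(x, "CellTypeScores"))
    x@strategy
}

setMethod("show", "CellTypeScores", function(object) {
    cat(class(object), ":", nrow(object@values), "cells x",
        ncol(object@values), "types, strategy =", object@strategy, "\n")
})

# ---------------------------------------------------------------------------
# SpecificityScores
# ---------------------------------------------------------------------------

#' Cell type specificity scores of pooled marker genes
#'
#' For each marker in the pooled catalog, the min-max rescaled inverse of
#' the number of cell types listing it: a marker private to one type (when
#' some marker is shared more widely) scores 1, the most widely shared
#' marker scores 0.
#'
#' @slot scores named numeric vector in [0, 1] (names = pooled markers).
#' @slot typesPerMarker named integer vector, number of types per marker.
#' @seealso [computeSpecificity()]
#' @export
setClass("SpecificityScores",
    representation(scores = "numeric", typesPerMarker = "integer"))

setValidity("SpecificityScores", function(object) {
    msg <- NULL
    if (!identical(names(object@scores), names(object@typesPerMarker)))
        msg <- c(msg, "scores and typesPerMarker must share names")
    if (any(object@scores < 0 | object@scores > 1))
        msg <- c(msg, "specificity scores must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
})

#' Specificity score vector
#'
#' @param x A \linkS4class{SpecificityScores}.
#' @return Named numeric vector in [0, 1].
#' @export
specificityScores <- function(x) {
    stopifnot(is(x, "SpecificityScores"))
    x@scores
}

#' Number of cell types listing each pooled marker
#'
#' @param x A \linkS4class{SpecificityScores}.
#' @return Named integer vector.
#' @export
typesPerMarker <- function(x) {
    stopifnot(is(x, "SpecificityScores"))
    x@typesPerMarker
}

setMethod("show", "SpecificityScores", function(object) {
    cat("SpecificityScores for", length(object@scores), "pooled markers;",
        sum(object@scores == 1), "fully specific\n")
})

# ---------------------------------------------------------------------------
# CellTypeEmbeddings
# ---------------------------------------------------------------------------

#' Cells and cell types mapped into a shared embedding space
#'
#' Cell vectors are expression-weighted averages of gene embeddings; type
#' vectors are unweighted averages of their marker gene embeddings.
#'
#' @slot cellVectors numeric matrix, cells x d (rownames cell ids).
#' @slot typeVectors numeric matrix, types x d (rownames type names).
#' @seealso [embedCellsAndTypes()]
#' @export
setClass("CellTypeEmbeddings",
    representation(cellVectors = "matrix", typeVectors = "matrix"))

setValidity("CellTypeEmbeddings", function(object) {
    msg <- NULL
    if (ncol(object@cellVectors) != ncol(object@typeVectors))
        msg <- c(msg, "cell and type vectors must share dimension")
    if (!all(is.finite(object@cellVectors)) ||
        !all(is.finite(object@typeVectors)))
        msg <- c(msg, "embedding vectors must be finite")
    if (is.null(msg)) TRUE else msg
})

#' @rdname typeNames
#' @export
setMethod("typeNames", "CellTypeEmbeddings",
    function(x) rownames(x@typeVectors))

#' Cell vectors of a CellTypeEmbeddings
#' @param x A \linkS4class{CellTypeEmbeddings}.
#' @return Numeric matrix, cells x d.
#' @export
cellVectors <- function(x) {
    stopifnot(is(x, "CellTypeEmbeddings"))
    x@cellVectors
}

#' Type vectors of a CellTypeEmbeddings
#' @param x A \linkS4class{CellTypeEmbeddings}.
#' @return Numeric matrix, types x d.
#' @export
typeVectors <- function(x) {
    stopifnot(is(x, "CellTypeEmbeddings"))
    x@typeVectors
}

setMethod("show", "CellTypeEmbeddings", function(object) {
    cat("CellTypeEmbeddings:", nrow(object@cellVectors), "cells,",
        nrow(object@typeVectors), "types in", ncol(object@cellVectors),
        "dimensions\n")
})

# ---------------------------------------------------------------------------
# PathwayMask
# ---------------------------------------------------------------------------

#' Binary pathway-membership mask over the model gene list
#'
#' k x G binary matrix: entry (p, g) is 1 iff gene g belongs to pathway p.
#' The classifier's embedding weights are multiplied elementwise by this
#' mask, so a pathway token can only read its member genes.
#'
#' @slot mask binary numeric matrix, pathways x genes, with dimnames.
#' @seealso [buildPathwayMask()], [PathwayTransformer()]
#' @export
setClass("PathwayMask", representation(mask = "matrix"))

setValidity("PathwayMask", function(object) {
    m <- object@mask
    msg <- NULL
    if (is.null(rownames(m)) || is.null(colnames(m)))
        msg <- c(msg, "mask must have pathway and gene dimnames")
    if (!all(m %in% c(0, 1)))
        msg <- c(msg, "mask entries must be 0 or 1")
    if (any(rowSums(m) == 0))
        msg <- c(msg, "no pathway row may be all zero")
    if (is.null(msg)) TRUE else msg
})

#' @rdname maskMatrix
#' @export
setMethod("maskMatrix", "PathwayMask", function(x) x@mask)

#' @rdname pathwayNames
#' @export
setMethod("pathwayNames", "PathwayMask", function(x) rownames(x@mask))

#' @rdname geneIds
#' @export
setMethod("geneIds", "PathwayMask", function(x) colnames(x@mask))

setMethod("show", "PathwayMask", function(object) {
    cat("PathwayMask:", nrow(object@mask), "pathways x", ncol(object@mask),
        "genes; density", signif(mean(object@mask), 3), "\n")
})

# ---------------------------------------------------------------------------
# PathwayTransformer
# ---------------------------------------------------------------------------

#' Pathway-masked single-layer attention classifier
#'
#' Interpretable cell type classifier: each cell's log-normalized
#' expression vector is embedded into one token per pathway through a
#' mask-constrained linear map, a trainable class (CLS) token is
#' prepended, one multi-head self-attention layer mixes the tokens, and a
#' linear softmax head on the CLS output yields type probabilities.
#'
#' @slot config list: embedDim (m), nHeads, dk = m / nHeads, nTypes.
#' @slot params list of weight matrices: Wemb ((k*G) x m, masked), cls
#'   (m), Wq / Wk / Wv (m x m, heads in column blocks), Wp (m x T), b (T).
#' @slot mask \linkS4class{PathwayMask} fixing gene order and membership.
#' @slot typeNames character vector of output classes.
#' @seealso [PathwayTransformer()], [predictTypes()], [pretrain()]
#' @export
setClass("PathwayTransformer",
    representation(config = "list", params = "list", mask = "PathwayMask",
                   typeNames = "character"))

setValidity("PathwayTransformer", function(object) {
    cfg <- object@config
    msg <- NULL
    if (cfg$embedDim %% cfg$nHeads != 0)
        msg <- c(msg, "embedDim must be divisible by nHeads")
    need <- c("Wemb", "cls", "Wq", "Wk", "Wv", "Wp", "b")
    if (!all(need %in% names(object@params)))
        msg <- c(msg, "incomplete parameter list")
    if (is.null(msg)) TRUE else msg
})

#' @rdname typeNames
#' @export
setMethod("typeNames", "PathwayTransformer", function(x) x@typeNames)

#' @rdname pathwayNames
#' @export
setMethod("pathwayNames", "PathwayTransformer",
    function(x) pathwayNames(x@mask))

#' @rdname maskMatrix
#' @export
setMethod("maskMatrix", "PathwayTransformer", function(x) maskMatrix(x@mask))

setMethod("show", "PathwayTransformer", function(object) {
    cfg <- object@config
    cat("PathwayTransformer:", nrow(object@mask@mask), "pathway tokens + CLS,",
        "embedDim", cfg$embedDim, "x", cfg$nHeads, "heads ->",
        length(object@typeNames), "types\n")
})

# ---------------------------------------------------------------------------
# AnnotationResult
# ---------------------------------------------------------------------------

#' Result of the annotation pipeline
#'
#' @slot predictedType character vector, argmax type per cell (ties are
#'   broken toward the lowest type index).
#' @slot probabilities numeric matrix, cells x types, row-stochastic.
#' @slot history data.frame of per-epoch losses and per-round
#'   label-change fractions.
#' @slot attention numeric matrix of head-averaged CLS-to-pathway
#'   attention (cells x pathways), or a 0 x 0 matrix for the logistic
#'   regression ablation.
#' @slot provenance list: strategy, seeds, configuration used.
#' @seealso [annotateCells()], [selfTrain()]
#' @export
setClass("AnnotationResult",
    representation(predictedType = "character", probabilities = "matrix",
                   history = "data.frame", attention = "matrix",
                   provenance = "list"))

setValidity("AnnotationResult", function(object) {
    msg <- NULL
    if (length(object@predictedType) != nrow(object@probabilities))
        msg <- c(msg, "one predicted type per probability row is required")
    if (any(abs(rowSums(object@probabilities) - 1) > 1e-6))
        msg <- c(msg, "probability rows must sum to 1 (tol 1e-6)")
    if (is.null(msg)) TRUE else msg
})

#' @rdname predictedTypes
#' @export
setMethod("predictedTypes", "AnnotationResult", function(x) x@predictedType)

#' @rdname typeProbabilities
#' @export
setMethod("typeProbabilities", "AnnotationResult", function(x) x@probabilities)

#' @rdname typeNames
#' @export
setMethod("typeNames", "AnnotationResult",
    function(x) colnames(x@probabilities))

#' @rdname trainingHistory
#' @export
setMethod("trainingHistory", "AnnotationResult", function(x) x@history)

#' @rdname attentionProfiles
#' @export
setMethod("attentionProfiles", "AnnotationResult", function(x) {
    if (nrow(x@attention) == 0L) NULL else x@attention
})

setMethod("show", "AnnotationResult", function(object) {
    tab <- table(object@predictedType)
    cat("AnnotationResult for", length(object@predictedType), "cells,",
        ncol(object@probabilities), "types\n")
    cat("  predicted composition:",
        paste0(names(tab), " (", as.integer(tab), ")", collapse = ", "), "\n")
    st <- object@history[object@history$phase == "self-train", , drop = FALSE]
    if (nrow(st))
        cat("  self-training rounds:", max(st$round), "\n")
})
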