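#' @import methods
NULL

#' Cell type names stored in an object
#'
#' @param x A \linkS4class{MarkerCatalog}, \linkS4class{CellTypeScores}
#'   derivative, \linkS4class{PathwayTransformer} or
#'   \linkS4class{AnnotationResult}.
#' @return Character vector of cell type names, in catalog order.
#' @export
setGeneric("typeNames", function(x) standardGeneric("typeNames"))

#' Marker gene lists of a catalog
#'
#' @param x A \linkS4class{MarkerCatalog}.
#' @param type Optional single type name; if given, that type's marker
#'   vector is returned instead of the full list.
#' @return Named list of character vectors (or one character vector).
#' @export
setGeneric("markerGenes", function(x, type = NULL) standardGeneric("markerGenes"))

#' Pathway names stored in an object
#'
#' @param x A \linkS4class{PathwayCollection}, \linkS4class{PathwayMask} or
#'   \linkS4class{PathwayTransformer}.
#' @return Character vector of pathway names.
#' @export
setGeneric("pathwayNames", function(x) standardGeneric("pathwayNames"))

#' Gene identifiers stored in an object
#'
#' @param x A \linkS4class{GeneEmbedding} or \linkS4class{PathwayMask}.
#' @return Character vector of gene identifiers.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' Numeric score matrix of a cells-by-types object
#'
#' @param x A \linkS4class{RelevanceMatrix} or
#'   \linkS4class{PseudoLabelMatrix}.
#' @return Numeric matrix, cells in rows, types in columns, with dimnames.
#' @export
setGeneric("scoreMatrix", function(x) standardGeneric("scoreMatrix"))

#' Binary pathway-by-gene mask matrix
#'
#' @param x A \linkS4class{PathwayMask} or \linkS4class{PathwayTransformer}.
#' @return Binary matrix, pathways in rows, genes in columns.
#' @export
setGeneric("maskMatrix", function(x) standardGeneric("maskMatrix"))

#' Predicted cell type labels
#'
#' @param x An \linkS4class{AnnotationResult}.
#' @return Character vector of predicted type names, one per cell.
#' @export
setGeneric("predictedTypes", function(x) standardGeneric("predictedTypes"))

#' Per-cell type probability matrix
#'
#' @param x An \linkS4class{AnnotationResult}.
#' @return Numeric matrix (cells x types); each row sums to one.
#' @export
setGeneric("typeProbabilities", function(x) standardGeneric("typeProbabilities"))

#' Training history of an annotation run
#'
#' @param x An \linkS4class{AnnotationResult}.
#' @return A data.frame with one row per epoch: phase, round, epoch, loss
#'   and (for self-training rounds) the argmax label-change fraction.
#' @export
setGeneric("trainingHistory", function(x) standardGeneric("trainingHistory"))

#' Head-averaged CLS-to-pathway attention profiles
#'
#' @param x An \linkS4class{AnnotationResult}.
#' @return Numeric matrix (cells x pathways), or NULL for the logistic
#'   regression ablation which has no attention mechanism.
#' @export
setGeneric("attentionProfiles", function(x) standardGeneric("attentionProfiles"))
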