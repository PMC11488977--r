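#' Multiclass classification report
#'
#' Standard single-label multiclass metrics from the confusion table:
#' per-class precision, recall and F1, their unweighted (macro) means,
#' and micro-F1 computed from pooled counts, which in this setting
#' equals plain accuracy. Classes with no predicted (or no true)
#' instances get precision (recall) 0 with a warning, so macro metrics
#' stay computable on unbalanced data.
#'
#' @param truth Character/factor vector of true labels.
#' @param pred Character/factor vector of predicted labels, same length.
#' @param classes Class list; defaults to the sorted union of labels.
#' @return List: \code{perClass} data.frame (class, precision, recall,
#'   f1, support), \code{precisionMacro}, \code{recallMacro},
#'   \code{f1Macro}, \code{f1Micro}.
#' @examples
#' classificationReport(c("A", "A", "B", "B"),
#'                      c("A", "B", "B", "B"))$f1Macro  # 11/15
#' @export
classificationReport <- function(truth, pred,
                                 classes = sort(union(truth, pred))) {
    if (!length(truth) || length(truth) != length(pred))
        stop("truth and pred must be non-empty vectors of equal length")
    truth <- factor(as.character(truth), levels = classes)
    pred <- factor(as.character(pred), levels = classes)
    if (anyNA(truth) || anyNA(pred))
        stop("labels outside the class list")
    cm <- table(truth, pred)                      # rows truth, cols pred
    tp <- diag(cm)
    predN <- colSums(cm)
    trueN <- rowSums(cm)
    if (any(predN == 0) || any(trueN == 0))
        warning("class(es) with zero predicted or true instances; ",
                "their undefined precision/recall set to 0")
    precision <- ifelse(predN == 0, 0, tp / predN)
    recall <- ifelse(trueN == 0, 0, tp / trueN)
    f1 <- ifelse(precision + recall == 0, 0,
                 2 * precision * recall / (precision + recall))
    list(perClass = data.frame(class = classes,
                               precision = as.numeric(precision),
                               recall = as.numeric(recall),
                               f1 = as.numeric(f1),
                               support = as.numeric(trueN),
                               row.names = NULL),
         precisionMacro = mean(precision),
         recallMacro = mean(recall),
         f1Macro = mean(f1),
         f1Micro = sum(tp) / length(truth))
}

# Memberships as consecutive integers for igraph::compare.
.asMembership <- function(x) as.integer(factor(as.character(x)))

#' Normalized mutual information between two partitions
#'
#' NMI with arithmetic-mean normalization (2 I / (H(a) + H(b))).
#' Permutation-invariant and symmetric. When exactly one partition is a
#' single cluster the value is defined as 0 (no shared information; the
#' raw formula would be 0/0); two identical single-cluster partitions
#' give 1.
#'
#' @param a,b Label vectors of equal length.
#' @return Number in [0, 1].
#' @export
nmi <- function(a, b) {
    stopifnot(length(a) == length(b), length(a) > 0)
    ka <- length(unique(a)); kb <- length(unique(b))
    if (ka == 1L || kb == 1L)
        return(if (ka == 1L && kb == 1L) 1 else 0)
    igraph::compare(.asMembership(a), .asMembership(b), method = "nmi")
}

#' Adjusted Rand index between two partitions
#'
#' Pair-counting agreement corrected for chance; 1 for identical
#' partitions (up to relabeling), around 0 for independent ones, and
#' possibly negative. Two single-cluster partitions are identical and
#' give 1.
#'
#' @param a,b Label vectors of equal length.
#' @return Number in (-1, 1].
#' @export
ari <- function(a, b) {
    stopifnot(length(a) == length(b), length(a) > 0)
    ka <- length(unique(a)); kb <- length(unique(b))
    if (ka == 1L && kb == 1L) return(1)
    igraph::compare(.asMembership(a), .asMembership(b),
                    method = "adjusted.rand")
}
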