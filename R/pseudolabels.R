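#' Normalize relevance scores into per-cell probability simplices
#'
#' Converts a raw cells-by-types relevance matrix into soft pseudo-labels.
#' The default row-wise softmax (after dividing by \code{temperature})
#' handles negative scores, which the cosine and specificity-weighted
#' strategies produce; "sum" divides each row by its total and therefore
#' requires nonnegative scores (an all-zero row maps to the uniform
#' distribution with a warning). "hard" one-hot encodes the row argmax
#' and exists only as an ablation: hard labels tend to overfit the early
#' mistakes of the relevance stage. Both soft methods preserve the
#' within-row ordering of scores, and softmax is invariant to adding a
#' constant to a row.
#'
#' @param R A \linkS4class{RelevanceMatrix} (or numeric matrix).
#' @param method "softmax" (default), "sum" or "hard".
#' @param temperature Positive softmax temperature (default 1).
#' @return A \linkS4class{PseudoLabelMatrix}.
#' @examples
#' R <- new("RelevanceMatrix",
#'     values = matrix(c(0, log(2)), 1, 2,
#'                     dimnames = list("c1", c("A", "B"))),
#'     strategy = "demo")
#' scoreMatrix(normalizeToSimplex(R))   # 1/3, 2/3
#' @export
normalizeToSimplex <- function(R, method = c("softmax", "sum", "hard"),
                               temperature = 1) {
    method <- match.arg(method)
    stopifnot(temperature > 0)
    v <- if (is(R, "CellTypeScores")) scoreMatrix(R) else as.matrix(R)
    if (!all(is.finite(v)))
        stop("non-finite relevance entries")
    src <- if (is(R, "CellTypeScores")) scoreStrategy(R) else "matrix"
    L <- switch(method,
        softmax = .rowSoftmax(v / temperature),
        sum = {
            if (any(v < 0))
                stop("method 'sum' requires nonnegative scores")
            tot <- rowSums(v)
            if (any(tot == 0))
                warning(sum(tot == 0), " all-zero row(s) mapped to the ",
                        "uniform distribution")
            out <- v / ifelse(tot == 0, 1, tot)
            out[tot == 0, ] <- 1 / ncol(v)
            out
        },
        hard = {
            out <- matrix(0, nrow(v), ncol(v), dimnames = dimnames(v))
            out[cbind(seq_len(nrow(v)), .rowArgmax(v))] <- 1
            out
        })
    dimnames(L) <- dimnames(v)
    .newScores("PseudoLabelMatrix", L, paste0(src, "+", method))
}

#' Kullback-Leibler divergence between row-stochastic matrices
#'
#' The training objective of both the pretraining and the self-training
#' phase: \eqn{\sum_i \sum_j t_{ij} \log(t_{ij} / p_{ij})}, accumulated
#' as a plain sum over cells and types (not averaged). Terms with
#' \eqn{t_{ij} = 0} contribute 0; predictions are floored at
#' \code{epsilon} inside the logarithm so a zero prediction cannot
#' produce an infinite loss.
#'
#' @param target Cells x types matrix of row-simplices (or a
#'   \linkS4class{PseudoLabelMatrix}).
#' @param pred Same shape, row-stochastic predictions.
#' @param epsilon Floor for predictions inside the log (default 1e-8).
#' @return Single nonnegative number (up to epsilon effects).
#' @examples
#' klDivergence(matrix(c(1, 0), 1), matrix(c(0.5, 0.5), 1))  # log(2)
#' @export
klDivergence <- function(target, pred, epsilon = 1e-8) {
    t <- if (is(target, "CellTypeScores")) scoreMatrix(target)
         else as.matrix(target)
    p <- if (is(pred, "CellTypeScores")) scoreMatrix(pred)
         else as.matrix(pred)
    if (!all(dim(t) == dim(p)))
        stop("shape mismatch between target and prediction")
    stopifnot(epsilon > 0)
    pos <- t > 0
    sum(t[pos] * (log(t[pos]) - log(pmax(p[pos], epsilon))))
}
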