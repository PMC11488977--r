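#' @useDynLib markerAttn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Construct and initialize a pathway-masked attention classifier
#'
#' Creates the interpretable classifier: one masked linear embedding
#' producing a token per pathway, a trainable CLS token, one multi-head
#' self-attention layer (no residual, LayerNorm or feed-forward sublayer)
#' and a linear softmax head reading the CLS output. Weights are drawn
#' from scaled uniform distributions (Glorot-style bounds); embedding
#' positions of genes outside a pathway are exactly zero and stay zero
#' through training.
#'
#' @param mask A \linkS4class{PathwayMask} (fixes pathway and gene order).
#' @param typeNames Character vector of output cell type names (>= 2).
#' @param embedDim Token embedding dimension m (default 100).
#' @param nHeads Number of attention heads (default 4); must divide
#'   \code{embedDim}.
#' @param seed Integer seed; initialization is bit-reproducible.
#' @return A \linkS4class{PathwayTransformer}.
#' @examples
#' pm <- buildPathwayMask(
#'     PathwayCollection(list(P1 = c("G1", "G2"), P2 = c("G2", "G3"))),
#'     c("G1", "G2", "G3"))
#' model <- PathwayTransformer(pm, c("A", "B"), embedDim = 8, nHeads = 2)
#' @export
PathwayTransformer <- function(mask, typeNames, embedDim = 100L,
                               nHeads = 4L, seed = 0L) {
    stopifnot(is(mask, "PathwayMask"), length(typeNames) >= 2L)
    embedDim <- as.integer(embedDim); nHeads <- as.integer(nHeads)
    if (embedDim %% nHeads != 0L)
        stop("embedDim must be divisible by nHeads")
    M <- maskMatrix(mask)
    k <- nrow(M); G <- ncol(M); T <- length(typeNames)
    m <- embedDim
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(.checkSeed(seed))
    # Per-pathway Glorot bound: fan-in = number of member genes.
    Wemb <- matrix(0, nrow = k * G, ncol = m)
    for (p in seq_len(k)) {
        np <- sum(M[p, ])
        s <- sqrt(6 / (np + m))
        rows <- (p - 1L) * G + which(M[p, ] == 1)
        Wemb[rows, ] <- matrix(stats::runif(length(rows) * m, -s, s),
                               ncol = m)
    }
    su <- sqrt(3 / m)
    cls <- stats::runif(m, -su, su)
    sa <- sqrt(6 / (2 * m))
    Wq <- matrix(stats::runif(m * m, -sa, sa), m, m)
    Wk <- matrix(stats::runif(m * m, -sa, sa), m, m)
    Wv <- matrix(stats::runif(m * m, -sa, sa), m, m)
    sp <- sqrt(6 / (m + T))
    Wp <- matrix(stats::runif(m * T, -sp, sp), m, T)
    b <- rep(0, T)
    new("PathwayTransformer",
        config = list(embedDim = m, nHeads = nHeads, dk = m %/% nHeads,
                      nTypes = T, seed = as.integer(seed)),
        params = list(Wemb = Wemb, cls = cls, Wq = Wq, Wk = Wk, Wv = Wv,
                      Wp = Wp, b = b),
        mask = mask, typeNames = as.character(typeNames))
}

# Save/restore the global RNG state so constructors don't perturb the
# caller's stream.
.Random.seed_save <- function() {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
        get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

# Flattened 0/1 vector matching Wemb's row order (pathway-major).
.maskVec <- function(model) {
    as.numeric(t(maskMatrix(model)))   # row p*G+g <-> mask[p, g]
}

#' Align a log-normalized expression matrix to a model's gene order
#'
#' Subsets and orders genes to the model's pathway-mask gene list and
#' returns the cells x genes matrix the classifier consumes. Model genes
#' absent from the data are filled with zeros (with a warning).
#'
#' @param model A \linkS4class{PathwayTransformer}.
#' @param x A \linkS4class{SingleCellExperiment} (log-normalized on
#'   demand) or a genes x cells log-normalized matrix.
#' @return Numeric cells x genes matrix, columns = \code{geneIds(model)}.
#' @export
modelInput <- function(model, x) {
    genes <- geneIds(model@mask)
    ln <- if (is(x, "SingleCellExperiment")) .logcountsOf(x) else as.matrix(x)
    found <- intersect(genes, rownames(ln))
    if (length(found) < length(genes))
        warning(length(genes) - length(found),
                " model gene(s) absent from the data; filled with zeros")
    out <- matrix(0, nrow = ncol(ln), ncol = length(genes),
                  dimnames = list(colnames(ln), genes))
    out[, found] <- t(ln[found, , drop = FALSE])
    out
}

#' Token embedding of a single cell
#'
#' Computes the (1+k) x m input token matrix I for one cell: row 1 is the
#' CLS token, rows 2..k+1 are the pathway tokens, where token p is the
#' masked linear image of the cell's expression restricted to pathway p's
#' member genes.
#'
#' @param model A \linkS4class{PathwayTransformer}.
#' @param x Numeric vector of log-normalized expression aligned to
#'   \code{geneIds(model)}.
#' @return Numeric (1+k) x m matrix with rownames c("CLS", pathways).
#' @export
embedTokens <- function(model, x) {
    M <- maskMatrix(model)
    k <- nrow(M); G <- ncol(M)
    if (length(x) != G)
        stop("expression vector length ", length(x),
             " does not match model gene count ", G)
    W <- model@params$Wemb
    I <- matrix(0, nrow = 1L + k, ncol = model@config$embedDim)
    I[1L, ] <- model@params$cls
    for (p in seq_len(k))
        I[p + 1L, ] <- as.numeric(x %*% W[(p - 1L) * G + seq_len(G), ,
                                          drop = FALSE])
    rownames(I) <- c("CLS", rownames(M))
    I
}

#' Forward pass: cell type probabilities (and attention) for a batch
#'
#' @param model A \linkS4class{PathwayTransformer}.
#' @param x Input cells: a \linkS4class{SingleCellExperiment} or a cells
#'   x genes matrix already aligned via [modelInput()].
#' @param attention Also return the head-averaged CLS-to-pathway
#'   attention row per cell (cells x pathways matrix).
#' @param fullAttention Also return, for the first cell only, the full
#'   (1+k) x (1+k) row-stochastic attention matrix of every head.
#' @return List with \code{probs} (cells x types, rows sum to 1) and
#'   optionally \code{attention} / \code{fullAttention}.
#' @export
predictTypes <- function(model, x, attention = FALSE,
                         fullAttention = FALSE) {
    X <- if (is.matrix(x)) x else modelInput(model, x)
    if (!all(is.finite(X))) stop("non-finite values in model input")
    out <- .cppForward(X, model@params, nrow(maskMatrix(model)),
                       model@config$nHeads, attention, fullAttention)
    if (!all(is.finite(out$probs)))
        stop("non-finite activations in forward pass (batch row ",
             which(!is.finite(rowSums(out$probs)))[1L], ")")
    dimnames(out$probs) <- list(rownames(X), model@typeNames)
    if (attention)
        dimnames(out$attention) <- list(rownames(X),
                                        pathwayNames(model))
    out
}

# Loss + gradients of the summed KL objective for a batch; used by the
# trainers. Returns list(loss, probs, grads).
.forwardBackward <- function(model, X, L) {
    .cppForwardBackward(X, L, model@params, .maskVec(model),
                        nrow(maskMatrix(model)), model@config$nHeads)
}
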