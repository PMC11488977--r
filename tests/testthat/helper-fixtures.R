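# Small in-code fixtures shared across test files. Everything is built
# programmatically; nothing is read from disk except through the
# package's own writers.

# 3-cell x 4-gene toy count matrix (cells in rows here for readability).
toyCounts <- function() {
    m <- matrix(c(1, 0, 3, 0,
                  2, 2, 0, 1,
                  0, 5, 1, 4), nrow = 3, byrow = TRUE,
                dimnames = list(c("c1", "c2", "c3"),
                                c("G1", "G2", "G3", "G4")))
    m
}

toySCE <- function() {
    SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = t(toyCounts())))
}

toyCatalog <- function() {
    MarkerCatalog(list(A = c("G1", "G3"), B = "G2"))
}

toyPathways <- function() {
    PathwayCollection(list(P1 = c("G1", "G2"), P2 = c("G2", "G3")))
}

toyEmbedding <- function(d = 4L, seed = 11L) {
    set.seed(seed)
    GeneEmbedding(matrix(rnorm(4 * d), nrow = 4,
                         dimnames = list(c("G1", "G2", "G3", "G4"), NULL)))
}

# Small but non-trivial simulated dataset for pipeline tests.
smallSim <- function(seed = 1L, nCells = 150L) {
    simulateCells(nCells = nCells, nGenes = 60L, nTypes = 3L,
                  markersPerType = 5L, nPathways = 8L, embedDim = 8L,
                  seed = seed)
}

# Random relevance-style matrix with dimnames.
randomScores <- function(n, t, seed = 1L) {
    set.seed(seed)
    matrix(rnorm(n * t), n, t,
           dimnames = list(sprintf("c%d", seq_len(n)),
                           sprintf("T%d", seq_len(t))))
}

# Independent R implementation of the classifier forward pass, written
# directly from the equations (token embedding, scaled dot-product
# attention per head, CLS head). Used as the oracle for the compiled
# forward pass.
referenceForward <- function(x, params, mask, nHeads) {
    k <- nrow(mask); G <- ncol(mask); m <- length(params$cls)
    dk <- m / nHeads
    I <- matrix(0, 1 + k, m)
    I[1, ] <- params$cls
    for (p in seq_len(k))
        I[p + 1, ] <- as.numeric(
            x %*% params$Wemb[(p - 1) * G + seq_len(G), , drop = FALSE])
    softmaxRows <- function(S) {
        S <- S - apply(S, 1, max); E <- exp(S); E / rowSums(E)
    }
    O <- matrix(0, 1 + k, m)
    attn <- vector("list", nHeads)
    V <- I %*% params$Wv
    for (h in seq_len(nHeads)) {
        cols <- (h - 1) * dk + seq_len(dk)
        Q <- I %*% params$Wq[, cols, drop = FALSE]
        K <- I %*% params$Wk[, cols, drop = FALSE]
        A <- softmaxRows(Q %*% t(K) / sqrt(dk))
        attn[[h]] <- A
        O[, cols] <- A %*% V[, cols, drop = FALSE]
    }
    logits <- as.numeric(O[1, ] %*% params$Wp + params$b)
    p <- exp(logits - max(logits)); p <- p / sum(p)
    list(probs = p, attention = attn, tokens = I)
}
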