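#' Count-based relevance: expressed markers per type
#'
#' The relevance of cell i to type j is the number of type-j marker genes
#' with nonzero expression in cell i. Only the "is expressed" predicate
#' matters, so the score is invariant to any monotone positive rescaling
#' of the counts.
#'
#' @param expr \linkS4class{SingleCellExperiment} with assay "counts".
#' @param cat \linkS4class{MarkerCatalog}.
#' @return A \linkS4class{RelevanceMatrix} of integer-valued scores.
#' @export
scoreCount <- function(expr, cat) {
    cts <- .countsOf(expr)
    mk <- .intersectCatalog(cat, rownames(cts))
    if (any(lengths(mk) == 0L))
        warning("type(s) with no marker present score 0 everywhere: ",
                paste(names(mk)[lengths(mk) == 0L], collapse = ", "))
    expressed <- t(cts > 0)                        # cells x genes
    R <- vapply(typeNames(cat), function(ty) {
        g <- mk[[ty]]
        if (!length(g)) return(numeric(nrow(expressed)))
        rowSums(expressed[, g, drop = FALSE])
    }, numeric(ncol(cts)))
    dimnames(R) <- list(colnames(cts), typeNames(cat))
    .newScores("RelevanceMatrix", R, "count")
}

#' Map cells and cell types into a shared gene-embedding space
#'
#' A cell's vector is the expression-weighted average of the embeddings
#' of genes shared between the data and the embedding table; a type's
#' vector is the unweighted mean of its marker gene embeddings. Cells
#' with zero total expression over the shared genes get a zero vector
#' (with a warning); markers missing from the embedding are dropped.
#'
#' @param expr \linkS4class{SingleCellExperiment}.
#' @param cat \linkS4class{MarkerCatalog}.
#' @param emb \linkS4class{GeneEmbedding}.
#' @return A \linkS4class{CellTypeEmbeddings}.
#' @export
embedCellsAndTypes <- function(expr, cat, emb) {
    E <- embeddingMatrix(emb)
    cts <- .countsOf(expr)
    shared <- intersect(rownames(cts), rownames(E))
    if (!length(shared))
        stop("no genes shared between expression matrix and embedding")
    Xs <- t(cts[shared, , drop = FALSE])           # cells x shared
    Es <- E[shared, , drop = FALSE]
    tot <- rowSums(Xs)
    if (any(tot == 0))
        warning(sum(tot == 0), " cell(s) with zero expression over ",
                "embedded genes get a zero vector")
    cellV <- (Xs %*% Es) / ifelse(tot == 0, 1, tot)
    rownames(cellV) <- colnames(cts)

    typeV <- t(vapply(typeNames(cat), function(ty) {
        g <- intersect(markerGenes(cat, ty), rownames(E))
        if (!length(g)) {
            warning("type '", ty, "' has no marker in the embedding; ",
                    "zero vector used")
            return(numeric(ncol(E)))
        }
        colMeans(E[g, , drop = FALSE])
    }, numeric(ncol(E))))
    dropped <- sum(lengths(markerGenes(cat))) -
        sum(vapply(markerGenes(cat),
                   function(g) length(intersect(g, rownames(E))), 1L))
    if (dropped > 0)
        warning(dropped, " marker(s) missing from the embedding were ",
                "dropped")
    new("CellTypeEmbeddings", cellVectors = cellV, typeVectors = typeV)
}

#' Cosine-similarity relevance in embedding space
#'
#' R_ij is the cosine similarity between cell i's embedding vector and
#' type j's embedding vector; a zero-norm vector on either side yields 0.
#'
#' @param ce A \linkS4class{CellTypeEmbeddings}.
#' @return A \linkS4class{RelevanceMatrix} with entries in [-1, 1].
#' @export
scoreCosine <- function(ce) {
    C <- cellVectors(ce); Ty <- typeVectors(ce)
    cn <- sqrt(rowSums(C^2)); tn <- sqrt(rowSums(Ty^2))
    R <- (C %*% t(Ty)) / (pmax(cn, .Machine$double.eps) %o%
                          pmax(tn, .Machine$double.eps))
    R[cn == 0, ] <- 0
    R[, tn == 0] <- 0
    dimnames(R) <- list(rownames(C), rownames(Ty))
    .newScores("RelevanceMatrix", R, "cos")
}

# Multinomial logistic classifier on (features, class) with L2 penalty;
# returns a cells x classes probability matrix for `newdata`.
.multinomProbs <- function(train, classes, newdata, classNames) {
    if (length(unique(classes)) < 2L)
        stop("fewer than 2 classes left to train the classifier")
    df <- data.frame(.y = factor(classes, levels = classNames), train)
    fit <- nnet::multinom(.y ~ ., data = df, trace = FALSE, decay = 1,
                          maxit = 1000)
    pr <- stats::predict(fit, newdata = data.frame(newdata), type = "probs")
    if (is.null(dim(pr)))                   # two-class case returns a vector
        pr <- cbind(1 - pr, pr)
    pr <- as.matrix(pr)
    colnames(pr) <- classNames
    rownames(pr) <- rownames(newdata)
    pr
}

#' Logistic-regression relevance from gene embeddings
#'
#' Trains a multinomial logistic classifier in embedding space and reads
#' R_ij as the predicted probability of type j for cell i. In mode
#' "label" the training set has one sample per class (the type's mean
#' marker embedding); in mode "marker" every marker gene embedding is one
#' training sample of its type. With one marker per type both modes see
#' identical training data.
#'
#' @param ce \linkS4class{CellTypeEmbeddings} for the cells to score.
#' @param cat \linkS4class{MarkerCatalog}.
#' @param emb \linkS4class{GeneEmbedding} (needed for mode "marker").
#' @param mode "label" or "marker".
#' @return A \linkS4class{RelevanceMatrix}; rows sum to 1.
#' @export
scoreLR <- function(ce, cat, emb, mode = c("label", "marker")) {
    mode <- match.arg(mode)
    cells <- cellVectors(ce)
    if (mode == "label") {
        train <- typeVectors(ce)
        classes <- rownames(train)
    } else {
        E <- embeddingMatrix(emb)
        rows <- list(); classes <- character()
        for (ty in typeNames(cat)) {
            g <- intersect(markerGenes(cat, ty), rownames(E))
            if (!length(g)) next
            rows[[ty]] <- E[g, , drop = FALSE]
            classes <- c(classes, rep(ty, length(g)))
        }
        train <- do.call(rbind, rows)
    }
    keep <- unique(classes)
    R <- .multinomProbs(train, classes, cells, keep)
    # types that lost every marker keep a zero column so shape is stable
    if (length(keep) < length(typeNames(cat))) {
        full <- matrix(0, nrow(R), length(typeNames(cat)),
                       dimnames = list(rownames(R), typeNames(cat)))
        full[, keep] <- R
        R <- full
        warning("type(s) without usable markers score 0: ",
                paste(setdiff(typeNames(cat), keep), collapse = ", "))
    }
    .newScores("RelevanceMatrix", R,
               if (mode == "label") "lr-label" else "lr-marker")
}

# One von Mises-Fisher draw of a unit direction in d dimensions around
# unit mean `mu` with concentration `kappa` (Wood's rejection sampler).
.rvmf <- function(n, mu, kappa) {
    d <- length(mu)
    b <- (-2 * kappa + sqrt(4 * kappa^2 + (d - 1)^2)) / (d - 1)
    x0 <- (1 - b) / (1 + b)
    cc <- kappa * x0 + (d - 1) * log(1 - x0^2)
    out <- matrix(0, n, d)
    for (i in seq_len(n)) {
        repeat {
            z <- stats::rbeta(1, (d - 1) / 2, (d - 1) / 2)
            w <- (1 - (1 + b) * z) / (1 - (1 - b) * z)
            u <- stats::runif(1)
            if (kappa * w + (d - 1) * log(1 - x0 * w) - cc >= log(u))
                break
        }
        v <- stats::rnorm(d)
        v <- v - sum(v * mu) * mu
        v <- v / sqrt(sum(v^2))
        out[i, ] <- sqrt(max(0, 1 - w^2)) * v + w * mu
    }
    out
}

#' Pseudo-cell relevance: classify cells against sampled type prototypes
#'
#' Each cell type is modeled as a spherical distribution in embedding
#' space: unit directions are drawn from a von Mises-Fisher distribution
#' centered on the normalized type embedding with concentration
#' \code{kappa}. Every sampled direction is turned into a pseudo-cell
#' whose gene profile is proportional to a softmax (sharpness
#' \code{lambda}) of the gene embeddings' projections on the direction,
#' scaled to \code{librarySize}. A multinomial logistic classifier
#' trained on (pseudo-cell embedding, type) then scores the real cells.
#'
#' @param expr \linkS4class{SingleCellExperiment}.
#' @param cat \linkS4class{MarkerCatalog}.
#' @param emb \linkS4class{GeneEmbedding}.
#' @param nPseudo Pseudo-cells per type (default 500).
#' @param kappa vMF concentration (default 50); must be positive.
#' @param lambda Softmax sharpness over genes (default 10).
#' @param librarySize Total counts per pseudo-cell profile (default 5000).
#' @param seed Integer seed; output is bit-reproducible.
#' @return A \linkS4class{RelevanceMatrix}; rows sum to 1.
#' @export
scorePseudoCell <- function(expr, cat, emb, nPseudo = 500L, kappa = 50,
                            lambda = 10, librarySize = 5000, seed = 0L) {
    if (kappa <= 0) stop("kappa must be positive")
    ce <- embedCellsAndTypes(expr, cat, emb)
    E <- embeddingMatrix(emb)
    shared <- intersect(rownames(.countsOf(expr)), rownames(E))
    Es <- E[shared, , drop = FALSE]
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(.checkSeed(seed))
    Ty <- typeVectors(ce)
    feats <- list(); classes <- character()
    for (ty in rownames(Ty)) {
        mu <- Ty[ty, ]
        nm <- sqrt(sum(mu^2))
        if (nm == 0) next
        dirs <- .rvmf(nPseudo, mu / nm, kappa)
        # gene profile per direction: librarySize * softmax(lambda * E d)
        proj <- Es %*% t(dirs) * lambda            # genes x nPseudo
        proj <- sweep(proj, 2L, apply(proj, 2L, max))
        w <- exp(proj); w <- sweep(w, 2L, colSums(w), "/")
        prof <- w * librarySize
        pcEmb <- t(prof) %*% Es / colSums(prof)    # pseudo-cell embeddings
        feats[[ty]] <- pcEmb
        classes <- c(classes, rep(ty, nPseudo))
    }
    if (length(unique(classes)) < 2L)
        stop("fewer than 2 types with usable embeddings")
    train <- do.call(rbind, feats)
    R <- .multinomProbs(train, classes, cellVectors(ce), unique(classes))
    if (ncol(R) < nrow(Ty)) {
        full <- matrix(0, nrow(R), nrow(Ty),
                       dimnames = list(rownames(R), rownames(Ty)))
        full[, colnames(R)] <- R
        R <- full
    }
    .newScores("RelevanceMatrix", R, "pseudo-cell")
}

#' Cell type specificity scores of the pooled marker catalog
#'
#' Pools all marker genes and, for each, counts how many cell types list
#' it. The score S is the min-max rescaled inverse of that count: a
#' marker listed by the fewest types scores 1, by the most types scores
#' 0. When every pooled marker is listed by the same number of types the
#' rescaling is undefined and S is 1 for all markers (all equally
#' specific).
#'
#' @param cat \linkS4class{MarkerCatalog}.
#' @return A \linkS4class{SpecificityScores}.
#' @examples
#' cat <- MarkerCatalog(list(A = c("G1", "G2"), B = c("G2", "G3")))
#' specificityScores(computeSpecificity(cat))   # G1=G3=1, G2=0
#' @export
computeSpecificity <- function(cat) {
    pool <- sort(unique(unlist(markerGenes(cat), use.names = FALSE)))
    counts <- vapply(pool, function(g)
        sum(vapply(markerGenes(cat), function(m) g %in% m, NA)), 1L)
    lo <- min(counts); hi <- max(counts)
    S <- if (lo == hi) rep(1, length(pool))
         else 1 - (counts - lo) / (hi - lo)
    names(S) <- pool
    new("SpecificityScores", scores = S, typesPerMarker = counts)
}

#' Specificity-weighted z-score relevance (default strategy)
#'
#' Counts are library-size normalized (to the median library, without
#' log compression, so count magnitudes keep their weight), z-scored per
#' gene across cells (population standard deviation; zero-variance genes
#' contribute 0), restricted to the pooled marker list, and each marker
#' column is weighted by its specificity score. R_ij is the mean of the
#' weighted z-scores of type j's markers present in the data. Scores can
#' be negative; a type with no marker present scores 0 (with a warning).
#'
#' @param expr \linkS4class{SingleCellExperiment}.
#' @param cat \linkS4class{MarkerCatalog}.
#' @param spec Optional precomputed \linkS4class{SpecificityScores}.
#' @return A \linkS4class{RelevanceMatrix}.
#' @export
scoreCellTypeSpecific <- function(expr, cat, spec = computeSpecificity(cat)) {
    ln <- .normcountsOf(expr)                     # genes x cells
    mk <- .intersectCatalog(cat, rownames(ln))
    if (any(lengths(mk) == 0L))
        warning("type(s) with no marker present score 0 everywhere: ",
                paste(names(mk)[lengths(mk) == 0L], collapse = ", "))
    pool <- intersect(names(specificityScores(spec)), rownames(ln))
    Z <- ln[pool, , drop = FALSE]
    mu <- rowMeans(Z)
    sd <- sqrt(rowMeans((Z - mu)^2))              # population sd per gene
    Z <- (Z - mu) / ifelse(sd == 0, 1, sd)
    Z[sd == 0, ] <- 0
    Zw <- Z * specificityScores(spec)[pool]       # weight marker rows by S
    R <- vapply(typeNames(cat), function(ty) {
        g <- intersect(mk[[ty]], pool)
        if (!length(g)) return(numeric(ncol(Zw)))
        colMeans(Zw[g, , drop = FALSE])
    }, numeric(ncol(Zw)))
    dimnames(R) <- list(colnames(ln), typeNames(cat))
    .newScores("RelevanceMatrix", R, "cell-type-specific")
}

#' Compute cell-type relevance scores by a named strategy
#'
#' Dispatcher over the six relevance strategies. "cell-type-specific"
#' (the default) and "count" need only expression + markers; "cos",
#' "lr-label", "lr-marker" and "pseudo-cell" additionally require a
#' \linkS4class{GeneEmbedding}.
#'
#' @param expr \linkS4class{SingleCellExperiment}.
#' @param cat \linkS4class{MarkerCatalog}.
#' @param strategy One of "cell-type-specific", "count", "cos",
#'   "lr-label", "lr-marker", "pseudo-cell".
#' @param embedding \linkS4class{GeneEmbedding}, required by the
#'   embedding-based strategies.
#' @param ... Passed on to [scorePseudoCell()] (nPseudo, kappa, lambda,
#'   librarySize, seed).
#' @return A \linkS4class{RelevanceMatrix}.
#' @export
scoreRelevance <- function(expr, cat,
                           strategy = c("cell-type-specific", "count",
                                        "cos", "lr-label", "lr-marker",
                                        "pseudo-cell"),
                           embedding = NULL, ...) {
    strategy <- match.arg(strategy)
    needEmb <- strategy %in% c("cos", "lr-label", "lr-marker", "pseudo-cell")
    if (needEmb && is.null(embedding))
        stop("strategy '", strategy, "' requires a gene embedding")
    switch(strategy,
        "count" = scoreCount(expr, cat),
        "cell-type-specific" = scoreCellTypeSpecific(expr, cat),
        "cos" = scoreCosine(embedCellsAndTypes(expr, cat, embedding)),
        "lr-label" = scoreLR(embedCellsAndTypes(expr, cat, embedding),
                             cat, embedding, mode = "label"),
        "lr-marker" = scoreLR(embedCellsAndTypes(expr, cat, embedding),
                              cat, embedding, mode = "marker"),
        "pseudo-cell" = scorePseudoCell(expr, cat, embedding, ...))
}
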