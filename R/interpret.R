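#' Extract head-averaged CLS-to-pathway attention profiles
#'
#' Runs the trained classifier in evaluation mode and returns, per cell,
#' the CLS token's attention row averaged over heads, restricted to the
#' pathway columns. Before the restriction each head's full CLS row
#' (including the CLS column) is row-stochastic, so the profile entries
#' lie in [0, 1]. These profiles are the interpretable low-dimensional
#' cell representation of the framework.
#'
#' @param model A trained \linkS4class{PathwayTransformer}.
#' @param x Cells: \linkS4class{SingleCellExperiment} or aligned matrix.
#' @return Numeric cells x pathways matrix.
#' @export
extractAttentionProfiles <- function(model, x) {
    if (!is(model, "PathwayTransformer"))
        stop("attention profiles require the attention classifier; ",
             "the logistic regression ablation has none")
    predictTypes(model, x, attention = TRUE)$attention
}

# Shared normalization of attention profiles: scale each cell's profile
# to a fixed total, then log1p.
.normLogProfiles <- function(profiles, totalScale = 1e4) {
    tot <- rowSums(profiles)
    tot[tot == 0] <- 1
    log1p(profiles / tot * totalScale)
}

#' Cluster cells by their attention profiles
#'
#' Scales each profile to a fixed total (default 1e4), logarithmizes,
#' reduces by PCA, builds a shared-nearest-neighbour (SNN) graph on the
#' PCA coordinates — edges weighted by the Jaccard overlap of the two
#' cells' k-nearest-neighbour sets and pruned below 1/15, the standard
#' single-cell construction — and partitions it with the Louvain
#' algorithm at the configured resolution (default 0.3).
#'
#' @param profiles Numeric cells x pathways matrix from
#'   [extractAttentionProfiles()].
#' @param totalScale Per-cell scaling total (default 1e4).
#' @param nComponents Maximum PCA components (default 50; capped at the
#'   number of pathways and cells - 1).
#' @param neighbors Neighbours of the kNN graph (default 15).
#' @param resolution Louvain resolution (default 0.3).
#' @param seed Integer seed (Louvain refinement is randomized).
#' @return Integer vector of 0-based contiguous cluster labels, named by
#'   cell id.
#' @export
clusterAttention <- function(profiles, totalScale = 1e4,
                             nComponents = 50L, neighbors = 15L,
                             resolution = 0.3, seed = 0L) {
    stopifnot(is.matrix(profiles), totalScale > 0, nComponents >= 1L,
              neighbors >= 1L, resolution > 0)
    n <- nrow(profiles)
    if (n < neighbors + 1L)
        stop("need at least neighbors + 1 cells")
    ln <- .normLogProfiles(profiles, totalScale)
    if (all(apply(ln, 2L, stats::sd) == 0)) {
        warning("all attention profiles identical; single cluster")
        out <- rep(0L, n); names(out) <- rownames(profiles)
        return(out)
    }
    npc <- min(nComponents, ncol(ln), n - 1L)
    pcs <- stats::prcomp(ln, center = TRUE, scale. = FALSE,
                         rank. = npc)$x
    d <- as.matrix(stats::dist(pcs))
    diag(d) <- Inf
    adj <- matrix(0L, n, n)
    for (i in seq_len(n))
        adj[i, order(d[i, ])[seq_len(neighbors)]] <- 1L
    shared <- tcrossprod(adj)                  # shared kNN counts
    jac <- shared / (2 * neighbors - shared)
    keep <- which(jac >= 1 / 15 & upper.tri(jac), arr.ind = TRUE)
    g <- igraph::graph_from_edgelist(keep, directed = FALSE)
    if (igraph::vcount(g) < n)
        g <- igraph::add_vertices(g, n - igraph::vcount(g))
    igraph::E(g)$weight <- jac[keep]
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(.checkSeed(seed))
    comm <- igraph::cluster_louvain(g, resolution = resolution)
    lab <- igraph::membership(comm)
    out <- as.integer(factor(lab)) - 1L            # 0-based contiguous
    names(out) <- rownames(profiles)
    out
}

#' Rank signature pathways of each attention subcluster
#'
#' For every cluster, each pathway's normalized log attention is compared
#' between the cluster's cells and all other cells with a one-vs-rest
#' Wilcoxon rank-sum test. Pathways are ranked by the standardized
#' rank-sum statistic z (positive = higher attention inside the
#' cluster), with ties broken by pathway name so the ranking is
#' deterministic. P-values come from the exact distribution when both
#' group sizes are at most 10 and there are no ties, otherwise from the
#' normal approximation with tie correction; q-values are
#' Benjamini-Hochberg adjusted across pathways within each cluster.
#'
#' @param profiles Numeric cells x pathways attention matrix.
#' @param labels Cluster labels (one per cell); clusters with fewer than
#'   3 cells are skipped with a warning.
#' @param totalScale Per-cell scaling total before log1p (default 1e4).
#' @return data.frame: cluster, pathway, statistic (z), p, q, rank.
#' @export
signatureAttentions <- function(profiles, labels, totalScale = 1e4) {
    stopifnot(is.matrix(profiles), nrow(profiles) == length(labels))
    ln <- .normLogProfiles(profiles, totalScale)
    labs <- as.character(labels)
    keep <- names(which(table(labs) >= 3L))
    if (length(keep) < length(unique(labs)))
        warning("cluster(s) with fewer than 3 cells skipped: ",
                paste(setdiff(unique(labs), keep), collapse = ", "))
    if (length(keep) < 2L)
        stop("need at least 2 clusters with >= 3 cells")
    res <- list()
    for (cl in sort(keep)) {
        inCl <- labs == cl
        n1 <- sum(inCl); n2 <- sum(!inCl)
        stat <- p <- numeric(ncol(ln))
        for (j in seq_len(ncol(ln))) {
            xj <- ln[inCl, j]; yj <- ln[!inCl, j]
            r <- rank(c(xj, yj))
            ties <- table(r)
            W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
            mu <- n1 * n2 / 2
            sig2 <- n1 * n2 / 12 *
                ((n1 + n2 + 1) - sum(ties^3 - ties) /
                     ((n1 + n2) * (n1 + n2 - 1)))
            stat[j] <- if (sig2 > 0) (W - mu) / sqrt(sig2) else 0
            exact <- max(n1, n2) <= 10L && !any(ties > 1)
            p[j] <- suppressWarnings(
                stats::wilcox.test(xj, yj, exact = exact)$p.value)
        }
        ord <- order(-stat, colnames(ln))
        res[[cl]] <- data.frame(
            cluster = cl, pathway = colnames(ln)[ord],
            statistic = stat[ord], p = p[ord],
            q = stats::p.adjust(p, method = "BH")[ord],
            rank = seq_len(ncol(ln)), row.names = NULL)
    }
    do.call(rbind, c(res, make.row.names = FALSE))
}
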