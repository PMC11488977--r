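#' Simulate a single-cell dataset with planted types, markers and pathways
#'
#' Draws counts gene-wise from a negative binomial with a type-specific
#' mean inflation on marker genes, followed by element-wise dropout —
#' the conventional overdispersed-counts-plus-zeros structure of
#' scRNA-seq. Each planted type owns a block of marker genes and one
#' "enriched" pathway holding most of them; further background pathways
#' group random non-marker genes. A type-structured gene embedding
#' (marker embeddings clustered near their type centroid, background
#' genes diffuse) supports the embedding-based relevance strategies.
#' Everything is bit-reproducible under the seed.
#'
#' @param nCells,nGenes,nTypes Dataset size (defaults 1000, 300, 5).
#' @param markersPerType Markers per planted type (default 10);
#'   \code{markersPerType * nTypes} must not exceed \code{nGenes}.
#' @param foldChange Marker mean inflation in the owning type (default
#'   4); 1 plants no signal.
#' @param baselineMean,dispersion Negative binomial baseline mean and
#'   dispersion alpha, with variance mu + alpha * mu^2 (defaults 2,
#'   0.5); the NB size parameter is 1/alpha.
#' @param proportions Type proportions (default uniform); must sum to 1.
#' @param nPathways Total gene sets (default 20; at least nTypes).
#' @param pathwayMarkerFrac Fraction of each type's markers concentrated
#'   in its enriched pathway (default 0.8).
#' @param dropout Element-wise zeroing probability (default 0.3).
#' @param embedDim Gene embedding dimension (default 16).
#' @param markerOverlapFrac Fraction of each type's markers additionally
#'   listed by the next type (default 0 = clean catalog); exercises the
#'   specificity weighting.
#' @param seed Integer seed.
#' @return List: \code{expr} (\linkS4class{SingleCellExperiment} with
#'   counts, logcounts and \code{colData(expr)$trueType}), \code{markers}
#'   (\linkS4class{MarkerCatalog}), \code{pathways}
#'   (\linkS4class{PathwayCollection}), \code{embedding}
#'   (\linkS4class{GeneEmbedding}), \code{trueTypes} (named character),
#'   \code{enrichedPathway} (named character: type -> its pathway),
#'   \code{config} (the arguments).
#' @examples
#' ds <- simulateCells(nCells = 60, nGenes = 50, nTypes = 3,
#'                     markersPerType = 4, nPathways = 6, seed = 1)
#' table(ds$trueTypes)
#' @export
simulateCells <- function(nCells = 1000L, nGenes = 300L, nTypes = 5L,
                          markersPerType = 10L, foldChange = 4,
                          baselineMean = 2, dispersion = 0.5,
                          proportions = rep(1 / nTypes, nTypes),
                          nPathways = 20L, pathwayMarkerFrac = 0.8,
                          dropout = 0.3, embedDim = 16L,
                          markerOverlapFrac = 0, seed = 0L) {
    if (markersPerType * nTypes > nGenes)
        stop("infeasible config: markersPerType * nTypes exceeds nGenes")
    if (abs(sum(proportions) - 1) > 1e-8 || length(proportions) != nTypes)
        stop("infeasible config: proportions must be length nTypes and ",
             "sum to 1")
    if (foldChange < 1)
        stop("infeasible config: foldChange must be >= 1")
    if (nPathways < nTypes)
        stop("infeasible config: need at least one pathway per type")
    if (dropout < 0 || dropout >= 1)
        stop("infeasible config: dropout must lie in [0, 1)")
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(.checkSeed(seed))

    genes <- sprintf("G%04d", seq_len(nGenes))
    cells <- sprintf("CELL%04d", seq_len(nCells))
    types <- sprintf("TYPE%d", seq_len(nTypes))
    markerIdx <- lapply(seq_len(nTypes), function(t)
        (t - 1L) * markersPerType + seq_len(markersPerType))
    names(markerIdx) <- types
    trueTypes <- types[sample.int(nTypes, nCells, replace = TRUE,
                                  prob = proportions)]
    names(trueTypes) <- cells

    if (dispersion <= 0)
        stop("infeasible config: dispersion must be positive")
    nbSize <- 1 / dispersion
    counts <- matrix(stats::rnbinom(nGenes * nCells, mu = baselineMean,
                                    size = nbSize),
                     nrow = nGenes, dimnames = list(genes, cells))
    for (t in seq_len(nTypes)) {
        cols <- which(trueTypes == types[t])
        rows <- markerIdx[[t]]
        counts[rows, cols] <- stats::rnbinom(
            length(rows) * length(cols), mu = baselineMean * foldChange,
            size = nbSize)
    }
    if (dropout > 0)
        counts <- counts * matrix(stats::rbinom(length(counts), 1L,
                                                1 - dropout),
                                  nrow = nGenes)

    markers <- lapply(seq_len(nTypes), function(t) {
        m <- genes[markerIdx[[t]]]
        if (markerOverlapFrac > 0) {
            nxt <- if (t == nTypes) 1L else t + 1L
            nShare <- ceiling(markerOverlapFrac * markersPerType)
            m <- c(m, genes[markerIdx[[nxt]]][seq_len(nShare)])
        }
        m
    })
    names(markers) <- types
    catalog <- MarkerCatalog(markers)

    # One enriched pathway per type holding most of its markers; the
    # remaining gene sets sample the rest of the genome (leftover
    # markers included, so every gene can reach the classifier).
    nEnr <- round(pathwayMarkerFrac * markersPerType)
    sets <- list()
    for (t in seq_len(nTypes))
        sets[[sprintf("PW%02d_%s", t, types[t])]] <-
            genes[markerIdx[[t]]][seq_len(nEnr)]
    rest <- setdiff(genes, unlist(sets, use.names = FALSE))
    for (p in seq_len(nPathways - nTypes)) {
        sz <- sample(10:20, 1L)
        sets[[sprintf("PW%02d_BG", nTypes + p)]] <-
            sample(rest, min(sz, length(rest)))
    }
    pathways <- PathwayCollection(sets)
    enriched <- names(sets)[seq_len(nTypes)]
    names(enriched) <- types

    centroids <- matrix(stats::rnorm(nTypes * embedDim), nTypes)
    centroids <- centroids / sqrt(rowSums(centroids^2))
    emb <- matrix(stats::rnorm(nGenes * embedDim, sd = 1 / sqrt(embedDim)),
                  nrow = nGenes, dimnames = list(genes, NULL))
    for (t in seq_len(nTypes))
        emb[markerIdx[[t]], ] <-
            matrix(rep(centroids[t, ], each = markersPerType),
                   nrow = markersPerType) +
            stats::rnorm(markersPerType * embedDim, sd = 0.15)
    embedding <- GeneEmbedding(emb)

    expr <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = counts),
        colData = S4Vectors::DataFrame(trueType = trueTypes))
    expr <- logNormalize(expr)

    if (foldChange > 1.5) {
        for (t in seq_len(nTypes)) {
            own <- rowMeans(counts[markerIdx[[t]],
                                   trueTypes == types[t], drop = FALSE])
            oth <- rowMeans(counts[markerIdx[[t]],
                                   trueTypes != types[t], drop = FALSE])
            if (any(own <= oth))
                warning("planted marker(s) of ", types[t],
                        " not overexpressed in their type (sampling ",
                        "noise); consider more cells or a larger fold")
        }
    }

    list(expr = expr, markers = catalog, pathways = pathways,
         embedding = embedding, trueTypes = trueTypes,
         enrichedPathway = enriched,
         config = list(nCells = nCells, nGenes = nGenes, nTypes = nTypes,
                       markersPerType = markersPerType,
                       foldChange = foldChange,
                       baselineMean = baselineMean,
                       dispersion = dispersion,
                       proportions = proportions, nPathways = nPathways,
                       pathwayMarkerFrac = pathwayMarkerFrac,
                       dropout = dropout, embedDim = embedDim,
                       markerOverlapFrac = markerOverlapFrac,
                       seed = seed))
}

#' Mix uniform noise into soft pseudo-labels
#'
#' Returns \code{(1 - noise) * L + noise / T}: every row stays on the
#' probability simplex. \code{noise = 0} is the identity, \code{noise =
#' 1} makes every row uniform. Used to study how self-training copes
#' with corrupted pseudo-labels.
#'
#' @param L A \linkS4class{PseudoLabelMatrix}.
#' @param noiseFraction Mixing weight in [0, 1].
#' @return A \linkS4class{PseudoLabelMatrix}.
#' @export
corruptPseudoLabels <- function(L, noiseFraction) {
    stopifnot(is(L, "PseudoLabelMatrix"))
    if (noiseFraction < 0 || noiseFraction > 1)
        stop("noiseFraction must lie in [0, 1]")
    v <- scoreMatrix(L)
    out <- (1 - noiseFraction) * v + noiseFraction / ncol(v)
    .newScores("PseudoLabelMatrix", out,
               paste0(scoreStrategy(L), "+noise", noiseFraction))
}

#' Write a simulated dataset to disk in the package's input dialects
#'
#' Emits \code{matrix.mtx} + \code{genes.tsv} + \code{barcodes.tsv}
#' (genes x cells Matrix Market), \code{markers.csv},
#' \code{pathways.gmt}, \code{embedding.tsv} and \code{truth.csv} into
#' \code{dir}; each file round-trips through the corresponding reader.
#'
#' @param ds A dataset from [simulateCells()].
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeFixture <- function(ds, dir) {
    if (!dir.exists(dir) &&
        !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
        stop("cannot create directory: ", dir)
    cts <- SummarizedExperiment::assay(ds$expr, "counts")
    Matrix::writeMM(methods::as(Matrix::Matrix(cts, sparse = TRUE),
                                "generalMatrix"),
                    file.path(dir, "matrix.mtx"))
    writeLines(rownames(cts), file.path(dir, "genes.tsv"))
    writeLines(colnames(cts), file.path(dir, "barcodes.tsv"))

    mk <- markerGenes(ds$markers)
    utils::write.csv(
        data.frame(cell_type = rep(names(mk), lengths(mk)),
                   gene = unlist(mk, use.names = FALSE)),
        file.path(dir, "markers.csv"), row.names = FALSE)

    sets <- pathwayGenes(ds$pathways)
    writeLines(vapply(names(sets), function(nm)
        paste(c(nm, "na", sets[[nm]]), collapse = "\t"), ""),
        file.path(dir, "pathways.gmt"))

    em <- embeddingMatrix(ds$embedding)
    writeLines(vapply(rownames(em), function(g)
        paste(c(g, format(em[g, ], digits = 17)), collapse = "\t"), ""),
        file.path(dir, "embedding.tsv"))

    utils::write.csv(
        data.frame(cell_id = names(ds$trueTypes),
                   true_type = unname(ds$trueTypes)),
        file.path(dir, "truth.csv"), row.names = FALSE)
    invisible(dir)
}
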