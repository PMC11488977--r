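test_that("count relevance counts expressed markers", {
    sce <- toySCE()
    cat <- toyCatalog()
    R <- scoreMatrix(scoreCount(sce, cat))
    # cell c1 = (1,0,3,0): A markers {G1,G3} both expressed, B marker G2 not
    expect_identical(unname(R["c1", ]), c(2, 0))

    # all-zero cell scores zero everywhere
    cts <- t(toyCounts()); cts[, "c2"] <- 0
    sce0 <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = cts))
    expect_identical(unname(scoreMatrix(scoreCount(sce0, cat))["c2", ]),
                     c(0, 0))
})

test_that("count relevance matches a per-marker loop oracle and is scale-invariant", {
    set.seed(7)
    cts <- matrix(rpois(20 * 10, 0.8), nrow = 10,
                  dimnames = list(sprintf("G%02d", 1:10),
                                  sprintf("c%02d", 1:20)))
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = cts))
    cat <- MarkerCatalog(list(A = c("G01", "G02", "G03"),
                              B = c("G04", "G05"),
                              C = c("G06", "G07", "G08", "G09")))
    R <- scoreMatrix(scoreCount(sce, cat))
    for (i in seq_len(20))
        for (ty in typeNames(cat)) {
            exp_ij <- sum(vapply(markerGenes(cat, ty),
                                 function(g) cts[g, i] > 0, NA))
            expect_identical(unname(R[i, ty]), as.numeric(exp_ij))
        }
    # monotone positive rescaling leaves the score unchanged
    sce2 <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = cts * 7.3))
    expect_identical(scoreMatrix(scoreCount(sce2, cat)), R)
})

test_that("cell and type embeddings follow the weighted-average rule", {
    emb <- toyEmbedding()
    E <- embeddingMatrix(emb)
    cat <- toyCatalog()
    # cell expressing only G2 embeds exactly at e_G2
    cts <- t(toyCounts()) * 0; cts["G2", "c1"] <- 5
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = cts))
    expect_warning(ce <- embedCellsAndTypes(sce, cat, emb), "zero")
    expect_equal(unname(cellVectors(ce)["c1", ]), unname(E["G2", ]))
    # type embedding = mean of its marker embeddings
    expect_equal(unname(typeVectors(ce)["A", ]),
                 unname(colMeans(E[c("G1", "G3"), ])))

    # random instance vs direct formula
    set.seed(5)
    cts2 <- matrix(rpois(4 * 6, 2), nrow = 4,
                   dimnames = list(rownames(E), sprintf("c%d", 1:6)))
    sce2 <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = cts2))
    ce2 <- embedCellsAndTypes(sce2, cat, emb)
    for (i in 1:6) {
        x <- cts2[, i]
        expect_equal(unname(cellVectors(ce2)[i, ]),
                     unname(as.numeric(x %*% E) / sum(x)),
                     tolerance = 1e-10)
    }
})

test_that("cosine relevance matches the dot/norm formula", {
    cv <- rbind(c(1, 0), c(0, 2), c(1, 1), c(0, 0))
    tv <- rbind(c(2, 0), c(-1, 1))
    rownames(cv) <- paste0("c", 1:4); rownames(tv) <- c("A", "B")
    ce <- new("CellTypeEmbeddings", cellVectors = cv, typeVectors = tv)
    R <- scoreMatrix(scoreCosine(ce))
    expect_equal(unname(R["c1", "A"]), 1)              # identical direction
    expect_equal(unname(R["c2", "A"]), 0)              # orthogonal
    expect_equal(unname(R["c4", ]), c(0, 0))           # zero vector
    for (i in 1:3)
        for (j in 1:2)
            expect_equal(unname(R[i, j]),
                         sum(cv[i, ] * tv[j, ]) /
                             (sqrt(sum(cv[i, ]^2)) * sqrt(sum(tv[j, ]^2))),
                         tolerance = 1e-12)
})

test_that("logistic-regression relevance behaves as a classifier", {
    ds <- smallSim()
    ce <- embedCellsAndTypes(ds$expr, ds$markers, ds$embedding)
    R1 <- scoreMatrix(scoreLR(ce, ds$markers, ds$embedding, mode = "label"))
    expect_equal(unname(rowSums(R1)), rep(1, nrow(R1)), tolerance = 1e-9)

    # cells placed exactly at linearly separable type embeddings recover them
    tv <- diag(3) * 4
    rownames(tv) <- c("A", "B", "C")
    cv <- tv[rep(1:3, each = 5), ] + matrix(rnorm(45, sd = 0.05), 15)
    rownames(cv) <- sprintf("c%02d", 1:15)
    ce2 <- new("CellTypeEmbeddings", cellVectors = cv, typeVectors = tv)
    cat2 <- MarkerCatalog(list(A = "G1", B = "G2", C = "G3"))
    emb2 <- GeneEmbedding(tv * 0 + tv, caseNormalize = FALSE)
    R2 <- scoreMatrix(scoreLR(ce2, cat2, emb2, mode = "label"))
    expect_identical(colnames(R2)[apply(R2, 1, which.max)],
                     rep(c("A", "B", "C"), each = 5))

    # one marker per type: marker mode sees the same training set
    set.seed(2)
    E <- matrix(rnorm(12), 3,
                dimnames = list(c("G1", "G2", "G3"), NULL))
    emb3 <- GeneEmbedding(E)
    cv3 <- matrix(rnorm(5 * 4), 5, 4, dimnames = list(paste0("c", 1:5), NULL))
    tv3 <- E  # type embedding = its single marker's embedding
    rownames(tv3) <- c("A", "B", "C")
    ce3 <- new("CellTypeEmbeddings", cellVectors = cv3, typeVectors = tv3)
    cat3 <- MarkerCatalog(list(A = "G1", B = "G2", C = "G3"))
    Rlab <- scoreMatrix(scoreLR(ce3, cat3, emb3, mode = "label"))
    Rmar <- scoreMatrix(scoreLR(ce3, cat3, emb3, mode = "marker"))
    expect_equal(Rlab, Rmar, tolerance = 1e-6)
})

test_that("pseudo-cell relevance is seeded and concentrates around types", {
    ds <- smallSim()
    expect_error(scorePseudoCell(ds$expr, ds$markers, ds$embedding,
                                 kappa = -1), "positive")
    R1 <- scorePseudoCell(ds$expr, ds$markers, ds$embedding,
                          nPseudo = 40L, seed = 4L)
    R2 <- scorePseudoCell(ds$expr, ds$markers, ds$embedding,
                          nPseudo = 40L, seed = 4L)
    expect_identical(scoreMatrix(R1), scoreMatrix(R2))  # bit-identical

    # very large concentration pins sampled directions at the mean
    mu <- c(1, 0, 0, 0) ; mu <- mu / sqrt(sum(mu^2))
    set.seed(1)
    dirs <- markerAttn:::.rvmf(20, mu, 1e6)
    expect_true(all(dirs %*% mu > 1 - 1e-4))   # cosine pinned at the mean
    expect_true(all(abs(sweep(dirs, 2, mu)) < 5e-3))

    # pseudo-cells lie closer to their own type than to others
    ce <- embedCellsAndTypes(ds$expr, ds$markers, ds$embedding)
    tv <- typeVectors(ce)
    set.seed(9)
    for (ty in rownames(tv)) {
        mu <- tv[ty, ] / sqrt(sum(tv[ty, ]^2))
        dirs <- markerAttn:::.rvmf(50, mu, 50)
        cosTo <- function(v) {
            w <- tv[v, ] / sqrt(sum(tv[v, ]^2)); mean(dirs %*% w)
        }
        own <- cosTo(ty)
        for (other in setdiff(rownames(tv), ty))
            expect_gt(own, cosTo(other))
    }
})

test_that("specificity scores follow the min-max rescaled type counts", {
    cat <- MarkerCatalog(list(A = c("M1", "M2", "M3"),
                              B = c("M2", "M3"),
                              C = "M3"))
    S <- specificityScores(computeSpecificity(cat))
    expect_equal(unname(S[c("M1", "M2", "M3")]), c(1, 0.5, 0))

    # every marker private to one type: degenerate rule gives all 1
    cat2 <- MarkerCatalog(list(A = c("M1", "M2"), B = "M3"))
    expect_true(all(specificityScores(computeSpecificity(cat2)) == 1))

    # random catalogs match direct evaluation, independent of ordering
    set.seed(21)
    for (r in 1:20) {
        genes <- sprintf("M%02d", 1:15)
        mk <- lapply(1:4, function(i) sample(genes, sample(2:8, 1)))
        names(mk) <- paste0("T", 1:4)
        sp <- computeSpecificity(MarkerCatalog(mk))
        counts <- typesPerMarker(sp)
        lo <- min(counts); hi <- max(counts)
        expected <- if (lo == hi) rep(1, length(counts))
                    else 1 - (counts - lo) / (hi - lo)
        expect_equal(unname(specificityScores(sp)), unname(expected))
        # invariance to type order
        sp2 <- computeSpecificity(MarkerCatalog(rev(mk)))
        expect_identical(specificityScores(sp),
                         specificityScores(sp2))
    }
})

test_that("specificity-weighted z-score relevance matches a naive loop", {
    # two cells, one single-type marker with expression [0, 2]:
    # population z-scores are [-1, +1] whatever the monotone scaling
    cts <- matrix(c(0, 2), nrow = 1,
                  dimnames = list("M1", c("c1", "c2")))
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = cts))
    cat <- MarkerCatalog(list(A = "M1", B = "M1"))
    suppressWarnings(R <- scoreMatrix(scoreCellTypeSpecific(sce, cat)))
    expect_equal(unname(R[, "A"]), c(-1, 1))

    # a gene constant after library normalization contributes exactly zero
    cts2 <- rbind(M1 = c(2, 4, 6), M2 = c(1, 3, 2), M3 = c(1, 1, 4))
    colnames(cts2) <- paste0("c", 1:3)   # M1 is half of every library
    sce2 <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = cts2))
    cat2 <- MarkerCatalog(list(A = "M1", B = "M2"))
    R2 <- scoreMatrix(scoreCellTypeSpecific(sce2, cat2))
    expect_equal(unname(R2[, "A"]), c(0, 0, 0))

    # random instance vs naive implementation
    ds <- smallSim()
    R3 <- scoreMatrix(scoreCellTypeSpecific(ds$expr, ds$markers))
    norm <- markerAttn:::.normcountsOf(ds$expr)
    sp <- specificityScores(computeSpecificity(ds$markers))
    naive <- matrix(0, ncol(norm), length(typeNames(ds$markers)),
                    dimnames = list(colnames(norm),
                                    typeNames(ds$markers)))
    for (ty in typeNames(ds$markers)) {
        g <- intersect(markerGenes(ds$markers, ty), rownames(norm))
        for (i in seq_len(ncol(norm))) {
            acc <- 0
            for (gg in g) {
                v <- norm[gg, ]
                sd <- sqrt(mean((v - mean(v))^2))
                z <- if (sd == 0) 0 else (norm[gg, i] - mean(v)) / sd
                acc <- acc + z * sp[[gg]]
            }
            naive[i, ty] <- acc / length(g)
        }
    }
    expect_equal(R3, naive, tolerance = 1e-10)
})

test_that("all strategies stay finite on degenerate cells", {
    ds <- smallSim(nCells = 80L)
    cts <- SummarizedExperiment::assay(ds$expr, "counts")
    cts[, 1:3] <- 0                       # plant all-zero cells
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = cts))
    suppressWarnings({
        for (s in c("count", "cell-type-specific", "cos")) {
            R <- scoreRelevance(sce, ds$markers, s,
                                embedding = ds$embedding)
            expect_true(all(is.finite(scoreMatrix(R))))
        }
    })
    expect_error(scoreRelevance(sce, ds$markers, "cos"), "embedding")
})
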