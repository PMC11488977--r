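test_that("the generator is seeded and validates its configuration", {
    d1 <- smallSim(seed = 5)
    d2 <- smallSim(seed = 5)
    expect_identical(
        as.matrix(SummarizedExperiment::assay(d1$expr, "counts")),
        as.matrix(SummarizedExperiment::assay(d2$expr, "counts")))
    expect_identical(d1$trueTypes, d2$trueTypes)
    expect_identical(markerGenes(d1$markers), markerGenes(d2$markers))
    expect_identical(embeddingMatrix(d1$embedding),
                     embeddingMatrix(d2$embedding))

    expect_error(simulateCells(nGenes = 20, nTypes = 5,
                               markersPerType = 10), "markersPerType")
    expect_error(simulateCells(proportions = c(0.5, 0.5)), "proportions")
    expect_error(simulateCells(foldChange = 0.5), "foldChange")
    expect_error(simulateCells(nPathways = 2, nTypes = 5), "pathway")
    expect_error(simulateCells(dropout = 1), "dropout")
})

test_that("planted markers are overexpressed at the configured fold", {
    ds <- simulateCells(nCells = 600, seed = 2)
    cts <- as.matrix(SummarizedExperiment::assay(ds$expr, "counts"))
    folds <- c()
    for (ty in typeNames(ds$markers)) {
        mk <- markerGenes(ds$markers, ty)
        own <- rowMeans(cts[mk, ds$trueTypes == ty, drop = FALSE])
        oth <- rowMeans(cts[mk, ds$trueTypes != ty, drop = FALSE])
        expect_true(all(own > oth))
        folds <- c(folds, own / oth)
    }
    # realized fold-change stays near the configured value of 4
    expect_gte(mean(folds >= 3 & folds <= 5), 0.9)
})

test_that("fold-change 1 plants no marker signal", {
    pvals <- vapply(1:5, function(sd) {
        ds <- simulateCells(nCells = 200, nGenes = 100, foldChange = 1,
                            seed = sd)
        cts <- as.matrix(SummarizedExperiment::assay(ds$expr, "counts"))
        mk <- unlist(markerGenes(ds$markers))
        bg <- setdiff(rownames(cts), mk)
        suppressWarnings(
            wilcox.test(rowMeans(cts[mk, ]), rowMeans(cts[bg, ]))$p.value)
    }, 0)
    expect_gte(sum(pvals > 0.05), 4)
})

test_that("a larger fold-change widens the count-relevance margin", {
    gap <- vapply(c(1.5, 3, 6), function(fc) {
        ds <- simulateCells(nCells = 300, foldChange = fc, seed = 8)
        R <- scoreMatrix(scoreCount(ds$expr, ds$markers))
        own <- R[cbind(seq_len(nrow(R)),
                       match(ds$trueTypes, colnames(R)))]
        bestOther <- vapply(seq_len(nrow(R)), function(i)
            max(R[i, colnames(R) != ds$trueTypes[i]]), 0)
        mean(own - bestOther)
    }, 0)
    expect_true(all(diff(gap) > 0))
})

test_that("pseudo-label corruption mixes toward the uniform simplex", {
    L <- normalizeToSimplex(new("RelevanceMatrix",
        values = randomScores(10, 4), strategy = "demo"))
    expect_identical(scoreMatrix(corruptPseudoLabels(L, 0)),
                     scoreMatrix(L))
    u <- scoreMatrix(corruptPseudoLabels(L, 1))
    expect_true(all(abs(u - 0.25) < 1e-12))

    onehot <- new("PseudoLabelMatrix",
                  values = matrix(c(1, 0), 1,
                                  dimnames = list("c1", c("A", "B"))),
                  strategy = "demo")
    expect_equal(unname(scoreMatrix(corruptPseudoLabels(onehot, 0.5))[1, ]),
                 c(0.75, 0.25))
    expect_error(corruptPseudoLabels(L, 1.2), "noiseFraction")
    # rows remain simplices at intermediate noise
    m <- scoreMatrix(corruptPseudoLabels(L, 0.37))
    expect_equal(unname(rowSums(m)), rep(1, 10), tolerance = 1e-9)
})

test_that("fixture files round-trip through the package readers", {
    ds <- smallSim(seed = 3)
    dir <- withr::local_tempdir()
    writeFixture(ds, dir)
    expect_setequal(list.files(dir),
                    c("matrix.mtx", "genes.tsv", "barcodes.tsv",
                      "markers.csv", "pathways.gmt", "embedding.tsv",
                      "truth.csv"))
    cat2 <- readMarkers(file.path(dir, "markers.csv"), fmt = "csv")
    expect_identical(markerGenes(cat2), markerGenes(ds$markers))
    pc2 <- readGMT(file.path(dir, "pathways.gmt"))
    expect_identical(lengths(pathwayGenes(pc2)),
                     lengths(pathwayGenes(ds$pathways)))
    emb2 <- readGeneEmbedding(file.path(dir, "embedding.tsv"))
    expect_equal(embeddingMatrix(emb2), embeddingMatrix(ds$embedding),
                 tolerance = 1e-12)
    truth <- read.csv(file.path(dir, "truth.csv"))
    expect_identical(truth$cell_id, names(ds$trueTypes))
    expect_identical(truth$true_type, unname(ds$trueTypes))
})
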