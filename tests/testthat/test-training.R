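# Shared small training setup: easy, well-separated data.
trainFixture <- function(seed = 1L) {
    ds <- simulateCells(nCells = 150L, nGenes = 60L, nTypes = 3L,
                        markersPerType = 5L, foldChange = 8,
                        dropout = 0.1, nPathways = 8L, embedDim = 8L,
                        seed = seed)
    ex <- logNormalize(ds$expr)
    mask <- buildPathwayMask(ds$pathways, rownames(ex))
    model <- PathwayTransformer(mask, typeNames(ds$markers),
                                embedDim = 16, nHeads = 2, seed = seed)
    list(ds = ds, ex = ex, model = model,
         X = modelInput(model, ex))
}

test_that("zero pretraining epochs leave parameters bit-identical", {
    fx <- trainFixture()
    L <- scoreMatrix(normalizeToSimplex(
        scoreRelevance(fx$ex, fx$ds$markers)))
    pt <- pretrain(fx$model, fx$X, L, epochs = 0)
    expect_identical(pt$model@params, fx$model@params)
    expect_length(pt$losses, 0)
})

test_that("pretraining reduces the loss and fits clean pseudo-labels", {
    fx <- trainFixture()
    # clean (one-hot truth) pseudo-labels on well-separated data
    types <- typeNames(fx$ds$markers)
    L <- diag(3)[match(fx$ds$trueTypes, types), ]
    colnames(L) <- types
    pt <- pretrain(fx$model, fx$X, L, epochs = 100, weightDecay = 0,
                   seed = 0)
    expect_lt(pt$losses[length(pt$losses)], pt$losses[1])
    pred <- types[markerAttn:::.rowArgmax(
        predictTypes(pt$model, fx$X)$probs)]
    agree <- mean(pred == types[markerAttn:::.rowArgmax(L)])
    expect_gte(agree, 0.95)
})

test_that("full-batch plain gradient descent decreases the loss monotonically", {
    fx <- trainFixture()
    L <- scoreMatrix(normalizeToSimplex(
        scoreRelevance(fx$ex, fx$ds$markers)))
    pt <- pretrain(fx$model, fx$X, L, epochs = 20,
                   batchSize = nrow(fx$X), lr = 1e-4,
                   optimizer = "sgd", weightDecay = 0, seed = 0)
    expect_true(all(diff(pt$losses) <= 1e-8))
})

test_that("self-training stops at a fixed point and obeys its contracts", {
    fx <- trainFixture()
    types <- typeNames(fx$ds$markers)
    L <- diag(3)[match(fx$ds$trueTypes, types), ]
    colnames(L) <- types
    pt <- pretrain(fx$model, fx$X, L, epochs = 120, seed = 0)
    # predictions are now sharp and self-consistent: one round, tiny change
    st <- selfTrain(pt$model, fx$X, maxRounds = 5, seed = 0)
    expect_true(st$converged)
    expect_identical(max(st$history$round), 1L)
    lastChange <- st$history$labelChange[!is.na(st$history$labelChange)]
    expect_lt(lastChange[length(lastChange)], 0.001)

    # never runs past maxRounds, and rounds are recorded densely
    st2 <- selfTrain(fx$model, fx$X, maxRounds = 2, epochsPerRound = 2,
                     delta = 1e-9, seed = 0)
    expect_lte(max(st2$history$round), 2L)
    expect_identical(unique(st2$history$phase), "self-train")
})

test_that("the end-to-end pipeline is reproducible and honours ablations", {
    ds <- smallSim()
    r1 <- annotateCells(ds$expr, ds$markers, ds$pathways,
                        embedDim = 16L, nHeads = 2L,
                        pretrainEpochs = 25L, maxRounds = 3L, seed = 3)
    r2 <- annotateCells(ds$expr, ds$markers, ds$pathways,
                        embedDim = 16L, nHeads = 2L,
                        pretrainEpochs = 25L, maxRounds = 3L, seed = 3)
    expect_identical(predictedTypes(r1), predictedTypes(r2))
    expect_identical(typeProbabilities(r1), typeProbabilities(r2))

    # predicted type is the row argmax
    expect_identical(predictedTypes(r1),
                     typeNames(r1)[apply(typeProbabilities(r1), 1,
                                         which.max)])

    r3 <- annotateCells(ds$expr, ds$markers, ds$pathways,
                        embedDim = 16L, nHeads = 2L,
                        pretrainEpochs = 25L, selfTraining = FALSE,
                        seed = 3)
    expect_identical(sum(trainingHistory(r3)$phase == "self-train"), 0L)

    r4 <- annotateCells(ds$expr, ds$markers, ds$pathways,
                        classifier = "lr", maxRounds = 2L, seed = 3)
    expect_null(attentionProfiles(r4))
    expect_equal(unname(rowSums(typeProbabilities(r4))),
                 rep(1, ncol(ds$expr)), tolerance = 1e-6)
})
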