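# A tiny model reused across blocks.
tinyModel <- function(seed = 7L, nHeads = 2L, embedDim = 8L) {
    pm <- buildPathwayMask(
        PathwayCollection(list(P1 = c("G1", "G2", "G3"),
                               P2 = c("G3", "G4"),
                               P3 = c("G2", "G5"))),
        paste0("G", 1:5))
    PathwayTransformer(pm, c("A", "B", "C"), embedDim = embedDim,
                       nHeads = nHeads, seed = seed)
}

test_that("initialization is seeded and respects the mask", {
    m1 <- tinyModel(seed = 3)
    m2 <- tinyModel(seed = 3)
    expect_identical(m1@params, m2@params)
    m3 <- tinyModel(seed = 4)
    expect_false(identical(m1@params$Wemb, m3@params$Wemb))

    mv <- markerAttn:::.maskVec(m1)
    expect_true(all(m1@params$Wemb[mv == 0, ] == 0))

    pm <- m1@mask
    expect_error(PathwayTransformer(pm, c("A", "B"), embedDim = 10,
                                    nHeads = 4), "divisible")
})

test_that("token embedding is linear, masked, and exact", {
    model <- tinyModel()
    G <- length(geneIds(model@mask))
    I0 <- embedTokens(model, rep(0, G))
    expect_equal(unname(I0[1, ]), model@params$cls)    # CLS unchanged
    expect_true(all(I0[-1, ] == 0))                    # zero cell, zero tokens

    # perturbing a gene outside pathway p leaves token p bit-identical
    x <- c(1, 2, 0, 3, 1)
    I1 <- embedTokens(model, x)
    x2 <- x; x2[4] <- 99                               # G4 not in P1 or P3
    I2 <- embedTokens(model, x2)
    expect_identical(I1["P1", ], I2["P1", ])
    expect_identical(I1["P3", ], I2["P3", ])
    expect_false(identical(I1["P2", ], I2["P2", ]))

    # single pathway containing one gene: token = weight row * x_g
    pm1 <- buildPathwayMask(PathwayCollection(list(P = "G1", Q = "G2")),
                            c("G1", "G2"))
    mod1 <- PathwayTransformer(pm1, c("A", "B"), embedDim = 4, nHeads = 2)
    w <- mod1@params$Wemb[1, ]                         # row of gene G1 in P
    I <- embedTokens(mod1, c(2.5, 7))
    expect_equal(unname(I["P", ]), unname(w * 2.5))

    expect_error(embedTokens(model, c(1, 2)), "does not match")
})

test_that("forward pass is row-stochastic and matches the reference", {
    model <- tinyModel()
    set.seed(1)
    X <- matrix(abs(rnorm(6 * 5)), 6, 5,
                dimnames = list(paste0("c", 1:6), paste0("G", 1:5)))
    out <- predictTypes(model, X, attention = TRUE, fullAttention = TRUE)
    expect_equal(unname(rowSums(out$probs)), rep(1, 6), tolerance = 1e-6)
    for (A in out$fullAttention) {
        expect_equal(unname(rowSums(A)), rep(1, nrow(A)), tolerance = 1e-5)
        expect_true(all(A >= 0 & A <= 1))
    }
    # compiled pass equals the plain-R reference implementation
    for (i in 1:6) {
        ref <- referenceForward(X[i, ], model@params,
                                maskMatrix(model), model@config$nHeads)
        expect_equal(unname(out$probs[i, ]), ref$probs, tolerance = 1e-8)
    }
})

test_that("hand-fixed one-head forward matches a by-hand computation", {
    # k = 2 pathways over 2 genes, m = 2, one head, hand-picked weights
    pm <- buildPathwayMask(PathwayCollection(list(P1 = "G1", P2 = "G2")),
                           c("G1", "G2"))
    model <- PathwayTransformer(pm, c("A", "B"), embedDim = 2, nHeads = 1)
    model@params <- list(
        Wemb = rbind(c(1, 0),      # P1 x G1
                     c(0, 0),      # P1 x G2 (masked)
                     c(0, 0),      # P2 x G1 (masked)
                     c(0, 1)),     # P2 x G2
        cls = c(0.5, -0.5),
        Wq = rbind(c(1, 0), c(0, 1)),
        Wk = rbind(c(0, 1), c(1, 0)),
        Wv = rbind(c(1, 1), c(0, 1)),
        Wp = rbind(c(2, 0), c(0, -1)),
        b = c(0.1, -0.1))
    x <- c(1, 2)
    # by hand: I = [cls; (1,0); (0,2)]
    I <- rbind(c(0.5, -0.5), c(1, 0), c(0, 2))
    Q <- I %*% model@params$Wq
    K <- I %*% model@params$Wk
    S <- Q %*% t(K) / sqrt(2)
    A <- t(apply(S, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
    V <- I %*% model@params$Wv
    O <- A %*% V
    logits <- as.numeric(O[1, ] %*% model@params$Wp + model@params$b)
    pHand <- exp(logits - max(logits)); pHand <- pHand / sum(pHand)

    out <- predictTypes(model, matrix(x, 1, dimnames = list("c1", NULL)),
                        fullAttention = TRUE)
    expect_equal(unname(out$probs[1, ]), pHand, tolerance = 1e-8)
    expect_equal(unname(out$fullAttention[[1]]), unname(A),
                 tolerance = 1e-8)
})

test_that("analytic gradients match finite differences", {
    model <- tinyModel(seed = 12)
    set.seed(2)
    X <- matrix(abs(rnorm(3 * 5)), 3, 5)
    L <- matrix(rgamma(9, 1), 3); L <- L / rowSums(L)
    fb <- markerAttn:::.forwardBackward(model, X, L)
    lossAt <- function(params) {
        m2 <- model; m2@params <- params
        markerAttn:::.forwardBackward(m2, X, L)$loss
    }
    h <- 1e-6
    mv <- markerAttn:::.maskVec(model)
    set.seed(3)
    for (nm in names(model@params)) {
        g <- fb$grads[[nm]]
        for (idx in sample(length(g), min(10, length(g)))) {
            if (nm == "Wemb" && mv[(idx - 1) %% nrow(g) + 1] == 0) next
            p1 <- model@params; p1[[nm]][idx] <- p1[[nm]][idx] + h
            p0 <- model@params; p0[[nm]][idx] <- p0[[nm]][idx] - h
            num <- (lossAt(p1) - lossAt(p0)) / (2 * h)
            expect_lt(abs(g[idx] - num), 1e-6 + 1e-4 * abs(num))
        }
    }
    # masked gradient positions are exactly zero
    expect_true(all(fb$grads$Wemb[mv == 0, ] == 0))
})

test_that("forward output is invariant to a joint gene permutation", {
    model <- tinyModel(seed = 5)
    set.seed(4)
    X <- matrix(abs(rnorm(4 * 5)), 4, 5)
    p1 <- predictTypes(model, X)$probs

    perm <- c(3, 1, 5, 2, 4)
    G <- 5; k <- nrow(maskMatrix(model))
    m2 <- model
    newMask <- maskMatrix(model)[, perm]
    m2@mask <- new("PathwayMask", mask = newMask)
    W <- model@params$Wemb
    Wp <- W
    for (p in seq_len(k))
        Wp[(p - 1) * G + seq_len(G), ] <- W[(p - 1) * G + perm, ]
    m2@params$Wemb <- Wp
    p2 <- predictTypes(m2, X[, perm])$probs
    expect_equal(p1, p2, tolerance = 1e-8)
})

test_that("masked weights stay exactly zero through training", {
    ds <- smallSim()
    ex <- logNormalize(ds$expr)
    mask <- buildPathwayMask(ds$pathways, rownames(ex))
    model <- PathwayTransformer(mask, typeNames(ds$markers),
                                embedDim = 8, nHeads = 2, seed = 0)
    X <- modelInput(model, ex)
    L <- scoreMatrix(normalizeToSimplex(scoreRelevance(ex, ds$markers)))
    pt <- pretrain(model, X, L, epochs = 8, seed = 0)
    mv <- markerAttn:::.maskVec(model)
    expect_true(all(pt$model@params$Wemb[mv == 0, ] == 0))
    # and the gradient at the trained point is still zero there
    fb <- markerAttn:::.forwardBackward(pt$model, X[1:20, ],
                                        L[1:20, typeNames(ds$markers)])
    expect_true(all(fb$grads$Wemb[mv == 0, ] == 0))
})
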