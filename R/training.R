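# Adam optimizer state and update over a named list of parameters.
.adamInit <- function(params) {
    list(m = lapply(params, function(p) p * 0),
         v = lapply(params, function(p) p * 0),
         t = 0L)
}

.adamStep <- function(params, grads, state, lr, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
    state$t <- state$t + 1L
    bc1 <- 1 - beta1^state$t
    bc2 <- 1 - beta2^state$t
    for (nm in names(params)) {
        g <- grads[[nm]]
        state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
        state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
        params[[nm]] <- params[[nm]] -
            lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    }
    list(params = params, state = state)
}

.emptyHistory <- function() {
    data.frame(phase = character(), round = integer(), epoch = integer(),
               loss = numeric(), labelChange = numeric())
}

# One optimization phase: minibatch descent on the summed-KL objective
# against fixed targets. Returns updated params, optimizer state and the
# per-epoch loss vector (sum over all cells seen in the epoch).
.trainPhase <- function(model, X, target, epochs, batchSize, lr,
                        optimizer, state = NULL, weightDecay = 0) {
    params <- model@params
    maskVec <- .maskVec(model)
    k <- nrow(maskMatrix(model)); nH <- model@config$nHeads
    if (optimizer == "adam" && is.null(state)) state <- .adamInit(params)
    losses <- numeric(epochs)
    n <- nrow(X)
    for (e in seq_len(epochs)) {
        idx <- sample.int(n)
        total <- 0
        for (start in seq(1L, n, by = batchSize)) {
            rows <- idx[start:min(start + batchSize - 1L, n)]
            fb <- .cppForwardBackward(X[rows, , drop = FALSE],
                                      target[rows, , drop = FALSE],
                                      params, maskVec, k, nH)
            if (!is.finite(fb$loss))
                stop("NaN/Inf loss in epoch ", e, "; lower the learning ",
                     "rate or check the inputs")
            total <- total + fb$loss
            grads <- lapply(fb$grads, function(g) g / length(rows))
            if (optimizer == "adam") {
                up <- .adamStep(params, grads, state, lr)
                params <- up$params; state <- up$state
            } else {                               # plain gradient descent
                for (nm in names(params))
                    params[[nm]] <- params[[nm]] - lr * grads[[nm]]
            }
            if (weightDecay > 0)                   # decoupled L2 shrinkage
                for (nm in setdiff(names(params), "b"))
                    params[[nm]] <- params[[nm]] * (1 - lr * weightDecay)
        }
        losses[e] <- total
    }
    model@params <- params
    list(model = model, state = state, losses = losses)
}

#' Pretrain the classifier on soft pseudo-labels
#'
#' Minimizes the summed KL divergence between the pseudo-labels and the
#' classifier's output by seeded mini-batch descent. With
#' \code{batchSize >=} number of cells and \code{optimizer = "sgd"} this
#' is full-batch gradient descent, under which the recorded loss is
#' non-increasing for a sufficiently small learning rate. Zero epochs
#' return the model bit-identical.
#'
#' @param model A \linkS4class{PathwayTransformer}.
#' @param x Cells: \linkS4class{SingleCellExperiment} or an aligned cells
#'   x genes matrix from [modelInput()].
#' @param labels A \linkS4class{PseudoLabelMatrix} (rows aligned to the
#'   cells of \code{x}).
#' @param epochs Number of passes over the data (default 200).
#' @param batchSize Mini-batch size (default 256).
#' @param lr Learning rate (default 1e-3).
#' @param optimizer "adam" (default) or "sgd".
#' @param weightDecay Decoupled L2 shrinkage rate per update (default 2):
#'   besides regularizing the fit, it prunes embedding and projection
#'   weights that do not help the objective, which concentrates the
#'   attention keys on informative genes and makes the CLS attention
#'   profiles far more type-discriminative.
#' @param seed Integer seed for the epoch shuffles.
#' @return List: \code{model} (trained), \code{losses} (per-epoch summed
#'   KL).
#' @export
pretrain <- function(model, x, labels, epochs = 200L, batchSize = 256L,
                     lr = 1e-3, optimizer = c("adam", "sgd"),
                     weightDecay = 2, seed = 0L) {
    optimizer <- match.arg(optimizer)
    stopifnot(epochs >= 0L, batchSize >= 1L, lr > 0)
    X <- if (is.matrix(x)) x else modelInput(model, x)
    L <- if (is(labels, "CellTypeScores")) scoreMatrix(labels)
         else as.matrix(labels)
    if (nrow(L) != nrow(X))
        stop("pseudo-label rows must align with cells")
    L <- L[, model@typeNames, drop = FALSE]
    if (epochs == 0L) return(list(model = model, losses = numeric()))
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(.checkSeed(seed))
    ph <- .trainPhase(model, X, L, epochs, batchSize, lr, optimizer,
                      weightDecay = weightDecay)
    list(model = ph$model, losses = ph$losses)
}

#' Refine a pretrained classifier by self-training
#'
#' Round t+1 freezes the model's current full-data predictions Y(t) and
#' trains for a few epochs to minimize KL(Y(t) || Y(t+1)), warm-starting
#' from the current parameters, then recomputes predictions. Rounds stop
#' when the fraction of cells whose argmax label changed falls below
#' \code{delta}, or after \code{maxRounds}. An optional sharpening
#' exponent (> 1 peaks the frozen targets before renormalization) is off
#' by default: targets are the raw predictions.
#'
#' @param model A pretrained \linkS4class{PathwayTransformer}.
#' @param x Cells as in [pretrain()].
#' @param maxRounds Maximum self-training rounds (default 20).
#' @param epochsPerRound Epochs per round (default 5).
#' @param batchSize Mini-batch size (default 256).
#' @param lr Learning rate (default 1e-4, a tenth of the pretraining
#'   default): refinement must converge to a fixed point of the model's
#'   own predictions, and Adam's gradient normalization turns the
#'   vanishing self-consistency gradients into full-size steps unless
#'   the rate is damped.
#' @param delta Convergence threshold on the label-change fraction
#'   (default 0.001).
#' @param weightDecay Decoupled L2 shrinkage rate (default 0). Unlike
#'   pretraining, self-training chases the model's own predictions, so
#'   near the fixed point the gradients vanish while a nonzero decay
#'   would keep eroding the fitted weights round after round.
#' @param sharpen Target sharpening exponent (default 1 = off).
#' @param seed Integer seed.
#' @return List: \code{model}, \code{history} (data.frame: round, epoch,
#'   loss, labelChange), \code{converged} (logical).
#' @export
selfTrain <- function(model, x, maxRounds = 20L, epochsPerRound = 5L,
                      batchSize = 256L, lr = 1e-4, delta = 0.001,
                      weightDecay = 0, sharpen = 1, seed = 0L) {
    stopifnot(maxRounds >= 1L, epochsPerRound >= 1L, delta > 0, delta < 1,
              sharpen > 0)
    X <- if (is.matrix(x)) x else modelInput(model, x)
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(.checkSeed(seed) + 1L)
    hist <- .emptyHistory()
    labels <- .rowArgmax(predictTypes(model, X)$probs)
    converged <- FALSE
    state <- NULL
    for (r in seq_len(maxRounds)) {
        Yt <- predictTypes(model, X)$probs         # frozen targets
        if (sharpen != 1) {
            Yt <- Yt^sharpen
            Yt <- Yt / rowSums(Yt)
        }
        ph <- .trainPhase(model, X, Yt, epochsPerRound, batchSize, lr,
                          "adam", state, weightDecay = weightDecay)
        model <- ph$model; state <- ph$state
        lastLoss <- ph$losses[length(ph$losses)]
        if (lastLoss > 10 * ph$losses[1L] && lastLoss > nrow(X) * 0.01) {
            warning("self-training diverged in round ", r,
                    "; stopping early")
            break
        }
        newLabels <- .rowArgmax(predictTypes(model, X)$probs)
        change <- mean(newLabels != labels)
        labels <- newLabels
        hist <- rbind(hist, data.frame(
            phase = "self-train", round = r,
            epoch = seq_len(epochsPerRound), loss = ph$losses,
            labelChange = c(rep(NA_real_, epochsPerRound - 1L), change)))
        if (change < delta) { converged <- TRUE; break }
    }
    list(model = model, history = hist, converged = converged)
}

# Logistic-regression ablation: multinomial logistic classifier on the
# full log-normalized gene vector, trained on soft targets, optionally
# self-trained by refitting on its own predictions.
.lrAnnotate <- function(expr, L, typeNms, selfTraining, maxRounds, delta) {
    Xf <- t(.logcountsOf(expr))
    df <- as.data.frame(Xf)
    names(df) <- make.names(names(df), unique = TRUE)
    fitOn <- function(target) {
        nnet::multinom(as.matrix(target) ~ ., data = df, trace = FALSE,
                       decay = 1, maxit = 500, MaxNWts = 1e6)
    }
    predProbs <- function(fit) {
        pr <- stats::predict(fit, type = "probs")
        if (is.null(dim(pr))) pr <- cbind(1 - pr, pr)
        pr <- as.matrix(pr)
        colnames(pr) <- typeNms
        rownames(pr) <- rownames(Xf)
        pr
    }
    fit <- fitOn(L)
    probs <- predProbs(fit)
    hist <- data.frame(phase = "pretrain", round = 0L, epoch = 1L,
                       loss = klDivergence(L, probs),
                       labelChange = NA_real_)
    if (selfTraining) {
        labels <- .rowArgmax(probs)
        for (r in seq_len(maxRounds)) {
            target <- probs
            fit <- fitOn(target)
            probs <- predProbs(fit)
            newLabels <- .rowArgmax(probs)
            change <- mean(newLabels != labels)
            labels <- newLabels
            hist <- rbind(hist, data.frame(
                phase = "self-train", round = r, epoch = 1L,
                loss = klDivergence(target, probs), labelChange = change))
            if (change < delta) break
        }
    }
    list(probs = probs, history = hist)
}

#' Annotate cells end to end
#'
#' Runs the full pipeline: relevance scoring from the marker catalog,
#' simplex normalization into soft pseudo-labels, pretraining of the
#' pathway-masked attention classifier on them, and iterative
#' self-training on the classifier's own predictions. Two ablations
#' mirror the framework's component analysis: \code{selfTraining =
#' FALSE} stops after pretraining, and \code{classifier = "lr"} replaces
#' the attention classifier with multinomial logistic regression on the
#' gene vector (which has no attention record).
#'
#' @param expr \linkS4class{SingleCellExperiment} with assay "counts".
#' @param markers \linkS4class{MarkerCatalog}.
#' @param pathways \linkS4class{PathwayCollection} (ignored by the LR
#'   ablation).
#' @param strategy Relevance strategy name (see [scoreRelevance()]).
#' @param embedding Optional \linkS4class{GeneEmbedding} for the
#'   embedding-based strategies.
#' @param pseudoLabels Optional precomputed
#'   \linkS4class{PseudoLabelMatrix}; when given, the relevance stage is
#'   skipped (used e.g. to study corrupted pseudo-labels).
#' @param normMethod,temperature Passed to [normalizeToSimplex()].
#' @param embedDim,nHeads Classifier size (defaults 100 / 4).
#' @param pretrainEpochs,batchSize,lr Pretraining schedule (defaults 200,
#'   256, 1e-3, Adam).
#' @param weightDecay Decoupled L2 shrinkage rate for pretraining
#'   (default 2), see [pretrain()]; self-training runs without decay.
#' @param selfTraining Run the self-training phase (default TRUE).
#' @param maxRounds,epochsPerRound,delta Self-training schedule (defaults
#'   20, 5, 0.001).
#' @param classifier "transformer" (default) or "lr" (ablation).
#' @param keepUnassigned Passed to [buildPathwayMask()].
#' @param seed Integer seed governing every random stage.
#' @return An \linkS4class{AnnotationResult}.
#' @export
annotateCells <- function(expr, markers, pathways,
                          strategy = "cell-type-specific",
                          embedding = NULL, pseudoLabels = NULL,
                          normMethod = "softmax", temperature = 1,
                          embedDim = 100L, nHeads = 4L,
                          pretrainEpochs = 200L, batchSize = 256L,
                          lr = 1e-3, weightDecay = 2, selfTraining = TRUE,
                          maxRounds = 20L, epochsPerRound = 5L,
                          delta = 0.001,
                          classifier = c("transformer", "lr"),
                          keepUnassigned = FALSE, seed = 0L) {
    classifier <- match.arg(classifier)
    expr <- logNormalize(expr)
    if (is.null(pseudoLabels)) {
        R <- scoreRelevance(expr, markers, strategy, embedding, seed = seed)
        pseudoLabels <- normalizeToSimplex(R, normMethod, temperature)
    }
    typeNms <- typeNames(markers)
    L <- scoreMatrix(pseudoLabels)[, typeNms, drop = FALSE]

    prov <- list(strategy = strategy, normMethod = normMethod,
                 temperature = temperature, classifier = classifier,
                 seed = as.integer(seed),
                 selfTraining = selfTraining)

    if (classifier == "lr") {
        lrRes <- .lrAnnotate(expr, L, typeNms, selfTraining, maxRounds,
                             delta)
        probs <- lrRes$probs
        hist <- lrRes$history
        attn <- matrix(numeric(), 0L, 0L)
    } else {
        mask <- buildPathwayMask(pathways, rownames(expr),
                                 keepUnassigned = keepUnassigned)
        model <- PathwayTransformer(mask, typeNms, embedDim = embedDim,
                                    nHeads = nHeads, seed = seed)
        X <- modelInput(model, expr)
        pt <- pretrain(model, X, L, epochs = pretrainEpochs,
                       batchSize = batchSize, lr = lr,
                       weightDecay = weightDecay, seed = seed)
        model <- pt$model
        hist <- if (length(pt$losses))
            data.frame(phase = "pretrain", round = 0L,
                       epoch = seq_along(pt$losses), loss = pt$losses,
                       labelChange = NA_real_)
        else .emptyHistory()
        if (selfTraining) {
            st <- selfTrain(model, X, maxRounds = maxRounds,
                            epochsPerRound = epochsPerRound,
                            batchSize = batchSize, lr = lr / 10,
                            delta = delta, seed = seed)
            model <- st$model
            hist <- rbind(hist, st$history)
            prov$converged <- st$converged
        }
        fwd <- predictTypes(model, X, attention = TRUE)
        probs <- fwd$probs
        attn <- fwd$attention
        prov$model <- model
    }
    pred <- typeNms[.rowArgmax(probs)]
    new("AnnotationResult", predictedType = pred, probabilities = probs,
        history = hist, attention = attn, provenance = prov)
}
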