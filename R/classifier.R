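# Stacked-autoencoder classification stage.
#
# Stage 1 (one per descriptor): three hidden autoencoder layers, each
# shrinking its input to two thirds (ceil(2 d / 3), width floor 2),
# greedily pretrained on the reconstruction objective and then
# fine-tuned end-to-end with a two-class softmax head. Stage 2 fuses the
# six per-descriptor malignancy probabilities through a single hidden
# autoencoder (width 4) plus softmax. Plain (non-denoising) autoencoders
# with sigmoid activations, MSE pretraining loss, cross-entropy
# fine-tuning loss and full-batch Adam; everything is deterministic
# given (data, config, seed). Malignant is the positive class.

sigmoid <- function(z) 1 / (1 + exp(-z))

adamInit <- function(shapes) {
  lapply(shapes, function(s) list(m = array(0, s), v = array(0, s)))
}

adamStep <- function(par, grad, state, t, lr, b1 = 0.9, b2 = 0.999,
                     eps = 1e-8) {
  state$m <- b1 * state$m + (1 - b1) * grad
  state$v <- b2 * state$v + (1 - b2) * grad^2
  mhat <- state$m / (1 - b1^t)
  vhat <- state$v / (1 - b2^t)
  list(par = par - lr * mhat / (sqrt(vhat) + eps), state = state)
}

glorot <- function(nin, nout) {
  r <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -r, r), nin, nout)
}

# One autoencoder layer trained on reconstruction MSE; returns encoder
# weights and the encoded data.
trainAutoencoderLayer <- function(X, h, epochs, lr) {
  d <- ncol(X); n <- nrow(X)
  W1 <- glorot(d, h); b1 <- rep(0, h)
  W2 <- glorot(h, d); b2 <- rep(0, d)
  st <- adamInit(list(dim(W1), length(b1), dim(W2), length(b2)))
  for (t in seq_len(epochs)) {
    H <- sigmoid(sweep(X %*% W1, 2, b1, `+`))
    Xh <- sigmoid(sweep(H %*% W2, 2, b2, `+`))
    dXh <- 2 * (Xh - X) / (n * d) * Xh * (1 - Xh)
    gW2 <- crossprod(H, dXh); gb2 <- colSums(dXh)
    dH <- tcrossprod(dXh, W2) * H * (1 - H)
    gW1 <- crossprod(X, dH); gb1 <- colSums(dH)
    u <- adamStep(W1, gW1, st[[1]], t, lr); W1 <- u$par; st[[1]] <- u$state
    u <- adamStep(b1, gb1, st[[2]], t, lr); b1 <- u$par; st[[2]] <- u$state
    u <- adamStep(W2, gW2, st[[3]], t, lr); W2 <- u$par; st[[3]] <- u$state
    u <- adamStep(b2, gb2, st[[4]], t, lr); b2 <- u$par; st[[4]] <- u$state
  }
  H <- sigmoid(sweep(X %*% W1, 2, b1, `+`))
  list(W = W1, b = b1, H = H)
}

# Supervised fine-tuning of the encoder stack + softmax head.
fineTuneStack <- function(X, y01, Ws, bs, epochs, lr) {
  n <- nrow(X); K <- length(Ws)
  hK <- length(bs[[K]])
  Wsm <- glorot(hK, 2); bsm <- rep(0, 2)
  Y <- cbind(1 - y01, y01)
  shapes <- c(unlist(lapply(Ws, function(w) list(dim(w))), recursive = FALSE),
              lapply(bs, length), list(dim(Wsm)), list(length(bsm)))
  st <- adamInit(shapes)
  for (t in seq_len(epochs)) {
    A <- vector("list", K + 1); A[[1]] <- X
    for (k in seq_len(K))
      A[[k + 1]] <- sigmoid(sweep(A[[k]] %*% Ws[[k]], 2, bs[[k]], `+`))
    Z <- sweep(A[[K + 1]] %*% Wsm, 2, bsm, `+`)
    Z <- Z - matrixStats::rowMaxs(Z)
    P <- exp(Z); P <- P / rowSums(P)
    dZ <- (P - Y) / n
    gWsm <- crossprod(A[[K + 1]], dZ); gbsm <- colSums(dZ)
    dA <- tcrossprod(dZ, Wsm)
    gW <- vector("list", K); gb <- vector("list", K)
    for (k in rev(seq_len(K))) {
      dZk <- dA * A[[k + 1]] * (1 - A[[k + 1]])
      gW[[k]] <- crossprod(A[[k]], dZk)
      gb[[k]] <- colSums(dZk)
      if (k > 1) dA <- tcrossprod(dZk, Ws[[k]])
    }
    s <- 1
    for (k in seq_len(K)) {
      u <- adamStep(Ws[[k]], gW[[k]], st[[s]], t, lr)
      Ws[[k]] <- u$par; st[[s]] <- u$state; s <- s + 1
    }
    for (k in seq_len(K)) {
      u <- adamStep(bs[[k]], gb[[k]], st[[s]], t, lr)
      bs[[k]] <- u$par; st[[s]] <- u$state; s <- s + 1
    }
    u <- adamStep(Wsm, gWsm, st[[s]], t, lr); Wsm <- u$par; st[[s]] <- u$state
    u <- adamStep(bsm, gbsm, st[[s + 1]], t, lr); bsm <- u$par
    st[[s + 1]] <- u$state
  }
  list(Ws = Ws, bs = bs, Wsm = Wsm, bsm = bsm)
}

#' Stacked-autoencoder architecture for one descriptor
#'
#' Three hidden layers, each reducing its input dimensionality by one
#' third (`ceil(2 d / 3)`, width floor 2); the last hidden layer feeds a
#' two-class softmax.
#'
#' @param inputDim descriptor length (>= 3).
#' @param seed training seed.
#' @param epochs pretraining and fine-tuning epochs (default 100 each;
#'   full-batch Adam at this rate plateaus well before that).
#' @param lr Adam learning rate (default 0.01).
#' @param nLayers number of hidden layers (default 3; the fusion stage
#'   uses 1).
#' @param layerDims optional explicit layer widths overriding the
#'   two-thirds rule.
#' @return A config list with `inputDim`, `layerDims`, `epochs`, `lr`,
#'   `seed`.
#' @export
buildStackedSAE <- function(inputDim, seed = 1, epochs = 100, lr = 0.01,
                            nLayers = 3, layerDims = NULL) {
  stopIfNot(inputDim >= 3, "inputDim must be >= 3")
  if (is.null(layerDims)) {
    d <- inputDim
    layerDims <- integer(nLayers)
    for (k in seq_len(nLayers)) {
      d <- max(2L, as.integer(ceiling(2 * d / 3)))
      layerDims[k] <- d
    }
  }
  list(inputDim = as.integer(inputDim), layerDims = as.integer(layerDims),
       epochs = as.integer(epochs), lr = lr, seed = as.integer(seed))
}

#' Train a per-descriptor stacked-autoencoder classifier
#'
#' Features are min-max scaled to `[0, 1]` (constant columns map to 0.5)
#' using the training ranges; the autoencoder layers are pretrained
#' greedily on the reconstruction objective and the whole stack is then
#' fine-tuned with the softmax head. Returns the model and the training
#' malignancy probabilities.
#'
#' @param features numeric matrix, samples x descriptor entries.
#' @param labels `"benign"` / `"malignant"` per sample (character or
#'   factor).
#' @param config from [buildStackedSAE()]; defaults are built from the
#'   feature dimension when `NULL`.
#' @return List with `model` and `prob` (training probabilities).
#' @export
trainDescriptorClassifier <- function(features, labels, config = NULL) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  stopIfNot(all(labels %in% c("benign", "malignant")),
            "labels must be benign/malignant")
  if (length(unique(labels)) < 2)
    stop("training set must contain both classes", call. = FALSE)
  stopIfNot(min(table(labels)) >= 2, "need >= 2 samples per class")
  if (is.null(config)) config <- buildStackedSAE(ncol(features))
  lo <- matrixStats::colMins(features)
  hi <- matrixStats::colMaxs(features)
  rngW <- hi - lo
  X <- scaleFeatures(features, lo, rngW)
  y01 <- as.numeric(labels == "malignant")
  model <- withSeed(config$seed, {
    Ws <- list(); bs <- list()
    H <- X
    for (h in config$layerDims) {
      lay <- trainAutoencoderLayer(H, h, config$epochs, config$lr)
      Ws <- c(Ws, list(lay$W)); bs <- c(bs, list(lay$b))
      H <- lay$H
    }
    ft <- fineTuneStack(X, y01, Ws, bs, config$epochs, config$lr)
    c(ft, list(lo = lo, rng = rngW, config = config))
  })
  class(model) <- "saeClassifier"
  list(model = model, prob = predictProb(model, features))
}

scaleFeatures <- function(features, lo, rng) {
  X <- sweep(features, 2, lo)
  X <- sweep(X, 2, pmax(rng, 1e-12), `/`)
  X[, rng <= 0] <- 0.5
  pmin(pmax(X, 0), 1)
}

#' Malignancy probability from a trained classifier
#'
#' @param model a model from [trainDescriptorClassifier()] or
#'   [fuseProbabilities()].
#' @param features matrix on the same descriptor (or probability) space.
#' @return Numeric vector of malignancy probabilities in `[0, 1]`.
#' @export
predictProb <- function(model, features) {
  X <- scaleFeatures(as.matrix(features), model$lo, model$rng)
  for (k in seq_along(model$Ws))
    X <- sigmoid(sweep(X %*% model$Ws[[k]], 2, model$bs[[k]], `+`))
  Z <- sweep(X %*% model$Wsm, 2, model$bsm, `+`)
  Z <- Z - matrixStats::rowMaxs(Z)
  P <- exp(Z); P <- P / rowSums(P)
  as.numeric(P[, 2])
}

#' Fuse per-descriptor probabilities into the final diagnosis
#'
#' One hidden autoencoder layer (default width 4) over the stage-1
#' probability vector, pretrained then fine-tuned with the softmax head.
#'
#' @param probMatrix samples x descriptors matrix of stage-1 malignancy
#'   probabilities (default contract: 6 columns; other widths are
#'   accepted when descriptors are disabled).
#' @param labels per-sample class labels.
#' @param seed training seed.
#' @param hidden hidden width (default 4).
#' @param epochs,lr training parameters (defaults 100, 0.01).
#' @return List with `model` and `prob` (training fused probabilities).
#' @export
fuseProbabilities <- function(probMatrix, labels, seed = 1, hidden = 4,
                              epochs = 100, lr = 0.01) {
  probMatrix <- as.matrix(probMatrix)
  stopIfNot(all(probMatrix >= 0 & probMatrix <= 1),
            "probabilities must lie in [0, 1]")
  cfg <- buildStackedSAE(max(ncol(probMatrix), 3), seed = seed,
                         epochs = epochs, lr = lr, nLayers = 1,
                         layerDims = hidden)
  cfg$inputDim <- ncol(probMatrix)
  trainDescriptorClassifier(probMatrix, labels, cfg)
}

#' Classification metrics at a decision threshold
#'
#' Accuracy, sensitivity, specificity and precision (percent) from the
#' confusion matrix at `threshold`, and the trapezoidal ROC AUC over all
#' thresholds. Malignant is the positive class.
#'
#' @param prob malignancy probabilities.
#' @param labels `"benign"` / `"malignant"` per sample.
#' @param threshold decision threshold (default 0.5).
#' @return An [EvalReport-class].
#' @export
evaluateClassifier <- function(prob, labels, threshold = 0.5) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2)
    stop("evaluation needs both classes", call. = FALSE)
  pos <- labels == "malignant"
  pred <- prob >= threshold
  TP <- sum(pred & pos); FP <- sum(pred & !pos)
  TN <- sum(!pred & !pos); FN <- sum(!pred & pos)
  auc <- as.numeric(pROC::auc(pROC::roc(
    response = factor(labels, levels = c("benign", "malignant")),
    predictor = prob, direction = "<", quiet = TRUE)))
  methods::new("EvalReport",
    confusion = c(TP = TP, FP = FP, TN = TN, FN = FN),
    accuracy = 100 * (TP + TN) / length(labels),
    sensitivity = 100 * TP / (TP + FN),
    specificity = 100 * TN / (TN + FP),
    precision = if (TP + FP > 0) 100 * TP / (TP + FP) else NaN,
    auc = auc)
}

#' Stratified train/test split
#'
#' Seeded stratified random split preserving the class proportions
#' within one sample.
#'
#' @param labels per-sample class labels.
#' @param trainFrac training fraction (default 0.70).
#' @param seed split seed.
#' @return List of integer index vectors `train` and `test`.
#' @export
splitTrainTest <- function(labels, trainFrac = 0.70, seed = 1) {
  labels <- as.character(labels)
  stopIfNot(length(labels) >= 2, "need >= 2 records")
  withSeed(seed, {
    train <- integer(0)
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      nTr <- round(trainFrac * length(idx))
      train <- c(train, sample(idx, nTr))
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(labels), train))
  })
}
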