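# Student architectures and training. All nets map a per-residue
# embedding (length d) to the 20 substitution scores of that residue:
#   linreg  d -> 20                       (no hidden layer)
#   fnn1    d -> h -> 20                  (reference: d=2560, h=256)
#   fnn2    d -> h1 -> h2 -> 20
#   cnn     1-D convolution (channels C, kernel k, same padding) over
#           the residue axis, then two dense hidden layers -> 20
# Hidden layers use LeakyReLU (slope 0.01 by default); the output layer
# has no activation. The convolution is realized as a dense layer on
# im2col features (each residue's window of k neighbouring embedding
# rows, zero-padded at the termini), which makes every architecture a
# dense stack and lets one backpropagation path serve all of them.
# Training minimizes the masked mean squared error against teacher
# landscapes with Adam, early-stopping on validation loss.

ARCHITECTURES <- c("linreg", "fnn1", "fnn2", "cnn")

#' ModelConfig: student architecture description
#'
#' @slot architecture one of linreg, fnn1, fnn2, cnn
#' @slot inputDim embedding width d
#' @slot hiddenSizes dense hidden layer sizes (none for linreg, one for
#'   fnn1, two for fnn2 and cnn)
#' @slot convChannels,convKernel 1-D convolution spec (cnn only; 0
#'   otherwise)
#' @slot outputDim number of outputs per residue (20)
#' @slot activation hidden nonlinearity name ("leaky_relu")
#' @slot leakySlope negative-side slope of the LeakyReLU
#' @slot seed initialization seed
#' @aliases ModelConfig-class
#' @export
setClass("ModelConfig",
  representation(architecture = "character", inputDim = "integer",
                 hiddenSizes = "integer", convChannels = "integer",
                 convKernel = "integer", outputDim = "integer",
                 activation = "character", leakySlope = "numeric",
                 seed = "integer"))

setValidity("ModelConfig", function(object) {
  if (!(object@architecture %in% ARCHITECTURES))
    return(paste("architecture must be one of:",
                 paste(ARCHITECTURES, collapse = ", ")))
  if (object@inputDim < 1L) return("inputDim must be positive")
  if (object@outputDim != 20L)
    return("outputDim must be 20 (one score per amino acid)")
  nh <- length(object@hiddenSizes)
  want <- switch(object@architecture, linreg = 0L, fnn1 = 1L, fnn2 = 2L,
                 cnn = 2L)
  if (nh != want)
    return(sprintf("%s requires exactly %d hidden size(s); got %d",
                   object@architecture, want, nh))
  if (nh && any(object@hiddenSizes < 1L))
    return("hidden sizes must be positive")
  if (object@architecture == "cnn" &&
      (object@convChannels < 1L || object@convKernel < 1L ||
       object@convKernel %% 2L == 0L))
    return("cnn needs convChannels >= 1 and an odd convKernel >= 1")
  if (object@activation != "leaky_relu")
    return("only the leaky_relu hidden activation is implemented")
  TRUE
})

#' Construct a ModelConfig
#'
#' Defaults follow the reference student: a one-hidden-layer
#' feed-forward net (`fnn1`) with 256 hidden units on d = 2560
#' embeddings and a 20-dimensional linear output.
#'
#' @param architecture one of "linreg", "fnn1", "fnn2", "cnn"
#' @param inputDim embedding width d (default 2560)
#' @param hiddenSizes hidden layer sizes; per-architecture defaults are
#'   256 (fnn1) and c(256, 64) (fnn2, cnn)
#' @param convChannels,convKernel cnn convolution spec (defaults 256
#'   channels, kernel 7, same padding)
#' @param outputDim output width (20)
#' @param leakySlope LeakyReLU negative slope (0.01)
#' @param seed initialization seed
#' @return A [ModelConfig-class].
#' @examples
#' modelConfig()                       # the reference architecture
#' modelConfig("linreg", inputDim = 64)
#' @export
modelConfig <- function(architecture = c("fnn1", "linreg", "fnn2", "cnn"),
                        inputDim = 2560, hiddenSizes = NULL,
                        convChannels = 256, convKernel = 7,
                        outputDim = 20, leakySlope = 0.01, seed = 0) {
  architecture <- match.arg(architecture)
  if (is.null(hiddenSizes))
    hiddenSizes <- switch(architecture, linreg = integer(0), fnn1 = 256L,
                          fnn2 = c(256L, 64L), cnn = c(256L, 64L))
  if (architecture != "cnn") convChannels <- convKernel <- 0L
  new("ModelConfig", architecture = architecture,
      inputDim = as.integer(inputDim),
      hiddenSizes = as.integer(hiddenSizes),
      convChannels = as.integer(convChannels),
      convKernel = as.integer(convKernel),
      outputDim = as.integer(outputDim), activation = "leaky_relu",
      leakySlope = leakySlope, seed = as.integer(seed))
}

setMethod("show", "ModelConfig", function(object) {
  cat(sprintf("ModelConfig %s: d=%d, hidden=(%s)%s, out=%d\n",
              object@architecture, object@inputDim,
              paste(object@hiddenSizes, collapse = ","),
              if (object@architecture == "cnn")
                sprintf(", conv %dch k=%d", object@convChannels,
                        object@convKernel) else "",
              object@outputDim))
})

#' StudentModel: a configured network with its weights
#'
#' @slot config the [ModelConfig-class]
#' @slot layers list of dense layers, each a list with matrices `W`
#'   (in x out) and bias `b`
#' @aliases StudentModel-class
#' @export
setClass("StudentModel",
  representation(config = "ModelConfig", layers = "list"))

#' @describeIn StudentModel the model's configuration
#' @param x,object a StudentModel
#' @export
setGeneric("modelConfigOf", function(x) standardGeneric("modelConfigOf"))

#' @export
setMethod("modelConfigOf", "StudentModel", function(x) x@config)

setMethod("show", "StudentModel", function(object) {
  cat(sprintf("StudentModel [%s]: %s parameters\n",
              object@config@architecture,
              format(countParameters(object), big.mark = ",")))
})

# dense layer sizes (in, out) implied by a config; for cnn the first
# dense layer consumes the im2col window of k embedding rows
layerDims <- function(config) {
  sizes <- switch(config@architecture,
    linreg = c(config@inputDim, config@outputDim),
    fnn1 = ,
    fnn2 = c(config@inputDim, config@hiddenSizes, config@outputDim),
    cnn = c(config@inputDim * config@convKernel, config@convChannels,
            config@hiddenSizes, config@outputDim))
  cbind(utils::head(sizes, -1L), sizes[-1L])
}

#' Build an untrained student model
#'
#' Weights are initialized with seeded He-style Gaussian draws
#' (sd = sqrt(2 / fan_in)); biases start at zero, so rebuilding with
#' the same config gives identical initial weights.
#'
#' @param config a [ModelConfig-class]
#' @return A [StudentModel-class].
#' @export
buildModel <- function(config) {
  stopifnot(is(config, "ModelConfig"))
  validObject(config)
  dims <- layerDims(config)
  layers <- withSeed(config@seed, {
    lapply(seq_len(nrow(dims)), function(i) {
      nin <- dims[i, 1]; nout <- dims[i, 2]
      list(W = matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)),
                      nin, nout),
           b = numeric(nout))
    })
  })
  new("StudentModel", config = config, layers = layers)
}

#' Count trainable parameters
#'
#' Sum over affine layers of `in * out + out` (weights plus biases).
#' The reference architecture (d = 2560, one hidden layer of 256, 20
#' outputs) has 2560*256 + 256 + 256*20 + 20 = 660,756 parameters.
#'
#' @param x a [StudentModel-class] or [ModelConfig-class]
#' @return Integer parameter count.
#' @export
countParameters <- function(x) {
  config <- if (is(x, "StudentModel")) x@config else x
  stopifnot(is(config, "ModelConfig"))
  dims <- layerDims(config)
  sum(dims[, 1] * dims[, 2] + dims[, 2])
}

leaky <- function(z, slope) ifelse(z > 0, z, slope * z)
leakyGrad <- function(z, slope) ifelse(z > 0, 1, slope)

# im2col for the 1-D convolution: row i holds the concatenated
# embedding rows of the window centered at residue i (zero-padded)
im2col <- function(X, k) {
  L <- nrow(X); d <- ncol(X); half <- (k - 1L) %/% 2L
  out <- matrix(0, L, d * k)
  for (j in seq_len(k)) {
    shift <- j - 1L - half
    src <- seq_len(L) + shift
    ok <- src >= 1L & src <= L
    out[ok, ((j - 1L) * d + 1L):(j * d)] <- X[src[ok], , drop = FALSE]
  }
  out
}

# features consumed by the dense stack (identity except for cnn)
modelFeatures <- function(config, X) {
  if (config@architecture == "cnn") im2col(X, config@convKernel) else X
}

# forward through the dense stack; returns activations when requested
denseForward <- function(layers, X, slope, keep = FALSE) {
  nl <- length(layers)
  A <- X
  acts <- if (keep) vector("list", nl + 1L)
  if (keep) acts[[1L]] <- A
  zs <- if (keep) vector("list", nl)
  for (i in seq_len(nl)) {
    Z <- A %*% layers[[i]]$W +
      matrix(layers[[i]]$b, nrow(A), length(layers[[i]]$b), byrow = TRUE)
    A <- if (i < nl) leaky(Z, slope) else Z
    if (keep) { zs[[i]] <- Z; acts[[i + 1L]] <- A }
  }
  if (keep) list(out = A, acts = acts, zs = zs) else A
}

#' Masked mean squared error
#'
#' Mean of squared prediction errors over unmasked (defined) cells
#' only; masked cells contribute to neither numerator nor denominator.
#'
#' @param pred,target numeric matrices of identical shape
#' @param maskM logical matrix, TRUE = include the cell
#' @return Numeric scalar loss.
#' @export
maskedMSE <- function(pred, target, maskM) {
  if (!identical(dim(pred), dim(target)) ||
      !identical(dim(pred), dim(maskM)))
    stopf("pred, target and mask must have identical shapes")
  n <- sum(maskM)
  if (n == 0L) stopf("masked MSE undefined: no unmasked cells")
  d <- (pred - target)[maskM]
  mean(d * d)
}

#' TrainConfig: optimization settings
#'
#' @slot optimizer optimizer name ("adam")
#' @slot learningRate Adam step size
#' @slot batchSize residues per minibatch
#' @slot maxEpochs maximum training epochs
#' @slot patience early-stopping patience (epochs without validation
#'   improvement)
#' @slot lrDecayEvery halve the learning rate every this many epochs
#'   (0 = constant rate)
#' @slot weightDecay decoupled L2 weight decay per step (0 = off)
#' @slot seed shuffling seed
#' @aliases TrainConfig-class
#' @export
setClass("TrainConfig",
  representation(optimizer = "character", learningRate = "numeric",
                 batchSize = "integer", maxEpochs = "integer",
                 patience = "integer", lrDecayEvery = "integer",
                 weightDecay = "numeric", seed = "integer"))

setValidity("TrainConfig", function(object) {
  if (object@optimizer != "adam") return("only the adam optimizer is implemented")
  if (object@learningRate <= 0 || object@batchSize < 1L ||
      object@maxEpochs < 1L || object@patience < 1L)
    return("learningRate, batchSize, maxEpochs and patience must be positive")
  if (object@lrDecayEvery < 0L)
    return("lrDecayEvery must be 0 (constant) or positive")
  if (object@weightDecay < 0)
    return("weightDecay must be >= 0")
  TRUE
})

#' Construct a TrainConfig
#'
#' The loss is fixed to the masked mean squared error against teacher
#' landscapes; undefined teacher cells (NA and wild-type self-cells)
#' are excluded from numerator and denominator alike.
#'
#' @param learningRate Adam step size (default 1e-4)
#' @param batchSize residues per minibatch (default 1024)
#' @param maxEpochs epoch cap (default 200)
#' @param patience early-stopping patience in epochs (default 10)
#' @param lrDecayEvery halve the learning rate every this many epochs;
#'   0 (default) keeps it constant. Step decay shrinks the optimizer's
#'   stationary noise so late epochs refine rather than oscillate.
#' @param weightDecay decoupled (AdamW-style) L2 weight decay applied
#'   to weight matrices each step; 0 (default) disables it. Decay
#'   limits how much a high-capacity student can fit observation noise
#'   in the teacher scores.
#' @param seed shuffling seed
#' @return A [TrainConfig-class].
#' @export
trainConfig <- function(learningRate = 1e-4, batchSize = 1024,
                        maxEpochs = 200, patience = 10,
                        lrDecayEvery = 0, weightDecay = 0, seed = 0) {
  new("TrainConfig", optimizer = "adam", learningRate = learningRate,
      batchSize = as.integer(batchSize), maxEpochs = as.integer(maxEpochs),
      patience = as.integer(patience),
      lrDecayEvery = as.integer(lrDecayEvery),
      weightDecay = weightDecay, seed = as.integer(seed))
}

# pool samples into feature/target/mask matrices for the dense stack
poolSamples <- function(config, samples) {
  X <- do.call(rbind, lapply(samples, function(s)
    modelFeatures(config, s$embedding)))
  Y <- do.call(rbind, lapply(samples, function(s) {
    t <- s$target; t[!s$mask] <- 0; t
  }))
  M <- do.call(rbind, lapply(samples, function(s) s$mask))
  list(X = X, Y = Y, M = M)
}

#' Train a student model
#'
#' Minibatch Adam on the masked MSE, with per-epoch training and
#' validation losses recorded and the best-validation weights restored
#' at the end. Runs are deterministic for a fixed seed.
#'
#' @param model an untrained (or warm) [StudentModel-class]
#' @param samples list of training samples from [assembleDataset()]
#' @param tc a [TrainConfig-class]
#' @param valSamples validation samples (same structure)
#' @param verbose print per-epoch losses
#' @return List with elements `model` (best weights) and `history`
#'   (data.frame epoch, train_loss, val_loss).
#' @export
trainStudent <- function(model, samples, tc = trainConfig(),
                         valSamples, verbose = FALSE) {
  stopifnot(is(model, "StudentModel"), is(tc, "TrainConfig"))
  if (!length(samples) || !length(valSamples))
    stopf("need non-empty training and validation sample lists")
  config <- model@config
  d <- ncol(samples[[1]]$embedding)
  if (d != config@inputDim)
    stopf("embedding width %d does not match model inputDim %d", d,
          config@inputDim)
  tr <- poolSamples(config, samples)
  va <- poolSamples(config, valSamples)
  layers <- model@layers
  slope <- config@leakySlope
  nl <- length(layers)
  adamM <- lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))
  adamV <- adamM
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  n <- nrow(tr$X)

  evalLoss <- function(ls, pooled)
    maskedMSE(denseForward(ls, pooled$X, slope), pooled$Y, pooled$M)

  bestVal <- Inf; bestLayers <- layers; bad <- 0L
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  withSeed(tc@seed, {
    for (epoch in seq_len(tc@maxEpochs)) {
      lrNow <- if (tc@lrDecayEvery > 0L)
        tc@learningRate * 0.5^((epoch - 1L) %/% tc@lrDecayEvery)
      else tc@learningRate
      ord <- sample.int(n)
      for (start in seq(1L, n, by = tc@batchSize)) {
        idx <- ord[start:min(start + tc@batchSize - 1L, n)]
        X <- tr$X[idx, , drop = FALSE]
        Y <- tr$Y[idx, , drop = FALSE]
        M <- tr$M[idx, , drop = FALSE]
        nm <- sum(M)
        if (nm == 0L) next
        fw <- denseForward(layers, X, slope, keep = TRUE)
        G <- 2 * (fw$out - Y) * M / nm
        step <- step + 1L
        for (i in rev(seq_len(nl))) {
          dW <- crossprod(fw$acts[[i]], G)
          db <- colSums(G)
          if (i > 1L)
            G <- (G %*% t(layers[[i]]$W)) *
              leakyGrad(fw$zs[[i - 1L]], slope)
          for (nm2 in c("W", "b")) {
            g <- if (nm2 == "W") dW else db
            adamM[[i]][[nm2]] <- beta1 * adamM[[i]][[nm2]] + (1 - beta1) * g
            adamV[[i]][[nm2]] <- beta2 * adamV[[i]][[nm2]] +
              (1 - beta2) * g * g
            mhat <- adamM[[i]][[nm2]] / (1 - beta1^step)
            vhat <- adamV[[i]][[nm2]] / (1 - beta2^step)
            layers[[i]][[nm2]] <- layers[[i]][[nm2]] -
              lrNow * mhat / (sqrt(vhat) + eps)
            if (nm2 == "W" && tc@weightDecay > 0)
              layers[[i]][[nm2]] <- layers[[i]][[nm2]] *
                (1 - lrNow * tc@weightDecay)
          }
        }
      }
      trLoss <- evalLoss(layers, tr)
      vaLoss <- evalLoss(layers, va)
      if (!is.finite(trLoss) || !is.finite(vaLoss))
        stopf("training diverged (non-finite loss) at epoch %d", epoch)
      history[epoch, ] <- list(epoch, trLoss, vaLoss)
      if (verbose)
        message(sprintf("epoch %3d  train %.6g  val %.6g", epoch, trLoss,
                        vaLoss))
      if (vaLoss < bestVal - 1e-12) {
        bestVal <- vaLoss; bestLayers <- layers; bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= tc@patience) break
      }
    }
  })
  list(model = new("StudentModel", config = config, layers = bestLayers),
       history = history)
}

#' Predict a protein's mutational landscape
#'
#' Runs the student on an embedding matrix and masks the wild-type
#' self-substitution cells using the protein sequence. No alignments or
#' external resources are used at inference time.
#'
#' @param model a [StudentModel-class]
#' @param emb an [EmbeddingMatrix-class] with `d == inputDim`
#' @param protein the matching [ProteinRecord-class] (supplies the
#'   sequence for self-cell masking)
#' @return A [Landscape-class] with role `predicted_raw`.
#' @export
predictLandscape <- function(model, emb, protein) {
  stopifnot(is(model, "StudentModel"), is(emb, "EmbeddingMatrix"),
            is(protein, "ProteinRecord"))
  if (embeddingDim(emb) != model@config@inputDim)
    stopf("embedding width %d does not match model inputDim %d",
          embeddingDim(emb), model@config@inputDim)
  if (seqLength(protein) != nrow(emb@values))
    stopf("sequence length %d does not match embedding rows %d for '%s'",
          seqLength(protein), nrow(emb@values), proteinId(protein))
  X <- modelFeatures(model@config, emb@values)
  pred <- denseForward(model@layers, X, model@config@leakySlope)
  Landscape(proteinId(protein), pred, role = "predicted_raw",
            sequence = proteinSeq(protein))
}

#' Ensemble prediction: mean of two student networks
#'
#' Cell-wise arithmetic mean of the raw landscapes of two separately
#' trained models (typically the feed-forward and convolutional
#' students).
#'
#' @param modelA,modelB trained [StudentModel-class] objects sharing
#'   `inputDim`
#' @param emb an [EmbeddingMatrix-class]
#' @param protein the matching [ProteinRecord-class]
#' @return A [Landscape-class] with role `predicted_raw`.
#' @export
ensemblePredict <- function(modelA, modelB, emb, protein) {
  if (modelA@config@inputDim != modelB@config@inputDim)
    stopf("ensemble members must share inputDim")
  a <- predictLandscape(modelA, emb, protein)
  b <- predictLandscape(modelB, emb, protein)
  sc <- (a@scores + b@scores) / 2
  sc[!a@mask] <- NA_real_
  new("Landscape", proteinId = a@proteinId, scores = sc, mask = a@mask,
      role = "predicted_raw")
}
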