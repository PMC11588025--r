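# Student architectures: construction, parameter accounting, masked
# loss, training behavior, inference.

test_that("buildModel produces seeded models with the right shapes", {
  cfg <- modelConfig()  # reference: fnn1, d = 2560, hidden 256
  m <- buildModel(cfg)
  set.seed(1)
  emb <- EmbeddingMatrix("ref", matrix(rnorm(5 * 2560), 5, 2560))
  rec <- ProteinRecord("ref", "MKVLA")
  ls <- predictLandscape(m, emb, rec)
  expect_equal(dim(scores(ls)), c(5L, 20L))
  expect_equal(sum(!mask(ls)), 5L)  # one self cell per residue

  # same seed -> identical initial weights
  m2 <- buildModel(modelConfig())
  expect_identical(m@layers, m2@layers)

  expect_error(modelConfig("fnn1", hiddenSizes = c(8L, 8L)), "exactly")
  expect_error(modelConfig("cnn", convKernel = 4), "odd")
})

test_that("linreg forward is affine", {
  m <- buildModel(modelConfig("linreg", inputDim = 4, seed = 3))
  rec <- ProteinRecord("t", "MKV")
  fwd <- function(X) scores(predictLandscape(
    m, EmbeddingMatrix("t", X), rec))
  set.seed(2)
  x <- matrix(rnorm(12), 3, 4); y <- matrix(rnorm(12), 3, 4)
  z <- matrix(0, 3, 4)
  lhs <- fwd(2 * x + 3 * y) - fwd(z)
  rhs <- (fwd(x) - fwd(z)) * 2 + (fwd(y) - fwd(z)) * 3
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("countParameters matches the closed-form layer sums", {
  expect_equal(countParameters(modelConfig("linreg", inputDim = 4,
                                           outputDim = 20)),
               4 * 20 + 20)
  # reference architecture: 2560*256 + 256 + 256*20 + 20
  expect_equal(countParameters(modelConfig()), 660756)
  expect_equal(countParameters(modelConfig("fnn2", inputDim = 8,
                                           hiddenSizes = c(4L, 3L))),
               8 * 4 + 4 + 4 * 3 + 3 + 3 * 20 + 20)
  # property: random dense configs vs an explicit loop
  set.seed(8)
  for (i in 1:10) {
    d <- sample(4:64, 1)
    h <- sample(2:32, 2)
    cfg <- modelConfig("fnn2", inputDim = d, hiddenSizes = h)
    sizes <- c(d, h, 20)
    manual <- 0
    for (j in seq_len(length(sizes) - 1))
      manual <- manual + sizes[j] * sizes[j + 1] + sizes[j + 1]
    expect_equal(countParameters(cfg), manual)
  }
  # cnn: conv as dense on the k-window + dense stack
  cfg <- modelConfig("cnn", inputDim = 8, hiddenSizes = c(4L, 3L),
                     convChannels = 6, convKernel = 3)
  expect_equal(countParameters(cfg),
               (8 * 3) * 6 + 6 + 6 * 4 + 4 + 4 * 3 + 3 + 3 * 20 + 20)
})

test_that("masked MSE ignores masked cells entirely", {
  a <- matrix(1:6, 2, 3) * 1.0
  expect_equal(maskedMSE(a, a, matrix(TRUE, 2, 3)), 0)

  pred <- matrix(0, 2, 3); target <- matrix(0, 2, 3)
  m <- matrix(FALSE, 2, 3); m[1, 1] <- m[2, 2] <- TRUE
  pred[1, 1] <- 1; pred[2, 2] <- -1
  expect_equal(maskedMSE(pred, target, m), 1)

  # invariance to masked-cell values
  pred[1, 2] <- 1e6
  expect_equal(maskedMSE(pred, target, m), 1)

  expect_error(maskedMSE(pred, target, matrix(FALSE, 2, 3)),
               "no unmasked")
  expect_error(maskedMSE(pred, matrix(0, 3, 2), m), "shape")

  # brute-force double loop oracle
  set.seed(10)
  for (i in 1:10) {
    p <- matrix(rnorm(40), 4, 10); t <- matrix(rnorm(40), 4, 10)
    mk <- matrix(runif(40) > 0.4, 4, 10)
    if (!any(mk)) next
    acc <- 0; n <- 0
    for (r in 1:4) for (cc in 1:10) if (mk[r, cc]) {
      acc <- acc + (p[r, cc] - t[r, cc])^2; n <- n + 1
    }
    expect_equal(maskedMSE(p, t, mk), acc / n)
  }
})

test_that("training fits a realizable linear teacher to near zero", {
  cp <- tinyCorpus(n = 12, lengthRange = c(30, 40), d = 16)
  tc <- trainConfig(learningRate = 0.05, batchSize = 64,
                    maxEpochs = 300, patience = 100, seed = 0)
  fit <- trainStudent(buildModel(modelConfig("linreg", inputDim = 16)),
                      corpusSamples(cp, 1:10), tc,
                      corpusSamples(cp, 11:12))
  expect_lt(min(fit$history$val_loss), 1e-3)
  # best-checkpoint contract: returned model <= epoch-0 val loss
  expect_lte(min(fit$history$val_loss), fit$history$val_loss[1])

  # determinism: identical seeds give identical histories
  fit2 <- trainStudent(buildModel(modelConfig("linreg", inputDim = 16)),
                       corpusSamples(cp, 1:10), tc,
                       corpusSamples(cp, 11:12))
  expect_identical(fit$history, fit2$history)

  expect_error(
    trainStudent(buildModel(modelConfig("linreg", inputDim = 8)),
                 corpusSamples(cp, 1:10), tc, corpusSamples(cp, 11:12)),
    "inputDim")
})

test_that("dense predictions are per-residue (no cross-residue leakage)", {
  cp <- tinyCorpus(n = 1, lengthRange = c(30, 30))
  rec <- cp$records[[1]]
  emb <- cp$embeddings[[1]]
  m <- buildModel(modelConfig("fnn1", inputDim = 16, hiddenSizes = 8L,
                              seed = 4))
  full <- scores(predictLandscape(m, emb, rec))
  ns <- asNamespace("mutscape")
  rowByRow <- t(vapply(seq_len(30), function(i)
    ns$denseForward(m@layers, embValues(emb)[i, , drop = FALSE],
                    0.01)[1, ], numeric(20)))
  maskNA <- is.na(full)
  rowByRow[maskNA] <- NA_real_
  dimnames(rowByRow) <- dimnames(full)
  expect_equal(full, rowByRow, tolerance = 1e-12)

  # permuting embedding rows permutes landscape rows identically
  set.seed(6)
  perm <- sample(30)
  rec2 <- ProteinRecord("perm", paste(strsplit(proteinSeq(rec), "")[[1]][perm],
                                      collapse = ""))
  permuted <- scores(predictLandscape(
    m, EmbeddingMatrix("perm", embValues(emb)[perm, ]), rec2))
  orig <- scores(predictLandscape(m, emb, rec))[perm, ]
  defined <- !is.na(permuted) & !is.na(orig)
  expect_equal(permuted[defined], orig[defined])
})

test_that("cnn predictions use the residue neighbourhood", {
  cp <- tinyCorpus(n = 1, lengthRange = c(30, 30))
  rec <- cp$records[[1]]
  m <- buildModel(modelConfig("cnn", inputDim = 16,
                              hiddenSizes = c(8L, 4L), convChannels = 6,
                              convKernel = 3, seed = 5))
  base <- scores(predictLandscape(m, cp$embeddings[[1]], rec))
  bumped <- embValues(cp$embeddings[[1]])
  bumped[10, ] <- bumped[10, ] + 5
  after <- scores(predictLandscape(
    m, EmbeddingMatrix(proteinId(rec), bumped), rec))
  changed <- which(rowSums(abs(after - base) > 1e-9, na.rm = TRUE) > 0)
  expect_setequal(changed, 9:11)  # kernel 3 window
})

test_that("zero-weight model predicts all-zero defined scores", {
  m <- buildModel(modelConfig("linreg", inputDim = 4))
  m@layers[[1]]$W[] <- 0; m@layers[[1]]$b[] <- 0
  rec <- ProteinRecord("z", "MKV")
  set.seed(7)
  ls <- predictLandscape(m, EmbeddingMatrix("z", matrix(rnorm(12), 3, 4)),
                         rec)
  expect_true(all(scores(ls)[mask(ls)] == 0))
})

test_that("ensemble prediction is the cell-wise mean of its members", {
  cp <- tinyCorpus(n = 1, lengthRange = c(30, 30))
  rec <- cp$records[[1]]
  emb <- cp$embeddings[[1]]
  a <- buildModel(modelConfig("fnn1", inputDim = 16, hiddenSizes = 8L,
                              seed = 1))
  b <- buildModel(modelConfig("cnn", inputDim = 16,
                              hiddenSizes = c(8L, 4L), convChannels = 6,
                              convKernel = 3, seed = 2))
  ens <- ensemblePredict(a, b, emb, rec)
  la <- scores(predictLandscape(a, emb, rec))
  lb <- scores(predictLandscape(b, emb, rec))
  expect_equal(scores(ens), (la + lb) / 2)

  # identical submodels -> ensemble equals either
  same <- ensemblePredict(a, a, emb, rec)
  expect_equal(scores(same), la)

  # constant submodels 0 and 1 -> all cells 0.5
  z <- buildModel(modelConfig("linreg", inputDim = 16))
  z@layers[[1]]$W[] <- 0; z@layers[[1]]$b[] <- 0
  one <- buildModel(modelConfig("linreg", inputDim = 16))
  one@layers[[1]]$W[] <- 0; one@layers[[1]]$b[] <- 1
  half <- ensemblePredict(z, one, emb, rec)
  expect_true(all(scores(half)[mask(half)] == 0.5))
})
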