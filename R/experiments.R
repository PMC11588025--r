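# Distillation recovery experiment: the package's end-to-end
# self-check. A synthetic corpus with a planted teacher is generated,
# students are trained on the 80/20 protein split, and each student is
# scored by the mean per-protein Spearman correlation between its
# predicted landscape and the teacher landscape on held-out proteins.
# With a noiseless affine teacher the linear student must recover the
# planted mapping almost perfectly; with teacher noise plus a mild
# nonlinearity the hidden-layer student should beat the linear one.

#' Held-out Spearman between a student and the teacher landscapes
#'
#' @param model a trained [StudentModel-class]
#' @param records,embeddings,landscapes parallel validation lists
#' @return Numeric vector of per-protein Spearman correlations.
#' @export
heldOutSpearman <- function(model, records, embeddings, landscapes) {
  mapply(function(rec, emb, ls) {
    pred <- predictLandscape(model, emb, rec)
    spearmanRho(pred@scores[ls@mask], ls@scores[ls@mask])
  }, records, embeddings, landscapes)
}

samplesFrom <- function(records, embeddings, landscapes) {
  mapply(function(r, e, l) list(
    proteinId = proteinId(r), embedding = e@values, target = l@scores,
    mask = l@mask, confidenceFlag = FALSE),
    records, embeddings, landscapes, SIMPLIFY = FALSE)
}

#' Run a distillation recovery experiment
#'
#' Generates a synthetic corpus (`nProteins` proteins, planted teacher,
#' optional noise and nonlinearity), splits proteins 80/20 into
#' train/validation, trains one student per requested architecture, and
#' reports each student's mean held-out Spearman correlation against
#' the teacher landscapes.
#'
#' @param architectures character vector of architectures to train
#' @param nProteins corpus size (default 200)
#' @param lengthRange protein length bounds (default c(30, 100))
#' @param d embedding width (default 64)
#' @param noiseSd teacher score noise sd (0 = noiseless)
#' @param nonlinearity teacher nonlinearity ("none" or "mild")
#' @param seed master seed for corpus, split and training
#' @param tc a [TrainConfig-class]; the default uses a larger Adam step
#'   (0.01) and smaller batches than [trainConfig()] so desk-scale
#'   corpora converge within ~100 epochs
#' @return List with `meanSpearman` (named by architecture),
#'   `perProtein` (list of per-protein vectors) and `history` (list of
#'   training histories).
#' @export
recoveryExperiment <- function(architectures = "linreg", nProteins = 200,
                               lengthRange = c(30, 100), d = 64,
                               noiseSd = 0,
                               nonlinearity = c("none", "mild"),
                               seed = 0, tc = NULL) {
  nonlinearity <- match.arg(nonlinearity)
  if (is.null(tc))
    tc <- trainConfig(learningRate = 0.01, batchSize = 256,
                      maxEpochs = 100, patience = 15, seed = seed)
  records <- genProteins(nProteins, lengthRange, seed)
  embeddings <- genEmbeddings(records, d, seed + 1000L)
  teacher <- plantedTeacher(d, seed + 2000L, noiseSd, nonlinearity)
  landscapes <- genTeacherLandscapes(records, embeddings, teacher,
                                     seed + 3000L)
  # students are scored against the planted ground truth (the clean
  # teacher map, before observation noise): recovery means learning
  # the mapping, not reproducing the noise realization
  cleanTeacher <- teacher; cleanTeacher$noiseSd <- 0
  cleanLandscapes <- if (noiseSd > 0)
    genTeacherLandscapes(records, embeddings, cleanTeacher,
                         seed + 3000L)
  else landscapes
  ids <- vapply(records, proteinId, "")
  sp <- splitTrainVal(ids, 0.8, seed = seed)
  trIdx <- ids %in% sp$train
  trainS <- samplesFrom(records[trIdx], embeddings[trIdx],
                        landscapes[trIdx])
  valS <- samplesFrom(records[!trIdx], embeddings[!trIdx],
                      landscapes[!trIdx])
  out <- list(meanSpearman = numeric(0), perProtein = list(),
              history = list())
  for (arch in architectures) {
    cfg <- modelConfig(arch, inputDim = d, seed = seed)
    fit <- trainStudent(buildModel(cfg), trainS, tc, valS)
    rho <- heldOutSpearman(fit$model, records[!trIdx],
                           embeddings[!trIdx], cleanLandscapes[!trIdx])
    out$meanSpearman[arch] <- mean(rho)
    out$perProtein[[arch]] <- rho
    out$history[[arch]] <- fit$history
  }
  out
}
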