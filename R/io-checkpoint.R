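# Model checkpoints: serialized weights plus the full ModelConfig
# header. Loading rebuilds a model whose predictions are bit-identical
# to the saved one.

CHECKPOINT_MAGIC <- "mutscape-checkpoint-v1"

#' Save a trained student model
#'
#' @param model a [StudentModel-class]
#' @param path output file
#' @return Invisibly, `path`.
#' @export
saveCheckpoint <- function(model, path) {
  stopifnot(is(model, "StudentModel"))
  cfg <- model@config
  obj <- list(
    magic = CHECKPOINT_MAGIC,
    config = list(architecture = cfg@architecture,
                  inputDim = cfg@inputDim, hiddenSizes = cfg@hiddenSizes,
                  convChannels = cfg@convChannels,
                  convKernel = cfg@convKernel, outputDim = cfg@outputDim,
                  leakySlope = cfg@leakySlope, seed = cfg@seed),
    layers = model@layers)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a student model checkpoint
#'
#' Verifies the architecture tag and that every stored weight matrix
#' matches the shape implied by the config header.
#'
#' @param path checkpoint file written by [saveCheckpoint()]
#' @return A [StudentModel-class].
#' @export
loadCheckpoint <- function(path) {
  if (!file.exists(path)) stopf("checkpoint not found: %s", path)
  obj <- tryCatch(readRDS(path), error = function(e)
    stopf("checkpoint integrity error (unreadable file): %s", path))
  if (!is.list(obj) || !identical(obj$magic, CHECKPOINT_MAGIC))
    stopf("checkpoint integrity error: %s is not a recognized checkpoint",
          path)
  cf <- obj$config
  if (!(cf$architecture %in% ARCHITECTURES))
    stopf("checkpoint version error: unknown architecture tag '%s'",
          cf$architecture)
  config <- new("ModelConfig", architecture = cf$architecture,
                inputDim = as.integer(cf$inputDim),
                hiddenSizes = as.integer(cf$hiddenSizes),
                convChannels = as.integer(cf$convChannels),
                convKernel = as.integer(cf$convKernel),
                outputDim = as.integer(cf$outputDim),
                activation = "leaky_relu", leakySlope = cf$leakySlope,
                seed = as.integer(cf$seed))
  dims <- layerDims(config)
  if (length(obj$layers) != nrow(dims))
    stopf("checkpoint integrity error: %d layers stored, config implies %d",
          length(obj$layers), nrow(dims))
  for (i in seq_along(obj$layers)) {
    W <- obj$layers[[i]]$W
    if (!identical(dim(W), c(dims[i, 1], dims[i, 2])) ||
        length(obj$layers[[i]]$b) != dims[i, 2])
      stopf("checkpoint integrity error: layer %d shape mismatch", i)
  }
  new("StudentModel", config = config, layers = obj$layers)
}
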