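# Per-protein embedding store: a directory holding one whitespace-free
# TSV matrix per protein (<id>.tsv, L rows x d columns, full double
# precision) plus a YAML manifest (store.yaml) recording the language
# model tag, the embedding width d and the stored ids. One store holds
# embeddings from exactly one pLM, so d is constant within a store.

STORE_MANIFEST <- "store.yaml"

readStoreManifest <- function(storeDir) {
  mf <- file.path(storeDir, STORE_MANIFEST)
  if (!file.exists(mf))
    stopf("not an embedding store (missing %s): %s", STORE_MANIFEST, storeDir)
  yaml::read_yaml(mf)
}

#' Write an embedding store
#'
#' @param embeddings list of [EmbeddingMatrix-class]; all must share the
#'   same width d and language-model tag
#' @param storeDir output directory (created if needed)
#' @return Invisibly, `storeDir`.
#' @export
writeEmbeddingStore <- function(embeddings, storeDir) {
  if (!length(embeddings)) stopf("no embeddings to write")
  ds <- vapply(embeddings, embeddingDim, 1L)
  if (length(unique(ds)) != 1L)
    stopf("embedding width must be constant within one store; got {%s}",
          paste(unique(ds), collapse = ", "))
  plms <- unique(vapply(embeddings, function(e) e@plmName, ""))
  if (length(plms) != 1L)
    stopf("one store holds one pLM; got {%s}", paste(plms, collapse = ", "))
  dir.create(storeDir, recursive = TRUE, showWarnings = FALSE)
  ids <- vapply(embeddings, proteinId, "")
  if (anyDuplicated(ids))
    stopf("duplicate protein ids in store: %s", ids[duplicated(ids)][1])
  for (e in embeddings) {
    fm <- matrix(sprintf("%.17g", e@values), nrow = nrow(e@values))
    writeLines(apply(fm, 1L, paste, collapse = "\t"),
               file.path(storeDir, paste0(e@proteinId, ".tsv")))
  }
  yaml::write_yaml(list(plm_name = plms, d = ds[1], ids = as.list(ids)),
                   file.path(storeDir, STORE_MANIFEST))
  invisible(storeDir)
}

#' List protein ids available in an embedding store
#' @param storeDir store directory
#' @return Character vector of ids.
#' @export
listEmbeddingIds <- function(storeDir) {
  unlist(readStoreManifest(storeDir)$ids)
}

#' Read one protein's embedding matrix from a store
#'
#' @param storeDir store directory written by [writeEmbeddingStore()]
#' @param proteinId id of the protein to load
#' @return An [EmbeddingMatrix-class] with `d` taken from the stored
#'   matrix shape and the language-model tag from the store manifest.
#' @export
readEmbedding <- function(storeDir, proteinId) {
  manifest <- readStoreManifest(storeDir)
  ids <- unlist(manifest$ids)
  if (!(proteinId %in% ids))
    stopf("protein '%s' not in store; available: %s", proteinId,
          paste(utils::head(ids, 10), collapse = ", "))
  f <- file.path(storeDir, paste0(proteinId, ".tsv"))
  dt <- data.table::fread(f, header = FALSE, sep = "\t")
  m <- as.matrix(dt)
  dimnames(m) <- NULL
  if (!is.numeric(m) || any(!is.finite(m)))
    stopf("embedding dataset for '%s' is not a finite numeric matrix",
          proteinId)
  EmbeddingMatrix(proteinId, m, manifest$plm_name)
}
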