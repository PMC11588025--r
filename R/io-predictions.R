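# Prediction CSV: header "variant,score_raw,score_normalized", one row
# per defined landscape cell, ordered position-major then alphabet-minor
# so diffs between runs are deterministic.

#' Write predicted landscapes to CSV
#'
#' One row per defined cell, in position-major then alphabet order.
#' When `lsNorm` is NULL the normalized column is omitted.
#'
#' @param lsRaw raw predicted [Landscape-class]
#' @param lsNorm matching normalized [Landscape-class], or NULL
#' @param path output CSV
#' @param sequence protein sequence (needed to name the wild-type
#'   letter in the variant string); length must equal L
#' @return Invisibly, `path`.
#' @export
writePredictions <- function(lsRaw, lsNorm = NULL, path, sequence) {
  stopifnot(is(lsRaw, "Landscape"))
  if (!is.null(lsNorm)) {
    stopifnot(is(lsNorm, "Landscape"))
    if (lsRaw@proteinId != lsNorm@proteinId ||
        !identical(lsRaw@mask, lsNorm@mask))
      stopf("raw and normalized landscapes must share protein and mask")
  }
  L <- nrow(lsRaw@scores)
  wt <- strsplit(toupper(sequence), "")[[1]]
  if (length(wt) != L)
    stopf("sequence length %d does not match landscape rows %d",
          length(wt), L)
  if (any(rowSums(lsRaw@mask) == 0L))
    stopf("residue %d has no defined cells",
          which(rowSums(lsRaw@mask) == 0L)[1])
  idx <- which(t(lsRaw@mask))            # position-major, alphabet-minor
  posv <- (idx - 1L) %/% 20L + 1L
  mutv <- AA_ALPHABET[(idx - 1L) %% 20L + 1L]
  rawv <- t(lsRaw@scores)[idx]
  lines <- data.frame(
    variant = sprintf("%s%d%s", wt[posv], posv, mutv),
    score_raw = sprintf("%.17g", rawv))
  header <- "variant,score_raw"
  if (!is.null(lsNorm)) {
    lines$score_normalized <- sprintf("%.17g", t(lsNorm@scores)[idx])
    header <- "variant,score_raw,score_normalized"
  }
  writeLines(c(header, do.call(paste, c(unname(lines), sep = ","))), path)
  invisible(path)
}

#' Read a prediction CSV back into landscapes
#'
#' Inverse of [writePredictions()]: rebuilds the raw (and, when
#' present, normalized) landscape matrices on the defined cells.
#'
#' @param path prediction CSV
#' @param protein the [ProteinRecord-class] the predictions belong to
#' @return List with elements `raw` and (optionally) `normalized`.
#' @export
readPredictions <- function(path, protein) {
  stopifnot(is(protein, "ProteinRecord"))
  if (!file.exists(path)) stopf("prediction file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("variant", "score_raw") %in% names(df)))
    stopf("prediction CSV must have columns variant and score_raw")
  L <- seqLength(protein)
  raw <- matrix(NA_real_, L, 20L)
  nrm <- matrix(NA_real_, L, 20L)
  maskM <- matrix(FALSE, L, 20L)
  for (i in seq_len(nrow(df))) {
    mv <- parseVariant(df$variant[i], protein)
    raw[mv@pos, aaIndex(mv@mut)] <- df$score_raw[i]
    maskM[mv@pos, aaIndex(mv@mut)] <- TRUE
    if ("score_normalized" %in% names(df))
      nrm[mv@pos, aaIndex(mv@mut)] <- df$score_normalized[i]
  }
  out <- list(raw = new("Landscape", proteinId = proteinId(protein),
                        scores = raw, mask = maskM, role = "predicted_raw"))
  if ("score_normalized" %in% names(df))
    out$normalized <- new("Landscape", proteinId = proteinId(protein),
                          scores = nrm, mask = maskM,
                          role = "predicted_normalized")
  out
}
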