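# FASTA input/output via Biostrings; records come back as ProteinRecord
# objects with ids taken from the header up to the first whitespace.

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file
#' @return List of [ProteinRecord-class], in file order; sequences are
#'   uppercased.
#' @export
readProteinFasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  aas <- Biostrings::readBStringSet(path)
  if (length(aas) == 0L) stopf("FASTA file is empty: %s", path)
  ids <- sub("\\s.*$", "", names(aas))
  if (anyDuplicated(ids))
    stopf("duplicate FASTA ids: %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(aas))
  mapply(ProteinRecord, ids, seqs, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write protein sequences to a FASTA file
#'
#' Inverse of [readProteinFasta()]; sequence lines wrap at 60 columns.
#' An empty record list writes an empty file.
#'
#' @param records list of [ProteinRecord-class]
#' @param path output file
#' @return Invisibly, `path`.
#' @export
writeProteinFasta <- function(records, path) {
  if (length(records) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  seqs <- vapply(records, proteinSeq, "")
  ids <- vapply(records, proteinId, "")
  x <- Biostrings::BStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}
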