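# DMS assay tables: CSV with a variant-notation column ("mutant") and a
# measured-score column ("DMS_score"), following the public ProteinGym
# convention; both names are configurable. Assay metadata (phenotype,
# taxon) travels in a sidecar CSV: assay_id, protein_id, phenotype,
# taxon.

#' Read a DMS assay table
#'
#' Every variant is parsed and validated against the protein via
#' [parseVariant()]; an unparsable or invalid variant is an error
#' naming the offending row. Extra columns are ignored and row order is
#' preserved.
#'
#' @param path CSV file
#' @param protein the assayed [ProteinRecord-class]
#' @param assayId assay identifier (default: file name without
#'   extension)
#' @param variantCol,scoreCol column names (defaults "mutant",
#'   "DMS_score")
#' @param phenotype,taxon assay metadata labels
#' @param sep multi-mutant token separator (default ":")
#' @return A [DMSAssay-class].
#' @export
readDMSTable <- function(path, protein, assayId = NULL,
                         variantCol = "mutant", scoreCol = "DMS_score",
                         phenotype = "Fitness", taxon = "Unknown",
                         sep = ":") {
  stopifnot(is(protein, "ProteinRecord"))
  if (!file.exists(path)) stopf("DMS table not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c(variantCol, scoreCol) %in% names(df)))
    stopf("DMS table %s lacks required column(s): %s", path,
          paste(setdiff(c(variantCol, scoreCol), names(df)), collapse = ", "))
  if (nrow(df) == 0L) stopf("DMS table is empty: %s", path)
  variants <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    variants[[i]] <- tryCatch(
      parseVariant(df[[variantCol]][i], protein, sep = sep),
      error = function(e)
        stopf("row %d of %s: %s", i, path, conditionMessage(e)))
  }
  DMSAssay(assayId %||% tools::file_path_sans_ext(basename(path)),
           proteinId(protein), variants, as.numeric(df[[scoreCol]]),
           phenotype = phenotype, taxon = taxon)
}

#' Write a DMS assay table
#'
#' Inverse of [readDMSTable()] with the default column names.
#'
#' @param assay a [DMSAssay-class]
#' @param path output CSV
#' @param sep multi-mutant token separator
#' @return Invisibly, `path`.
#' @export
writeDMSTable <- function(assay, path, sep = ":") {
  stopifnot(is(assay, "DMSAssay"))
  df <- data.frame(
    mutant = vapply(assay@variants, formatVariant, "", sep = sep),
    DMS_score = assay@measured)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an assay metadata sidecar table
#'
#' @param path CSV with columns assay_id, protein_id, phenotype, taxon
#' @return data.frame with those four columns.
#' @export
readAssayMetadata <- function(path) {
  if (!file.exists(path)) stopf("metadata file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("assay_id", "protein_id", "phenotype", "taxon")
  if (!all(need %in% names(df)))
    stopf("metadata must have columns: %s", paste(need, collapse = ", "))
  bad <- setdiff(unique(df$phenotype), DMS_PHENOTYPES)
  if (length(bad))
    stopf("unknown phenotype label(s): %s", paste(bad, collapse = ", "))
  df[need]
}
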