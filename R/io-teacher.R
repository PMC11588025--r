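# Teacher substitution-matrix text dialect (GEMME-style): a
# whitespace-separated file whose first line is a position header
# (1..L), followed by exactly 20 rows, each beginning with a one-letter
# amino-acid code (case-insensitive, quotes tolerated) and holding L
# values; "NA" marks undefined cells. Rows may arrive in any amino-acid
# order; the reader remaps them to the canonical alphabet. A transpose
# flag accepts the L x 20 orientation (header of 20 letters, one row
# per position).

#' Read a teacher substitution matrix
#'
#' Parses the 20 x L text dialect into a teacher-role
#' [Landscape-class]: values are transposed to L x 20 with canonical
#' column order, `NA` cells and wild-type self-substitution cells are
#' masked, and defined values are checked against the teacher score
#' range [-10, 2] unless `strictRange = FALSE`.
#'
#' @param path matrix file
#' @param protein the [ProteinRecord-class] the matrix belongs to;
#'   its length must equal the file's L
#' @param strictRange reject defined values outside [-10, 2]
#'   (default TRUE). With `strictRange = FALSE`, marginally exceeding
#'   values are clipped to the range so the teacher invariant holds.
#' @param transpose set TRUE if the file is L x 20 (one row per
#'   position, header of 20 amino-acid letters)
#' @return A [Landscape-class] with role `teacher`.
#' @export
readTeacherMatrix <- function(path, protein, strictRange = TRUE,
                              transpose = FALSE) {
  stopifnot(is(protein, "ProteinRecord"))
  if (!file.exists(path)) stopf("teacher matrix file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stopf("teacher matrix file is empty: %s", path)
  body <- lines[-1L]  # first line is the position (or letter) header
  tok <- strsplit(trimws(body), "[ \t]+")
  L <- seqLength(protein)

  if (!transpose) {
    if (length(tok) != 20L)
      stopf("expected 20 amino-acid rows, found %d in %s", length(tok), path)
    letters20 <- toupper(gsub("\"|'", "", vapply(tok, `[`, "", 1L)))
    idx <- aaIndex(letters20)
    if (any(is.na(idx)) || anyDuplicated(idx))
      stopf("row labels must be the 20 canonical amino acids exactly once")
    nvals <- vapply(tok, length, 1L) - 1L
    if (any(nvals != L))
      stopf("column count %d does not match protein length %d for '%s'",
            nvals[nvals != L][1], L, proteinId(protein))
    m <- matrix(NA_real_, nrow = L, ncol = 20L)
    for (i in seq_len(20L)) {
      v <- suppressWarnings(as.numeric(tok[[i]][-1L]))
      bad <- is.na(v) & toupper(tok[[i]][-1L]) != "NA"
      if (any(bad))
        stopf("unparsable value '%s' in row %s", tok[[i]][-1L][bad][1],
              letters20[i])
      m[, idx[i]] <- v
    }
  } else {
    header <- strsplit(trimws(lines[1L]), "[ \t]+")[[1]]
    header <- toupper(gsub("\"|'", "", header))
    header <- header[header %in% AA_ALPHABET]
    if (length(header) != 20L || anyDuplicated(header))
      stopf("transposed file needs a header with the 20 amino-acid letters")
    if (length(tok) != L)
      stopf("row count %d does not match protein length %d for '%s'",
            length(tok), L, proteinId(protein))
    m <- matrix(NA_real_, nrow = L, ncol = 20L)
    for (i in seq_len(L)) {
      row <- tok[[i]]
      if (length(row) == 21L) row <- row[-1L]  # leading position index
      if (length(row) != 20L)
        stopf("row %d has %d values; expected 20", i, length(row))
      v <- suppressWarnings(as.numeric(row))
      bad <- is.na(v) & toupper(row) != "NA"
      if (any(bad)) stopf("unparsable value '%s' in row %d", row[bad][1], i)
      m[i, aaIndex(header)] <- v
    }
  }

  maskM <- !is.na(m)
  wt <- aaIndex(strsplit(proteinSeq(protein), "")[[1]])
  maskM[cbind(seq_len(L), wt)] <- FALSE
  m[!maskM] <- NA_real_
  defined <- m[maskM]
  if (strictRange && length(defined) &&
      (min(defined) < -10 || max(defined) > 2))
    stopf("teacher score %.4g outside [-10, 2]; pass strictRange = FALSE to accept",
          defined[defined < -10 | defined > 2][1])
  role <- "teacher"
  if (!strictRange && length(defined) &&
      (min(defined) < -10 || max(defined) > 2)) {
    # out-of-range exports cannot carry the teacher role invariant
    m <- pmin(pmax(m, -10), 2)
  }
  new("Landscape", proteinId = proteinId(protein), scores = m,
      mask = maskM, role = role)
}

#' Write a landscape in the teacher matrix dialect
#'
#' Inverse of [readTeacherMatrix()] (20 rows x L columns orientation).
#' Undefined cells are written as `NA`.
#'
#' @param ls a [Landscape-class]
#' @param path output file
#' @return Invisibly, `path`.
#' @export
writeTeacherMatrix <- function(ls, path) {
  stopifnot(is(ls, "Landscape"))
  L <- nrow(ls@scores)
  if (L < 1L) stopf("cannot write a landscape with no residues")
  out <- character(21L)
  out[1L] <- paste(seq_len(L), collapse = "\t")
  for (k in seq_len(20L)) {
    v <- ls@scores[, k]
    vs <- ifelse(ls@mask[, k], sprintf("%.17g", v), "NA")
    out[k + 1L] <- paste(c(AA_ALPHABET[k], vs), collapse = "\t")
  }
  writeLines(out, path)
  invisible(path)
}
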