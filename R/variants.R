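# Variant notation: "X<pos>Y" tokens (wild-type letter, 1-based position,
# mutant letter), joined by a separator (default ":") for multi-mutants.
# The same notation is used in the API, CSV columns and the CLI.

#' Parse variant notation against a protein sequence
#'
#' Parses one or more `X<pos>Y` tokens (e.g. `"G76A"`, `"M1A:V3L"`) into
#' a [MultiVariant-class], validating every token against the protein:
#' the sequence character at `pos` must equal the wild-type letter.
#'
#' @param text variant string, tokens joined by `sep`
#' @param protein a [ProteinRecord-class] (or a plain sequence string)
#' @param sep token separator for multi-mutants (default ":")
#' @return A [MultiVariant-class].
#' @examples
#' p <- ProteinRecord("toy", "MKV")
#' parseVariant("M1A", p)
#' parseVariant("M1A:V3L", p)
#' @export
parseVariant <- function(text, protein, sep = ":") {
  seqchars <- strsplit(if (is(protein, "ProteinRecord")) proteinSeq(protein)
                       else toupper(as.character(protein)), "")[[1]]
  L <- length(seqchars)
  if (length(text) != 1L || is.na(text) || !nzchar(text))
    stopf("variant string must be a single non-empty string")
  tokens <- strsplit(text, sep, fixed = TRUE)[[1]]
  if (!length(tokens) || any(!nzchar(tokens)))
    stopf("malformed variant string '%s'", text)
  m <- regmatches(tokens, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", tokens))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad))
    stopf("malformed variant token '%s'", tokens[bad][1])
  wt <- toupper(vapply(m, `[`, "", 2L))
  pos <- as.integer(vapply(m, `[`, "", 3L))
  mut <- toupper(vapply(m, `[`, "", 4L))
  if (any(pos < 1L | pos > L))
    stopf("position %d outside [1, %d]", pos[pos < 1L | pos > L][1], L)
  if (any(wt == mut))
    stopf("token '%s' is synonymous (wt == mut); not representable in a landscape",
          tokens[wt == mut][1])
  mismatch <- seqchars[pos] != wt
  if (any(mismatch))
    stopf("wild-type mismatch at position %d: sequence has '%s', variant says '%s'",
          pos[mismatch][1], seqchars[pos[mismatch][1]], wt[mismatch][1])
  MultiVariant(wt, pos, mut)
}

#' Format a variant in `X<pos>Y` notation
#'
#' Inverse of [parseVariant()]: `parseVariant(formatVariant(mv), p)`
#' reproduces `mv` for any variant valid on protein `p`.
#'
#' @param mv a [MultiVariant-class]
#' @param sep token separator (default ":")
#' @return Character string.
#' @examples
#' formatVariant(MultiVariant(c("M", "V"), c(1, 3), c("A", "L")))
#' @export
formatVariant <- function(mv, sep = ":") {
  stopifnot(is(mv, "MultiVariant"))
  paste(sprintf("%s%d%s", mv@wt, mv@pos, mv@mut), collapse = sep)
}
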