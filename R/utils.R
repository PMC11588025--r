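#' Canonical amino-acid alphabet
#'
#' The 20 canonical one-letter amino-acid codes in fixed alphabetical
#' order. Every landscape matrix in the package uses this order for its
#' 20 columns; all file readers remap incoming rows/columns to it so
#' that column k always means the same substitution.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# column index of a mutant letter in the canonical order; NA if non-canonical
aaIndex <- function(letters) match(letters, AA_ALPHABET)

isCanonicalSeq <- function(s) {
  !grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"), s)
}

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
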