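#' @import methods
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

# ---- ProteinRecord ----------------------------------------------------------

#' ProteinRecord: one protein sequence with an identifier
#'
#' Minimal container for a curated protein: an id and an uppercase
#' amino-acid sequence. The query length L is `nchar(sequence(x))`.
#'
#' @slot id single protein identifier
#' @slot sequence uppercase amino-acid sequence
#' @aliases ProteinRecord-class
#' @export
setClass("ProteinRecord",
  representation(id = "character", sequence = "character"))

setValidity("ProteinRecord", function(object) {
  if (length(object@id) != 1L || !nzchar(object@id))
    return("'id' must be a single non-empty string")
  if (length(object@sequence) != 1L || nchar(object@sequence) < 1L)
    return("'sequence' must be a single non-empty string")
  if (object@sequence != toupper(object@sequence))
    return("'sequence' must be uppercase")
  TRUE
})

#' Construct a ProteinRecord
#'
#' @param id protein identifier
#' @param sequence amino-acid sequence (uppercased on construction)
#' @return A [ProteinRecord-class] object.
#' @examples
#' p <- ProteinRecord("P1", "MKVLA")
#' seqLength(p)
#' @export
ProteinRecord <- function(id, sequence) {
  new("ProteinRecord", id = as.character(id),
      sequence = toupper(as.character(sequence)))
}

#' @describeIn ProteinRecord protein identifier
#' @param x,object a ProteinRecord
#' @export
setGeneric("proteinId", function(x) standardGeneric("proteinId"))

#' @export
setMethod("proteinId", "ProteinRecord", function(x) x@id)

#' @describeIn ProteinRecord the amino-acid sequence
#' @export
setGeneric("proteinSeq", function(x) standardGeneric("proteinSeq"))

#' @export
setMethod("proteinSeq", "ProteinRecord", function(x) x@sequence)

#' @describeIn ProteinRecord sequence length L
#' @export
setGeneric("seqLength", function(x) standardGeneric("seqLength"))

#' @export
setMethod("seqLength", "ProteinRecord", function(x) nchar(x@sequence))

setMethod("show", "ProteinRecord", function(object) {
  s <- object@sequence
  if (nchar(s) > 40) s <- paste0(substr(s, 1, 37), "...")
  cat(sprintf("ProteinRecord %s (L=%d): %s\n",
              object@id, nchar(object@sequence), s))
})

# ---- MultiVariant -----------------------------------------------------------

#' MultiVariant: one or more single substitutions on one protein
#'
#' Parallel vectors of wild-type letter, 1-based position and mutant
#' letter; the mutation depth is the number of substitutions. Positions
#' are pairwise distinct and wt != mut everywhere (synonymous changes
#' are not representable in a landscape).
#'
#' @slot wt wild-type letters
#' @slot pos 1-based positions
#' @slot mut mutant letters
#' @aliases MultiVariant-class
#' @export
setClass("MultiVariant",
  representation(wt = "character", pos = "integer", mut = "character"))

setValidity("MultiVariant", function(object) {
  n <- length(object@pos)
  if (n < 1L) return("a variant must contain at least one substitution")
  if (length(object@wt) != n || length(object@mut) != n)
    return("wt, pos and mut must have equal length")
  if (anyDuplicated(object@pos))
    return("substitution positions must be pairwise distinct")
  if (any(object@wt == object@mut))
    return("wild-type and mutant letter must differ")
  if (any(is.na(aaIndex(object@wt))) || any(is.na(aaIndex(object@mut))))
    return("letters must be canonical amino-acid codes")
  if (any(object@pos < 1L)) return("positions must be >= 1")
  TRUE
})

#' Construct a MultiVariant
#'
#' @param wt wild-type one-letter codes
#' @param pos 1-based positions
#' @param mut mutant one-letter codes
#' @return A [MultiVariant-class] object.
#' @examples
#' MultiVariant(c("M", "V"), c(1L, 3L), c("A", "L"))
#' @export
MultiVariant <- function(wt, pos, mut) {
  new("MultiVariant", wt = toupper(wt), pos = as.integer(pos),
      mut = toupper(mut))
}

#' @describeIn MultiVariant the mutation depth (number of substitutions)
#' @param x,object a MultiVariant
#' @export
setGeneric("depth", function(x) standardGeneric("depth"))

#' @export
setMethod("depth", "MultiVariant", function(x) length(x@pos))

setMethod("show", "MultiVariant", function(object) {
  cat(sprintf("MultiVariant depth %d: %s\n", depth(object),
              formatVariant(object)))
})

# ---- Landscape --------------------------------------------------------------

LANDSCAPE_ROLES <- c("teacher", "predicted_raw", "predicted_normalized",
                     "experimental")

#' Landscape: an L x 20 single-substitution score matrix
#'
#' Scores for every (position, mutant amino acid) pair of one protein,
#' with a logical mask marking which cells are defined. Wild-type
#' self-substitution cells are always undefined. The role records
#' where the scores came from: `teacher` matrices carry evolutionary
#' scores in [-10, 2] (lower = more deleterious), `predicted_raw` the
#' student's output on the same scale, `predicted_normalized` scores
#' rescaled to [0, 1] (1 = high functional impact), `experimental`
#' measured values on an assay-specific scale.
#'
#' @slot proteinId protein identifier
#' @slot scores numeric L x 20 matrix, columns in [AA_ALPHABET] order
#' @slot mask logical L x 20 matrix, TRUE = defined
#' @slot role one of teacher, predicted_raw, predicted_normalized,
#'   experimental
#' @aliases Landscape-class
#' @export
setClass("Landscape",
  representation(proteinId = "character", scores = "matrix",
                 mask = "matrix", role = "character"))

setValidity("Landscape", function(object) {
  sc <- object@scores; mk <- object@mask
  if (!is.numeric(sc)) return("'scores' must be numeric")
  if (!is.logical(mk)) return("'mask' must be logical")
  if (!identical(dim(sc), dim(mk)))
    return("'scores' and 'mask' must have identical shape")
  if (ncol(sc) != 20L) return("landscape must have exactly 20 columns")
  if (nrow(sc) < 1L) return("landscape must cover at least one residue")
  if (!identical(object@role, object@role[1]) ||
      !(object@role %in% LANDSCAPE_ROLES))
    return(paste("'role' must be one of:",
                 paste(LANDSCAPE_ROLES, collapse = ", ")))
  v <- sc[mk]
  if (any(!is.finite(v)))
    return("defined cells must hold finite scores")
  if (object@role == "teacher" && length(v) &&
      (min(v) < -10 - 1e-9 || max(v) > 2 + 1e-9))
    return("teacher scores must lie in [-10, 2]")
  if (object@role == "predicted_normalized" && length(v) &&
      (min(v) < -1e-9 || max(v) > 1 + 1e-9))
    return("normalized scores must lie in [0, 1]")
  TRUE
})

#' Construct a Landscape
#'
#' Wild-type self-substitution cells are forced to be masked when the
#' protein sequence is supplied.
#'
#' @param proteinId protein identifier
#' @param scores numeric L x 20 matrix (columns in canonical order)
#' @param mask logical L x 20 matrix (TRUE = defined); default all TRUE
#'   except self-cells
#' @param role landscape role
#' @param sequence optional protein sequence used to mask self-cells
#' @return A [Landscape-class] object.
#' @export
Landscape <- function(proteinId, scores, mask = NULL,
                      role = c("teacher", "predicted_raw",
                               "predicted_normalized", "experimental"),
                      sequence = NULL) {
  role <- match.arg(role)
  scores <- as.matrix(scores)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(scores), ncol(scores))
  if (!is.null(sequence)) {
    wt <- aaIndex(strsplit(toupper(sequence), "")[[1]])
    if (length(wt) != nrow(scores))
      stopf("sequence length %d does not match landscape rows %d",
            length(wt), nrow(scores))
    mask[cbind(seq_along(wt), wt)] <- FALSE
  }
  scores[!mask] <- NA_real_
  dimnames(scores) <- dimnames(mask) <- NULL
  new("Landscape", proteinId = as.character(proteinId), scores = scores,
      mask = mask, role = role)
}

#' @describeIn Landscape the L x 20 score matrix (NA at undefined cells)
#' @param x,object a Landscape
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @export
setMethod("scores", "Landscape", function(x) x@scores)

#' @describeIn Landscape the logical defined-cell mask
#' @export
setGeneric("mask", function(x) standardGeneric("mask"))

#' @export
setMethod("mask", "Landscape", function(x) x@mask)

#' @describeIn Landscape the landscape role
#' @export
setGeneric("landscapeRole", function(x) standardGeneric("landscapeRole"))

#' @export
setMethod("landscapeRole", "Landscape", function(x) x@role)

#' @export
setMethod("proteinId", "Landscape", function(x) x@proteinId)

#' @describeIn Landscape number of residues L
#' @export
setMethod("seqLength", "Landscape", function(x) nrow(x@scores))

setMethod("show", "Landscape", function(object) {
  v <- object@scores[object@mask]
  cat(sprintf(
    "Landscape %s [%s]: L=%d, %d defined cells, range [%.3g, %.3g]\n",
    object@proteinId, object@role, nrow(object@scores), length(v),
    if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
})

# ---- SensitivityRanking -----------------------------------------------------

#' SensitivityRanking: per-residue mutation-sensitivity ranks
#'
#' For each residue, the mean score over its defined substitutions and
#' the fractional (tie-averaged) rank of that mean, with rank 1 = the
#' most mutation-sensitive residue.
#'
#' @slot proteinId protein identifier
#' @slot perResidueMean mean defined score per residue
#' @slot ranks fractional ranks, 1 = most sensitive
#' @aliases SensitivityRanking-class
#' @export
setClass("SensitivityRanking",
  representation(proteinId = "character", perResidueMean = "numeric",
                 ranks = "numeric"))

setValidity("SensitivityRanking", function(object) {
  L <- length(object@ranks)
  if (length(object@perResidueMean) != L)
    return("means and ranks must have equal length")
  if (abs(sum(object@ranks) - L * (L + 1) / 2) > 1e-8)
    return("ranks must sum to L(L+1)/2")
  TRUE
})

#' @describeIn SensitivityRanking the fractional ranks (1 = most sensitive)
#' @param x,object a SensitivityRanking
#' @export
setGeneric("ranks", function(x) standardGeneric("ranks"))

#' @export
setMethod("ranks", "SensitivityRanking", function(x) x@ranks)

#' @export
setMethod("proteinId", "SensitivityRanking", function(x) x@proteinId)

setMethod("show", "SensitivityRanking", function(object) {
  cat(sprintf("SensitivityRanking %s: L=%d, most sensitive residue %d\n",
              object@proteinId, length(object@ranks),
              which.min(object@ranks)))
})

# ---- EmbeddingMatrix --------------------------------------------------------

#' EmbeddingMatrix: per-residue embedding vectors for one protein
#'
#' An L x d real matrix, one row per residue, extracted upstream from a
#' protein language model's last encoder layer (d = 2560 for the
#' reference ESM-2 style backbone).
#'
#' @slot proteinId protein identifier
#' @slot values numeric L x d matrix
#' @slot plmName tag naming the language model the rows came from
#' @aliases EmbeddingMatrix-class
#' @export
setClass("EmbeddingMatrix",
  representation(proteinId = "character", values = "matrix",
                 plmName = "character"))

setValidity("EmbeddingMatrix", function(object) {
  if (!is.numeric(object@values)) return("'values' must be numeric")
  if (nrow(object@values) < 1L || ncol(object@values) < 1L)
    return("'values' must be a non-empty matrix")
  TRUE
})

#' Construct an EmbeddingMatrix
#' @param proteinId protein identifier
#' @param values numeric L x d matrix
#' @param plmName language-model tag
#' @return An [EmbeddingMatrix-class] object.
#' @export
EmbeddingMatrix <- function(proteinId, values, plmName = "unknown") {
  new("EmbeddingMatrix", proteinId = as.character(proteinId),
      values = as.matrix(values), plmName = as.character(plmName))
}

#' @describeIn EmbeddingMatrix the L x d value matrix
#' @param x,object an EmbeddingMatrix
#' @export
setGeneric("embValues", function(x) standardGeneric("embValues"))

#' @export
setMethod("embValues", "EmbeddingMatrix", function(x) x@values)

#' @describeIn EmbeddingMatrix embedding width d
#' @export
setGeneric("embeddingDim", function(x) standardGeneric("embeddingDim"))

#' @export
setMethod("embeddingDim", "EmbeddingMatrix", function(x) ncol(x@values))

#' @export
setMethod("proteinId", "EmbeddingMatrix", function(x) x@proteinId)

#' @export
setMethod("seqLength", "EmbeddingMatrix", function(x) nrow(x@values))

setMethod("show", "EmbeddingMatrix", function(object) {
  cat(sprintf("EmbeddingMatrix %s: L=%d, d=%d (%s)\n", object@proteinId,
              nrow(object@values), ncol(object@values), object@plmName))
})

# ---- DMSAssay ---------------------------------------------------------------

DMS_PHENOTYPES <- c("Activity", "Binding", "Expression", "Fitness",
                    "Stability")

#' DMSAssay: a deep mutational scanning assay
#'
#' A list of variants with measured phenotype scores for one protein,
#' plus assay metadata (phenotype class from the closed vocabulary
#' Activity/Binding/Expression/Fitness/Stability, and a taxon label).
#'
#' @slot assayId assay identifier
#' @slot proteinId protein identifier
#' @slot phenotype one of Activity, Binding, Expression, Fitness,
#'   Stability
#' @slot taxon taxon label (e.g. "Human", "Virus")
#' @slot variants list of [MultiVariant-class]
#' @slot measured numeric measured scores, parallel to `variants`
#' @aliases DMSAssay-class
#' @export
setClass("DMSAssay",
  representation(assayId = "character", proteinId = "character",
                 phenotype = "character", taxon = "character",
                 variants = "list", measured = "numeric"))

setValidity("DMSAssay", function(object) {
  if (length(object@variants) < 1L) return("assay must have >= 1 entry")
  if (length(object@measured) != length(object@variants))
    return("variants and measured scores must be parallel")
  if (!(object@phenotype %in% DMS_PHENOTYPES))
    return(paste("phenotype must be one of:",
                 paste(DMS_PHENOTYPES, collapse = ", ")))
  if (!all(vapply(object@variants, is, TRUE, "MultiVariant")))
    return("all entries must be MultiVariant objects")
  TRUE
})

#' Construct a DMSAssay
#' @param assayId assay identifier
#' @param proteinId protein identifier
#' @param variants list of [MultiVariant-class]
#' @param measured numeric measured scores
#' @param phenotype phenotype class
#' @param taxon taxon label
#' @return A [DMSAssay-class] object.
#' @export
DMSAssay <- function(assayId, proteinId, variants, measured,
                     phenotype = "Fitness", taxon = "Unknown") {
  new("DMSAssay", assayId = as.character(assayId),
      proteinId = as.character(proteinId), variants = variants,
      measured = as.numeric(measured), phenotype = as.character(phenotype),
      taxon = as.character(taxon))
}

#' @describeIn DMSAssay number of assay entries
#' @param x,object a DMSAssay
#' @export
setMethod("length", "DMSAssay", function(x) length(x@variants))

#' @export
setMethod("proteinId", "DMSAssay", function(x) x@proteinId)

#' @describeIn DMSAssay assay identifier
#' @export
setGeneric("assayId", function(x) standardGeneric("assayId"))

#' @export
setMethod("assayId", "DMSAssay", function(x) x@assayId)

#' @describeIn DMSAssay the variant list
#' @export
setGeneric("assayVariants", function(x) standardGeneric("assayVariants"))

#' @export
setMethod("assayVariants", "DMSAssay", function(x) x@variants)

#' @describeIn DMSAssay the measured scores
#' @export
setGeneric("measuredScores", function(x) standardGeneric("measuredScores"))

#' @export
setMethod("measuredScores", "DMSAssay", function(x) x@measured)

#' @describeIn DMSAssay phenotype label
#' @export
setGeneric("phenotype", function(x) standardGeneric("phenotype"))

#' @export
setMethod("phenotype", "DMSAssay", function(x) x@phenotype)

#' @describeIn DMSAssay taxon label
#' @export
setGeneric("taxon", function(x) standardGeneric("taxon"))

#' @export
setMethod("taxon", "DMSAssay", function(x) x@taxon)

setMethod("show", "DMSAssay", function(object) {
  cat(sprintf("DMSAssay %s on %s [%s/%s]: %d variants\n", object@assayId,
              object@proteinId, object@phenotype, object@taxon,
              length(object@variants)))
})
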