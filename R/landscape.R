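# Landscape arithmetic: lookup, additive multi-mutant scoring,
# normalization to [0,1], residue sensitivity ranks and rank agreement.

#' Look up the score of a single substitution
#'
#' Returns `scores(ls)[pos, mut]` for a depth-1 variant. Looking up an
#' undefined (masked) cell — including any wild-type self-substitution —
#' is an error, as is a position outside the landscape.
#'
#' @param ls a [Landscape-class]
#' @param sv a depth-1 [MultiVariant-class]
#' @return Numeric scalar.
#' @export
landscapeLookup <- function(ls, sv) {
  stopifnot(is(ls, "Landscape"), is(sv, "MultiVariant"))
  if (depth(sv) != 1L)
    stopf("landscapeLookup expects a single substitution; got depth %d",
          depth(sv))
  L <- nrow(ls@scores)
  pos <- sv@pos
  if (pos < 1L || pos > L)
    stopf("position %d outside landscape range [1, %d]", pos, L)
  col <- aaIndex(sv@mut)
  if (!ls@mask[pos, col])
    stopf("score undefined (masked) for %s at position %d", sv@mut, pos)
  unname(ls@scores[pos, col])
}

#' Score a multi-mutant additively
#'
#' The landscape holds only single-substitution scores, so multi-mutants
#' are scored with the minimal epistasis-free model: the sum of the
#' single-substitution scores. For depth 1 this equals
#' [landscapeLookup()].
#'
#' @param ls a [Landscape-class]
#' @param mv a [MultiVariant-class]
#' @return Numeric scalar.
#' @export
scoreMulti <- function(ls, mv) {
  stopifnot(is(ls, "Landscape"), is(mv, "MultiVariant"))
  total <- 0
  for (i in seq_len(depth(mv))) {
    total <- total +
      landscapeLookup(ls, MultiVariant(mv@wt[i], mv@pos[i], mv@mut[i]))
  }
  total
}

#' Normalize a raw landscape to the [0, 1] impact scale
#'
#' Linearly rescales raw scores so that the most tolerated score
#' (`sMax`, default 2, the upper end of the teacher range) maps to 0
#' and the most deleterious (`sMin`, default -10) maps to 1, clipping
#' values outside `[sMin, sMax]`. The map is order-reversing: lower raw
#' score (more deleterious) gives higher normalized impact. The mask is
#' unchanged and the result has role `predicted_normalized`; applying
#' the normalization to an already-normalized landscape is rejected.
#'
#' @param raw a [Landscape-class] with role `teacher` or `predicted_raw`
#' @param sMin,sMax raw score bounds (defaults -10 and 2)
#' @return A [Landscape-class] with role `predicted_normalized`.
#' @examples
#' p <- ProteinRecord("toy", "MK")
#' ls <- Landscape("toy", matrix(-4, 2, 20), role = "teacher",
#'                 sequence = proteinSeq(p))
#' range(scores(normalizeLandscape(ls)), na.rm = TRUE)  # all 0.5
#' @export
normalizeLandscape <- function(raw, sMin = -10, sMax = 2) {
  stopifnot(is(raw, "Landscape"))
  if (sMin >= sMax) stopf("sMin (%g) must be < sMax (%g)", sMin, sMax)
  if (!raw@role %in% c("teacher", "predicted_raw"))
    stopf("can only normalize a teacher or predicted_raw landscape, not '%s'",
          raw@role)
  sc <- (sMax - raw@scores) / (sMax - sMin)
  sc <- pmin(pmax(sc, 0), 1)
  sc[!raw@mask] <- NA_real_
  new("Landscape", proteinId = raw@proteinId, scores = sc,
      mask = raw@mask, role = "predicted_normalized")
}

#' Rank residues by mutation sensitivity
#'
#' For each residue, averages the defined substitution scores in its
#' row, then assigns fractional (tie-averaged) ranks with rank 1 = the
#' most mutation-sensitive residue. For teacher and raw predicted
#' landscapes "more sensitive" means a more negative mean; for
#' normalized landscapes a higher mean; experimental landscapes carry no
#' implied sign convention, so `lowerIsMoreSensitive` must be given.
#'
#' @param ls a [Landscape-class]; every residue needs >= 1 defined cell
#' @param lowerIsMoreSensitive direction override; defaults from role
#' @return A [SensitivityRanking-class].
#' @export
residueSensitivityRanks <- function(ls, lowerIsMoreSensitive = NULL) {
  stopifnot(is(ls, "Landscape"))
  if (is.null(lowerIsMoreSensitive)) {
    lowerIsMoreSensitive <- switch(ls@role,
      teacher = TRUE, predicted_raw = TRUE,
      predicted_normalized = FALSE,
      stopf("direction is ambiguous for an experimental landscape; set 'lowerIsMoreSensitive'"))
  }
  nDefined <- rowSums(ls@mask)
  if (any(nDefined == 0L))
    stopf("residue %d has no defined substitution scores",
          which(nDefined == 0L)[1])
  m <- vapply(seq_len(nrow(ls@scores)), function(i)
    mean(ls@scores[i, ls@mask[i, ]]), numeric(1))
  r <- if (lowerIsMoreSensitive) rank(m) else rank(-m)
  new("SensitivityRanking", proteinId = ls@proteinId,
      perResidueMean = m, ranks = as.numeric(r))
}

#' Per-residue agreement between two sensitivity rankings
#'
#' Labels each residue by the absolute difference between its ranks in
#' the two rankings: `agree` when the difference is below `agreeLt`
#' (default 5), `disagree` when above `disagreeGt` (default 15),
#' `neither` otherwise.
#'
#' @param a,b [SensitivityRanking-class] objects for the same protein
#' @param agreeLt,disagreeGt thresholds on the absolute rank difference
#' @return Factor of length L with levels agree/neither/disagree.
#' @export
rankAgreement <- function(a, b, agreeLt = 5, disagreeGt = 15) {
  stopifnot(is(a, "SensitivityRanking"), is(b, "SensitivityRanking"))
  if (length(a@ranks) != length(b@ranks))
    stopf("rankings have different lengths (%d vs %d)",
          length(a@ranks), length(b@ranks))
  d <- abs(a@ranks - b@ranks)
  labels <- ifelse(d < agreeLt, "agree",
                   ifelse(d > disagreeGt, "disagree", "neither"))
  factor(labels, levels = c("agree", "neither", "disagree"))
}
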