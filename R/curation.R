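# Dataset curation: length filtering (keep 25 <= L <= 1024),
# canonical-residue screening, two-step redundancy reduction (first
# against the test set to prevent leakage, then within the training set)
# and the random 80/20 train/validation split. Each protein is removed
# for exactly one first-matching reason, in that fixed order, so the
# curation report counts always sum to the input size.

#' CurationReport: bookkeeping of the curation pipeline
#'
#' @slot nInput,nTooShort,nTooLong,nNoncanonical,nRedundantVsTest,nRedundantSelf,nKept integer counters; the removal counts plus
#'   `nKept` always sum to `nInput`
#' @aliases CurationReport-class
#' @export
setClass("CurationReport",
  representation(nInput = "integer", nTooShort = "integer",
                 nTooLong = "integer", nNoncanonical = "integer",
                 nRedundantVsTest = "integer", nRedundantSelf = "integer",
                 nKept = "integer"))

setValidity("CurationReport", function(object) {
  total <- object@nTooShort + object@nTooLong + object@nNoncanonical +
    object@nRedundantVsTest + object@nRedundantSelf + object@nKept
  if (total != object@nInput)
    return("removal counts plus kept count must sum to the input count")
  TRUE
})

curationReport <- function(nInput = 0L, nTooShort = 0L, nTooLong = 0L,
                           nNoncanonical = 0L, nRedundantVsTest = 0L,
                           nRedundantSelf = 0L, nKept = 0L) {
  new("CurationReport", nInput = as.integer(nInput),
      nTooShort = as.integer(nTooShort), nTooLong = as.integer(nTooLong),
      nNoncanonical = as.integer(nNoncanonical),
      nRedundantVsTest = as.integer(nRedundantVsTest),
      nRedundantSelf = as.integer(nRedundantSelf),
      nKept = as.integer(nKept))
}

setMethod("show", "CurationReport", function(object) {
  cat(sprintf(paste0(
    "CurationReport: %d in -> %d kept (%d too short, %d too long, ",
    "%d non-canonical, %d redundant vs test, %d self-redundant)\n"),
    object@nInput, object@nKept, object@nTooShort, object@nTooLong,
    object@nNoncanonical, object@nRedundantVsTest, object@nRedundantSelf))
})

#' @describeIn CurationReport report counters as a named integer vector
#' @param x,object a CurationReport
#' @export
setGeneric("reportCounts", function(x) standardGeneric("reportCounts"))

#' @export
setMethod("reportCounts", "CurationReport", function(x) {
  c(n_input = x@nInput, n_too_short = x@nTooShort,
    n_too_long = x@nTooLong, n_noncanonical = x@nNoncanonical,
    n_redundant_vs_test = x@nRedundantVsTest,
    n_redundant_self = x@nRedundantSelf, n_kept = x@nKept)
})

#' Filter proteins by sequence length
#'
#' Keeps records with `minLen <= L <= maxLen` (both bounds inclusive;
#' shorter or longer proteins are removed). Defaults 25 and 1024.
#'
#' @param records list of [ProteinRecord-class]
#' @param minLen,maxLen inclusive length bounds
#' @return List with `kept` (records) and `report`
#'   ([CurationReport-class]).
#' @export
filterByLength <- function(records, minLen = 25, maxLen = 1024) {
  if (minLen > maxLen) stopf("minLen (%d) > maxLen (%d)", minLen, maxLen)
  lens <- vapply(records, seqLength, 1L)
  short <- lens < minLen
  long <- lens > maxLen
  keep <- !short & !long
  list(kept = records[keep],
       report = curationReport(nInput = length(records),
                               nTooShort = sum(short),
                               nTooLong = sum(long), nKept = sum(keep)))
}

#' Screen out sequences with non-canonical residues
#'
#' Drops any sequence containing letters outside the 20-letter
#' canonical alphabet (X, U, B, Z, \code{*}, ...), since neither teacher
#' matrices nor embeddings are defined for them.
#'
#' @param records list of [ProteinRecord-class]
#' @return List with `kept` and `report`.
#' @export
screenCanonical <- function(records) {
  ok <- vapply(records, function(r) isCanonicalSeq(proteinSeq(r)), TRUE)
  list(kept = records[ok],
       report = curationReport(nInput = length(records),
                               nNoncanonical = sum(!ok),
                               nKept = sum(ok)))
}

# Alignment-free identity estimate between two sequences: 1 for exact
# match or containment, otherwise the Jaccard similarity of 6-mer sets
# (0 when either sequence is shorter than k).
sequenceIdentity <- function(a, b, k = 6L) {
  if (a == b) return(1)
  if (nchar(a) >= nchar(b)) { long <- a; short <- b } else { long <- b; short <- a }
  if (grepl(short, long, fixed = TRUE)) return(1)
  if (nchar(short) < k) return(0)
  kmers <- function(s) {
    n <- nchar(s) - k + 1L
    unique(substring(s, seq_len(n), seq_len(n) + k - 1L))
  }
  ka <- kmers(a); kb <- kmers(b)
  length(intersect(ka, kb)) / length(union(ka, kb))
}

#' Two-step redundancy reduction of a training set
#'
#' Step 1 removes every training record whose estimated sequence
#' identity to any test record reaches `identityThreshold` (leakage
#' control). Step 2 greedily clusters the survivors — seeds taken
#' longest-first, ties broken by lexicographic id — and keeps one
#' representative per cluster. The default identity estimate is exact
#' match/containment plus a 6-mer Jaccard similarity; precomputed
#' cluster assignments (e.g. from an external MMseqs2 run) can be
#' injected instead via `clusters`, a data.frame with columns
#' `protein_id` and `cluster_id`, in which case step 2 keeps the first
#' member of each cluster in the step-1 survivor order.
#'
#' @param trainRecords,testRecords lists of [ProteinRecord-class]
#' @param identityThreshold similarity at or above which a pair is
#'   redundant; in (0, 1]
#' @param clusters optional external cluster assignment data.frame
#' @return List with `kept` and `report`.
#' @export
reduceRedundancy <- function(trainRecords, testRecords = list(),
                             identityThreshold = 0.8, clusters = NULL) {
  if (identityThreshold <= 0 || identityThreshold > 1)
    stopf("identityThreshold must be in (0, 1]")
  seqs <- vapply(trainRecords, proteinSeq, "")
  ids <- vapply(trainRecords, proteinId, "")
  testSeqs <- vapply(testRecords, proteinSeq, "")

  vsTest <- vapply(seqs, function(s)
    any(vapply(testSeqs, function(t)
      sequenceIdentity(s, t) >= identityThreshold, TRUE)), TRUE)
  surv <- which(!vsTest)

  if (!is.null(clusters)) {
    if (!all(c("protein_id", "cluster_id") %in% names(clusters)))
      stopf("clusters must have columns protein_id and cluster_id")
    cl <- clusters$cluster_id[match(ids[surv], clusters$protein_id)]
    if (any(is.na(cl)))
      stopf("cluster assignment missing for: %s",
            ids[surv][is.na(cl)][1])
    keepSelf <- surv[!duplicated(cl)]
  } else {
    ord <- surv[order(-nchar(seqs[surv]), ids[surv])]
    reps <- integer(0)
    for (i in ord) {
      dup <- any(vapply(reps, function(r)
        sequenceIdentity(seqs[i], seqs[r]) >= identityThreshold, TRUE))
      if (!dup) reps <- c(reps, i)
    }
    keepSelf <- sort(reps)
  }
  list(kept = trainRecords[keepSelf],
       report = curationReport(
         nInput = length(trainRecords), nRedundantVsTest = sum(vsTest),
         nRedundantSelf = length(surv) - length(keepSelf),
         nKept = length(keepSelf)))
}

#' Run the full curation pipeline
#'
#' Fixed filter order: length, canonical screen, redundancy vs test,
#' self-redundancy. Each protein is counted under the first filter that
#' removes it, so the combined report conserves the input count. The
#' pipeline is idempotent: curating its own output changes nothing.
#'
#' @inheritParams filterByLength
#' @inheritParams reduceRedundancy
#' @return List with `kept` and the combined `report`.
#' @export
curateProteins <- function(records, testRecords = list(), minLen = 25,
                           maxLen = 1024, identityThreshold = 0.8,
                           clusters = NULL) {
  s1 <- filterByLength(records, minLen, maxLen)
  s2 <- screenCanonical(s1$kept)
  s3 <- reduceRedundancy(s2$kept, testRecords, identityThreshold, clusters)
  list(kept = s3$kept,
       report = curationReport(
         nInput = length(records),
         nTooShort = s1$report@nTooShort, nTooLong = s1$report@nTooLong,
         nNoncanonical = s2$report@nNoncanonical,
         nRedundantVsTest = s3$report@nRedundantVsTest,
         nRedundantSelf = s3$report@nRedundantSelf,
         nKept = length(s3$kept)))
}

#' Random train/validation split of protein ids
#'
#' Per-protein partition (no protein contributes residues to both
#' sides): `round(trainFraction * n)` ids go to training, the rest to
#' validation. Deterministic for a fixed seed.
#'
#' @param ids character vector of protein ids
#' @param trainFraction fraction of ids for training (default 0.8)
#' @param seed split seed
#' @return List with `train` and `val` id vectors.
#' @export
splitTrainVal <- function(ids, trainFraction = 0.8, seed = 0) {
  if (length(ids) < 2L) stopf("need at least 2 ids to split")
  if (trainFraction <= 0 || trainFraction >= 1)
    stopf("trainFraction must be in (0, 1)")
  nTrain <- round(trainFraction * length(ids))
  nTrain <- max(1L, min(length(ids) - 1L, nTrain))
  trainIdx <- withSeed(seed, sample.int(length(ids), nTrain))
  list(train = ids[sort(trainIdx)], val = ids[-sort(trainIdx)])
}

#' Pair embeddings with teacher landscapes into training samples
#'
#' For each record, loads the embedding from the store and the teacher
#' matrix `<id>.txt` from `teacherDir`; proteins missing either input,
#' or with inconsistent lengths, are skipped and reported. Each sample
#' is a list with `proteinId`, `embedding` (L x d), `target` (L x 20),
#' `mask` (L x 20) and `confidenceFlag` (TRUE when the teacher
#' landscape is low-confidence, i.e. derived from few homologs).
#'
#' @param records list of [ProteinRecord-class]
#' @param storeDir embedding store directory
#' @param teacherDir directory of teacher matrix files
#' @param lowConfidenceIds ids whose teacher landscapes are flagged
#'   low-confidence
#' @param strictRange passed to [readTeacherMatrix()]
#' @return List with `samples` and `skipped` (data.frame id, reason).
#' @export
assembleDataset <- function(records, storeDir, teacherDir,
                            lowConfidenceIds = character(0),
                            strictRange = TRUE) {
  available <- listEmbeddingIds(storeDir)
  samples <- list()
  skipped <- data.frame(id = character(0), reason = character(0))
  skip <- function(id, why)
    rbind(skipped, data.frame(id = id, reason = why))
  for (rec in records) {
    id <- proteinId(rec)
    tf <- file.path(teacherDir, paste0(id, ".txt"))
    if (!(id %in% available)) {
      skipped <- skip(id, "no embedding"); next
    }
    if (!file.exists(tf)) {
      skipped <- skip(id, "no teacher matrix"); next
    }
    emb <- readEmbedding(storeDir, id)
    if (nrow(emb@values) != seqLength(rec)) {
      skipped <- skip(id, sprintf("embedding L=%d vs sequence L=%d",
                                  nrow(emb@values), seqLength(rec)))
      next
    }
    ls <- tryCatch(readTeacherMatrix(tf, rec, strictRange = strictRange),
                   error = function(e) conditionMessage(e))
    if (is.character(ls)) { skipped <- skip(id, ls); next }
    samples[[length(samples) + 1L]] <- list(
      proteinId = id, embedding = emb@values, target = ls@scores,
      mask = ls@mask, confidenceFlag = id %in% lowConfidenceIds)
  }
  list(samples = samples, skipped = skipped)
}
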