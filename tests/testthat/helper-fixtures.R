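# Shared fixture builders. Everything is generated in code; nothing is
# read from disk except through the package's own writers.

# A landscape with all defined cells set to `value` (self-cells masked).
constantLandscape <- function(protein, value = -1,
                              role = "teacher") {
  Landscape(proteinId(protein),
            matrix(value, seqLength(protein), 20),
            role = role, sequence = proteinSeq(protein))
}

# A small deterministic corpus in memory: records, embeddings, teacher
# landscapes and the planted teacher.
tinyCorpus <- function(n = 8, lengthRange = c(30, 40), d = 16, seed = 42,
                       noiseSd = 0, nonlinearity = "none") {
  records <- genProteins(n, lengthRange, seed)
  embeddings <- genEmbeddings(records, d, seed + 1)
  teacher <- plantedTeacher(d, seed + 2, noiseSd, nonlinearity)
  landscapes <- genTeacherLandscapes(records, embeddings, teacher,
                                     seed + 3)
  list(records = records, embeddings = embeddings, teacher = teacher,
       landscapes = landscapes)
}

corpusSamples <- function(cp, idx = seq_along(cp$records)) {
  mapply(function(r, e, l) list(
    proteinId = proteinId(r), embedding = embValues(e),
    target = scores(l), mask = mask(l), confidenceFlag = FALSE),
    cp$records[idx], cp$embeddings[idx], cp$landscapes[idx],
    SIMPLIFY = FALSE)
}

# Independent fractional-ranking + Pearson oracle for Spearman.
bruteSpearman <- function(x, y) {
  fracRank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v))
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    r
  }
  rx <- fracRank(x); ry <- fracRank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}
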