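# Variant notation, landscape lookup/scoring, normalization and
# sensitivity ranking.

test_that("parseVariant handles single and multi-substitution notation", {
  p <- ProteinRecord("toy", "MKV")
  mv <- parseVariant("M1A", p)
  expect_s4_class(mv, "MultiVariant")
  expect_equal(depth(mv), 1L)
  expect_equal(formatVariant(mv), "M1A")

  mv2 <- parseVariant("M1A:V3L", p)
  expect_equal(depth(mv2), 2L)
  expect_equal(formatVariant(mv2), "M1A:V3L")

  # residue-label convention: letter then 1-based position (e.g. G76)
  long <- ProteinRecord("ubi", paste(c(rep("A", 75), "G", "A"),
                                     collapse = ""))
  g76 <- parseVariant("G76A", long)
  expect_equal(g76@pos, 76L)
  expect_equal(g76@wt, "G")
})

test_that("parseVariant rejects invalid input with informative errors", {
  p <- ProteinRecord("toy", "MKV")
  expect_error(parseVariant("A1C", p), "position 1")      # wt mismatch
  expect_error(parseVariant("M4A", p), "outside")          # out of range
  expect_error(parseVariant("M1M", p), "synonymous")       # wt == mut
  expect_error(parseVariant("M1", p), "malformed")
  expect_error(parseVariant("M1A;V3L", p), "malformed")    # wrong sep
  expect_equal(depth(parseVariant("M1A;V3L", p, sep = ";")), 2L)
})

test_that("parse/format round-trip on random valid variants", {
  set.seed(7)
  p <- ProteinRecord("rnd", paste(sample(AA_ALPHABET, 80, TRUE),
                                  collapse = ""))
  seqchars <- strsplit(proteinSeq(p), "")[[1]]
  for (i in 1:50) {
    k <- sample(1:4, 1)
    pos <- sort(sample(80, k))
    mut <- vapply(pos, function(q)
      sample(setdiff(AA_ALPHABET, seqchars[q]), 1), "")
    mv <- MultiVariant(seqchars[pos], pos, mut)
    back <- parseVariant(formatVariant(mv), p)
    expect_equal(back@wt, mv@wt)
    expect_equal(back@pos, mv@pos)
    expect_equal(back@mut, mv@mut)
  }
})

test_that("landscapeLookup returns cell values and rejects masked cells", {
  p <- ProteinRecord("toy", "MK")
  ls <- constantLandscape(p, value = -1)
  expect_equal(landscapeLookup(ls, parseVariant("M1A", p)), -1)

  sc <- matrix(-1, 2, 20)
  sc[2, 1] <- -3.5  # K2A
  ls2 <- Landscape("toy", sc, role = "teacher", sequence = "MK")
  expect_equal(landscapeLookup(ls2, parseVariant("K2A", p)), -3.5)

  # wild-type self-substitution is masked by construction
  wtCell <- MultiVariant("M", 1L, "K")
  expect_equal(landscapeLookup(ls2, wtCell), -1)
  expect_error(landscapeLookup(ls2, MultiVariant("K", 2L, "A")), NA)
  selfish <- new("MultiVariant", wt = "A", pos = 1L, mut = "M")
  expect_error(landscapeLookup(ls2, selfish), "masked")
})

test_that("scoreMulti is additive, permutation-invariant and linear", {
  p <- ProteinRecord("toy", "MKV")
  sc <- matrix(-1, 3, 20)
  sc[1, match("A", AA_ALPHABET)] <- -1.0
  sc[3, match("L", AA_ALPHABET)] <- -2.5
  ls <- Landscape("toy", sc, role = "teacher", sequence = "MKV")
  mv <- parseVariant("M1A:V3L", p)
  expect_equal(scoreMulti(ls, mv), -3.5)
  expect_equal(scoreMulti(ls, parseVariant("M1A", p)),
               landscapeLookup(ls, parseVariant("M1A", p)))
  # permutation invariance
  expect_equal(scoreMulti(ls, parseVariant("V3L:M1A", p)), -3.5)
  # linearity on random fixtures vs an explicit summation loop
  set.seed(11)
  p2 <- ProteinRecord("rnd", paste(sample(AA_ALPHABET, 50, TRUE),
                                   collapse = ""))
  sc2 <- matrix(runif(50 * 20, -10, 2), 50, 20)
  ls2 <- Landscape("rnd", sc2, role = "teacher",
                   sequence = proteinSeq(p2))
  seqchars <- strsplit(proteinSeq(p2), "")[[1]]
  for (i in 1:20) {
    k <- sample(1:5, 1)
    pos <- sort(sample(50, k))
    mut <- vapply(pos, function(q)
      sample(setdiff(AA_ALPHABET, seqchars[q]), 1), "")
    mv <- MultiVariant(seqchars[pos], pos, mut)
    manual <- 0
    for (j in seq_len(k))
      manual <- manual + scores(ls2)[pos[j], match(mut[j], AA_ALPHABET)]
    expect_equal(scoreMulti(ls2, mv), manual)
  }
})

test_that("normalizeLandscape maps the teacher range linearly onto [0,1]", {
  p <- ProteinRecord("toy", "MKVL")
  sc <- matrix(-4, 4, 20)
  sc[1, 2] <- 2    # teacher maximum -> 0
  sc[2, 3] <- -10  # teacher minimum -> 1
  ls <- Landscape("toy", sc, role = "teacher", sequence = "MKVL")
  nm <- normalizeLandscape(ls)
  expect_equal(landscapeRole(nm), "predicted_normalized")
  expect_equal(scores(nm)[1, 2], 0)
  expect_equal(scores(nm)[2, 3], 1)
  expect_equal(scores(nm)[3, 1], 0.5)  # midpoint -4 -> 0.5
  expect_identical(mask(nm), mask(ls))

  # clipping below the range
  raw <- Landscape("toy", matrix(-12, 4, 20), role = "predicted_raw",
                   sequence = "MKVL")
  expect_true(all(scores(normalizeLandscape(raw))[mask(raw)] == 1))
  # order reversal: lower raw => higher normalized
  set.seed(3)
  raw2 <- Landscape("toy", matrix(rnorm(80, -4, 2), 4, 20),
                    role = "predicted_raw", sequence = "MKVL")
  nm2 <- normalizeLandscape(raw2)
  v <- scores(raw2)[mask(raw2)]; w <- scores(nm2)[mask(nm2)]
  expect_true(all(diff(w[order(v)]) <= 0))
  # applying it twice is rejected (role check), bad bounds rejected
  expect_error(normalizeLandscape(nm2), "teacher or predicted_raw")
  expect_error(normalizeLandscape(raw2, sMin = 2, sMax = -10), "sMin")
})

test_that("residueSensitivityRanks averages rows and tie-averages ranks", {
  p4 <- ProteinRecord("t4", "MKVL")
  expect_equal(ranks(residueSensitivityRanks(constantLandscape(p4))),
               rep(2.5, 4))

  p3 <- ProteinRecord("t3", "MKV")
  sc <- matrix(0, 3, 20)
  sc[1, ] <- -5; sc[2, ] <- -1; sc[3, ] <- -3
  ls <- Landscape("t3", sc, role = "teacher", sequence = "MKV")
  expect_equal(ranks(residueSensitivityRanks(ls)), c(1, 3, 2))

  # direction flips for normalized landscapes (1 = high impact)
  nm <- normalizeLandscape(ls)
  expect_equal(ranks(residueSensitivityRanks(nm)), c(1, 3, 2))

  # experimental landscapes need an explicit direction
  ex <- Landscape("t3", sc, role = "experimental", sequence = "MKV")
  expect_error(residueSensitivityRanks(ex), "lowerIsMoreSensitive")
  expect_equal(ranks(residueSensitivityRanks(ex, TRUE)), c(1, 3, 2))

  # random fixture vs independent sort-then-average-ties oracle
  set.seed(5)
  p50 <- ProteinRecord("t50", paste(sample(AA_ALPHABET, 50, TRUE),
                                    collapse = ""))
  sc50 <- matrix(round(rnorm(1000, -4, 2), 1), 50, 20)
  sc50 <- pmin(pmax(sc50, -10), 2)
  ls50 <- Landscape("t50", sc50, role = "teacher",
                    sequence = proteinSeq(p50))
  sr <- residueSensitivityRanks(ls50)
  means <- vapply(1:50, function(i) {
    row <- scores(ls50)[i, ]; mean(row[mask(ls50)[i, ]])
  }, 1)
  oracle <- rank(means)  # base R fractional ranks as the oracle
  expect_equal(ranks(sr), unname(oracle))
  expect_equal(sum(ranks(sr)), 50 * 51 / 2)
})

test_that("rank agreement labels follow the <5 / >15 thresholds", {
  p <- ProteinRecord("t", paste(rep("AC", 10), collapse = ""))
  mk <- function(v) new("SensitivityRanking", proteinId = "t",
                        perResidueMean = v, ranks = rank(v))
  a <- mk(1:20)
  expect_true(all(rankAgreement(a, a) == "agree"))
  rev <- mk(20:1)
  lab <- rankAgreement(a, rev)
  expect_equal(as.character(lab[1]), "disagree")   # |1 - 20| = 19 > 15
  expect_equal(as.character(lab[10]), "agree")     # |10 - 11| = 1 < 5
  # brute-force threshold loop on random pairs
  set.seed(9)
  for (i in 1:10) {
    x <- mk(rnorm(20)); y <- mk(rnorm(20))
    lab <- rankAgreement(x, y)
    d <- abs(ranks(x) - ranks(y))
    manual <- ifelse(d < 5, "agree", ifelse(d > 15, "disagree", "neither"))
    expect_equal(as.character(lab), manual)
  }
  short <- new("SensitivityRanking", proteinId = "t",
               perResidueMean = 1:3, ranks = rank(1:3))
  expect_error(rankAgreement(a, short), "length")
})

test_that("landscape invariants hold: self-cells masked, roles enforced", {
  p <- ProteinRecord("toy", "MK")
  ls <- constantLandscape(p)
  wt <- c(match("M", AA_ALPHABET), match("K", AA_ALPHABET))
  expect_false(mask(ls)[1, wt[1]])
  expect_false(mask(ls)[2, wt[2]])
  expect_equal(sum(mask(ls)), 38)  # 19 per residue
  expect_error(
    Landscape("bad", matrix(5, 2, 20), role = "teacher", sequence = "MK"),
    "-10")
})
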