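# Curation pipeline: length filter boundaries, canonical screen,
# two-step redundancy reduction, report conservation, split behavior.

randomSeq <- function(L) paste(sample(AA_ALPHABET, L, TRUE), collapse = "")

test_that("length filter keeps [25, 1024] inclusively", {
  set.seed(1)
  recs <- lapply(c(24, 25, 1024, 1025), function(L)
    ProteinRecord(paste0("L", L), randomSeq(L)))
  out <- filterByLength(recs)
  kept <- vapply(out$kept, seqLength, 1L)
  expect_equal(kept, c(25L, 1024L))
  rc <- reportCounts(out$report)
  expect_equal(unname(rc["n_too_short"]), 1L)
  expect_equal(unname(rc["n_too_long"]), 1L)
  expect_equal(unname(rc["n_kept"]), 2L)

  empty <- filterByLength(list())
  expect_equal(length(empty$kept), 0L)
  expect_equal(unname(reportCounts(empty$report)["n_input"]), 0L)
  expect_error(filterByLength(recs, minLen = 100, maxLen = 50), "minLen")

  # random lengths vs the brute-force predicate
  lens <- sample(10:40, 30, TRUE)
  recs2 <- lapply(seq_along(lens), function(i)
    ProteinRecord(paste0("R", i), randomSeq(lens[i])))
  out2 <- filterByLength(recs2, minLen = 20, maxLen = 30)
  expect_equal(vapply(out2$kept, proteinId, ""),
               vapply(recs2[lens >= 20 & lens <= 30], proteinId, ""))
})

test_that("canonical screen drops non-canonical residues", {
  set.seed(2)
  clean <- lapply(1:5, function(i) ProteinRecord(paste0("C", i),
                                                 randomSeq(30)))
  out <- screenCanonical(clean)
  expect_equal(length(out$kept), 5L)

  dirty <- c(clean, list(ProteinRecord("X1", "MKVXLA"),
                         ProteinRecord("U1", "MKVULA")))
  out2 <- screenCanonical(dirty)
  expect_equal(length(out2$kept), 5L)
  expect_equal(unname(reportCounts(out2$report)["n_noncanonical"]), 2L)

  # oracle comprehension
  hasOnly <- vapply(dirty, function(r)
    all(strsplit(proteinSeq(r), "")[[1]] %in% AA_ALPHABET), TRUE)
  expect_equal(vapply(out2$kept, proteinId, ""),
               vapply(dirty[hasOnly], proteinId, ""))
})

test_that("redundancy reduction removes leakage then self-duplicates", {
  set.seed(3)
  test1 <- ProteinRecord("TEST1", randomSeq(40))
  trainDup <- ProteinRecord("TR1", proteinSeq(test1))  # identical to test
  a <- ProteinRecord("TR2", randomSeq(40))
  aCopy <- ProteinRecord("TR3", proteinSeq(a))
  b <- ProteinRecord("TR4", randomSeq(40))

  out <- reduceRedundancy(list(trainDup, a, aCopy, b), list(test1))
  rc <- reportCounts(out$report)
  expect_equal(unname(rc["n_redundant_vs_test"]), 1L)
  expect_equal(unname(rc["n_redundant_self"]), 1L)
  ids <- vapply(out$kept, proteinId, "")
  expect_true("TR4" %in% ids)
  expect_false("TR1" %in% ids)
  expect_equal(sum(c("TR2", "TR3") %in% ids), 1L)

  expect_error(reduceRedundancy(list(a), list(), identityThreshold = 0),
               "identityThreshold")
})

test_that("threshold-1.0 reduction equals hash deduplication", {
  set.seed(4)
  base <- replicate(10, randomSeq(35))
  seqs <- c(base, base[1:4])  # 4 exact duplicates
  recs <- lapply(seq_along(seqs), function(i)
    ProteinRecord(sprintf("P%02d", i), seqs[i]))
  out <- reduceRedundancy(recs, list(), identityThreshold = 1.0)
  expect_equal(length(out$kept), length(unique(seqs)))
  expect_setequal(vapply(out$kept, proteinSeq, ""), unique(seqs))
})

test_that("external cluster assignments drive step 2 when provided", {
  set.seed(5)
  recs <- lapply(1:6, function(i) ProteinRecord(paste0("P", i),
                                                randomSeq(30)))
  cl <- data.frame(protein_id = paste0("P", 1:6),
                   cluster_id = c("a", "a", "b", "b", "b", "c"))
  out <- reduceRedundancy(recs, list(), clusters = cl)
  expect_equal(length(out$kept), 3L)
  expect_error(reduceRedundancy(recs, list(),
                                clusters = cl[1:3, ]), "missing")
})

test_that("full curation conserves counts and is idempotent", {
  set.seed(6)
  recs <- c(
    lapply(1:8, function(i) ProteinRecord(paste0("K", i), randomSeq(30))),
    list(ProteinRecord("SHORT", randomSeq(10)),
         ProteinRecord("LONG", randomSeq(1100)),
         ProteinRecord("BADX", paste0(randomSeq(29), "X"))))
  recs <- c(recs, list(ProteinRecord("DUPK1",
                                     proteinSeq(recs[[1]]))))
  testRecs <- list(ProteinRecord("TESTK2", proteinSeq(recs[[2]])))
  out <- curateProteins(recs, testRecs)
  rc <- reportCounts(out$report)
  expect_equal(unname(rc["n_input"]), 12L)
  expect_equal(unname(rc["n_too_short"]), 1L)
  expect_equal(unname(rc["n_too_long"]), 1L)
  expect_equal(unname(rc["n_noncanonical"]), 1L)
  expect_equal(unname(rc["n_redundant_vs_test"]), 1L)
  expect_equal(unname(rc["n_redundant_self"]), 1L)
  expect_equal(unname(rc["n_kept"]), 7L)
  expect_equal(unname(rc["n_input"]),
               sum(rc[c("n_too_short", "n_too_long", "n_noncanonical",
                        "n_redundant_vs_test", "n_redundant_self",
                        "n_kept")]))

  # idempotence: curating the kept set again changes nothing
  again <- curateProteins(out$kept, testRecs)
  expect_equal(vapply(again$kept, proteinId, ""),
               vapply(out$kept, proteinId, ""))
})

test_that("train/val split is a deterministic disjoint 80/20 partition", {
  ids <- sprintf("P%03d", 1:10)
  sp <- splitTrainVal(ids, 0.8, seed = 1)
  expect_equal(length(sp$train), 8L)
  expect_equal(length(sp$val), 2L)
  expect_length(intersect(sp$train, sp$val), 0L)
  expect_setequal(c(sp$train, sp$val), ids)

  expect_identical(splitTrainVal(ids, 0.8, seed = 1), sp)
  ids100 <- sprintf("Q%03d", 1:100)
  parts <- lapply(1:5, function(s) splitTrainVal(ids100, 0.8, s)$train)
  expect_gt(length(unique(parts)), 1L)
  expect_error(splitTrainVal("one"), "at least 2")
  expect_error(splitTrainVal(ids, 1.2), "trainFraction")
})

test_that("assembleDataset pairs inputs and reports mismatches", {
  cp <- tinyCorpus(n = 3, lengthRange = c(30, 30))
  dir <- withr::local_tempdir()
  store <- file.path(dir, "emb"); teacherDir <- file.path(dir, "teach")
  dir.create(teacherDir)
  writeEmbeddingStore(cp$embeddings, store)
  for (i in 1:3)
    writeTeacherMatrix(cp$landscapes[[i]],
                       file.path(teacherDir,
                                 paste0(proteinId(cp$records[[i]]),
                                        ".txt")))
  out <- assembleDataset(cp$records, store, teacherDir,
                         lowConfidenceIds = proteinId(cp$records[[2]]))
  expect_equal(length(out$samples), 3L)
  expect_equal(nrow(out$skipped), 0L)
  expect_true(out$samples[[2]]$confidenceFlag)
  expect_false(out$samples[[1]]$confidenceFlag)

  # masked-cell count equals NA count + L self cells
  s <- out$samples[[1]]
  expect_equal(sum(!s$mask), 30L)  # zero NA cells + 30 self cells
  expect_equal(dim(s$embedding)[1], dim(s$target)[1])

  # length mismatch -> skip + report
  recs2 <- c(cp$records[1:2],
             list(ProteinRecord(proteinId(cp$records[[3]]),
                                paste0(proteinSeq(cp$records[[3]]),
                                       "A"))))
  out2 <- assembleDataset(recs2, store, teacherDir)
  expect_equal(length(out2$samples), 2L)
  expect_equal(nrow(out2$skipped), 1L)

  # missing teacher file -> skip + report
  file.remove(file.path(teacherDir,
                        paste0(proteinId(cp$records[[1]]), ".txt")))
  out3 <- assembleDataset(cp$records, store, teacherDir)
  expect_equal(out3$skipped$reason[1], "no teacher matrix")
})
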