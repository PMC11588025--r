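# Synthetic fixture generation with planted ground truth. A planted
# teacher maps each residue embedding e to 20 scores W'e + b (optionally
# through a mild bounded squashing), adds Gaussian noise, and clips to
# the teacher range [-10, 2]. With no noise and no squashing the
# resulting corpora are exactly realizable by the linear student, which
# is what the recovery experiments exploit. W is scaled so the affine
# output is roughly N(-4, 1.2): centred in the teacher range and ~5
# standard deviations from both bounds, so clipping is negligible and
# realizability holds in practice.

#' Create a planted synthetic teacher
#'
#' @param d embedding width
#' @param seed seed for drawing W and b
#' @param noiseSd per-cell Gaussian noise sd added to the scores
#' @param nonlinearity "none" for a pure affine teacher or "mild" for a
#'   smooth bounded squashing of the affine output (a tanh centred at
#'   -4 with half-range 6, so scores stay inside (-10, 2))
#' @return List of class `PlantedTeacher` with elements W (d x 20), b,
#'   noiseSd, nonlinearity and scoreBounds.
#' @export
plantedTeacher <- function(d, seed = 0, noiseSd = 0,
                           nonlinearity = c("none", "mild")) {
  nonlinearity <- match.arg(nonlinearity)
  if (d < 1) stopf("d must be positive")
  if (noiseSd < 0) stopf("noiseSd must be >= 0")
  W <- withSeed(seed,
                matrix(stats::rnorm(d * 20L, sd = 1.2 / sqrt(d)), d, 20L))
  structure(list(W = W, b = rep(-4, 20L), noiseSd = noiseSd,
                 nonlinearity = nonlinearity, scoreBounds = c(-10, 2)),
            class = "PlantedTeacher")
}

# Mild squashing: per-column tanh of the affine output, centred at -4
# (the middle of the teacher range) with half-range 6 and a steepness
# that varies across the 20 amino-acid columns (steep columns saturate
# like low-resolution evolutionary landscapes; shallow ones stay nearly
# affine). Keeping every column a
# smooth bounded monotone map of its affine score while varying the
# curvature between columns makes the landscape non-realizable by any
# single linear map (which has to share one slope across columns), so
# the hidden-layer student has something measurable to gain.
MILD_STEEPNESS <- seq(0.5, 2, length.out = 20L)

teacherMap <- function(teacher, E) {
  Z <- E %*% teacher$W +
    matrix(teacher$b, nrow(E), 20L, byrow = TRUE)
  if (teacher$nonlinearity == "mild")
    for (k in seq_len(20L))
      Z[, k] <- -4 + 6 * tanh((Z[, k] + 4) / MILD_STEEPNESS[k])
  Z
}

#' Generate random synthetic proteins
#'
#' Uniform-random sequences over the canonical alphabet with lengths
#' uniform in `lengthRange`; deterministic per seed.
#'
#' @param n number of proteins
#' @param lengthRange inclusive length bounds (default c(30, 100))
#' @param seed generation seed
#' @param prefix id prefix
#' @return List of [ProteinRecord-class].
#' @export
genProteins <- function(n, lengthRange = c(30, 100), seed = 0,
                        prefix = "SYN") {
  if (n < 1) stopf("n must be positive")
  if (length(lengthRange) != 2L || lengthRange[1] > lengthRange[2] ||
      lengthRange[1] < 1)
    stopf("invalid length range")
  withSeed(seed, {
    lens <- lengthRange[1] +
      sample.int(lengthRange[2] - lengthRange[1] + 1L, n,
                 replace = TRUE) - 1L
    lapply(seq_len(n), function(i)
      ProteinRecord(sprintf("%s%04d", prefix, i),
                    paste(sample(AA_ALPHABET, lens[i], replace = TRUE),
                          collapse = "")))
  })
}

#' Generate synthetic residue embeddings
#'
#' i.i.d. standard normal entries, one L x d matrix per protein.
#'
#' @param records list of [ProteinRecord-class]
#' @param d embedding width (default 64 for desk-scale fixtures)
#' @param seed generation seed
#' @param plmName language-model tag recorded in the store
#' @return List of [EmbeddingMatrix-class].
#' @export
genEmbeddings <- function(records, d = 64, seed = 0,
                          plmName = "synthetic-gaussian") {
  if (d < 1) stopf("d must be positive")
  withSeed(seed, {
    lapply(records, function(r)
      EmbeddingMatrix(proteinId(r),
                      matrix(stats::rnorm(seqLength(r) * d),
                             seqLength(r), d),
                      plmName))
  })
}

#' Generate teacher landscapes from planted ground truth
#'
#' Per-residue scores are the planted affine map of the embedding row
#' (optionally squashed), plus i.i.d. Gaussian noise, clipped to
#' [-10, 2]; wild-type self-cells are masked.
#'
#' @param records list of [ProteinRecord-class]
#' @param embeddings matching list of [EmbeddingMatrix-class]
#' @param teacher a [plantedTeacher()] object
#' @param seed noise seed
#' @return List of teacher-role [Landscape-class].
#' @export
genTeacherLandscapes <- function(records, embeddings, teacher, seed = 0) {
  stopifnot(inherits(teacher, "PlantedTeacher"),
            length(records) == length(embeddings))
  withSeed(seed, {
    mapply(function(rec, emb) {
      if (embeddingDim(emb) != nrow(teacher$W))
        stopf("embedding width %d does not match teacher d %d",
              embeddingDim(emb), nrow(teacher$W))
      Z <- teacherMap(teacher, emb@values)
      if (teacher$noiseSd > 0)
        Z <- Z + matrix(stats::rnorm(length(Z), sd = teacher$noiseSd),
                        nrow(Z), ncol(Z))
      Z <- pmin(pmax(Z, teacher$scoreBounds[1]), teacher$scoreBounds[2])
      Landscape(proteinId(rec), Z, role = "teacher",
                sequence = proteinSeq(rec))
    }, records, embeddings, SIMPLIFY = FALSE)
  })
}

#' Generate a synthetic DMS assay from a landscape
#'
#' Samples variants without replacement (single substitutions from the
#' defined cells; deeper variants from distinct positions), scores them
#' additively on the landscape, applies a monotone transform and adds
#' Gaussian measurement noise. At zero noise with the identity
#' transform, the assay correlates perfectly with the landscape.
#'
#' @param ls a [Landscape-class]
#' @param protein the matching [ProteinRecord-class]
#' @param nVariants number of assay entries
#' @param depthDist named numeric vector of depth probabilities, e.g.
#'   c(`1` = 0.8, `2` = 0.2); default all depth 1
#' @param noiseSd measurement noise sd
#' @param transform monotone function applied to the true score
#' @param seed sampling seed
#' @param assayId,phenotype,taxon assay metadata
#' @return A [DMSAssay-class].
#' @export
genAssay <- function(ls, protein, nVariants, depthDist = c(`1` = 1),
                     noiseSd = 0, transform = identity, seed = 0,
                     assayId = NULL, phenotype = "Fitness",
                     taxon = "Synthetic") {
  stopifnot(is(ls, "Landscape"), is(protein, "ProteinRecord"))
  defined <- which(ls@mask)
  if (nVariants > length(defined))
    stopf("cannot sample %d variants from %d defined cells", nVariants,
          length(defined))
  wt <- strsplit(proteinSeq(protein), "")[[1]]
  L <- nrow(ls@scores)
  withSeed(seed, {
    depths <- as.integer(sample(names(depthDist), nVariants,
                                replace = TRUE, prob = depthDist))
    singles <- sample(defined, nVariants)  # without replacement (depth 1)
    variants <- vector("list", nVariants)
    for (i in seq_len(nVariants)) {
      if (depths[i] == 1L) {
        cell <- singles[i]
        pos <- (cell - 1L) %% L + 1L
        mutIdx <- (cell - 1L) %/% L + 1L
        variants[[i]] <- MultiVariant(wt[pos], pos, AA_ALPHABET[mutIdx])
      } else {
        pos <- sort(sample.int(L, depths[i]))
        muts <- vapply(pos, function(p)
          sample(AA_ALPHABET[ls@mask[p, ]], 1L), "")
        variants[[i]] <- MultiVariant(wt[pos], pos, muts)
      }
    }
    true <- vapply(variants, function(v) scoreMulti(ls, v), 1)
    meas <- vapply(true, transform, 1)
    if (noiseSd > 0) meas <- meas + stats::rnorm(nVariants, sd = noiseSd)
    DMSAssay(assayId %||% paste0(proteinId(protein), "_assay"),
             proteinId(protein), variants, meas, phenotype = phenotype,
             taxon = taxon)
  })
}

#' Generate a complete on-disk synthetic corpus
#'
#' One call produces a curation-passing input set: FASTA, embedding
#' store, teacher matrix files, DMS assay CSVs with a metadata sidecar,
#' and a YAML manifest recording all seeds and the planted parameters.
#' Everything is written through the package's own readers/writers, so
#' the corpus doubles as a format round-trip fixture. The returned
#' ground truth carries the planted (W, b) for recovery experiments.
#'
#' @param outDir output directory (created)
#' @param nProteins number of proteins (default 200)
#' @param lengthRange protein length bounds (default c(30, 100))
#' @param d embedding width (default 64)
#' @param noiseSd teacher score noise sd (default 0)
#' @param nonlinearity teacher nonlinearity ("none" or "mild")
#' @param nAssays number of proteins that also get a synthetic assay
#' @param assayNoiseSd assay measurement noise sd
#' @param depthDist assay depth distribution
#' @param seed master seed; sub-generator seeds are derived from it
#' @return Invisibly, a list with `manifest`, `teacher` (planted ground
#'   truth) and the in-memory `records`, `embeddings`, `landscapes`.
#' @export
genCorpus <- function(outDir, nProteins = 200, lengthRange = c(30, 100),
                      d = 64, noiseSd = 0,
                      nonlinearity = c("none", "mild"), nAssays = 5,
                      assayNoiseSd = 0, depthDist = c(`1` = 1), seed = 0) {
  nonlinearity <- match.arg(nonlinearity)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  seeds <- list(proteins = seed, embeddings = seed + 1000L,
                teacher = seed + 2000L, noise = seed + 3000L,
                assays = seed + 4000L)
  records <- genProteins(nProteins, lengthRange, seeds$proteins)
  embeddings <- genEmbeddings(records, d, seeds$embeddings)
  teacher <- plantedTeacher(d, seeds$teacher, noiseSd, nonlinearity)
  landscapes <- genTeacherLandscapes(records, embeddings, teacher,
                                     seeds$noise)

  writeProteinFasta(records, file.path(outDir, "proteins.fasta"))
  writeEmbeddingStore(embeddings, file.path(outDir, "embeddings"))
  teacherDir <- file.path(outDir, "teacher")
  dir.create(teacherDir, showWarnings = FALSE)
  for (i in seq_along(records))
    writeTeacherMatrix(landscapes[[i]],
                       file.path(teacherDir,
                                 paste0(proteinId(records[[i]]), ".txt")))

  assayDir <- file.path(outDir, "assays")
  dir.create(assayDir, showWarnings = FALSE)
  nAssays <- min(nAssays, nProteins)
  phenos <- rep_len(DMS_PHENOTYPES, nAssays)
  meta <- data.frame(assay_id = character(0), protein_id = character(0),
                     phenotype = character(0), taxon = character(0))
  for (i in seq_len(nAssays)) {
    ls <- landscapes[[i]]
    nv <- min(100L, sum(ls@mask))
    assay <- genAssay(ls, records[[i]], nv, depthDist = depthDist,
                      noiseSd = assayNoiseSd, seed = seeds$assays + i,
                      assayId = sprintf("assay%03d", i),
                      phenotype = phenos[i], taxon = "Synthetic")
    writeDMSTable(assay, file.path(assayDir,
                                   paste0(assayId(assay), ".csv")))
    meta <- rbind(meta, data.frame(assay_id = assayId(assay),
                                   protein_id = proteinId(records[[i]]),
                                   phenotype = phenos[i],
                                   taxon = "Synthetic"))
  }
  utils::write.csv(meta, file.path(outDir, "assay_metadata.csv"),
                   row.names = FALSE, quote = FALSE)

  manifest <- list(
    n_proteins = nProteins, length_range = as.list(lengthRange), d = d,
    teacher = list(noise_sd = noiseSd, nonlinearity = nonlinearity,
                   score_bounds = list(-10, 2)),
    n_assays = nAssays, assay_noise_sd = assayNoiseSd,
    seeds = seeds,
    files = list(fasta = "proteins.fasta", embeddings = "embeddings",
                 teacher_dir = "teacher", assay_dir = "assays",
                 metadata = "assay_metadata.csv"))
  yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
  invisible(list(manifest = manifest, teacher = teacher,
                 records = records, embeddings = embeddings,
                 landscapes = landscapes))
}
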