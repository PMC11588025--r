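# mutscape

Predicting complete mutational landscapes of proteins directly from
protein language model (pLM) embeddings, by distilling evolutionary
substitution scores into a shallow student network.

## What it does, and for whom

Deep mutational scans measure variant effects for single proteins;
alignment-based predictors such as GEMME score variants accurately but
need a multiple sequence alignment per protein; pLM log-odds scoring is
alignment-free but slow at proteome scale. `mutscape` implements the
student–teacher shortcut between these worlds, for computational
biologists who want fast, alignment-free substitution scores and a fully
testable training/evaluation pipeline:

* a **student network** `f : R^d -> R^20` maps the embedding `e_i` of
  residue `i` (width `d`; 2560 for the reference ESM-2-style backbone)
  to the scores of all 20 substitutions at that position, giving the
  complete `L x 20` landscape in one forward pass per residue;
* training minimizes the **masked mean squared error**
  `mean((f(e_i)_a - T_{i,a})^2)` over cells where the teacher matrix `T`
  (GEMME-style evolutionary scores in `[-10, 2]`, lower = more
  deleterious) is defined; NA cells and wild-type self-substitutions are
  excluded from numerator and denominator;
* the reference architecture is a one-hidden-layer feed-forward net with
  256 units (660,756 trainable parameters at `d = 2560`, i.e. ~660k);
  linear regression, a two-hidden-layer net, a 1-D convolutional net and
  a two-model ensemble are also provided;
* evaluation against DMS assays uses Spearman rank correlations with
  tie-averaged ranks, grouped means with `±1.96·SE` 95% confidence
  intervals, phenotype-balanced averaging, one-tailed paired t-tests,
  mutation-depth stratification and per-residue sensitivity ranks;
* dataset curation: length filter (keep 25–1024 residues), canonical
  alphabet screen, two-step redundancy reduction (against the test set,
  then within the training set), seeded 80/20 per-protein splits;
* a **synthetic corpus generator** with planted ground truth makes every
  stage testable offline — no downloads, no pretrained model.

## Worked example

Generate a synthetic corpus, curate it, train a student, predict and
evaluate (abridged; see `vignettes/mutscape-methods.Rmd` for the model
details):

```r
library(mutscape)

dir <- file.path(tempdir(), "demo")
genCorpus(dir, nProteins = 40, lengthRange = c(30, 60), d = 32,
          nAssays = 5, seed = 7)

recs <- readProteinFasta(file.path(dir, "proteins.fasta"))
cur  <- curateProteins(recs)
cur$report
#> CurationReport: 40 in -> 40 kept (0 too short, 0 too long,
#>   0 non-canonical, 0 redundant vs test, 0 self-redundant)

asm <- assembleDataset(cur$kept, file.path(dir, "embeddings"),
                       file.path(dir, "teacher"))
ids <- vapply(asm$samples, function(s) s$proteinId, "")
sp  <- splitTrainVal(ids, 0.8, seed = 7)
fit <- trainStudent(
  buildModel(modelConfig("fnn1", inputDim = 32, hiddenSizes = 64L)),
  asm$samples[ids %in% sp$train],
  trainConfig(learningRate = 0.02, batchSize = 256,
              maxEpochs = 120, patience = 20, seed = 7),
  asm$samples[ids %in% sp$val])
min(fit$history$val_loss)
#> best validation masked MSE: 0.004578 after 120 epochs

rec <- recs[[1]]
emb <- readEmbedding(file.path(dir, "embeddings"), proteinId(rec))
raw <- predictLandscape(fit$model, emb, rec)
raw
#> Landscape SYN0001 [predicted_raw]: L=39, 741 defined cells,
#>   range [-8.37, -0.378]

assay <- readDMSTable(file.path(dir, "assays", "assay001.csv"), rec)
evaluateAssay(raw, assay)
#> AssayResult assay001 [Fitness]: rho = 0.9972 over 100 variants (0 dropped)
```

The validation MSE near zero and the per-assay Spearman near 1 are what
a planted, noise-free teacher should give: the student has recovered the
generating map, and the synthetic assay is a monotone function of the
landscape it is scored against. `normalizeLandscape()` rescales raw
scores to the `[0, 1]` impact convention (1 = high functional impact),
and `writePredictions()` emits one CSV row per substitution
(`G76A`-style variant notation).

The same four stages are available as shell workflows via the script in
`inst/cli/`:

```sh
Rscript inst/cli/mutscape.R generate --out corpus --seed 1
Rscript inst/cli/mutscape.R train --fasta corpus/proteins.fasta \
  --embeddings corpus/embeddings --teacher-dir corpus/teacher --out run
Rscript inst/cli/mutscape.R predict --checkpoint run/checkpoint.rds \
  --embeddings corpus/embeddings --fasta corpus/proteins.fasta --out pred \
  --normalize true
Rscript inst/cli/mutscape.R eval --predictions pred --dms-dir corpus/assays \
  --metadata corpus/assay_metadata.csv --fasta corpus/proteins.fasta --out eval
```

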