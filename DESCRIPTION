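Package: mutscape
Title: Mutational Landscape Prediction by Distilling Evolutionary Scores
    from Protein Language Model Embeddings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts complete single-substitution mutational landscapes
    (L x 20 score matrices) for proteins directly from precomputed
    per-residue protein language model embeddings. A shallow student
    network (linear regression, one- or two-hidden-layer feed-forward
    nets, or a 1-D convolutional net) is trained by masked mean squared
    error against teacher matrices of evolutionary substitution scores in
    the GEMME output range [-10, 2]. Includes dataset curation (length
    filtering, canonical-residue screening, two-step redundancy
    reduction, train/validation splitting), readers and writers for
    FASTA, teacher-matrix text files, deep mutational scanning (DMS)
    tables and a per-protein embedding store, a full evaluation suite
    (per-assay Spearman correlations, grouped aggregates with 95%
    confidence intervals, phenotype-balanced means, one-tailed paired
    t-tests, mutation-depth stratification, residue sensitivity ranks),
    and a synthetic corpus generator with planted ground truth so the
    entire pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    yaml,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
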