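Package: drugFlow
Title: Heterogeneous Network Propagation for Drug Response Prediction
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts cancer cell line drug sensitivity by information-flow
    propagation over a heterogeneous network that joins five sub-networks: a
    cell line similarity network (Pearson correlation of expression profiles),
    a drug similarity network (Pearson correlation of chemical descriptors), a
    target-gene similarity network (noisy-OR fusion of degree-normalized
    protein-protein interaction confidences with gene co-expression), the
    known cell line-drug sensitivity matrix and the drug-target interaction
    matrix. Similarity networks are sparsified by a top-fraction absolute
    correlation rank together with a t-test p-value cut. Scores for every cell
    line-drug pair are obtained by iterating a pair of coupled, degree
    normalized propagation updates to convergence. Includes leave-one-out
    cross-validation with per-drug ROC/AUC, percentile retrieval and
    tissue-stratified summaries, and a planted-block synthetic data generator
    so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, yaml, optparse, pROC, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'drugFlow-package.R'
    'AllClasses.R'
    'io_tables.R'
    'similarity.R'
    'target_fusion.R'
    'binarize.R'
    'network.R'
    'propagate.R'
    'evaluate.R'
    'synthetic.R'
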