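Package: goconsensus
Title: Consensus Gene Ontology Annotation by Semantic-Similarity-Guided
    Meta-Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Re-scores gene-term Gene Ontology (GO) annotations produced by
    multiple function-prediction methods and merges them into a single
    consensus set. Candidate annotations are described by their predictor
    probability scores, term information content estimated from a reference
    annotation corpus, and Lin semantic similarity of supporting terms from
    the other methods over the ontology graph; a calibrated boosted-tree
    model re-evaluates every candidate and splits the result into confident
    and rejected annotations. Includes OBO and GAF readers, DAG propagation,
    protein-centric evaluation (precision-recall curves, Fmax, Smin, AUPR,
    bootstrap confidence intervals), re-evaluation transition accounting,
    and a synthetic benchmark generator with controllable per-method error
    structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    jsonlite,
    rpart,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
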