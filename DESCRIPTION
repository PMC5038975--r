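Package: phenosim
Title: Phenotypic Similarity Between Drug Side-Effect and Gene Phenotype Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Scores the phenotypic similarity of drugs and genes by comparing
    drug side-effect profiles with (mouse-derived) gene phenotype profiles
    annotated to a shared multi-parent phenotype ontology. Term specificity is
    measured with an intrinsic, descendant-count based information content;
    term pairs are scored through their most informative common ancestor,
    downweighted by frequency and co-occurrence weights, and aggregated by
    best-match averaging with a top-20 side-effect correction for drug
    polypharmacology. Includes benchmark evaluation (ROC/AUC, precision, lift,
    accuracy), causal side-effect fraction and protein-interaction proximity
    analyses, a synthetic study generator with planted gene-drug ground truth,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
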