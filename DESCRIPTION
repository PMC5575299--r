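Package: xenozyme
Title: Prediction of Gut Bacterial Enzymes Mediating Xenobiotic Biotransformation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts which enzyme class, subclass, specific EC number and
    gut-bacterial species can carry out the first biotransformation step of a
    query drug or xenobiotic molecule. Implements curation of an EC-tagged
    substrate database (cofactor removal, multi-class exclusion, Tanimoto
    redundancy removal), hybrid-fingerprint feature engineering via
    correlation-based feature selection with best-first search, a two-level
    random-forest cascade with class-imbalance upsampling and out-of-bag
    hyperparameter tuning, and a three-fingerprint consensus Tanimoto
    similarity stage that links predictions to bacterial enzymes, genomes and
    taxonomy. Includes a deterministic synthetic-data generator so every stage
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    ChemmineR,
    ChemmineOB,
    randomForest,
    caret,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'ec.R'
    'AllClasses.R'
    'chem-io.R'
    'fingerprints.R'
    'feature-select.R'
    'substrate-db.R'
    'enzyme-db.R'
    'models.R'
    'evaluation.R'
    'similarity.R'
    'pipeline.R'
    'fixtures.R'
    'xenozyme-package.R'
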