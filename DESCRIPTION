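Package: rulepath
Title: Rule-Based Prediction and Evaluation of Microbial Biotransformation Pathways
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts microbial biotransformation pathways of xenobiotic
    compounds by iteratively applying SMIRKS transformation rules, scores
    candidate transformations with a fingerprint k-nearest-neighbour
    relative-reasoning model, and evaluates predicted pathways against
    experimentally observed ones with a depth-weighted multi-generation
    score that does not penalize unreported transient intermediates.
    Also provides a four-part applicability-domain assessment for
    rule-based predictions (compound applicability, functional-group
    coverage, per-transformation reliability and local goodness of fit),
    derivation of linkages between transformation rules and 3rd-level EC
    enzyme classes from EC-annotated reaction corpora, a JSON package
    schema for compounds, rules, reactions, pathways and scenario
    metadata, and a deterministic synthetic-fixture generator that
    emulates observed pathways with collapsed intermediates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    jsonlite,
    igraph,
    ggplot2,
    generics,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC,
    ChemmineOB
SystemRequirements: Python (>= 3.8) with RDKit, available as 'python' on
    the PATH (override via option 'rulepath.python' or env var
    RULEPATH_PYTHON).
Config/testthat/edition: 3
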