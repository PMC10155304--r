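Package: pharmphen
Title: Pharmacophenotyping of ICU Medication Administration Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-level unsupervised pharmacophenotyping of intensive care
    unit medication administration records. Medication orders are
    canonicalized into composite order keys and encoded as a binary
    patient-by-order exposure matrix; a Bernoulli restricted Boltzmann
    machine trained by contrastive divergence groups co-occurring
    medications into pharmacophenotypes (with an explicit unassigned
    bucket); each patient's normalized phenotype distribution is then
    clustered by hierarchical agglomerative clustering, and patient
    clusters are compared pairwise on clinical outcomes with rank-sum and
    Fisher's exact tests under Holm familywise adjustment. A synthetic
    cohort generator with planted medication groups and patient archetypes
    makes every stage testable without access to protected health data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
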