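Package: ejacdyn
Title: Strategic Ejaculate Allocation and Seminal Fluid Proteome Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to analyse strategic ejaculate allocation over sequential
    matings and the accompanying dynamics of the seminal fluid proteome in
    fowl mating trials. Provides AICc-based selection and Akaike-weight
    averaging of mixed-effects models for ejaculation probability and
    sperm/seminal-fluid expenditure; a per-male depletion-prediction test of
    preferential investment in sexually novel females (the Coolidge effect)
    with exact signed-rank inference; compositional spectral-count protein
    quantitation with detectability weights; hierarchical clustering of
    seminal fluid samples with multiscale-bootstrap edge confidence (AU/BP);
    fuzzy c-means clustering of temporal protein profiles with fuzzifier
    estimation and profile classification; hypergeometric set enrichment and
    principal component analysis; and seeded synthetic-data generators with
    known ground truth so every stage has parameter-recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071,
    yaml
Config/testthat/edition: 3
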