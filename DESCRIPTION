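Package: amdmodules
Title: Disease-Module Discovery from Macular Degeneration Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable pipeline for transcriptome disease-module
    discovery in age-related macular degeneration (AMD) cohorts profiled in
    two ocular tissues (RPE-choroid and neural retina). Provides net-intensity
    scaling and quantile normalization, cross-tissue and gender contaminant
    filtering, combinatorial two-class differential expression with
    permutation-adjusted p-values and Storey-Tibshirani q-values, signed
    significance-score matrices clustered into phenotype-specific disease
    modules by consensus clustering, biomarker validation by stratified
    cross-validated classification with a label-permutation null, and
    protein-network connectivity enrichment with interactome assembly under
    source precedence. A synthetic-cohort generator with planted modules,
    contaminants and gender-specific genes makes every stage testable without
    external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    limma,
    igraph,
    e1071,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
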