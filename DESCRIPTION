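Package: pmltcr
Title: TCR Repertoire Diversity, Sharing and Clonal Expansion in Bronchial
    Premalignant Lesions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of T cell receptor (TCR) CDR3 clonotype tables
    assembled from bulk RNA-seq of bronchial premalignant lesion biopsies
    and brushes. Implements repertoire diversity metrics (clonotypes per
    kilo-read, Shannon entropy, Gini-Simpson), mixed-model tests of depth
    dependence and of the association between diversity and an immune
    metagene score, all-pairs clone-sharing enrichment by Fisher's exact
    test with joint FDR control and patient/location/timepoint grouping,
    clonal-expansion calling by a cohort-wide counts-per-thousand threshold
    with a permutation test for recurrent expansion, and public/private
    clonotype classification with antigen-specificity database annotation.
    A synthetic cohort generator with planted ground truth makes every
    stage testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    lme4,
    Matrix,
    stats,
    tibble,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
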