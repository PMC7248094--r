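Package: qmanifold
Title: Information-Geometric Embedding of Categorical Questionnaire Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exploratory analysis of categorical questionnaire data on the
    statistical manifold. Respondent groups are represented by
    non-parametric, factorized estimates of their response distributions,
    mapped to the positive quadrant of the unit hypersphere via square-root
    coordinates, compared with Fisher-Rao (great-circle) distances, and
    embedded in low dimension with classical multidimensional scaling.
    Includes a hypersphere-curve simulation framework with exact ground
    truth for validating the pipeline, multipartite-information (total
    correlation) diagnostics, Procrustes alignment and PCA post-reduction
    of embeddings, and a question-ablation procedure that attributes an
    outlying group to individual questions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    vegan
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
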