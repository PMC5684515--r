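Package: pregcohort
Title: Discovering Pregnancy Cohorts from Short Social-Media Posts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for discovering cohorts of pregnant women
    from short social-media posts. Candidate pregnancy announcements are
    retrieved with a registry of fourteen high-precision query patterns behind
    a seed-term prefilter, false positives are removed with supervised
    classifiers over a hybrid sparse-plus-dense feature representation (word
    n-grams with Porter stemming, summed word embeddings, hierarchical word
    clusters, sentiment lexicon scores, structural features), and the
    resulting user timelines are mined for longitudinal signal: rule-based
    detection of pregnancy-progress statements, estimation of the pregnancy
    start date, trimester categorization of every post, and
    trimester-stratified counts of medication mentions. A seeded synthetic
    generator produces corpora, resource fixtures and timelines with known
    ground truth so that every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    randomForest,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
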