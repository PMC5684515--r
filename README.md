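# pregcohort

Discovering cohorts of pregnant women from short social-media posts, for
pharmacovigilance research.

Pregnancy exposure registries — the standard source of evidence on
medication safety in pregnancy — enroll slowly and selectively. Public
social-media streams contain a complementary signal: women announcing their
own pregnancies ("im 25 weeks pregnant...", "my pregnancy cravings...").
`pregcohort` implements the full pipeline that turns that signal into an
analyzable cohort:

1. **Pattern retrieval.** A seed-term prefilter ("pregnancy", "pregnant",
   "baby", "family", "mom") followed by a registry of 14 high-precision
   query patterns identifies candidate *pregnancy-indicating posts* (PITs),
   with per-pattern provenance and frequency tables.
2. **Supervised filtering.** False positives (third-person announcements,
   figurative "baby", hypothetical futures) are removed by classifiers —
   linear SVM, random forest, Gaussian Naive Bayes baseline, majority-vote
   ensemble — over a hybrid feature vector
   `x = [n-grams | Σ word embeddings | cluster indicators | sentiment | structural]`,
   where the n-gram block holds counts of 1–3-grams of Porter stems and the
   embedding block is the elementwise sum of token vectors.
3. **Longitudinal analysis.** For each cohort member's timeline, a
   rule-based extractor finds progress statements ("6 weeks into the
   pregnancy"), dates the pregnancy start as the median of
   `timestamp − 7 × gestational_week` days over all mentions, assigns every
   post a phase (pre, trimester 1: weeks 1–12, trimester 2: 13–27,
   trimester 3: 28–term, post), and counts medication mentions per
   trimester against a configurable drug lexicon.

Evaluation utilities reproduce the full protocol: stratified splits,
pooled 10-fold cross-validation, per-pattern breakdowns, learning curves
with ROC/AUC, leave-one-out feature ablations, and accuracy with Wilson
95% intervals. A seeded synthetic generator produces corpora, resource
fixtures and timelines with known ground truth, so everything is testable
offline. See the vignette (`vignettes/cohort-discovery.Rmd`) for the
methods and the design decisions.

## Worked example

```r
library(pregcohort)

# 1. retrieval
registry <- compile_pattern_registry()
match_patterns("well... im currently 39 weeks and 6 days pregnant...", registry)
#> [1] 1          # fires pattern 1: first person + time unit + "pregnant"

# 2. a labeled synthetic corpus + fitted resources
corpus <- generate_corpus(n_posts = 2000, seed = 42)
vocab  <- corpus_vocabulary(corpus$text)
paths  <- generate_resource_fixtures(vocab, dim = 8, n_clusters = 20,
                                     seed = 42, dir = tempfile())
split  <- stratified_split(corpus$label, test_fraction = 0.2, seed = 42)
res <- feature_resources(
  vocabulary = fit_ngram_vocabulary(corpus$text[split$train], min_count = 2),
  embeddings = read_word_embeddings(paths["embeddings"]),
  clusters   = read_word_clusters(paths["clusters"]),
  lexicons   = read_sentiment_lexicons(paths["positive"], paths["negative"],
                                       paths["polarity"], paths["subjectivity"]))
x <- featurize_corpus(corpus$text, res)

# 3. train the margin classifier, evaluate held out
model <- fit_classifier(x[split$train, ], corpus$label[split$train],
                        kind = "svm", seed = 42)
pred <- predict(model, x[split$test, ])
evaluate_predictions(pred$label, corpus$label[split$test], pred$score)
#> <evaluation_report> n = 400
#>    class precision recall f1 support
#>  NOT_PIT         1      1  1     124
#>      PIT         1      1  1     276
#> accuracy 1.000 (95% CI 0.990-1.000), AUC 1.000

# 4. timelines: start date, phases, medication counts
ts  <- generate_timeline_set(n_users = 200, seed = 42)
lex <- load_drug_lexicon(system.file("extdata", "example_drug_lexicon.txt",
                                     package = "pregcohort"))
ana <- run_timeline_analysis(ts$posts, lex)
round(ana$detectable_fraction, 3)
#> [1] 0.44
head(ana$summary[ana$summary$detected, ], 3)
#>     user_id detected          start_date n_mentions dispersion_days
#> 2 user00002     TRUE 2016-04-22T00:00:00          2               0
#> 3 user00003     TRUE 2016-01-13T00:00:00          2               0
#> 4 user00004     TRUE 2016-04-11T00:00:00          2               0
```

The held-out report shows the filtering stage separating announcements from
confounders on the default synthetic conditions (the templates have
disjoint filler vocabularies; raise `vocab_overlap` to make the task
harder). `detectable_fraction` is the share of timeline users whose
gestational progress could be dated from their posts — 0.44 by
construction of the generator's defaults — and `dispersion_days = 0` means
each user's progress statements agree exactly on the start date.
`ana$medication_counts` is the drug × trimester mention-count matrix (the
example lexicon is a synthetic stand-in of a dozen common drugs; mentions
are counted, intake is not inferred).

A thin CLI over the same functions ships at `inst/cli/pregcohort`
(subcommands `simulate`, `match`, `detect`, `timeline-analyze`).

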