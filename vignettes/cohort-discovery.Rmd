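---
title: "Discovering pregnancy cohorts from short social-media posts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering pregnancy cohorts from short social-media posts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pregcohort)
```

## The problem

Pregnancy exposure registries — the traditional instruments for studying
medication safety during pregnancy — enroll slowly, cost much, and suffer
from selection bias and loss to follow-up. Public social-media streams offer
a complementary signal: women frequently announce their own pregnancies in
short posts ("im 25 weeks pregnant...", "my pregnancy cravings..."). If such
announcements can be found with high precision, the posting history of each
author becomes a longitudinal record in which gestational timing, medication
mentions and other health chatter can be mined.

`pregcohort` implements that pipeline end to end:

1. **retrieval** — a seed-term prefilter plus a registry of 14
   high-precision query patterns identifies candidate pregnancy-indicating
   posts (*PITs*);
2. **filtering** — supervised classifiers over a hybrid sparse+dense feature
   representation remove false positives (third-person announcements,
   figurative "baby", hypothetical futures);
3. **longitudinal analysis** — a rule-based extractor finds
   pregnancy-progress statements in each author's timeline, estimates the
   pregnancy start date, assigns every post to a phase (pre-pregnancy,
   trimester 1–3, post-pregnancy), and tallies medication mentions per
   trimester.

A seeded synthetic generator emulates all of these phenomena with known
ground truth, so the full pipeline is testable offline, without any access
to a social network.

## Retrieval: seed terms and query patterns

Streaming APIs track broad keywords, not regular expressions, so retrieval
is two-staged: a substring prefilter on the five seed terms ("pregnancy",
"pregnant", "baby", "family", "mom") followed by 14 case-insensitive regular
expressions applied to normalized text (lowercased, typographic apostrophes
mapped to `'`, whitespace collapsed). Every pattern realization contains at
least one seed term, so the prefilter is a necessary condition for any
match — a property the test suite asserts.

The patterns are published as *simplified forms* ("baby & arriving",
"my pregnancy", ...). Realizing them as concrete expressions required three
conventions, all auditable in the shipped config
(`system.file("extdata", "default_patterns.json", package = "pregcohort")`):

* terms joined by `&` must all be present, in any order (lookahead
  conjunction);
* an "exact sequence" allows any run of whitespace or punctuation between
  consecutive terms (`[[:space:][:punct:]]+`);
* pattern 1 — first person + time unit + "pregnant" — is realized as a
  conjunction of its three term groups in **any order**, with the time-unit
  list extended to `day|days`, and no digit required before the unit.
  The ordered reading (`im ... weeks ... pregnant`) misses documented
  retrievals in which the first-person marker follows the word "pregnant"
  ("... five weeks and three days pregnant. I'm going to be an auntie ...");
  deployed queries in this setting are known to have varied slightly around
  the simplified forms, and the conjunction reading reproduces the full
  documented retrieval set while remaining first-person-anchored.

`scan_corpus()` additionally collapses exact duplicates (same user, same
normalized text) to the earliest timestamp — retweet noise — and can
optionally drop posts with fewer than 80% of characters in the printable
Latin-1 range (encoding-broken or non-English posts; off by default because
such filtering was a manual step in the original workflow).

```{r}
registry <- compile_pattern_registry()
match_patterns("well... im currently 39 weeks and 6 days pregnant...",
               registry)
```

## Features

A post is represented as the fixed-order concatenation of five blocks:

| block | content | length |
|---|---|---|
| `ngram` | counts of 1–3-grams of Porter stems | vocabulary size |
| `embedding` | elementwise sum of token embedding vectors | embedding dim (400 for the published tweet vectors) |
| `cluster` | binary indicators of occupied word clusters | number of clusters (1000 for the published tweet clusters) |
| `sentiment` | six lexicon summaries | 6 |
| `structural` | six shape features | 6 |

Decisions that the published description leaves open, frozen here for
reproducibility:

* **Tokenizer.** Split on whitespace, strip surrounding (not internal)
  punctuation, keep contractions whole ("i'm" is one token — it is part of
  the retrieval vocabulary), keep hashtags and @-mentions as single tokens
  with the marker stripped and flagged.
* **Stems vs surface forms.** n-grams are built over Porter stems; embedding
  and cluster lookups use raw surface tokens, because published embedding
  and cluster resources are keyed by surface form. The Porter stemmer is
  implemented in full (no stemming package is assumed) and validated against
  the canonical worked examples of the algorithm.
* **Vocabulary pruning.** `min_count = 2` by default; indices are assigned
  lexicographically so the layout is reproducible.
* **Sentiment block (6 slots).** positive-term count, negative-term count,
  prior-polarity sum, prior-polarity mean over matched tokens (0 when no
  match), subjectivity-polarity sum, subjectivity-strength sum. The three
  lexicon families mirror the standard trio (polar term lists, prior
  polarities, subjectivity); the exact statistics are this package's choice
  and are configurable by supplying different lexicons.
* **Structural block (6 slots).** word count, character count, sentence
  count (split on runs of `.!?`), mean sentence length in words,
  punctuation-character count, uppercase ratio. Ratios are 0 when undefined.
* **Scaling.** Margin-based training is scale-sensitive, so the dense
  blocks (embedding, sentiment, structural) are standardized with means and
  standard deviations estimated **on the training data only**; count blocks
  are left raw. This happens inside `fit_classifier()` and is stored with
  the model.

Stopwords are kept everywhere (both in n-grams and in the embedding sum);
synonym expansion is deliberately not implemented.

## Classifiers

Four kinds share one interface (`fit_classifier()` / `predict()`):

* **SVM** (the production choice): linear kernel, cost 1, class weights
  proportional to inverse class frequency — annotated announcement corpora
  are imbalanced roughly 7:3 toward the positive class.
* **Random forest**: 100 trees, `sqrt(p)` features per split, seeded.
* **Naive Bayes** (baseline): Gaussian event model over the full vector —
  dense blocks can be negative, so a multinomial model does not apply.
  Within-class standard deviations are floored at 0.05 (variance
  smoothing): without it, features that are constant within one class
  contribute unbounded density spikes and the posterior degenerates.
* **Ensemble**: majority voting over an odd number (≥ 3) of members;
  the built-in default trains {NB, SVM, RF}. (The original ensemble also
  contained a convolutional network; deep models are out of scope here, and
  the voting machinery accepts any odd set of fitted members.)

Scores are oriented so that larger always means "more announcement-like":
signed margin (SVM), positive-vote fraction (RF), positive posterior (NB).
No probability calibration is performed; ROC analysis uses the raw scores.
All fitting is deterministic given the seed.

## Evaluation protocol

`evaluate_predictions()` reports per-class precision/recall/F1, accuracy
with a **Wilson score** 95% interval (the interval method is this package's
choice; it behaves well at the sample sizes and accuracies typical here),
and ROC/AUC from a threshold sweep over distinct scores. The sweep equals
the pairwise probability-of-correct-ranking estimator (ties counted half);
the test suite verifies this equivalence by brute force, and against an
independent ROC implementation.

Cross-validation (`cross_validate()`) uses stratified folds and **pools**
out-of-fold predictions before computing metrics, rather than averaging
per-fold metrics — pooled metrics compose exactly into the per-pattern
breakdown (`per_pattern_evaluation()`), where a post retrieved by several
patterns counts toward each.

`learning_curve()` trains on **nested** stratified subsets (the 10% subset
is contained in the 20% subset, and so on, under one seed), mirroring an
annotation campaign that grows by increments and reducing between-fraction
variance. `ablation_study()` re-runs cross-validation with each feature
block removed in turn and with each block alone, identifying blocks by the
column-name prefixes that `featurize()` writes.

## Trimester inference

The gestational timeline is segmented as: trimester 1 = weeks 1–12,
trimester 2 = weeks 13–27, trimester 3 = week 28 to birth, term length 40
weeks. `assign_trimester()` implements exactly this boundary rule
(week 12 → 1, week 13 → 2, week 27 → 2, week 28 → 3).

Progress statements ("6 weeks into the pregnancy", "i am 25 weeks
pregnant") are found by a windowed co-occurrence rule around the seed terms
"pregnant"/"pregnancy". Open points resolved as explicit, configurable
decisions:

* **Window.** "Symmetric context window of size 6" is read as 6 tokens on
  each side (`window_mode = "per_side"`); the reading "6 tokens in total"
  is selectable.
* **Numbers.** Digit strings, digit ordinals ("25th"), and number words
  one–forty (including compounds) are accepted; the number is paired with
  the nearest following unit term.
* **Unit priority.** A week pair wins over month and day pairs in the same
  window; a day pair alongside a week pair contributes `days/7`
  ("39 weeks and 6 days" → 39.86). Months convert at 4.345 weeks/month
  (365.25/12/7); day-only phrasings are accepted only in "since/been"-style
  wordings, where they plausibly measure elapsed pregnancy time.
* **Range.** Converted weeks outside [1, 45] are discarded as implausible.
* **Hashtag forms.** "#37weekspregnant" is recovered only when
  `segment_hashtags = TRUE` (digit/letter and unit-word splitting); off by
  default because the base rule set does not describe hashtag handling.

`estimate_pregnancy_start()` dates each mention back by 7 × gestational-week
days and takes the **median** candidate, reporting the median absolute
deviation in days. The median (rather than, say, the earliest or latest
mention) is robust to joke and quoted mentions; the dispersion lets callers
drop unreliable estimates. This robustness layer is an extension beyond the
original rule set, motivated by the observation that naive categorization
was accurate only about half the time. Phases are then assigned from
elapsed weeks since the estimated start: `pre` below week 1, `T1`–`T3` per
the boundary rule, `post` beyond the term length. Birth-event detection is
out of scope; the 40-week term is the post-birth boundary.

```{r}
tl <- data.frame(id = "p1", user_id = "u1",
                 created_at = "2016-06-01T12:00:00",
                 text = "i am 25 weeks pregnant today")
est <- estimate_pregnancy_start(tl)
est
```

## Medication mentions

`count_drug_mentions()` counts tokens equal (case-insensitively) to a
lexicon surface form, in posts whose phase is a trimester; pre- and
post-pregnancy posts are ignored. Matching is exact token equality — no
fuzzy matching; variant lists are the extension point. Counts are counts of
*mentions*: no claim about actual intake is made, since only a fraction of
drug mentions in timelines describe consumption. The shipped example
lexicon is a synthetic stand-in (a dozen common drugs); the real medication
set of interest is supplied by the user.

## The synthetic generator as study conditions

`generate_corpus()` emulates the retrieved-post mixture: announcement
templates co-designed with the 14 patterns (sampled with weights following
the published relative retrieval frequencies, where "my pregnancy" and the
first-person time pattern dominate) versus three confounder families —
third-person pregnancies, figurative "baby", hypothetical futures — the
documented false-positive modes. Defaults are fixed once as the study
conditions: 2000 posts, announcement fraction 0.69 (the composition of the
14,156-post annotated corpus: 9819 true announcements), lexical noise
(hashtags, emoticons, stretched words) at rate 0.1, and disjoint
filler vocabularies (`vocab_overlap = 0`; raising it degrades separability,
which the tests exploit). Exactly `round(n_posts × pit_fraction)` posts are
announcements, so class counts are not subject to binomial noise.

`generate_timeline_set()` emulates cohort timelines: 1000 users, each with
a true start date; exactly `round(n_users × 0.44)` of them post progress
statements at known integer weeks (the 44% default mirrors the fraction of
cohort timelines in which trimester information was detectable in
practice); drug mentions are planted mid-trimester for those users.
Progress posts sit at exact completed-week offsets from the true start
(`jitter_days = 0` by default): "X weeks pregnant" carries no sub-week
information, so exact offsets make the planted truth recoverable exactly
and parameter-recovery failures attributable to the extractor rather than
to unidentifiable jitter.

What the generator does **not** emulate — and hence what green tests do not
show about real data: misspellings and creative orthography beyond the
simple noise model, sarcasm and quotation, announcements phrased outside
the 14 patterns (recall of the pattern stage is not measurable here),
inconsistent or deceptive progress statements, and the ~50% real-world
error rate of naive trimester categorization. Results on the synthetic
conditions are upper bounds on rule/classifier correctness, not estimates
of real-world performance.

## Problem sizes and numerical choices

The test suite and the acceptance script run the classifier recovery at
n = 2000 posts (80/20 split) and timeline recovery at 1000 users — sizes at
which the stochastic bounds asserted (held-out announcement-class F1 ≥
0.95, start-date error ≤ 3 days, exact phase and drug-count recovery,
detectable fraction within ±2% of the planted prevalence) are stable across
seeds while keeping a full run in the low minutes on one CPU. Other
numerical conventions: Wilson intervals at 95%; ROC ties grouped (one point
per distinct score); SVM decision values sign-oriented to the positive
class; random-forest vote ties (exactly 0.5) resolved to the negative
class for determinism; empty-input conventions (empty text → empty token
sequence, ratio features 0 when undefined) chosen so that degenerate posts
never error out of a corpus run.

## Limitations

Beyond the synthetic-realism caveats above: the pattern registry is
English-specific and platform-tuned (short posts); the trimester rules
assume first-person present-tense progress statements; medication matching
is lexicon-bound; and no attempt is made to infer demographics, detect
birth outcomes, or distinguish mention from intake — all deliberately out
of scope.
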