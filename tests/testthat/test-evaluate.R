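test_that("stratified split preserves class proportions within rounding", {
  y <- c(rep("PIT", 60), rep("NOT_PIT", 40))
  sp <- stratified_split(y, test_fraction = 0.2, seed = 2)
  expect_equal(sum(y[sp$test] == "PIT"), 12L)
  expect_equal(sum(y[sp$test] == "NOT_PIT"), 8L)
  expect_setequal(c(sp$train, sp$test), seq_along(y))
  expect_length(intersect(sp$train, sp$test), 0)
  # balanced data, half split
  yb <- rep(c("PIT", "NOT_PIT"), each = 50)
  sb <- stratified_split(yb, 0.5, seed = 4)
  expect_equal(table(yb[sb$test]), table(yb[sb$train]))
  # determinism
  expect_identical(stratified_split(y, 0.2, seed = 9),
                   stratified_split(y, 0.2, seed = 9))
  expect_error(stratified_split(c("PIT", "NOT_PIT"), 0.2, 1), "2 members")
})

test_that("evaluation reproduces hand-computed confusion metrics", {
  gold <- c(rep("PIT", 10), rep("NOT_PIT", 10))
  pred <- c(rep("PIT", 8), rep("NOT_PIT", 2), rep("NOT_PIT", 8), rep("PIT", 2))
  rep_ <- evaluate_predictions(pred, gold)
  pit <- rep_$per_class[rep_$per_class$class == "PIT", ]
  expect_equal(pit$precision, 0.8)
  expect_equal(pit$recall, 0.8)
  expect_equal(pit$f1, 0.8)
  expect_equal(rep_$accuracy, 0.8)
  expect_gte(rep_$accuracy, rep_$accuracy_ci["low"])
  expect_lte(rep_$accuracy, rep_$accuracy_ci["high"])
})

test_that("perfect predictions give unit metrics", {
  gold <- c(rep("PIT", 5), rep("NOT_PIT", 5))
  rep_ <- evaluate_predictions(gold, gold, scores = c(rep(1, 5), rep(0, 5)))
  expect_true(all(rep_$per_class[c("precision", "recall", "f1")] == 1))
  expect_equal(rep_$accuracy, 1)
  expect_equal(rep_$auc, 1)
})

test_that("evaluation rejects mismatched lengths and single-class gold", {
  expect_error(evaluate_predictions(c("PIT"), c("PIT", "NOT_PIT")), "length")
  expect_error(evaluate_predictions(c("PIT", "PIT"), c("PIT", "PIT")),
               "single class")
})

test_that("uninformative scores give AUC one half and a sane ROC shape", {
  gold <- rep(c("PIT", "NOT_PIT"), 10)
  sweep <- roc_sweep(gold, rep(0.3, 20))
  expect_equal(sweep$auc, 0.5)
  pts <- sweep$points
  expect_equal(unlist(pts[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(pts[nrow(pts), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
})

test_that("swept AUC equals the pairwise-ranking estimator on random inputs", {
  set.seed(55)
  for (trial in 1:40) {
    n <- sample(10:200, 1)
    gold <- sample(c("PIT", "NOT_PIT"), n, replace = TRUE)
    if (length(unique(gold)) < 2) next
    scores <- round(stats::rnorm(n), sample(c(0, 1, 3), 1))  # induce ties
    expect_equal(roc_sweep(gold, scores)$auc, auc_pairwise(gold, scores))
  }
})

test_that("swept AUC agrees with an external ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(66)
  gold <- sample(c("PIT", "NOT_PIT"), 150, replace = TRUE)
  scores <- stats::rnorm(150) + (gold == "PIT")
  ours <- roc_sweep(gold, scores)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(
    response = gold, predictor = scores, levels = c("NOT_PIT", "PIT"),
    direction = "<", quiet = TRUE)))
  expect_equal(ours, theirs)
})

test_that("Wilson interval contains the point estimate and shrinks like 1/sqrt(n)", {
  w100 <- wilson_ci(80, 100)
  w10000 <- wilson_ci(8000, 10000)
  expect_true(w100["low"] <= 0.8 && 0.8 <= w100["high"])
  ratio <- diff(w100) / diff(w10000)
  expect_gt(ratio, 8); expect_lt(ratio, 12)
})

test_that("cross-validation folds partition the data and separate the corpus", {
  fix <- small_corpus_resources(n = 120, seed = 31)
  y <- fix$corpus$label
  folds <- stratified_folds(y, k = 4, seed = 3)
  expect_equal(sort(unique(folds)), 1:4)
  expect_length(folds, length(y))
  expect_identical(folds, stratified_folds(y, k = 4, seed = 3))
  cv <- cross_validate(fix$x, y, k = 2, kind = "svm", seed = 5)
  expect_gte(cv$report$accuracy, 0.97)
  expect_error(stratified_folds(c("a", "a", "b"), k = 2), "k members")
})

test_that("per-pattern metrics pool to the overall confusion", {
  fix <- small_corpus_resources(n = 120, seed = 31)
  y <- fix$corpus$label
  pid <- ifelse(is.na(fix$corpus$template_pattern_id), 99L,
                fix$corpus$template_pattern_id)
  tab <- per_pattern_evaluation(fix$x, y, as.list(pid), k = 4, seed = 5)
  expect_true(all(tab$f1 >= 0 & tab$f1 <= 1))
  # single-membership patterns partition the set, so n sums to the corpus
  expect_equal(sum(tab$n), length(y))
  # single-pattern corpus: per-pattern F1 equals overall F1
  one <- per_pattern_evaluation(fix$x, y, as.list(rep(1L, length(y))),
                                k = 4, seed = 5)
  cv <- attr(one, "cv")
  expect_equal(one$f1, class_f1(cv$report))
  expect_error(per_pattern_evaluation(fix$x, y, rep(list(integer(0)),
                                                    length(y))),
               "at least one")
})

test_that("a pattern whose instances defy the majority rule scores zero F1", {
  # labels follow one feature except within pattern B, whose instances are
  # deliberately mislabeled; the classifier learns the dominant rule
  set.seed(8)
  n <- 100
  f <- rep(c(1, 0), each = n / 2)
  x <- cbind(ngram.signal = f + stats::rnorm(n, 0, 0.01),
             ngram.noise = stats::rnorm(n))
  y <- ifelse(f == 1, "PIT", "NOT_PIT")
  pattern <- c(rep("A", 80), rep("B", 20))
  y[pattern == "B"] <- ifelse(f[pattern == "B"] == 1, "NOT_PIT", "PIT")
  tab <- per_pattern_evaluation(x, y, as.list(pattern), k = 5, seed = 2)
  expect_equal(tab$f1[tab$pattern_id == "A"], 1)
  expect_equal(tab$f1[tab$pattern_id == "B"], 0)
})

test_that("learning curve at fraction 1 equals a direct train-on-all run", {
  fix <- small_corpus_resources(n = 160, seed = 31)
  y <- fix$corpus$label
  sp <- stratified_split(y, 0.25, seed = 7)
  lc <- learning_curve(fix$x[sp$train, ], y[sp$train],
                       fix$x[sp$test, ], y[sp$test],
                       fractions = c(0.2, 0.6, 1.0), seed = 13)
  model <- fit_classifier(fix$x[sp$train, ], y[sp$train], seed = 13)
  p <- predict(model, fix$x[sp$test, ])
  direct <- evaluate_predictions(p$label, y[sp$test], p$score)
  expect_equal(lc$accuracy[lc$fraction == 1], direct$accuracy)
  expect_equal(lc$auc[lc$fraction == 1], direct$auc)
  # subset sizes are round(fraction * class size) summed over classes
  cls <- table(y[sp$train])
  expect_equal(lc$n_train,
               vapply(c(0.2, 0.6, 1.0),
                      function(f) sum(round(f * cls)), numeric(1)))
})

test_that("more training data does not hurt AUC on the template corpus", {
  aucs <- sapply(1:3, function(s) {
    fix <- small_corpus_resources(n = 160, seed = 30 + s, overlap = 0.5)
    y <- fix$corpus$label
    sp <- stratified_split(y, 0.25, seed = s)
    lc <- learning_curve(fix$x[sp$train, ], y[sp$train],
                         fix$x[sp$test, ], y[sp$test],
                         fractions = c(0.1, 1.0), seed = s)
    diff(lc$auc)
  })
  expect_gte(mean(aucs), 0)
})

test_that("ablation reproduces the full-feature cross-validation and ranks blocks", {
  fix <- small_corpus_resources(n = 120, seed = 31)
  y <- fix$corpus$label
  tab <- ablation_study(fix$x, y, k = 3, seed = 5)
  cv_all <- cross_validate(fix$x, y, k = 3, seed = 5)
  expect_equal(tab$f1[tab$configuration == "all"], class_f1(cv_all$report))
  # labels are carried by the template vocabulary, so n-grams alone must
  # beat structural features alone
  expect_gt(tab$f1[tab$configuration == "ngram"],
            tab$f1[tab$configuration == "structural"])
  ngram_only <- cross_validate(
    fix$x[, pregcohort:::feature_block_of(colnames(fix$x)) == "ngram"],
    y, k = 3, seed = 5)
  expect_equal(tab$f1[tab$configuration == "ngram"],
               class_f1(ngram_only$report))
})
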