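make_seq <- function(tokens, stems = tokens) {
  s <- tokenize(paste(tokens, collapse = " "))
  s$stems <- stems  # override when a test wants explicit stems
  s
}

test_that("vocabulary over one three-stem document has 3+2+1 grams", {
  seq <- make_seq(c("i", "am", "pregnant"))
  vocab <- fit_ngram_vocabulary(list(seq), min_count = 1)
  expect_equal(length(vocab$gram_to_index), 6L)
  expect_true(all(c("i", "am pregnant", "i am pregnant") %in%
                    names(vocab$gram_to_index)))
})

test_that("vocabulary edge cases: min_count too high, duplicate documents, empty corpus", {
  seq <- make_seq(c("a1", "b2"))
  expect_warning(v <- fit_ngram_vocabulary(list(seq), min_count = 99),
                 "empty")
  expect_equal(length(v$gram_to_index), 0L)
  v1 <- fit_ngram_vocabulary(list(seq), min_count = 1)
  v2 <- fit_ngram_vocabulary(list(seq, seq), min_count = 1)
  expect_equal(names(v1$gram_to_index), names(v2$gram_to_index))
  expect_error(fit_ngram_vocabulary(list()), "empty")
})

test_that("ngram_vector counts in-vocabulary grams and ignores the rest", {
  vocab <- fit_ngram_vocabulary(list(make_seq(c("babi", "babi"))),
                                min_count = 1)
  v <- ngram_vector(make_seq(c("babi", "babi")), vocab)
  expect_equal(unname(v[["babi"]]), 2)
  expect_true(all(ngram_vector(make_seq(character(0)), vocab) == 0))
  expect_true(all(ngram_vector(make_seq(c("zq8", "qx9")), vocab) == 0))
})

test_that("vectorizer agrees with a brute-force enumerator on random sequences", {
  set.seed(401)
  alphabet <- c("am", "pregnant", "babi", "week", "so", "the", "love", "due")
  for (trial in 1:200) {
    stems <- sample(alphabet, sample(0:12, 1), replace = TRUE)
    seq <- list(tokens = stems, stems = stems)
    class(seq) <- "token_seq"
    vocab <- fit_ngram_vocabulary(list(make_seq(sample(alphabet, 8,
                                                       replace = TRUE))),
                                  min_count = 1)
    v <- ngram_vector(seq, vocab)
    brute <- table(brute_force_ngrams(stems))
    for (g in names(vocab$gram_to_index)) {
      expect_identical(unname(v[[g]]),
                       as.numeric(if (g %in% names(brute)) brute[[g]] else 0))
    }
  }
})

embedding_fixture <- function() {
  mat <- rbind(love = c(1, 2, -1), baby = c(0.5, -0.5, 2))
  pregcohort:::new_embedding_table(mat)
}

test_that("embedding block sums token vectors and is additive", {
  tab <- embedding_fixture()
  expect_equal(unname(embed_post(make_seq("love"), tab)), c(1, 2, -1))
  expect_equal(unname(embed_post(make_seq(c("love", "baby"), ), tab)),
               c(1.5, 1.5, 1))
  expect_equal(embed_post(make_seq(c("zzz", "qqq")), tab), numeric(3))
  # additivity over concatenation
  s1 <- make_seq(c("love", "zzz")); s2 <- make_seq(c("baby", "love"))
  s12 <- make_seq(c("love", "zzz", "baby", "love"))
  expect_equal(embed_post(s12, tab),
               embed_post(s1, tab) + embed_post(s2, tab))
})

test_that("cluster block is binary with one bit per occupied cluster", {
  map <- structure(list(n_clusters = 300L,
                        token_to_cluster = c(love = 17L, baby = 17L,
                                             week = 245L)),
                   class = "cluster_map")
  v <- cluster_vector(make_seq(c("love", "baby", "week")), map)
  expect_equal(which(v == 1), c(17L, 245L))
  expect_true(all(v %in% c(0, 1)))
  expect_true(all(cluster_vector(make_seq("zzz"), map) == 0))
  one <- cluster_vector(make_seq(c("love", "baby")), map)
  expect_equal(sum(one), 1)
})

lexicon_fixture <- function() {
  structure(list(positive = "love", negative = "hate",
                 prior_polarity = c(love = 0.8, hate = -0.6),
                 subjectivity = list(polarity = c(love = 1, hate = -1),
                                     strength = c(love = 0.9, hate = 0.7))),
            class = "sentiment_lexicons")
}

test_that("sentiment block counts polar terms and aggregates scores", {
  lex <- lexicon_fixture()
  v <- sentiment_scores(make_seq(c("love", "love", "hate")), lex)
  expect_equal(unname(v[c("pos_count", "neg_count")]), c(2, 1))
  expect_equal(unname(v[["polarity_sum"]]), 0.8 + 0.8 - 0.6)
  expect_equal(unname(v[["polarity_mean"]]), (0.8 + 0.8 - 0.6) / 3)
  expect_equal(unname(v[["subj_strength_sum"]]), 0.9 + 0.9 + 0.7)
  expect_true(all(sentiment_scores(make_seq(character(0)), lex) == 0))
  expect_true(all(sentiment_scores(make_seq(c("the", "cat")), lex) == 0))
})

test_that("structural block measures words, characters and sentences", {
  v <- structural_features("Hello world.")
  expect_equal(unname(v[c("word_count", "char_count", "sentence_count",
                          "mean_sentence_words")]),
               c(2, 12, 1, 2))
  expect_equal(unname(structural_features("A! B!")[["sentence_count"]]), 2)
  expect_true(all(structural_features("") == 0))
})

test_that("featurize concatenates blocks in fixed order and honors ablation", {
  fix <- small_corpus_resources(n = 60, seed = 21)
  res <- fix$resources
  text <- fix$corpus$text[1]
  full <- featurize(text, res)
  V <- length(res$vocabulary$gram_to_index)
  D <- res$embeddings$dimension
  C <- res$clusters$n_clusters
  expect_equal(length(full), V + D + C + 6 + 6)
  blocks <- pregcohort:::feature_block_of(names(full))
  expect_equal(rle(blocks)$values,
               c("ngram", "embedding", "cluster", "sentiment", "structural"))
  # block-wise equality
  seq <- tokenize(text)
  expect_equal(unname(full[blocks == "ngram"]),
               unname(ngram_vector(seq, res$vocabulary)))
  expect_equal(unname(full[blocks == "embedding"]),
               unname(embed_post(seq, res$embeddings)))
  # ablation identity
  only <- featurize(text, res, blocks = "ngram")
  expect_equal(unname(only), unname(ngram_vector(seq, res$vocabulary)))
  # determinism
  expect_identical(full, featurize(text, res))
})

test_that("feature length is invariant across a corpus", {
  fix <- small_corpus_resources(n = 60, seed = 21)
  expect_equal(length(unique(apply(fix$x, 1, length))), 1L)
  expect_true(all(fix$x[, pregcohort:::feature_block_of(colnames(fix$x)) ==
                          "ngram"] >= 0))
})

test_that("resource files round-trip through their readers", {
  paths <- generate_resource_fixtures(
    c("love", "baby", "week", "due", "bump", "glow", "cat", "dog", "sun",
      "sky"),
    dim = 5, n_clusters = 4, seed = 99, dir = withr::local_tempdir())
  expect_equal(readLines(paths["embeddings"], n = 1L), "10 5")
  emb <- read_word_embeddings(paths["embeddings"])
  expect_equal(emb$dimension, 5L)
  expect_equal(nrow(emb$vectors), 10L)
  clu <- read_word_clusters(paths["clusters"])
  expect_true(all(clu$token_to_cluster <= clu$n_clusters))
  expect_setequal(names(clu$token_to_cluster), rownames(emb$vectors))
  lex <- read_sentiment_lexicons(paths["positive"], paths["negative"],
                                 paths["polarity"], paths["subjectivity"])
  expect_length(intersect(lex$positive, lex$negative), 0)
})

test_that("fixture generation is seed-deterministic", {
  p1 <- generate_resource_fixtures(c("aa", "bb", "cc"), dim = 3,
                                   n_clusters = 2, seed = 5,
                                   dir = withr::local_tempdir())
  p2 <- generate_resource_fixtures(c("aa", "bb", "cc"), dim = 3,
                                   n_clusters = 2, seed = 5,
                                   dir = withr::local_tempdir())
  for (nm in names(p1)) {
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]))
  }
})

test_that("fitted resources survive the archive round trip", {
  fix <- small_corpus_resources(n = 60, seed = 21)
  path <- withr::local_tempfile(fileext = ".json")
  save_feature_resources(fix$resources, path)
  res2 <- load_feature_resources(path)
  text <- fix$corpus$text[5]
  expect_equal(featurize(text, res2), featurize(text, fix$resources))
})
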