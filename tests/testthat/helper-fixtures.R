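# Shared fixtures, built in code once per test run.

# the 20 annotated sample texts used for pattern-coverage checks: first 14
# are true announcements (at least one per query), last 6 false positives
sample_announcement_texts <- function() {
  c("one month today (give or take) I am going to be a mom...I can not wait to see what my baby girl looks like :-)",
    "So I thought I would let Twitter know that I am expecting a baby in eight months!!!",
    "this belly and the sweet baby growing inside is the best christmas gift I could ever ask for!!! Merry Christmas e...",
    "been 3 weeks since I've heard bebes heart or seen it. So sometimes I don't feel pregnant but this new stretch mark is proving otherwise",
    "Just s few short months from adding another one to our family!",
    "Ready for Christmas and pumped to announce that baby boy **** will be arriving May 2017! #MC3",
    "Pregnancy announcement Our family is growing by 2 feet and 1 heart",
    "Hoping & praying for a solution to income issues. Baby coming soon! Need better #job & better #pay",
    "i literally cannot wrap my head around the fact that I am going to have a baby in 16 days or less..",
    "so I am having a baby and super excited",
    "swear since I have been pregnant everyone's forgot about me and doesn't involve me in anything",
    "well... im currently 39 weeks and 6 days pregnant... you can come any time now sweetie",
    "i just took my pregnancy cravings to a whole new level: I put ranch on my macaroni and cheese. #Yummmmmmmm",
    "i'm so crafty since I’ve been pregnant before I couldn't even color a rainbow.",
    "forever amazed at the number of women that ask me when I am going to have a baby instead of asking me about my career goals.",
    "i swear I’ve been pregnant for 2 years now. #theobesityneedstostop #ineedwine",
    "I'm having a baby JB day and it's killing me. I love him so much @justinbieber",
    "my sister is five weeks and three days pregnant. I’m going to be an auntie oh my god",
    "girls will be two days pregnant already posting pictures talking bout “I’m getting big.”",
    "Cant believe im having a baby brother!")
}

# small labeled corpus + fitted resources, cached across tests
fixture_cache <- new.env(parent = emptyenv())

small_corpus_resources <- function(n = 300, seed = 11, overlap = 0) {
  key <- sprintf("corpus_%d_%d_%s", n, seed, overlap)
  if (!is.null(fixture_cache[[key]])) return(fixture_cache[[key]])
  corpus <- generate_corpus(n_posts = n, seed = seed, vocab_overlap = overlap)
  vocab <- corpus_vocabulary(corpus$text)
  paths <- generate_resource_fixtures(vocab, dim = 6, n_clusters = 15,
                                      seed = seed,
                                      dir = file.path(tempdir(), key))
  res <- feature_resources(
    vocabulary = fit_ngram_vocabulary(corpus$text, min_count = 2),
    embeddings = read_word_embeddings(paths["embeddings"]),
    clusters = read_word_clusters(paths["clusters"]),
    lexicons = read_sentiment_lexicons(paths["positive"], paths["negative"],
                                       paths["polarity"],
                                       paths["subjectivity"]))
  x <- featurize_corpus(corpus$text, res)
  out <- list(corpus = corpus, resources = res, x = x, paths = paths)
  fixture_cache[[key]] <- out
  out
}

# brute-force n-gram enumerator, independent of the vectorizer
brute_force_ngrams <- function(stems, orders = 1:3) {
  out <- character(0)
  for (k in orders) {
    if (length(stems) >= k) {
      for (i in seq_len(length(stems) - k + 1)) {
        out <- c(out, paste(stems[i:(i + k - 1)], collapse = " "))
      }
    }
  }
  out
}

# direct transcription of the Fleiss agreement formula over a count matrix
fleiss_kappa_direct <- function(labels_matrix) {
  m <- as.matrix(labels_matrix)
  cats <- sort(unique(as.vector(m)))
  N <- nrow(m); r <- ncol(m)
  counts <- sapply(cats, function(ct) rowSums(m == ct))
  counts <- matrix(counts, nrow = N)
  P_i <- (rowSums(counts^2) - r) / (r * (r - 1))
  P_bar <- mean(P_i)
  p_j <- colSums(counts) / (N * r)
  P_e <- sum(p_j^2)
  (P_bar - P_e) / (1 - P_e)
}

make_timeline <- function(user_id, texts, times) {
  data.frame(id = sprintf("%s_p%02d", user_id, seq_along(texts)),
             user_id = user_id,
             created_at = format(as.POSIXct(times, tz = "UTC"),
                                 "%Y-%m-%dT%H:%M:%S"),
             text = texts, stringsAsFactors = FALSE)
}
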