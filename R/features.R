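#' Fit the n-gram vocabulary
#'
#' Collects all 1-, 2- and 3-grams of Porter stems over a training corpus and
#' keeps those occurring at least \code{min_count} times. Index assignment is
#' deterministic (lexicographic over the gram strings), so the same corpus
#' always yields the same column layout.
#'
#' @param corpus list of \code{token_seq} objects (or character texts, which
#'   are tokenized first).
#' @param min_count minimum corpus frequency for a gram to enter the
#'   vocabulary; default 2 (controls sparsity).
#' @param orders integer n-gram orders; default \code{1:3}.
#' @return an object of class \code{ngram_vocabulary}: list with
#'   \code{gram_to_index} (named integer vector, 1-based dense indices),
#'   \code{order_range}, \code{fitted_on} (corpus digest).
#' @export
fit_ngram_vocabulary <- function(corpus, min_count = 2L, orders = 1:3) {
  if (length(corpus) == 0L) stop("cannot fit a vocabulary on an empty corpus")
  seqs <- lapply(corpus, function(x) if (inherits(x, "token_seq")) x else tokenize(x))
  grams <- unlist(lapply(seqs, function(s) stem_ngrams(s$stems, orders)),
                  use.names = FALSE)
  tab <- table(grams)
  kept <- sort(names(tab)[tab >= min_count])
  if (!length(kept)) {
    warning("min_count = ", min_count,
            " exceeds every gram frequency; vocabulary is empty")
  }
  digest <- sprintf("n%d-g%d", length(seqs), length(grams))
  new_ngram_vocabulary(kept, as.integer(orders), digest)
}

new_ngram_vocabulary <- function(grams, orders, fitted_on) {
  structure(list(gram_to_index = stats::setNames(seq_along(grams), grams),
                 order_range = orders,
                 fitted_on = fitted_on),
            class = "ngram_vocabulary")
}

#' @export
print.ngram_vocabulary <- function(x, ...) {
  cat("<ngram_vocabulary> ", length(x$gram_to_index), " grams, orders ",
      paste(range(x$order_range), collapse = "-"), "\n", sep = "")
  invisible(x)
}

stem_ngrams <- function(stems, orders = 1:3) {
  n <- length(stems)
  out <- character(0)
  for (k in orders) {
    if (n >= k) {
      idx <- seq_len(n - k + 1L)
      gram <- stems[idx]
      if (k > 1L) for (j in 2:k) gram <- paste(gram, stems[idx + j - 1L])
      out <- c(out, gram)
    }
  }
  out
}

#' n-gram count block
#'
#' Counts of each in-vocabulary stem n-gram; out-of-vocabulary grams are
#' ignored.
#'
#' @param seq a \code{token_seq}.
#' @param vocab an \code{ngram_vocabulary}.
#' @return named numeric vector of length \code{length(vocab$gram_to_index)}.
#' @export
ngram_vector <- function(seq, vocab) {
  v <- numeric(length(vocab$gram_to_index))
  names(v) <- names(vocab$gram_to_index)
  grams <- stem_ngrams(seq$stems, vocab$order_range)
  hit <- vocab$gram_to_index[grams]
  hit <- hit[!is.na(hit)]
  if (length(hit)) {
    tab <- table(hit)
    v[as.integer(names(tab))] <- as.numeric(tab)
  }
  v
}

#' Summed embedding block
#'
#' The dense representation of a post is the elementwise sum of the embedding
#' vectors of its tokens (raw surface tokens, not stems; stopwords included).
#' Tokens absent from the table contribute nothing; a post with no in-table
#' token maps to the zero vector.
#'
#' @param seq a \code{token_seq}.
#' @param table an \code{embedding_table}.
#' @return numeric vector of length \code{table$dimension}.
#' @export
embed_post <- function(seq, table) {
  stopifnot(table$dimension > 0L)
  idx <- match(seq$tokens, rownames(table$vectors))
  idx <- idx[!is.na(idx)]
  if (!length(idx)) return(numeric(table$dimension))
  colSums(table$vectors[idx, , drop = FALSE])
}

#' Binary word-cluster block
#'
#' Position c is 1 iff some token of the post maps to cluster c. Lookup is on
#' the raw token, matching how published cluster resources are keyed.
#'
#' @param seq a \code{token_seq}.
#' @param map a \code{cluster_map}.
#' @return 0/1 numeric vector of length \code{map$n_clusters}.
#' @export
cluster_vector <- function(seq, map) {
  v <- numeric(map$n_clusters)
  idx <- map$token_to_cluster[seq$tokens]
  idx <- idx[!is.na(idx)]
  v[unique(idx)] <- 1
  v
}

sentiment_slot_names <- c("pos_count", "neg_count", "polarity_sum",
                          "polarity_mean", "subj_polarity_sum",
                          "subj_strength_sum")

#' Sentiment score block
#'
#' A fixed 6-slot summary over the three lexicon families: positive-term
#' count, negative-term count, sum of prior-polarity scores, mean
#' prior-polarity over matched tokens (0 when no token matches), sum of
#' subjectivity polarity, sum of subjectivity strength.
#'
#' @param seq a \code{token_seq}.
#' @param lex a \code{sentiment_lexicons}.
#' @return named numeric vector of length 6.
#' @export
sentiment_scores <- function(seq, lex) {
  tok <- seq$tokens
  pol <- lex$prior_polarity[tok]
  pol <- pol[!is.na(pol)]
  sp <- lex$subjectivity$polarity[tok]
  ss <- lex$subjectivity$strength[tok]
  out <- c(
    sum(tok %in% lex$positive),
    sum(tok %in% lex$negative),
    sum(pol),
    if (length(pol)) mean(pol) else 0,
    sum(sp, na.rm = TRUE),
    sum(ss, na.rm = TRUE)
  )
  stats::setNames(as.numeric(out), sentiment_slot_names)
}

structural_slot_names <- c("word_count", "char_count", "sentence_count",
                           "mean_sentence_words", "punct_count",
                           "uppercase_ratio")

#' Structural feature block
#'
#' Shape features of the raw (unnormalized) text: word count, character
#' count, sentence count (split on runs of \code{. ! ?}), mean sentence length
#' in words, punctuation-character count, and the uppercase-character ratio.
#' Ratios are 0 when undefined (empty text).
#'
#' @param text a single raw text string.
#' @return named numeric vector of length 6.
#' @export
#' @examples
#' structural_features("Hello world.")
structural_features <- function(text) {
  stopifnot(length(text) == 1L)
  if (is.na(text) || !nzchar(text)) {
    return(stats::setNames(numeric(6), structural_slot_names))
  }
  words <- strsplit(trimws(text), "\\s+")[[1]]
  words <- words[nzchar(words)]
  sentences <- strsplit(text, "[.!?]+")[[1]]
  sentences <- trimws(sentences)
  sentences <- sentences[nzchar(sentences)]
  sent_words <- vapply(sentences, function(s) {
    length(strsplit(trimws(s), "\\s+")[[1]])
  }, numeric(1), USE.NAMES = FALSE)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  out <- c(
    length(words),
    nchar(text),
    length(sentences),
    if (length(sent_words)) mean(sent_words) else 0,
    sum(grepl("[[:punct:]]", chars)),
    mean(grepl("[A-Z]", chars))
  )
  stats::setNames(as.numeric(out), structural_slot_names)
}

feature_block_names <- c("ngram", "embedding", "cluster", "sentiment",
                         "structural")

#' Featurize a post
#'
#' Deterministic concatenation of the five feature blocks in fixed order:
#' n-gram counts, summed embeddings, binary cluster indicators, sentiment
#' scores, structural features. Individual blocks can be disabled (for
#' ablation runs) via \code{blocks}; a disabled block contributes no columns.
#' Column names are prefixed with the block name, which is how downstream
#' scaling and ablation identify blocks.
#'
#' @param post a raw text string, or a list/row with a \code{text} field.
#' @param resources a \code{feature_resources} bundle; each enabled block
#'   needs its resource present.
#' @param blocks character subset of
#'   \code{c("ngram", "embedding", "cluster", "sentiment", "structural")}.
#' @return named numeric feature vector.
#' @export
featurize <- function(post, resources,
                      blocks = feature_block_names) {
  text <- if (is.character(post)) post else post$text
  blocks <- match.arg(blocks, feature_block_names, several.ok = TRUE)
  seq <- tokenize(text)
  parts <- list()
  if ("ngram" %in% blocks) {
    stopifnot(!is.null(resources$vocabulary))
    parts$ngram <- ngram_vector(seq, resources$vocabulary)
  }
  if ("embedding" %in% blocks) {
    stopifnot(!is.null(resources$embeddings))
    v <- embed_post(seq, resources$embeddings)
    parts$embedding <- stats::setNames(v, sprintf("d%03d", seq_along(v)))
  }
  if ("cluster" %in% blocks) {
    stopifnot(!is.null(resources$clusters))
    v <- cluster_vector(seq, resources$clusters)
    parts$cluster <- stats::setNames(v, sprintf("c%04d", seq_along(v)))
  }
  if ("sentiment" %in% blocks) {
    stopifnot(!is.null(resources$lexicons))
    parts$sentiment <- sentiment_scores(seq, resources$lexicons)
  }
  if ("structural" %in% blocks) {
    parts$structural <- structural_features(text)
  }
  out <- unlist(lapply(names(parts), function(b) {
    stats::setNames(parts[[b]], paste(b, names(parts[[b]]), sep = "."))
  }))
  if (is.null(out)) numeric(0) else out
}

#' Featurize a corpus into a matrix
#'
#' Row-binds [featurize()] over a vector of texts. All rows share the layout
#' fixed by the resources, so the matrix is suitable for classifier training.
#'
#' @param texts character vector of raw post texts.
#' @inheritParams featurize
#' @return numeric matrix, one row per text.
#' @export
featurize_corpus <- function(texts, resources,
                             blocks = feature_block_names) {
  stopifnot(length(texts) > 0L)
  rows <- lapply(texts, featurize, resources = resources, blocks = blocks)
  mat <- do.call(rbind, rows)
  rownames(mat) <- NULL
  mat
}

#' Block membership of feature columns
#'
#' @param colnames character vector of feature column names (block-prefixed).
#' @return character vector of block names per column.
#' @keywords internal
feature_block_of <- function(colnames) {
  sub("\\..*$", "", colnames)
}
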