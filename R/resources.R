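#' Read a word-embedding table (word2vec text format)
#'
#' Expects the standard text format: a header line \code{"V D"} followed by
#' one line per token: the token and D whitespace-separated floats.
#'
#' @param path path to the embedding file.
#' @return an object of class \code{embedding_table}: list with
#'   \code{dimension} and \code{vectors} (numeric matrix, one row per token,
#'   rownames = tokens).
#' @export
read_word_embeddings <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty embedding file: ", path)
  header <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(header) != 2L || anyNA(header)) {
    stop("malformed word2vec header in ", path)
  }
  v <- header[1]; d <- header[2]
  body <- lines[-1]
  if (length(body) != v) {
    stop("embedding file declares ", v, " vectors but has ", length(body))
  }
  parts <- strsplit(trimws(body), "\\s+")
  tokens <- vapply(parts, `[[`, character(1), 1L)
  mat <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(d)))
  rownames(mat) <- tokens
  new_embedding_table(mat)
}

new_embedding_table <- function(mat) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  structure(list(dimension = ncol(mat), vectors = mat),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat("<embedding_table> ", nrow(x$vectors), " tokens, dimension ",
      x$dimension, "\n", sep = "")
  invisible(x)
}

#' Read a hierarchical word-cluster table
#'
#' Tab-separated lines \code{bitstring-path<TAB>token<TAB>frequency}. The
#' cluster index of a token is the rank (1-based) of its distinct bitstring
#' path in file order; \code{n_clusters} is the number of distinct paths.
#'
#' @param path path to the cluster file.
#' @return an object of class \code{cluster_map}: list with \code{n_clusters}
#'   and \code{token_to_cluster} (named integer vector).
#' @export
read_word_clusters <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty cluster file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(parts) >= 2L
  if (!all(ok)) stop("malformed cluster line(s) in ", path)
  paths <- vapply(parts, `[[`, character(1), 1L)
  tokens <- vapply(parts, `[[`, character(1), 2L)
  idx <- match(paths, unique(paths))
  token_to_cluster <- stats::setNames(as.integer(idx), tokens)
  token_to_cluster <- token_to_cluster[!duplicated(tokens)]
  structure(list(n_clusters = length(unique(paths)),
                 token_to_cluster = token_to_cluster),
            class = "cluster_map")
}

#' @export
print.cluster_map <- function(x, ...) {
  cat("<cluster_map> ", length(x$token_to_cluster), " tokens in ",
      x$n_clusters, " clusters\n", sep = "")
  invisible(x)
}

#' Read sentiment lexicons
#'
#' Three lexicon families feed the sentiment feature block:
#' \enumerate{
#'   \item polar term lists: plain text, one token per line, for positive and
#'     negative terms (the two sets must be disjoint);
#'   \item prior polarity: tab-separated \code{token<TAB>score};
#'   \item subjectivity: tab-separated
#'     \code{token<TAB>polarity<TAB>strength}.
#' }
#'
#' @param positive_path,negative_path paths to the polar term lists.
#' @param polarity_path path to the prior-polarity file.
#' @param subjectivity_path path to the subjectivity file.
#' @return an object of class \code{sentiment_lexicons}.
#' @export
read_sentiment_lexicons <- function(positive_path, negative_path,
                                    polarity_path, subjectivity_path) {
  pos <- unique(tolower(trimws(readLines(positive_path, warn = FALSE))))
  neg <- unique(tolower(trimws(readLines(negative_path, warn = FALSE))))
  pos <- pos[nzchar(pos)]; neg <- neg[nzchar(neg)]
  overlap <- intersect(pos, neg)
  if (length(overlap)) {
    stop("positive and negative lexicons overlap: ",
         paste(utils::head(overlap, 5), collapse = ", "))
  }
  pol <- utils::read.delim(polarity_path, header = FALSE,
                           col.names = c("token", "score"),
                           stringsAsFactors = FALSE)
  subj <- utils::read.delim(subjectivity_path, header = FALSE,
                            col.names = c("token", "polarity", "strength"),
                            stringsAsFactors = FALSE)
  stopifnot(all(is.finite(pol$score)),
            all(is.finite(subj$polarity)), all(is.finite(subj$strength)))
  structure(list(
    positive = pos,
    negative = neg,
    prior_polarity = stats::setNames(pol$score, tolower(pol$token)),
    subjectivity = list(
      polarity = stats::setNames(subj$polarity, tolower(subj$token)),
      strength = stats::setNames(subj$strength, tolower(subj$token)))
  ), class = "sentiment_lexicons")
}

#' @export
print.sentiment_lexicons <- function(x, ...) {
  cat("<sentiment_lexicons> ", length(x$positive), " positive, ",
      length(x$negative), " negative, ",
      length(x$prior_polarity), " polarity-scored, ",
      length(x$subjectivity$polarity), " subjectivity-scored tokens\n",
      sep = "")
  invisible(x)
}

#' Bundle fitted feature resources
#'
#' Collects the fitted n-gram vocabulary and loaded lookup resources into one
#' object consumed by [featurize()]. Any component may be \code{NULL}; the
#' corresponding feature block is then unavailable.
#'
#' @param vocabulary an \code{ngram_vocabulary} from [fit_ngram_vocabulary()].
#' @param embeddings an \code{embedding_table}.
#' @param clusters a \code{cluster_map}.
#' @param lexicons a \code{sentiment_lexicons}.
#' @return an object of class \code{feature_resources}.
#' @export
feature_resources <- function(vocabulary = NULL, embeddings = NULL,
                              clusters = NULL, lexicons = NULL) {
  structure(list(vocabulary = vocabulary, embeddings = embeddings,
                 clusters = clusters, lexicons = lexicons),
            class = "feature_resources")
}

#' Save / load fitted feature resources
#'
#' Serializes the resource bundle to a single JSON archive (a versioned,
#' text-only model-resource file) and restores it bit-identically.
#'
#' @param resources a \code{feature_resources} object.
#' @param path archive path.
#' @return \code{load_feature_resources}: the restored bundle.
#' @export
save_feature_resources <- function(resources, path) {
  payload <- list(
    format = "pregcohort-resources",
    version = 1L,
    vocabulary = if (!is.null(resources$vocabulary)) list(
      order_range = resources$vocabulary$order_range,
      grams = names(resources$vocabulary$gram_to_index),
      fitted_on = resources$vocabulary$fitted_on),
    embeddings = if (!is.null(resources$embeddings)) list(
      tokens = rownames(resources$embeddings$vectors),
      vectors = unname(apply(resources$embeddings$vectors, 1, identity,
                             simplify = FALSE))),
    clusters = if (!is.null(resources$clusters)) list(
      n_clusters = resources$clusters$n_clusters,
      tokens = names(resources$clusters$token_to_cluster),
      index = unname(resources$clusters$token_to_cluster)),
    lexicons = if (!is.null(resources$lexicons)) list(
      positive = resources$lexicons$positive,
      negative = resources$lexicons$negative,
      polarity_tokens = names(resources$lexicons$prior_polarity),
      polarity_scores = unname(resources$lexicons$prior_polarity),
      subj_tokens = names(resources$lexicons$subjectivity$polarity),
      subj_polarity = unname(resources$lexicons$subjectivity$polarity),
      subj_strength = unname(resources$lexicons$subjectivity$strength))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_feature_resources
#' @export
load_feature_resources <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(p$format, "pregcohort-resources")) {
    stop("not a pregcohort resource archive: ", path)
  }
  vocab <- if (!is.null(p$vocabulary)) {
    new_ngram_vocabulary(p$vocabulary$grams,
                         as.integer(p$vocabulary$order_range),
                         p$vocabulary$fitted_on)
  }
  emb <- if (!is.null(p$embeddings)) {
    v <- p$embeddings$vectors
    mat <- if (is.matrix(v)) v else do.call(rbind, v)
    rownames(mat) <- p$embeddings$tokens
    new_embedding_table(mat)
  }
  clu <- if (!is.null(p$clusters)) {
    structure(list(n_clusters = as.integer(p$clusters$n_clusters),
                   token_to_cluster = stats::setNames(
                     as.integer(p$clusters$index), p$clusters$tokens)),
              class = "cluster_map")
  }
  lex <- if (!is.null(p$lexicons)) {
    structure(list(
      positive = as.character(p$lexicons$positive),
      negative = as.character(p$lexicons$negative),
      prior_polarity = stats::setNames(as.numeric(p$lexicons$polarity_scores),
                                       p$lexicons$polarity_tokens),
      subjectivity = list(
        polarity = stats::setNames(as.numeric(p$lexicons$subj_polarity),
                                   p$lexicons$subj_tokens),
        strength = stats::setNames(as.numeric(p$lexicons$subj_strength),
                                   p$lexicons$subj_tokens))),
      class = "sentiment_lexicons")
  }
  feature_resources(vocab, emb, clu, lex)
}
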