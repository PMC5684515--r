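#' @title Query-pattern registry for pregnancy-announcement retrieval
#'
#' @description
#' Candidate pregnancy-indicating posts are retrieved in two stages: a cheap
#' seed-term prefilter (mirroring keyword tracking against a streaming API)
#' followed by a registry of 14 case-insensitive regular expressions, each the
#' realization of one high-precision announcement pattern. Every realized
#' expression operates on [normalize_text()] output.
#'
#' The default registry realizes the published simplified forms as follows:
#' \itemize{
#'   \item terms joined by \code{&} (any order) become lookahead conjunctions;
#'   \item "exact sequence with whitespace or punctuations in between" becomes
#'     terms in order separated by \code{[[:space:][:punct:]]+};
#'   \item pattern 1 (first-person + time unit + "pregnant") is realized as a
#'     conjunction of the three term groups in any order, with the time-unit
#'     list extended to \code{day|days}. The deployed queries varied slightly
#'     around the simplified forms, and announcement word order in practice is
#'     free ("... days pregnant. i'm ..."); the ordered reading misses
#'     documented retrievals, so the conjunction reading is the default. No
#'     digit is required before the time unit.
#' }
#' The full table ships as a JSON config (see
#' \code{system.file("extdata", "default_patterns.json", package =
#' "pregcohort")}) so users can audit or override every expression.
#'
#' @name pattern_registry
NULL

#' Default seed terms
#'
#' Broad keywords used to prefilter the post stream before any regular
#' expression is tested: "pregnancy", "pregnant", "baby", "family", "mom".
#'
#' @return character vector of lowercase seed terms.
#' @export
default_seed_terms <- function() {
  c("pregnancy", "pregnant", "baby", "family", "mom")
}

# simplified forms as printed; realized expressions per the rules above
default_pattern_table <- function() {
  seq_punct <- function(...) paste(c(...), collapse = "[[:space:][:punct:]]+")
  conj <- function(...) paste0(vapply(list(...), function(p)
    paste0("(?=.*", p, ")"), character(1)), collapse = "")
  im <- "\\b(im|i am|i'm)\\b"
  data.frame(
    pattern_id = 1:14,
    simplified_form = c(
      "(im|i am|i'm).*[time].*pregnant",
      "baby & arriving",
      "baby coming soon",
      "been.*[time] & since & i & pregnant",
      "growing & baby & belly",
      "(im|i am|i'm) expecting.*baby",
      "(im|i am|i'm) going to (b|be) a mom",
      "(im|i am|i'm) having a baby",
      "i (hav|have) been pregnant",
      "(ive|i've) been pregnant",
      "adding & one & \"our family\"",
      "my pregnancy",
      "(im|i am|i'm) going to have a baby",
      "our family.*growing.*(2|two) feet"
    ),
    realized_expression = c(
      conj(im, "\\b(week|weeks|month|months|day|days)\\b", "\\bpregnant\\b"),
      conj("\\bbaby\\b", "\\barriving\\b"),
      paste0("\\b", seq_punct("baby", "coming", "soon"), "\\b"),
      conj("\\bbeen\\b.*\\b(day|days|week|weeks|month|months)\\b",
           "\\bsince\\b", "\\bi\\b", "\\bpregnant\\b"),
      conj("\\bgrowing\\b", "\\bbaby\\b", "\\bbelly\\b"),
      paste0(im, "[[:space:][:punct:]]+expecting\\b.*\\bbaby\\b"),
      paste0(im, "[[:space:][:punct:]]+",
             seq_punct("going", "to", "(b|be)", "a", "mom"), "\\b"),
      paste0(im, "[[:space:][:punct:]]+",
             seq_punct("having", "a", "baby"), "\\b"),
      paste0("\\bi[[:space:][:punct:]]+",
             seq_punct("(hav|have)", "been", "pregnant"), "\\b"),
      paste0("\\b(ive|i've)[[:space:][:punct:]]+",
             seq_punct("been", "pregnant"), "\\b"),
      conj("\\badding\\b", "\\bone\\b",
           paste0("\\b", seq_punct("our", "family"), "\\b")),
      paste0("\\b", seq_punct("my", "pregnancy"), "\\b"),
      paste0(im, "[[:space:][:punct:]]+",
             seq_punct("going", "to", "have", "a", "baby"), "\\b"),
      paste0("\\b", seq_punct("our", "family"),
             "\\b.*\\bgrowing\\b.*\\b(2|two)[[:space:][:punct:]]+feet\\b")
    ),
    notes = c(
      "time unit: week(s), month(s) or day(s); term groups in any order",
      "both terms present, any order",
      "exact sequence, whitespace or punctuation between terms",
      "'been ... [time]' in order; since, i, pregnant anywhere",
      "all three terms present, any order",
      "exact sequence for the announcement; 'baby' anywhere after",
      "exact sequence, whitespace or punctuation between terms",
      "exact sequence, whitespace or punctuation between terms",
      "exact sequence, whitespace or punctuation between terms",
      "exact sequence, whitespace or punctuation between terms",
      "'our family' as a sequence; adding, one anywhere",
      "exact sequence, whitespace or punctuation between terms",
      "exact sequence, whitespace or punctuation between terms",
      "ordered: our family ... growing ... (2|two) feet"
    ),
    stringsAsFactors = FALSE
  )
}

#' Compile the query-pattern registry
#'
#' Compiles the default 14 retrieval patterns, or a custom set from a config
#' document, and attaches the seed terms used by [prefilter_by_seeds()]. Every
#' expression is test-compiled; a malformed expression aborts with the
#' offending \code{pattern_id} named.
#'
#' @param config \code{NULL} for the default registry, a path to a JSON config
#'   file, or a data frame with columns \code{pattern_id},
#'   \code{simplified_form}, \code{realized_expression} (optional
#'   \code{notes}).
#' @param seed_terms lowercase prefilter terms; default [default_seed_terms()].
#' @return an object of class \code{pattern_registry} with components
#'   \code{patterns} (data frame) and \code{seed_terms}.
#' @export
#' @examples
#' reg <- compile_pattern_registry()
#' nrow(reg$patterns)  # 14
compile_pattern_registry <- function(config = NULL,
                                     seed_terms = default_seed_terms()) {
  if (is.null(config)) {
    tab <- default_pattern_table()
  } else if (is.character(config) && length(config) == 1L) {
    tab <- read_pattern_config(config)
  } else if (is.data.frame(config)) {
    tab <- as.data.frame(config, stringsAsFactors = FALSE)
  } else {
    stop("`config` must be NULL, a file path, or a data frame")
  }
  if (nrow(tab) == 0L) stop("pattern config is empty")
  required <- c("pattern_id", "simplified_form", "realized_expression")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("pattern config lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(tab$notes)) tab$notes <- ""
  if (anyDuplicated(tab$pattern_id)) stop("duplicate pattern_id in config")
  for (k in seq_len(nrow(tab))) {
    ok <- tryCatch({
      grepl(tab$realized_expression[k], "probe text", perl = TRUE)
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) {
      stop("pattern_id ", tab$pattern_id[k],
           ": realized_expression does not compile")
    }
  }
  structure(list(patterns = tab[required_pattern_cols()],
                 seed_terms = tolower(seed_terms)),
            class = "pattern_registry")
}

required_pattern_cols <- function() {
  c("pattern_id", "simplified_form", "realized_expression", "notes")
}

#' @export
print.pattern_registry <- function(x, ...) {
  cat("<pattern_registry> ", nrow(x$patterns), " patterns, seeds: ",
      paste(x$seed_terms, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read / write a pattern config file
#'
#' The config is a JSON array of objects with fields \code{pattern_id},
#' \code{simplified_form}, \code{realized_expression} and optional
#' \code{notes}.
#'
#' @param path file path.
#' @return \code{read_pattern_config}: a data frame of patterns.
#' @export
read_pattern_config <- function(path) {
  tab <- jsonlite::fromJSON(path)
  if (!is.data.frame(tab) || nrow(tab) == 0L) {
    stop("pattern config at ", path, " is empty or malformed")
  }
  tab
}

#' @rdname read_pattern_config
#' @param registry a \code{pattern_registry}.
#' @export
write_pattern_config <- function(registry, path) {
  jsonlite::write_json(registry$patterns, path, auto_unbox = FALSE,
                       pretty = TRUE)
  invisible(path)
}

#' Seed-term prefilter
#'
#' \code{TRUE} iff the lowercased text contains at least one seed term as a
#' substring (substring containment matches keyword tracking against a
#' streaming API, which also catches hashtag forms like "#pregnant"). Posts
#' failing the prefilter are never pattern-tested.
#'
#' @param text character vector of raw texts.
#' @param registry a \code{pattern_registry}.
#' @return logical vector.
#' @export
#' @examples
#' prefilter_by_seeds("MOM!!!", compile_pattern_registry())
prefilter_by_seeds <- function(text, registry = compile_pattern_registry()) {
  norm <- tolower(as.character(text))
  out <- rep(FALSE, length(norm))
  for (seed in registry$seed_terms) {
    out <- out | grepl(seed, norm, fixed = TRUE)
  }
  out
}

#' Match a post against the pattern registry
#'
#' Tests the normalized text against every realized expression and returns all
#' pattern ids that fire, or \code{NULL} when none does. Matching is
#' case-insensitive (normalization lowercases) and invariant to Unicode
#' apostrophes.
#'
#' @param post a single raw text string, or a list/row with a \code{text}
#'   field.
#' @param registry a \code{pattern_registry}.
#' @return integer vector of matched pattern ids, or \code{NULL} for no match.
#' @export
#' @examples
#' match_patterns("i just took my pregnancy cravings to a whole new level")
match_patterns <- function(post, registry = compile_pattern_registry()) {
  text <- if (is.character(post)) post else post$text
  stopifnot(length(text) == 1L)
  norm <- normalize_text(text)
  hits <- vapply(registry$patterns$realized_expression,
                 function(rx) grepl(rx, norm, perl = TRUE),
                 logical(1), USE.NAMES = FALSE)
  ids <- registry$patterns$pattern_id[hits]
  if (length(ids)) as.integer(ids) else NULL
}

#' Scan a corpus of posts for pattern matches
#'
#' Applies the prefilter and pattern matcher to every post, collapses exact
#' duplicates (same \code{user_id} + normalized text, retweet noise) to the
#' earliest timestamp, and tallies a per-pattern frequency table. A post
#' matching several patterns is attributed to each of them, so per-pattern
#' counts can sum to more than the number of distinct matched posts.
#'
#' @param posts data frame with columns \code{id}, \code{user_id},
#'   \code{created_at}, \code{text} (see [read_posts_jsonl()]).
#' @param registry a \code{pattern_registry}.
#' @param dedupe collapse duplicate (user, text) pairs; default \code{TRUE}.
#' @param latin1_filter optionally drop posts with fewer than 80\% of
#'   characters in the printable Latin-1 range (encoding-broken or non-English
#'   posts); off by default.
#' @return list with components \code{matches} (data frame: \code{post_id},
#'   \code{pattern_ids} list-column), \code{frequency_table} (data frame:
#'   \code{pattern_id}, \code{simplified_form}, \code{count},
#'   \code{relative_frequency_percent}), and \code{counts} (named vector of
#'   stage tallies: input, deduplicated, prefiltered, matched, rejects).
#' @export
scan_corpus <- function(posts, registry = compile_pattern_registry(),
                        dedupe = TRUE, latin1_filter = FALSE) {
  stopifnot(is.data.frame(posts))
  n_input <- nrow(posts)
  rejects <- 0L
  if (n_input > 0L) {
    bad <- is.na(posts$text) | is.na(posts$id)
    rejects <- sum(bad)
    if (rejects > 0L) {
      warning(rejects, " unreadable post record(s) skipped")
      posts <- posts[!bad, , drop = FALSE]
    }
  }
  if (latin1_filter && nrow(posts) > 0L) {
    frac <- vapply(posts$text, latin1_fraction, numeric(1), USE.NAMES = FALSE)
    posts <- posts[frac >= 0.8, , drop = FALSE]
  }
  if (dedupe && nrow(posts) > 0L) {
    key <- paste(posts$user_id, normalize_text(posts$text), sep = "\r")
    ord <- order(posts$created_at)
    posts <- posts[ord, , drop = FALSE][!duplicated(key[ord]), , drop = FALSE]
  }
  n_dedup <- nrow(posts)
  pre <- if (n_dedup > 0L) prefilter_by_seeds(posts$text, registry) else logical(0)
  candidates <- posts[pre, , drop = FALSE]
  match_list <- lapply(candidates$text, match_patterns, registry = registry)
  hit <- !vapply(match_list, is.null, logical(1))
  matches <- data.frame(post_id = candidates$id[hit],
                        stringsAsFactors = FALSE)
  matches$pattern_ids <- match_list[hit]
  counts_per_pattern <- vapply(registry$patterns$pattern_id, function(pid) {
    sum(vapply(matches$pattern_ids, function(ids) pid %in% ids, logical(1)))
  }, integer(1))
  n_matched <- nrow(matches)
  freq <- data.frame(
    pattern_id = registry$patterns$pattern_id,
    simplified_form = registry$patterns$simplified_form,
    count = counts_per_pattern,
    relative_frequency_percent =
      if (n_matched > 0L) round(100 * counts_per_pattern / n_matched, 2) else
        rep(0, nrow(registry$patterns)),
    stringsAsFactors = FALSE
  )
  list(matches = matches,
       frequency_table = freq,
       counts = c(input = n_input, deduplicated = n_dedup,
                  prefiltered = sum(pre), matched = n_matched,
                  rejects = rejects))
}

latin1_fraction <- function(text) {
  if (!nzchar(text)) return(1)
  ch <- utf8ToInt(enc2utf8(text))
  mean((ch >= 32 & ch <= 126) | (ch >= 160 & ch <= 255))
}
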