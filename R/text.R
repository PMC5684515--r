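#' Normalize raw post text
#'
#' Canonical normalization applied before pattern matching and tokenization:
#' lowercase, map typographic apostrophes (\code{’}, \code{‘},
#' \code{´}) to the ASCII apostrophe, and collapse runs of whitespace to
#' a single space. Matching and feature extraction are therefore invariant to
#' letter case and to Unicode-vs-ASCII apostrophes.
#'
#' @param text character vector of raw post texts.
#' @return character vector of normalized texts.
#' @export
#' @examples
#' normalize_text("I’m   PREGNANT!")
normalize_text <- function(text) {
  text <- tolower(as.character(text))
  text <- gsub("[’‘´`]", "'", text)
  text <- gsub("\\s+", " ", text)
  trimws(text)
}

#' Tokenize a post into a token sequence
#'
#' Splits normalized text on whitespace and strips surrounding punctuation
#' from each token. Contractions are kept whole ("i'm" is one token) so the
#' retrieval vocabulary stays intact. Hashtags and @-mentions are kept as
#' single tokens: the leading marker is stripped from the token content and
#' recorded in a parallel flag.
#'
#' @param text a single character string (raw post text).
#' @return an object of class \code{token_seq}: a list with components
#'   \code{tokens} (lowercase tokens), \code{stems} (Porter stems, parallel to
#'   \code{tokens}), \code{is_hashtag}, \code{is_mention} (logical flags).
#' @seealso [porter_stem()]
#' @export
#' @examples
#' tokenize("Loving my pregnancy cravings! #25weeks")$tokens
tokenize <- function(text) {
  stopifnot(length(text) == 1L)
  norm <- normalize_text(text)
  if (!nzchar(norm)) {
    return(new_token_seq(character(0), character(0), logical(0), logical(0)))
  }
  raw <- strsplit(norm, " ", fixed = TRUE)[[1]]
  is_hashtag <- startsWith(raw, "#")
  is_mention <- startsWith(raw, "@")
  body <- sub("^[#@]", "", raw)
  # strip surrounding (not internal) punctuation: keeps "i'm", "mother-in-law"
  body <- gsub("^[^a-z0-9]+|[^a-z0-9]+$", "", body)
  keep <- nzchar(body)
  new_token_seq(body[keep], porter_stem(body[keep]),
                is_hashtag[keep], is_mention[keep])
}

new_token_seq <- function(tokens, stems, is_hashtag, is_mention) {
  stopifnot(length(tokens) == length(stems))
  structure(list(tokens = tokens, stems = stems,
                 is_hashtag = is_hashtag, is_mention = is_mention),
            class = "token_seq")
}

#' @export
print.token_seq <- function(x, ...) {
  cat("<token_seq> ", length(x$tokens), " tokens\n", sep = "")
  if (length(x$tokens)) {
    cat(" tokens: ", paste(x$tokens, collapse = " "), "\n", sep = "")
    cat(" stems:  ", paste(x$stems, collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
length.token_seq <- function(x) length(x$tokens)

#' Preprocess a post for feature extraction
#'
#' Convenience wrapper: [normalize_text()] then [tokenize()]. Exposed
#' separately because classification features and the rule-based temporal
#' extractor share exactly this preprocessing.
#'
#' @inheritParams tokenize
#' @return a \code{token_seq}.
#' @export
preprocess <- function(text) tokenize(text)
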