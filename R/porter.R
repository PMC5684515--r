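#' Porter stemmer
#'
#' An implementation of the classic Porter suffix-stripping algorithm for
#' English. Stems are used as the units of the word n-gram features; raw
#' surface tokens are retained for embedding and cluster lookups. Tokens of
#' two letters or fewer, and tokens containing non-alphabetic characters
#' (numbers, contractions such as "i'm", hashtag bodies with digits), are
#' returned unchanged.
#'
#' @param words character vector of lowercase tokens.
#' @return character vector of stems, same length as \code{words}.
#' @export
#' @examples
#' porter_stem(c("running", "babies", "pregnancy", "caresses"))
porter_stem <- function(words) {
  vapply(as.character(words), porter_stem_one, character(1), USE.NAMES = FALSE)
}

porter_stem_one <- function(word) {
  if (is.na(word) || nchar(word) <= 2L || grepl("[^a-z]", word)) return(word)
  w <- p_step1a(word)
  w <- p_step1b(w)
  w <- p_step1c(w)
  w <- p_step2(w)
  w <- p_step3(w)
  w <- p_step4(w)
  w <- p_step5a(w)
  p_step5b(w)
}

# -- consonant/vowel machinery ------------------------------------------------
# y is a consonant at word start or after a vowel, a vowel after a consonant.

p_shape <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (n == 0L) return(character(0))
  out <- character(n)
  for (i in seq_len(n)) {
    c0 <- ch[i]
    out[i] <- if (c0 %in% c("a", "e", "i", "o", "u")) {
      "V"
    } else if (c0 == "y") {
      # y after a consonant acts as a vowel; at word start or after a vowel
      # it is a consonant
      if (i > 1L && out[i - 1L] == "C") "V" else "C"
    } else {
      "C"
    }
  }
  out
}

p_measure <- function(s) {
  if (!nzchar(s)) return(0L)
  collapsed <- paste(rle(p_shape(s))$values, collapse = "")
  length(gregexpr("VC", collapsed, fixed = TRUE)[[1]][
    gregexpr("VC", collapsed, fixed = TRUE)[[1]] > 0])
}

p_has_vowel <- function(s) any(p_shape(s) == "V")

p_double_cons <- function(s) {
  n <- nchar(s)
  n >= 2L &&
    substr(s, n - 1L, n - 1L) == substr(s, n, n) &&
    p_shape(s)[n] == "C"
}

# ends consonant-vowel-consonant, final consonant not w, x or y
p_cvc <- function(s) {
  n <- nchar(s)
  if (n < 3L) return(FALSE)
  sh <- p_shape(s)
  sh[n - 2L] == "C" && sh[n - 1L] == "V" && sh[n] == "C" &&
    !(substr(s, n, n) %in% c("w", "x", "y"))
}

p_drop <- function(s, k) substr(s, 1L, nchar(s) - k)

# -- steps --------------------------------------------------------------------

p_step1a <- function(w) {
  if (endsWith(w, "sses")) return(p_drop(w, 2L))
  if (endsWith(w, "ies"))  return(paste0(p_drop(w, 3L), "i"))
  if (endsWith(w, "ss"))   return(w)
  if (endsWith(w, "s"))    return(p_drop(w, 1L))
  w
}

p_step1b <- function(w) {
  if (endsWith(w, "eed")) {
    stem <- p_drop(w, 3L)
    return(if (p_measure(stem) > 0L) paste0(stem, "ee") else w)
  }
  stripped <- NULL
  if (endsWith(w, "ed") && p_has_vowel(p_drop(w, 2L))) {
    stripped <- p_drop(w, 2L)
  } else if (endsWith(w, "ing") && p_has_vowel(p_drop(w, 3L))) {
    stripped <- p_drop(w, 3L)
  }
  if (is.null(stripped)) return(w)
  w <- stripped
  if (endsWith(w, "at") || endsWith(w, "bl") || endsWith(w, "iz")) {
    return(paste0(w, "e"))
  }
  if (p_double_cons(w) && !(substr(w, nchar(w), nchar(w)) %in% c("l", "s", "z"))) {
    return(p_drop(w, 1L))
  }
  if (p_measure(w) == 1L && p_cvc(w)) return(paste0(w, "e"))
  w
}

p_step1c <- function(w) {
  if (endsWith(w, "y") && p_has_vowel(p_drop(w, 1L))) {
    return(paste0(p_drop(w, 1L), "i"))
  }
  w
}

# ordered tables: on the first suffix that matches, apply the m-condition and
# stop (no fallthrough), mirroring the reference switch-on-penultimate-letter
p_apply_table <- function(w, table, min_m) {
  for (k in seq_len(nrow(table))) {
    suf <- table$suffix[k]
    if (endsWith(w, suf)) {
      stem <- p_drop(w, nchar(suf))
      if (p_measure(stem) > min_m) w <- paste0(stem, table$repl[k])
      return(w)
    }
  }
  w
}

p_step2_table <- data.frame(
  suffix = c("ational", "tional", "enci", "anci", "izer", "abli", "alli",
             "entli", "eli", "ousli", "ization", "ation", "ator", "alism",
             "iveness", "fulness", "ousness", "aliti", "iviti", "biliti"),
  repl   = c("ate", "tion", "ence", "ance", "ize", "able", "al",
             "ent", "e", "ous", "ize", "ate", "ate", "al",
             "ive", "ful", "ous", "al", "ive", "ble"),
  stringsAsFactors = FALSE
)

p_step2 <- function(w) p_apply_table(w, p_step2_table, 0L)

p_step3_table <- data.frame(
  suffix = c("icate", "ative", "alize", "iciti", "ical", "ful", "ness"),
  repl   = c("ic", "", "al", "ic", "ic", "", ""),
  stringsAsFactors = FALSE
)

p_step3 <- function(w) p_apply_table(w, p_step3_table, 0L)

p_step4_suffixes <- c("al", "ance", "ence", "er", "ic", "able", "ible", "ant",
                      "ement", "ment", "ent", "ion", "ou", "ism", "ate",
                      "iti", "ous", "ive", "ize")

p_step4 <- function(w) {
  for (suf in p_step4_suffixes) {
    if (endsWith(w, suf)) {
      stem <- p_drop(w, nchar(suf))
      ok <- p_measure(stem) > 1L
      if (suf == "ion") {
        last <- substr(stem, nchar(stem), nchar(stem))
        ok <- ok && last %in% c("s", "t")
      }
      if (ok) w <- stem
      return(w)
    }
  }
  w
}

p_step5a <- function(w) {
  if (!endsWith(w, "e")) return(w)
  stem <- p_drop(w, 1L)
  m <- p_measure(stem)
  if (m > 1L || (m == 1L && !p_cvc(stem))) stem else w
}

p_step5b <- function(w) {
  if (p_measure(w) > 1L && p_double_cons(w) && endsWith(w, "l")) {
    return(p_drop(w, 1L))
  }
  w
}
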