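#' Load a drug lexicon
#'
#' One drug per line, \code{"canonical: variant, variant, ..."}. All variants
#' are lowercased and deduplicated. The canonical name is not stored as a
#' variant, but [count_drug_mentions()] matches it too. A surface form
#' (variant or canonical) listed under two different drugs is a load error
#' naming both, since counts could not be attributed.
#'
#' @param path lexicon file path.
#' @return an object of class \code{drug_lexicon}: named list canonical name
#'   -> character vector of variants.
#' @export
load_drug_lexicon <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    warning("empty drug lexicon: ", path)
    return(structure(list(), class = "drug_lexicon"))
  }
  entries <- list()
  for (ln in lines) {
    parts <- strsplit(ln, ":", fixed = TRUE)[[1]]
    canonical <- tolower(trimws(parts[1]))
    variants <- if (length(parts) > 1L) {
      tolower(trimws(strsplit(paste(parts[-1], collapse = ":"), ",")[[1]]))
    } else character(0)
    entries[[canonical]] <- unique(variants[nzchar(variants)])
  }
  seen <- character(0)
  owner <- character(0)
  for (drug in names(entries)) {
    surfaces <- unique(c(drug, entries[[drug]]))
    clash <- intersect(surfaces, seen)
    if (length(clash)) {
      stop("variant \"", clash[1], "\" listed under both \"",
           owner[match(clash[1], seen)], "\" and \"", drug, "\"")
    }
    seen <- c(seen, surfaces)
    owner <- c(owner, rep(drug, length(surfaces)))
  }
  structure(entries, class = "drug_lexicon")
}

#' @export
print.drug_lexicon <- function(x, ...) {
  cat("<drug_lexicon> ", length(x), " drugs, ",
      sum(lengths(unclass(x))), " surface variants\n", sep = "")
  invisible(x)
}

#' Count drug mentions per trimester
#'
#' A mention is a token (case-insensitive, after tokenization) equal to a
#' lexicon variant, in a post whose phase is one of the three trimesters.
#' Posts categorized pre-pregnancy or post-birth are ignored. Only mentions
#' are counted; no claim about actual intake is made.
#'
#' @param posts data frame with at least \code{text} and \code{phase}
#'   columns (phase as produced by [categorize_timeline()]).
#' @param lexicon a \code{drug_lexicon}.
#' @return an object of class \code{medication_mention_counts}: integer
#'   matrix drugs x phases (T1, T2, T3).
#' @export
count_drug_mentions <- function(posts, lexicon) {
  stopifnot(is.data.frame(posts), all(c("text", "phase") %in% names(posts)))
  phases <- c("T1", "T2", "T3")
  counts <- matrix(0L, nrow = length(lexicon), ncol = 3L,
                   dimnames = list(names(lexicon), phases))
  surfaces <- lapply(names(lexicon), function(d) unique(c(d, lexicon[[d]])))
  variant_to_drug <- stats::setNames(
    rep(names(lexicon), lengths(surfaces)),
    unlist(surfaces, use.names = FALSE))
  in_trimester <- as.character(posts$phase) %in% phases
  for (i in which(in_trimester)) {
    toks <- tokenize(posts$text[i])$tokens
    drugs <- variant_to_drug[toks]
    drugs <- drugs[!is.na(drugs)]
    if (length(drugs)) {
      ph <- as.character(posts$phase[i])
      tab <- table(drugs)
      counts[names(tab), ph] <- counts[names(tab), ph] + as.integer(tab)
    }
  }
  structure(counts, class = c("medication_mention_counts", class(counts)))
}

#' @export
print.medication_mention_counts <- function(x, ...) {
  cat("<medication_mention_counts>\n")
  print(unclass(x))
  invisible(x)
}
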