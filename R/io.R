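#' Read / write posts as JSON lines
#'
#' One JSON object per line with keys \code{id}, \code{user_id},
#' \code{created_at} (ISO-8601, UTC) and \code{text}. Malformed lines are
#' skipped with a warning and counted in the \code{"rejects"} attribute of
#' the result.
#'
#' @param path file path.
#' @return \code{read_posts_jsonl}: data frame with those four character
#'   columns.
#' @export
read_posts_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  parsed <- lapply(lines, function(ln) {
    tryCatch(jsonlite::fromJSON(ln), error = function(e) NULL)
  })
  ok <- !vapply(parsed, is.null, logical(1))
  ok[ok] <- vapply(parsed[ok], function(p) {
    all(c("id", "user_id", "created_at", "text") %in% names(p))
  }, logical(1))
  if (any(!ok)) warning(sum(!ok), " malformed post line(s) skipped")
  rows <- lapply(parsed[ok], function(p) {
    data.frame(id = as.character(p$id), user_id = as.character(p$user_id),
               created_at = as.character(p$created_at),
               text = as.character(p$text), stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(0), user_id = character(0),
               created_at = character(0), text = character(0),
               stringsAsFactors = FALSE)
  attr(out, "rejects") <- sum(!ok)
  out
}

#' @rdname read_posts_jsonl
#' @param posts data frame with columns \code{id}, \code{user_id},
#'   \code{created_at}, \code{text}.
#' @export
write_posts_jsonl <- function(posts, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(posts))) {
    writeLines(jsonlite::toJSON(list(id = posts$id[i],
                                     user_id = posts$user_id[i],
                                     created_at = posts$created_at[i],
                                     text = posts$text[i]),
                                auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Write the per-pattern frequency table
#'
#' CSV with columns \code{pattern_id}, \code{simplified_form}, \code{count},
#' \code{relative_frequency_percent}.
#'
#' @param frequency_table as returned by [scan_corpus()].
#' @param path output CSV path.
#' @export
write_frequency_table <- function(frequency_table, path) {
  utils::write.csv(frequency_table, path, row.names = FALSE)
  invisible(path)
}
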