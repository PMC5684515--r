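#' Trimester boundary rule
#'
#' The clinical trimester segmentation used throughout: first trimester weeks
#' 1-12, second weeks 13-27, third week 28 to birth, with a default term
#' length of 40 weeks marking the post-birth boundary.
#'
#' @param term_length_weeks gestation length marking the end of trimester 3;
#'   default 40.
#' @return an object of class \code{trimester_rule}.
#' @export
trimester_rule <- function(term_length_weeks = 40) {
  stopifnot(term_length_weeks > 28)
  structure(list(t1_end = 12, t2_end = 27,
                 term_length_weeks = term_length_weeks),
            class = "trimester_rule")
}

#' Assign a gestational week to a trimester
#'
#' Weeks up to 12 are first trimester, weeks in (12, 27] second, above 27
#' third; monotone nondecreasing in the week.
#'
#' @param week gestational week(s), numeric in \eqn{[1, 45]}.
#' @param rule a \code{trimester_rule}.
#' @return integer vector of trimester ordinals 1, 2, 3.
#' @export
#' @examples
#' assign_trimester(c(12, 13, 27, 28, 36))
assign_trimester <- function(week, rule = trimester_rule()) {
  if (any(week < 1 | week > 45)) stop("gestational week out of range [1, 45]")
  ifelse(week <= rule$t1_end, 1L, ifelse(week <= rule$t2_end, 2L, 3L))
}

# number words accepted in progress statements (1..40, plus tens compounds)
number_word_map <- local({
  units <- c(one = 1, two = 2, three = 3, four = 4, five = 5, six = 6,
             seven = 7, eight = 8, nine = 9, ten = 10, eleven = 11,
             twelve = 12, thirteen = 13, fourteen = 14, fifteen = 15,
             sixteen = 16, seventeen = 17, eighteen = 18, nineteen = 19)
  tens <- c(twenty = 20, thirty = 30, forty = 40)
  out <- c(units, tens)
  for (t in names(tens)) {
    for (u in names(units)[1:9]) {
      out[paste0(t, "-", u)] <- tens[[t]] + units[[u]]
      out[paste0(t, u)] <- tens[[t]] + units[[u]]
    }
  }
  out[out <= 45]
})

parse_number_token <- function(token) {
  # plain digits, digit ordinals ("25th"), number words, hyphen compounds
  if (grepl("^[0-9]+(\\.[0-9]+)?$", token)) return(as.numeric(token))
  if (grepl("^[0-9]+(st|nd|rd|th)$", token)) {
    return(as.numeric(sub("(st|nd|rd|th)$", "", token)))
  }
  if (token %in% names(number_word_map)) return(unname(number_word_map[token]))
  NA_real_
}

unit_of_token <- function(token) {
  if (token %in% c("week", "weeks", "wk", "wks")) return("week")
  if (token %in% c("month", "months")) return("month")
  if (token %in% c("day", "days")) return("day")
  NA_character_
}

#' Extract pregnancy-progress mentions from a post
#'
#' Rule-based detection of statements like "6 weeks into the pregnancy" or
#' "25 weeks pregnant": for every occurrence of a seed term ("pregnant",
#' "pregnancy") the surrounding token window is scanned for a temporal unit
#' term (week/month/day) and a number mention; a mention is emitted only when
#' both co-occur. Number and unit are paired by adjacency: the nearest number
#' preceding the unit. When a window holds both a week pair and a day pair
#' ("39 weeks and 6 days"), the week pair is primary and the days are added
#' as a fraction; months are used only when no week pair exists; day-only
#' phrasings are accepted only in "since/been"-style wordings. Optional
#' hashtag segmentation splits forms like "#37weekspregnant" on digit/letter
#' boundaries before scanning.
#'
#' @param post raw text string, or a list/row with \code{id} and \code{text}.
#' @param window tokens scanned on each side of the seed term; default 6.
#' @param window_mode \code{"per_side"} (default: \code{window} tokens on
#'   each side) or \code{"total"} (a symmetric window of \code{window} tokens
#'   overall, i.e. \code{window / 2} per side).
#' @param segment_hashtags split hashtag bodies on digit/letter boundaries;
#'   off by default.
#' @param rule a \code{trimester_rule} used for the validity range.
#' @return data frame of mentions (possibly 0 rows): \code{post_id},
#'   \code{seed_term}, \code{quantity}, \code{unit}, \code{gestational_week},
#'   \code{trimester}, \code{window_tokens}. Mentions whose converted week
#'   falls outside \eqn{[1, 45]} are discarded.
#' @export
#' @examples
#' extract_progress_mentions("6 weeks into the pregnancy")
extract_progress_mentions <- function(post, window = 6L,
                                      window_mode = c("per_side", "total"),
                                      segment_hashtags = FALSE,
                                      rule = trimester_rule()) {
  window_mode <- match.arg(window_mode)
  text <- if (is.character(post)) post else post$text
  post_id <- if (is.character(post)) NA_character_ else
    (post$id %||% NA_character_)
  seq <- tokenize(text)
  tokens <- seq$tokens
  if (segment_hashtags && any(seq$is_hashtag)) {
    expanded <- lapply(seq_along(tokens), function(i) {
      if (seq$is_hashtag[i]) {
        # split on digit/letter boundaries and around the unit/seed words,
        # so "#37weekspregnant" becomes "37", "weeks", "pregnant"
        t <- gsub("(?<=[a-z])(?=[0-9])|(?<=[0-9])(?=[a-z])", " ",
                  tokens[i], perl = TRUE)
        t <- gsub("(weeks|week|months|month|days|day|pregnancy|pregnant)",
                  " \\1 ", t)
        strsplit(trimws(gsub("\\s+", " ", t)), " ")[[1]]
      } else tokens[i]
    })
    tokens <- unlist(expanded)
  }
  side <- if (window_mode == "per_side") window else max(1L, window %/% 2L)
  seeds <- which(tokens %in% c("pregnant", "pregnancy"))
  rows <- list()
  for (s in seeds) {
    lo <- max(1L, s - side)
    hi <- min(length(tokens), s + side)
    win <- tokens[lo:hi]
    nums <- vapply(win, parse_number_token, numeric(1), USE.NAMES = FALSE)
    units <- vapply(win, unit_of_token, character(1), USE.NAMES = FALSE)
    pair <- pair_number_unit(nums, units, win)
    if (is.null(pair)) next
    gw <- switch(pair$unit,
                 week = pair$quantity + pair$extra_days / 7,
                 month = pair$quantity * 4.345,
                 day = pair$quantity / 7)
    if (gw < 1 || gw > 45) next
    rows[[length(rows) + 1L]] <- data.frame(
      post_id = post_id,
      seed_term = tokens[s],
      quantity = pair$quantity,
      unit = pair$unit,
      gestational_week = gw,
      trimester = assign_trimester(gw, rule),
      window_tokens = paste(win, collapse = " "),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(post_id = character(0), seed_term = character(0),
                      quantity = numeric(0), unit = character(0),
                      gestational_week = numeric(0), trimester = integer(0),
                      window_tokens = character(0), stringsAsFactors = FALSE))
  }
  unique(do.call(rbind, rows))
}

# nearest number preceding each unit token; week pairs take priority, with a
# day pair in the same window added as a fraction of a week; month pairs only
# when no week pair; day-only mentions need a "since"/"been" style wording
pair_number_unit <- function(nums, units, win) {
  unit_pos <- which(!is.na(units))
  if (!length(unit_pos)) return(NULL)
  pairs <- list()
  for (u in unit_pos) {
    before <- which(!is.na(nums) & seq_along(nums) < u)
    if (!length(before)) next
    q <- nums[max(before)]
    if (q <= 0) next
    pairs[[length(pairs) + 1L]] <- list(unit = units[u], quantity = q)
  }
  if (!length(pairs)) return(NULL)
  kinds <- vapply(pairs, `[[`, character(1), "unit")
  if ("week" %in% kinds) {
    wk <- pairs[[which(kinds == "week")[1]]]
    extra <- if ("day" %in% kinds) pairs[[which(kinds == "day")[1]]]$quantity else 0
    return(list(unit = "week", quantity = wk$quantity, extra_days = extra))
  }
  if ("month" %in% kinds) {
    mo <- pairs[[which(kinds == "month")[1]]]
    return(list(unit = "month", quantity = mo$quantity, extra_days = 0))
  }
  if (any(win %in% c("since", "been"))) {
    dy <- pairs[[which(kinds == "day")[1]]]
    return(list(unit = "day", quantity = dy$quantity, extra_days = 0))
  }
  NULL
}

#' Convert a progress mention to a gestational week
#'
#' Weeks pass through unchanged; months convert at 4.345 weeks per month
#' (365.25 / 12 / 7); days divide by 7. Values outside \eqn{[1, 45]} weeks
#' are rejected as implausible.
#'
#' @param quantity positive number reported in the mention.
#' @param unit \code{"week"}, \code{"month"} or \code{"day"}.
#' @return gestational week, or \code{NA} with a warning when out of range.
#' @export
#' @examples
#' gestational_week(6, "month")  # 26.07
gestational_week <- function(quantity, unit = c("week", "month", "day")) {
  unit <- match.arg(unit)
  stopifnot(quantity > 0)
  gw <- switch(unit, week = quantity, month = quantity * 4.345,
               day = quantity / 7)
  if (gw < 1 || gw > 45) {
    warning("converted gestational week ", round(gw, 2),
            " outside [1, 45]; mention discarded")
    return(NA_real_)
  }
  gw
}

#' Estimate the pregnancy start date of a timeline
#'
#' For every progress mention found in the timeline the candidate start date
#' is the post timestamp minus 7 x gestational-week days; the estimate is the
#' median candidate (robust to joke/quoted mentions) and the dispersion is
#' the median absolute deviation of the candidates in days, reported so
#' callers can filter unreliable estimates.
#'
#' @param timeline data frame of one user's posts: columns \code{id},
#'   \code{user_id}, \code{created_at} (POSIXct or ISO-8601 string),
#'   \code{text}.
#' @param window,window_mode,segment_hashtags passed to
#'   [extract_progress_mentions()].
#' @param rule a \code{trimester_rule}.
#' @return an object of class \code{pregnancy_estimate} (list with
#'   \code{user_id}, \code{start_date} (POSIXct, UTC),
#'   \code{supporting_mentions}, \code{dispersion_days}, \code{n_mentions}),
#'   or \code{NULL} when the timeline has no valid mention.
#' @export
estimate_pregnancy_start <- function(timeline, window = 6L,
                                     window_mode = "per_side",
                                     segment_hashtags = FALSE,
                                     rule = trimester_rule()) {
  stopifnot(nrow(timeline) > 0L)
  ts <- as_post_time(timeline$created_at)
  mentions <- lapply(seq_len(nrow(timeline)), function(i) {
    m <- extract_progress_mentions(list(id = timeline$id[i],
                                        text = timeline$text[i]),
                                   window = window,
                                   window_mode = window_mode,
                                   segment_hashtags = segment_hashtags,
                                   rule = rule)
    if (nrow(m)) m$timestamp <- ts[i]
    m
  })
  mentions <- do.call(rbind, mentions[vapply(mentions, nrow, integer(1)) > 0])
  if (is.null(mentions) || nrow(mentions) == 0L) return(NULL)
  candidates <- mentions$timestamp - mentions$gestational_week * 7 * 86400
  start <- as.POSIXct(stats::median(as.numeric(candidates)),
                      origin = "1970-01-01", tz = "UTC")
  disp <- stats::median(abs(as.numeric(candidates) - as.numeric(start))) / 86400
  structure(list(user_id = timeline$user_id[1],
                 start_date = start,
                 supporting_mentions = mentions,
                 dispersion_days = disp,
                 n_mentions = nrow(mentions)),
            class = "pregnancy_estimate")
}

#' @export
print.pregnancy_estimate <- function(x, ...) {
  cat("<pregnancy_estimate> user ", x$user_id, ": start ",
      format(x$start_date, "%Y-%m-%d"), " (", x$n_mentions,
      " mention(s), dispersion ", round(x$dispersion_days, 1), " d)\n",
      sep = "")
  invisible(x)
}

#' Categorize every post of a timeline into a pregnancy phase
#'
#' Phases follow elapsed weeks since the estimated start: under 1 week (or
#' before the start) \code{pre}; weeks 1-12 \code{T1}; (12, 27] \code{T2};
#' (27, term] \code{T3}; beyond the term length \code{post}.
#'
#' @param timeline data frame of one user's posts (see
#'   [estimate_pregnancy_start()]).
#' @param estimate a \code{pregnancy_estimate} for that user.
#' @param rule a \code{trimester_rule}.
#' @return data frame: \code{post_id}, \code{phase} (factor pre/T1/T2/T3/post
#'   in time order), \code{gestational_week_at_post} (continuous weeks since
#'   start, negative before it).
#' @export
categorize_timeline <- function(timeline, estimate, rule = trimester_rule()) {
  stopifnot(inherits(estimate, "pregnancy_estimate"))
  ts <- as_post_time(timeline$created_at)
  weeks <- as.numeric(ts - as.numeric(estimate$start_date)) / (7 * 86400)
  phase <- ifelse(weeks < 1, "pre",
           ifelse(weeks <= rule$t1_end, "T1",
           ifelse(weeks <= rule$t2_end, "T2",
           ifelse(weeks <= rule$term_length_weeks, "T3", "post"))))
  data.frame(post_id = timeline$id,
             phase = factor(phase, levels = phase_levels),
             gestational_week_at_post = weeks,
             stringsAsFactors = FALSE)
}

phase_levels <- c("pre", "T1", "T2", "T3", "post")

as_post_time <- function(x) {
  if (inherits(x, "POSIXct")) return(as.numeric(x))
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  fallback <- is.na(out)
  if (any(fallback)) {
    out[fallback] <- as.POSIXct(x[fallback], tz = "UTC")
  }
  if (anyNA(out)) stop("unparseable timestamp(s)")
  as.numeric(out)
}
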