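#' Split a post table into per-user timelines
#'
#' @param posts data frame with columns \code{id}, \code{user_id},
#'   \code{created_at}, \code{text}.
#' @return named list of data frames, one per user, posts sorted ascending by
#'   timestamp.
#' @export
build_timelines <- function(posts) {
  stopifnot(is.data.frame(posts))
  split_posts <- split(posts, posts$user_id)
  lapply(split_posts, function(tl) {
    tl[order(as_post_time(tl$created_at)), , drop = FALSE]
  })
}

#' Run the detection stage of the cohort pipeline
#'
#' The funnel: deduplicate, seed-prefilter, pattern-match, featurize the
#' matched posts and classify them; users owning at least one
#' positively-classified matched post form the cohort roster. Stage counts
#' are monotone nonincreasing down the funnel.
#'
#' @param posts data frame of posts (see [read_posts_jsonl()]).
#' @param model a fitted \code{pit_classifier}.
#' @param resources the \code{feature_resources} the model was trained with.
#' @param registry a \code{pattern_registry}.
#' @param blocks feature blocks the model was trained on.
#' @return list with \code{roster} (data frame: \code{user_id},
#'   \code{n_positive_posts}, \code{post_ids}, \code{pattern_ids},
#'   \code{max_score}, \code{detection_date}), \code{classified} (per
#'   matched post: post_id, user_id, label, score, pattern ids) and
#'   \code{report} (named stage counts).
#' @export
run_detection <- function(posts, model, resources,
                          registry = compile_pattern_registry(),
                          blocks = feature_block_names) {
  stopifnot(inherits(model, "pit_classifier"))
  scan <- scan_corpus(posts, registry)
  counts <- scan$counts
  matched_ids <- scan$matches$post_id
  matched <- posts[match(matched_ids, posts$id), , drop = FALSE]
  if (nrow(matched) > 0L) {
    x <- featurize_corpus(matched$text, resources, blocks = blocks)
    pred <- predict(model, x)
    classified <- data.frame(post_id = matched$id,
                             user_id = matched$user_id,
                             created_at = matched$created_at,
                             label = as.character(pred$label),
                             score = pred$score,
                             stringsAsFactors = FALSE)
    classified$pattern_ids <- scan$matches$pattern_ids
  } else {
    classified <- data.frame(post_id = character(0), user_id = character(0),
                             created_at = character(0), label = character(0),
                             score = numeric(0), stringsAsFactors = FALSE)
    classified$pattern_ids <- list()
  }
  pos <- classified[classified$label == "PIT", , drop = FALSE]
  roster <- if (nrow(pos) > 0L) {
    per_user <- split(pos, pos$user_id)
    do.call(rbind, lapply(per_user, function(g) {
      data.frame(user_id = g$user_id[1],
                 n_positive_posts = nrow(g),
                 post_ids = I(list(g$post_id)),
                 pattern_ids = I(list(sort(unique(unlist(g$pattern_ids))))),
                 max_score = max(g$score),
                 detection_date = min(g$created_at),
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(user_id = character(0), n_positive_posts = integer(0),
               post_ids = I(list()), pattern_ids = I(list()),
               max_score = numeric(0), detection_date = character(0),
               stringsAsFactors = FALSE)
  }
  rownames(roster) <- NULL
  report <- c(counts["input"], counts["deduplicated"], counts["prefiltered"],
              counts["matched"], classified_positive = nrow(pos),
              roster_users = nrow(roster), counts["rejects"])
  list(roster = roster, classified = classified, report = report)
}

#' Run the longitudinal (timeline) stage of the cohort pipeline
#'
#' For each cohort user: estimate the pregnancy start from progress
#' statements, categorize every post into a phase, and accumulate
#' trimester-stratified medication-mention counts. Users without a timeline
#' are reported as missing; users whose timeline has no usable progress
#' statement get no estimate but stay listed.
#'
#' @param timelines named list of per-user post data frames (see
#'   [build_timelines()]), or a post data frame (split internally).
#' @param drug_lexicon a \code{drug_lexicon}.
#' @param roster optional roster from [run_detection()]; default: analyze
#'   every user present in \code{timelines}.
#' @param window,window_mode,segment_hashtags passed to the progress-mention
#'   extractor.
#' @param rule a \code{trimester_rule}.
#' @return list with \code{summary} (per user: user_id, detected,
#'   start_date, n_mentions, dispersion_days), \code{posts} (per categorized
#'   post: user_id, post_id, phase, gestational_week_at_post),
#'   \code{medication_counts} (drug x trimester matrix),
#'   \code{detectable_fraction} (share of analyzed users with an estimate)
#'   and \code{missing_users}.
#' @export
run_timeline_analysis <- function(timelines, drug_lexicon, roster = NULL,
                                  window = 6L, window_mode = "per_side",
                                  segment_hashtags = FALSE,
                                  rule = trimester_rule()) {
  if (is.data.frame(timelines)) timelines <- build_timelines(timelines)
  users <- if (is.null(roster)) names(timelines) else roster$user_id
  missing_users <- setdiff(users, names(timelines))
  users <- intersect(users, names(timelines))
  summaries <- vector("list", length(users))
  post_rows <- vector("list", length(users))
  for (i in seq_along(users)) {
    tl <- timelines[[users[i]]]
    est <- estimate_pregnancy_start(tl, window = window,
                                    window_mode = window_mode,
                                    segment_hashtags = segment_hashtags,
                                    rule = rule)
    if (is.null(est)) {
      summaries[[i]] <- data.frame(user_id = users[i], detected = FALSE,
                                   start_date = NA_character_,
                                   n_mentions = 0L,
                                   dispersion_days = NA_real_,
                                   stringsAsFactors = FALSE)
      next
    }
    cat_posts <- categorize_timeline(tl, est, rule = rule)
    cat_posts <- data.frame(user_id = users[i], cat_posts,
                            text = tl$text, stringsAsFactors = FALSE)
    post_rows[[i]] <- cat_posts
    summaries[[i]] <- data.frame(
      user_id = users[i], detected = TRUE,
      start_date = format(est$start_date, "%Y-%m-%dT%H:%M:%S"),
      n_mentions = est$n_mentions,
      dispersion_days = est$dispersion_days,
      stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, summaries)
  posts <- do.call(rbind, post_rows[!vapply(post_rows, is.null, logical(1))])
  med <- if (!is.null(posts) && nrow(posts) > 0L) {
    count_drug_mentions(posts, drug_lexicon)
  } else {
    count_drug_mentions(data.frame(text = character(0),
                                   phase = character(0)), drug_lexicon)
  }
  if (length(missing_users)) {
    warning(length(missing_users), " roster user(s) without a timeline")
  }
  list(summary = summary,
       posts = posts,
       medication_counts = med,
       detectable_fraction = if (length(users)) mean(summary$detected) else
         NA_real_,
       missing_users = missing_users)
}
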