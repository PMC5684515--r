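#' @title Seeded synthetic corpora, timelines and resource fixtures
#'
#' @description
#' Template-grammar generators that emulate the phenomena the pipeline must
#' separate: first-person pregnancy announcements phrased to match the
#' retrieval patterns, confounder posts (third-person pregnancies, figurative
#' "baby", hypothetical futures), user timelines carrying progress statements
#' at known gestational weeks, and drug mentions at known trimesters. Every
#' generator is deterministic given its seed and emits ground truth alongside
#' the data, so parameter-recovery tests can score the pipeline exactly.
#'
#' @name synthetic_data
NULL

pit_filler <- c("sweetie", "cravings", "nursery", "glowing", "kicking",
                "ultrasound", "bump", "midwife", "maternity", "overjoyed",
                "blessed", "excited", "thrilled", "showing", "due")

confounder_filler <- c("sister", "brother", "auntie", "cousin", "puppy",
                       "kitten", "project", "album", "deadline", "someday",
                       "jealous", "drama", "wish", "dream", "lol")

neutral_filler <- c("coffee", "weather", "traffic", "morning", "tonight",
                    "weekend", "dinner", "movie", "music", "garden")

noise_hashtags <- c("#blessed", "#sooo", "#cantwait", "#omg", "#yay")

# announcement templates: each is guaranteed to fire its pattern id; slots
# {f} draw from the active filler pool, {w}/{m} are week/month numbers
pit_templates <- list(
  list(id = 1L,  text = "im {w} weeks pregnant and feeling {f} {f2}"),
  list(id = 1L,  text = "i am {m} months pregnant today so {f} {f2}"),
  list(id = 2L,  text = "our baby will be arriving in {m} months {f} {f2}"),
  list(id = 3L,  text = "baby coming soon cant wait {f} {f2}"),
  list(id = 4L,  text = "been {w} weeks since i found out im pregnant {f} {f2}"),
  list(id = 5L,  text = "my belly keeps growing and the baby is {f} {f2}"),
  list(id = 6L,  text = "i'm expecting a baby this spring {f} {f2}"),
  list(id = 7L,  text = "i'm going to be a mom and im so {f} {f2}"),
  list(id = 8L,  text = "i am having a baby and feeling {f} {f2}"),
  list(id = 9L,  text = "i have been pregnant for {m} months now {f} {f2}"),
  list(id = 10L, text = "i've been pregnant all summer and so {f} {f2}"),
  list(id = 11L, text = "adding one more to our family this year {f} {f2}"),
  list(id = 12L, text = "my pregnancy {f} are out of control {f2}"),
  list(id = 13L, text = "i am going to have a baby and im {f} {f2}"),
  list(id = 14L, text = "our family is growing by two feet {f} {f2}")
)

# Table-1-style sampling weights per announcement pattern (relative retrieval
# frequencies of the 14 queries, percent)
pattern_weights <- c(30.90, 2.65, 2.10, 0.5, 1.06, 0.5, 1.26, 9.86, 0.5,
                     5.19, 0.5, 43.88, 1.65, 0.5)

confounder_templates <- list(
  third_person = c(
    "my sister is {w} weeks pregnant and im going to be an auntie {f} {f2}",
    "my cousin says she is {m} months pregnant {f} {f2}",
    "cant believe im having a baby brother {f} {f2}"),
  figurative = c(
    "i'm having a baby {f} day and its killing me {f2}",
    "miss my baby {f} so much right now {f2}",
    "baby coming soon to the {f} charts {f2}"),
  hypothetical = c(
    "someday i am going to have a baby but first {f} {f2}",
    "one day i'm going to be a mom until then {f} {f2}",
    "when i am having a baby ill stop with the {f} {f2}")
)

fill_template <- function(template, pool) {
  out <- template
  out <- sub("{w}", sample(5:39, 1L), out, fixed = TRUE)
  out <- sub("{m}", sample(2:8, 1L), out, fixed = TRUE)
  out <- sub("{f}", sample(pool, 1L), out, fixed = TRUE)
  sub("{f2}", sample(pool, 1L), out, fixed = TRUE)
}

add_noise <- function(text, rate) {
  if (stats::runif(1) >= rate) return(text)
  switch(sample(3L, 1L),
         paste(text, sample(noise_hashtags, 1L)),
         paste(text, ":-)"),
         paste0(text, sub("(.)$", "\\1\\1\\1", sample(neutral_filler, 1L))))
}

#' Generate a labeled synthetic corpus of posts
#'
#' Builds exactly \code{round(n_posts * pit_fraction)} announcement posts
#' from templates co-designed with the default pattern registry (every one
#' matches at least one pattern) and fills the remainder from three
#' confounder families. The default class balance matches the composition of
#' a large annotated announcement corpus (roughly 69\% true announcements
#' among retrieved posts).
#'
#' @param n_posts corpus size; default 2000.
#' @param pit_fraction fraction of true announcements; default 0.69.
#' @param confounder_mix weights over the confounder families
#'   \code{third_person}, \code{figurative}, \code{hypothetical}; normalized
#'   to sum to 1.
#' @param vocab_overlap probability that a confounder filler slot draws from
#'   the announcement filler vocabulary instead of its own (0 = disjoint
#'   template vocabularies; raising it makes the classes harder to separate).
#' @param noise_rate probability of lexical noise (appended hashtag,
#'   emoticon, or stretched word) per post; default 0.1.
#' @param seed integer seed; mandatory.
#' @return data frame: \code{id}, \code{user_id}, \code{created_at},
#'   \code{text}, \code{label} ("PIT"/"NOT_PIT"), \code{family} (template
#'   family), \code{template_pattern_id} (the pattern the announcement was
#'   built for; NA for confounders).
#' @export
generate_corpus <- function(n_posts = 2000L, pit_fraction = 0.69,
                            confounder_mix = c(third_person = 0.4,
                                               figurative = 0.35,
                                               hypothetical = 0.25),
                            vocab_overlap = 0, noise_rate = 0.1, seed) {
  if (missing(seed)) stop("`seed` is mandatory")
  stopifnot(pit_fraction >= 0, pit_fraction <= 1,
            vocab_overlap >= 0, vocab_overlap <= 1)
  confounder_mix <- confounder_mix / sum(confounder_mix)
  set.seed(seed)
  n_pit <- round(n_posts * pit_fraction)
  rows <- vector("list", n_posts)
  pit_idx <- sample(seq_len(max(n_posts, 1L)), n_pit)
  is_pit <- seq_len(n_posts) %in% pit_idx
  template_ids <- vapply(pit_templates, `[[`, integer(1), "id")
  tpl_w <- pattern_weights[template_ids]
  base_time <- as.POSIXct("2016-03-01 00:00:00", tz = "UTC")
  for (i in seq_len(n_posts)) {
    if (is_pit[i]) {
      k <- sample(length(pit_templates), 1L, prob = tpl_w)
      text <- fill_template(pit_templates[[k]]$text, pit_filler)
      fam <- "announcement"
      pid <- template_ids[k]
      label <- "PIT"
    } else {
      fam <- sample(names(confounder_mix), 1L, prob = confounder_mix)
      tpl <- sample(confounder_templates[[fam]], 1L)
      pool <- if (stats::runif(1) < vocab_overlap) pit_filler else
        confounder_filler
      text <- fill_template(tpl, pool)
      pid <- NA_integer_
      label <- "NOT_PIT"
    }
    rows[[i]] <- data.frame(
      id = sprintf("p%06d", i),
      user_id = sprintf("u%06d", i),
      created_at = format(base_time + (i - 1L) * 97, "%Y-%m-%dT%H:%M:%S"),
      text = add_noise(text, noise_rate),
      label = label, family = fam, template_pattern_id = pid,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

progress_templates <- c(
  "im {w} weeks pregnant and feeling {f}",
  "{w} weeks into the pregnancy and all is {f}",
  "i am {w} weeks pregnant today {f}")

#' Generate synthetic user timelines with ground truth
#'
#' Every user is a cohort member with a true pregnancy start date. Exactly
#' \code{round(n_users * mention_prevalence)} users (chosen by a seeded
#' draw) additionally post progress statements at known integer gestational
#' weeks; the rest post only neutral filler, so the fraction of users whose
#' trimester information is detectable is fixed by construction, mirroring a
#' cohort in which such statements are present for about 44\% of members.
#' Users with progress statements also receive drug-mention posts at
#' scheduled trimesters.
#'
#' @param n_users number of users; default 1000.
#' @param posts_per_user filler posts per user; default 12.
#' @param mention_prevalence fraction of users with progress statements;
#'   default 0.44.
#' @param mentions_per_user progress statements per mention-user; default 2.
#' @param drug_rate probability that a mention-user posts a drug mention in
#'   any given trimester; default 0.5.
#' @param drug_lexicon a \code{drug_lexicon} supplying surface variants to
#'   plant; default: the example lexicon shipped with the package.
#' @param jitter_days timestamp jitter (in days, uniform on
#'   \code{[0, jitter_days]}) added to progress-statement posts relative to
#'   the exact week offset; default 0 (sub-week dating is not recoverable
#'   from "X weeks pregnant" statements).
#' @param seed integer seed; mandatory.
#' @return list with \code{posts} (data frame: id, user_id, created_at,
#'   text), \code{truth_users} (user_id, start_date, has_mentions,
#'   n_mentions), \code{truth_posts} (post_id, user_id, true_week,
#'   true_phase), \code{truth_drugs} (user_id, post_id, drug, phase).
#' @export
generate_timeline_set <- function(n_users = 1000L, posts_per_user = 12L,
                                  mention_prevalence = 0.44,
                                  mentions_per_user = 2L, drug_rate = 0.5,
                                  drug_lexicon = NULL, jitter_days = 0,
                                  seed) {
  if (missing(seed)) stop("`seed` is mandatory")
  stopifnot(mention_prevalence >= 0, mention_prevalence <= 1)
  if (is.null(drug_lexicon)) {
    drug_lexicon <- load_drug_lexicon(
      system.file("extdata", "example_drug_lexicon.txt",
                  package = "pregcohort"))
  }
  set.seed(seed)
  n_mention <- round(n_users * mention_prevalence)
  mention_users <- sample(n_users, n_mention)
  rule <- trimester_rule()
  variants <- unlist(unclass(drug_lexicon), use.names = FALSE)
  variant_drug <- rep(names(drug_lexicon), lengths(unclass(drug_lexicon)))
  posts <- list(); truth_posts <- list(); truth_drugs <- list()
  truth_users <- vector("list", n_users)
  post_no <- 0L
  next_id <- function() {
    post_no <<- post_no + 1L
    sprintf("t%07d", post_no)
  }
  phase_of_week <- function(w) {
    ifelse(w < 1, "pre",
    ifelse(w <= rule$t1_end, "T1",
    ifelse(w <= rule$t2_end, "T2",
    ifelse(w <= rule$term_length_weeks, "T3", "post"))))
  }
  for (u in seq_len(n_users)) {
    uid <- sprintf("user%05d", u)
    start <- as.POSIXct("2016-01-01 00:00:00", tz = "UTC") +
      sample(0:180, 1L) * 86400
    has_mentions <- u %in% mention_users
    # neutral filler posts across the whole pregnancy window and beyond
    for (j in seq_len(posts_per_user)) {
      w <- stats::runif(1, -8, 46)
      id <- next_id()
      posts[[length(posts) + 1L]] <- data.frame(
        id = id, user_id = uid,
        created_at = format(start + w * 7 * 86400, "%Y-%m-%dT%H:%M:%S"),
        text = paste("the", sample(neutral_filler, 1L), "was great",
                     sample(neutral_filler, 1L)),
        stringsAsFactors = FALSE)
      truth_posts[[length(truth_posts) + 1L]] <- data.frame(
        post_id = id, user_id = uid, true_week = w,
        true_phase = phase_of_week(w), stringsAsFactors = FALSE)
    }
    n_mentions_u <- 0L
    if (has_mentions) {
      weeks <- sort(sample(5:38, mentions_per_user))
      for (w in weeks) {
        id <- next_id()
        offset <- w * 7 + stats::runif(1, 0, jitter_days)
        tpl <- sample(progress_templates, 1L)
        text <- sub("{w}", w, tpl, fixed = TRUE)
        text <- sub("{f}", sample(pit_filler, 1L), text, fixed = TRUE)
        posts[[length(posts) + 1L]] <- data.frame(
          id = id, user_id = uid,
          created_at = format(start + offset * 86400, "%Y-%m-%dT%H:%M:%S"),
          text = text, stringsAsFactors = FALSE)
        truth_posts[[length(truth_posts) + 1L]] <- data.frame(
          post_id = id, user_id = uid, true_week = w,
          true_phase = phase_of_week(w), stringsAsFactors = FALSE)
        n_mentions_u <- n_mentions_u + 1L
      }
      # drug mentions planted mid-trimester
      for (ph in c("T1", "T2", "T3")) {
        if (stats::runif(1) < drug_rate && length(variants)) {
          w <- switch(ph, T1 = 6, T2 = 20, T3 = 33) + sample(0:2, 1L)
          vi <- sample(length(variants), 1L)
          id <- next_id()
          posts[[length(posts) + 1L]] <- data.frame(
            id = id, user_id = uid,
            created_at = format(start + w * 7 * 86400, "%Y-%m-%dT%H:%M:%S"),
            text = paste("took some", variants[vi], "for my",
                         sample(c("headache", "nausea", "cold"), 1L)),
            stringsAsFactors = FALSE)
          truth_posts[[length(truth_posts) + 1L]] <- data.frame(
            post_id = id, user_id = uid, true_week = w, true_phase = ph,
            stringsAsFactors = FALSE)
          truth_drugs[[length(truth_drugs) + 1L]] <- data.frame(
            user_id = uid, post_id = id, drug = variant_drug[vi],
            phase = ph, stringsAsFactors = FALSE)
        }
      }
    }
    truth_users[[u]] <- data.frame(
      user_id = uid, start_date = format(start, "%Y-%m-%dT%H:%M:%S"),
      has_mentions = has_mentions, n_mentions = n_mentions_u,
      stringsAsFactors = FALSE)
  }
  list(posts = do.call(rbind, posts),
       truth_users = do.call(rbind, truth_users),
       truth_posts = do.call(rbind, truth_posts),
       truth_drugs = if (length(truth_drugs)) do.call(rbind, truth_drugs) else
         data.frame(user_id = character(0), post_id = character(0),
                    drug = character(0), phase = character(0),
                    stringsAsFactors = FALSE))
}

#' Generate deterministic resource fixtures on disk
#'
#' Writes a small embedding table (word2vec text format), a hierarchical
#' cluster table, and the four sentiment lexicon files for a given
#' vocabulary, in exactly the formats the resource readers consume.
#'
#' @param vocab character vector of tokens to cover.
#' @param dim embedding dimension (>= 2); default 8.
#' @param n_clusters number of clusters; default 20.
#' @param seed integer seed; mandatory.
#' @param dir output directory (created if needed).
#' @return named character vector of the six file paths (\code{embeddings},
#'   \code{clusters}, \code{positive}, \code{negative}, \code{polarity},
#'   \code{subjectivity}).
#' @export
generate_resource_fixtures <- function(vocab, dim = 8L, n_clusters = 20L,
                                       seed, dir = tempfile("fixtures")) {
  if (missing(seed)) stop("`seed` is mandatory")
  stopifnot(dim >= 2L, length(vocab) > 0L)
  vocab <- unique(tolower(vocab))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  paths <- c(embeddings = file.path(dir, "embeddings.txt"),
             clusters = file.path(dir, "clusters.tsv"),
             positive = file.path(dir, "positive.txt"),
             negative = file.path(dir, "negative.txt"),
             polarity = file.path(dir, "polarity.tsv"),
             subjectivity = file.path(dir, "subjectivity.tsv"))
  emb <- matrix(round(stats::rnorm(length(vocab) * dim), 6), ncol = dim)
  lines <- c(paste(length(vocab), dim),
             vapply(seq_along(vocab), function(i) {
               paste(vocab[i], paste(formatC(emb[i, ], format = "f",
                                             digits = 6), collapse = " "))
             }, character(1)))
  writeLines(lines, paths["embeddings"])
  cl <- sample(n_clusters, length(vocab), replace = TRUE)
  path_of <- vapply(cl, function(k) {
    paste(rev(as.integer(intToBits(k - 1L))[1:10]), collapse = "")
  }, character(1))
  ord <- order(cl)
  writeLines(paste(path_of[ord], vocab[ord],
                   sample(50:5000, length(vocab), replace = TRUE)[ord],
                   sep = "\t"),
             paths["clusters"])
  # positive/negative built from the filler vocabularies where present,
  # padded with random vocab tokens
  pos <- intersect(vocab, pit_filler)
  neg <- intersect(vocab, c("killing", "drama", "jealous", "deadline"))
  rest <- setdiff(vocab, c(pos, neg))
  extra <- sample(rest, min(length(rest), 6L))
  pos <- unique(c(pos, extra[seq_len(length(extra) %/% 2)]))
  neg <- unique(c(neg, setdiff(extra, pos)))
  writeLines(pos, paths["positive"])
  writeLines(neg, paths["negative"])
  scored <- sample(vocab, min(length(vocab), 30L))
  writeLines(paste(scored,
                   formatC(round(stats::runif(length(scored), -1, 1), 3),
                           format = "f", digits = 3), sep = "\t"),
             paths["polarity"])
  writeLines(paste(scored,
                   formatC(round(stats::runif(length(scored), -1, 1), 3),
                           format = "f", digits = 3),
                   formatC(round(stats::runif(length(scored), 0, 1), 3),
                           format = "f", digits = 3), sep = "\t"),
             paths["subjectivity"])
  paths
}

#' Tokens of a corpus (convenience for fixture generation)
#'
#' @param texts character vector of texts.
#' @return unique lowercase tokens across the corpus.
#' @export
corpus_vocabulary <- function(texts) {
  unique(unlist(lapply(texts, function(t) tokenize(t)$tokens)))
}
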