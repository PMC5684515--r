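reg <- compile_pattern_registry()

test_that("default registry has 14 compiled patterns and the five seed terms", {
  expect_s3_class(reg, "pattern_registry")
  expect_equal(nrow(reg$patterns), 14L)
  expect_setequal(reg$seed_terms,
                  c("pregnancy", "pregnant", "baby", "family", "mom"))
})

test_that("custom configs are honored and malformed ones rejected", {
  one <- compile_pattern_registry(data.frame(
    pattern_id = 1L, simplified_form = "my pregnancy",
    realized_expression = "\\bmy[[:space:][:punct:]]+pregnancy\\b"))
  expect_equal(nrow(one$patterns), 1L)
  expect_error(compile_pattern_registry(data.frame(
    pattern_id = 7L, simplified_form = "broken",
    realized_expression = "((unbalanced")), "pattern_id 7")
  expect_error(
    compile_pattern_registry(data.frame(pattern_id = integer(0),
                                        simplified_form = character(0),
                                        realized_expression = character(0))),
    "empty")
})

test_that("seed prefilter is substring-based and case-folding", {
  expect_true(prefilter_by_seeds(
    "i just took my pregnancy cravings to a whole new level", reg))
  expect_false(prefilter_by_seeds("hello world", reg))
  expect_true(prefilter_by_seeds("MOM!!!", reg))
  expect_true(prefilter_by_seeds("#pregnant and happy", reg))
})

test_that("every curated sample announcement text matches at least one pattern", {
  texts <- sample_announcement_texts()
  hits <- lapply(texts, match_patterns, registry = reg)
  expect_true(all(!vapply(hits, is.null, logical(1))))
})

test_that("specific sample texts match their expected patterns", {
  expect_true(1L %in% match_patterns(
    "well... im currently 39 weeks and 6 days pregnant... you can come any time now sweetie",
    reg))
  expect_true(12L %in% match_patterns(
    "i just took my pregnancy cravings to a whole new level: I put ranch on my macaroni and cheese.",
    reg))
  expect_true(8L %in% match_patterns("Cant believe im having a baby brother!",
                                     reg))
  expect_null(match_patterns("completely unrelated text", reg))
})

test_that("matching is invariant to case and apostrophe variant", {
  a <- match_patterns("I’M HAVING A BABY", reg)
  b <- match_patterns("i'm having a baby", reg)
  expect_equal(a, b)
  expect_true(8L %in% a)
})

test_that("prefilter is a necessary condition for any pattern match", {
  corpus <- generate_corpus(n_posts = 150, seed = 3)
  extra <- c("hello world", "no seeds here at all", corpus$text)
  for (t in extra) {
    if (!prefilter_by_seeds(t, reg)) {
      expect_null(match_patterns(t, reg))
    }
  }
})

test_that("scan_corpus tallies per-pattern counts with multi-pattern attribution", {
  posts <- data.frame(
    id = as.character(1:4), user_id = letters[1:4],
    created_at = rep("2016-01-01T00:00:00", 4),
    text = c("im 12 weeks pregnant",                     # pattern 1
             "been 3 weeks since i knew im pregnant",    # patterns 1 and 4
             "my pregnancy is lovely",                   # pattern 12
             "nothing relevant"),
    stringsAsFactors = FALSE)
  out <- scan_corpus(posts, reg)
  freq <- out$frequency_table
  expect_equal(freq$count[freq$pattern_id == 1], 2L)
  expect_equal(freq$count[freq$pattern_id == 4], 1L)
  expect_equal(freq$count[freq$pattern_id == 12], 1L)
  expect_equal(nrow(out$matches), 3L)
  # per-pattern counts sum >= distinct matched posts
  expect_gte(sum(freq$count), nrow(out$matches))
  expect_equal(unname(out$counts["matched"]), 3L)
})

test_that("scan_corpus on an empty corpus yields zero counts", {
  empty <- data.frame(id = character(0), user_id = character(0),
                      created_at = character(0), text = character(0),
                      stringsAsFactors = FALSE)
  out <- scan_corpus(empty, reg)
  expect_equal(nrow(out$matches), 0L)
  expect_true(all(out$frequency_table$count == 0))
})

test_that("planted pattern-1 announcements are counted exactly", {
  k <- 7L
  planted <- data.frame(
    id = sprintf("s%d", 1:10),
    user_id = sprintf("u%d", 1:10),
    created_at = rep("2016-05-01T10:00:00", 10),
    text = c(sprintf("im %d weeks pregnant and happy", 5:(4 + k)),
             rep("nice weather today", 10 - k)),
    stringsAsFactors = FALSE)
  out <- scan_corpus(planted, reg)
  expect_equal(out$frequency_table$count[1], k)
})

test_that("duplicate user+text posts collapse to the earliest timestamp", {
  posts <- data.frame(
    id = c("a", "b", "c"), user_id = c("u1", "u1", "u2"),
    created_at = c("2016-01-02T00:00:00", "2016-01-01T00:00:00",
                   "2016-01-03T00:00:00"),
    text = rep("my pregnancy is lovely", 3), stringsAsFactors = FALSE)
  out <- scan_corpus(posts, reg)
  expect_equal(sort(out$matches$post_id), c("b", "c"))
})

test_that("unreadable records are skipped and tallied", {
  posts <- data.frame(id = c("a", NA), user_id = c("u1", "u2"),
                      created_at = rep("2016-01-01T00:00:00", 2),
                      text = c("my pregnancy glow", "x"),
                      stringsAsFactors = FALSE)
  expect_warning(out <- scan_corpus(posts, reg), "skipped")
  expect_equal(unname(out$counts["rejects"]), 1L)
})

test_that("pattern config round-trips through the JSON file format", {
  path <- withr::local_tempfile(fileext = ".json")
  write_pattern_config(reg, path)
  reg2 <- compile_pattern_registry(path)
  expect_equal(reg2$patterns, reg$patterns)
})
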