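test_that("trimester boundaries follow the week-1/13/28 segmentation", {
  expect_equal(assign_trimester(c(1, 12, 13, 27, 28, 36, 45)),
               c(1L, 1L, 2L, 2L, 3L, 3L, 3L))
  expect_error(assign_trimester(0.5), "out of range")
  expect_error(assign_trimester(46), "out of range")
})

test_that("trimester assignment is monotone in gestational week", {
  weeks <- seq(1, 45, by = 0.25)
  expect_true(!is.unsorted(assign_trimester(weeks)))
})

test_that("the canonical worked example extracts quantity 6, unit week", {
  m <- extract_progress_mentions("6 weeks into the pregnancy")
  expect_equal(nrow(m), 1L)
  expect_equal(m$quantity, 6)
  expect_equal(m$unit, "week")
  expect_equal(m$seed_term, "pregnancy")
  expect_equal(m$gestational_week, 6)
})

test_that("timeline-style statements map to their trimesters", {
  m25 <- extract_progress_mentions(
    "Looking forward to #oneborneveryminute, love baby shows even if I am 25 weeks pregnant")
  expect_equal(m25$quantity, 25)
  expect_equal(m25$unit, "week")
  expect_equal(m25$trimester, 2L)
  m36 <- extract_progress_mentions(
    "me! 36 weeks pregnant and travelling from sunny weston super mare to see you!")
  expect_equal(m36$gestational_week, 36)
  expect_equal(m36$trimester, 3L)
})

test_that("no mention without a seed term or without number+unit in the window", {
  expect_equal(nrow(extract_progress_mentions("love my baby so much")), 0L)
  expect_equal(nrow(extract_progress_mentions("pregnant")), 0L)
  expect_equal(nrow(extract_progress_mentions("im pregnant and happy")), 0L)
  # number+unit outside the 6-token window
  far <- "im pregnant and one two three four five six seven 12 weeks"
  expect_equal(nrow(extract_progress_mentions(far)), 0L)
})

test_that("week+day combinations and number words are handled", {
  m <- extract_progress_mentions(
    "well... im currently 39 weeks and 6 days pregnant... come any time now")
  expect_equal(m$unit, "week")
  expect_equal(m$gestational_week, 39 + 6 / 7, tolerance = 1e-10)
  mw <- extract_progress_mentions("my sister is five weeks pregnant")
  expect_equal(mw$quantity, 5)
  mo <- extract_progress_mentions("25th week of my pregnancy going fine")
  expect_equal(mo$quantity, 25)
})

test_that("day-only phrasings need a since/been style wording", {
  ok <- extract_progress_mentions("been 21 days since i learned im pregnant")
  expect_equal(ok$unit[1], "day")
  expect_equal(ok$gestational_week[1], 3)
  no <- extract_progress_mentions("girls will be two days pregnant already")
  expect_equal(nrow(no), 0L)
})

test_that("unit conversion follows week/month/day rules with range checks", {
  expect_equal(gestational_week(25, "week"), 25)
  expect_equal(gestational_week(6, "month"), 26.07, tolerance = 0.01)
  expect_warning(out <- gestational_week(50, "week"), "discarded")
  expect_true(is.na(out))
})

test_that("hashtag segmentation recovers mentions like #37weekspregnant when enabled", {
  text <- "not burnt as i am mainly inside #37weekspregnant"
  expect_equal(nrow(extract_progress_mentions(text)), 0L)
  m <- extract_progress_mentions(text, segment_hashtags = TRUE)
  expect_equal(m$quantity, 37)
  expect_equal(m$trimester, 3L)
})

test_that("a single mention dates the start 7*week days back", {
  t0 <- as.POSIXct("2016-06-01 12:00:00", tz = "UTC")
  tl <- make_timeline("u1", "i am 25 weeks pregnant today", t0)
  est <- estimate_pregnancy_start(tl)
  expect_equal(as.numeric(difftime(t0, est$start_date, units = "days")), 175)
  expect_equal(est$dispersion_days, 0)
})

test_that("consistent mentions 14 days apart agree exactly", {
  t0 <- as.POSIXct("2016-06-01 12:00:00", tz = "UTC")
  tl <- make_timeline("u1",
                      c("i am 20 weeks pregnant today",
                        "i am 22 weeks pregnant today"),
                      c(t0, t0 + 14 * 86400))
  est <- estimate_pregnancy_start(tl)
  expect_equal(est$dispersion_days, 0)
  expect_equal(est$n_mentions, 2L)
  expect_true(as.numeric(est$start_date) <
                min(pregcohort:::as_post_time(tl$created_at)))
})

test_that("timelines without usable mentions yield no estimate", {
  tl <- make_timeline("u2", c("nice weather", "great coffee"),
                      as.POSIXct("2016-01-01", tz = "UTC") + c(0, 86400))
  expect_null(estimate_pregnancy_start(tl))
})

test_that("phase categorization respects the boundary arithmetic", {
  t0 <- as.POSIXct("2016-06-01 12:00:00", tz = "UTC")
  tl <- make_timeline("u1", "i am 10 weeks pregnant today", t0)
  est <- estimate_pregnancy_start(tl)
  s <- est$start_date
  probe <- make_timeline("u1", rep("x", 4),
                         c(s - 5 * 86400,    # before start
                           s + 70 * 86400,   # week 10
                           s + 120 * 86400,  # week ~17
                           s + 301 * 86400)) # beyond term
  ph <- categorize_timeline(probe, est)
  expect_equal(as.character(ph$phase), c("pre", "T1", "T2", "post"))
})

test_that("phases are monotone along a timeline", {
  set.seed(19)
  t0 <- as.POSIXct("2016-02-01", tz = "UTC")
  tl <- make_timeline("u1",
                      c(rep("hello", 30), "i am 18 weeks pregnant today"),
                      c(t0 + sort(runif(30, -50, 320)) * 86400,
                        t0 + 126 * 86400))
  est <- estimate_pregnancy_start(tl)
  ph <- categorize_timeline(tl[order(pregcohort:::as_post_time(tl$created_at)), ],
                            est)
  ord <- as.integer(factor(as.character(ph$phase),
                           levels = c("pre", "T1", "T2", "T3", "post")))
  expect_true(!is.unsorted(ord))
})

test_that("window interpretation is configurable", {
  # number+unit sit 3 tokens from the seed: found per-side, missed with a
  # 6-token total window (3 per side) pushed to 2 per side
  text <- "12 weeks along now into this pregnancy"
  expect_equal(nrow(extract_progress_mentions(text, window = 6,
                                              window_mode = "per_side")), 1L)
  expect_equal(nrow(extract_progress_mentions(text, window = 4,
                                              window_mode = "total")), 0L)
})
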