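test_that("per-stimulus group means average over participants", {
  p1 <- make_rating_df(2, participant = "p1")
  p2 <- make_rating_df(2, participant = "p2")
  p3 <- make_rating_df(2, participant = "p3")
  p1$valence <- c(40, 30)
  p2$valence <- c(60, 45)
  p3$valence <- c(50, 90)
  trials <- rating_trials(rbind(p1, p2, p3))
  gm <- stimulus_group_means(trials, "valence", "self_rating")
  expect_equal(unname(gm["s01"]), 50)        # (40+60+50)/3
  expect_equal(unname(gm["s02"]), 55)        # (30+45+90)/3
  # one participant only: mean of one equals own rating
  gm1 <- stimulus_group_means(rating_trials(p1), "valence", "self_rating")
  expect_equal(unname(gm1), c(40, 30))
})

test_that("differences follow the four normative definitions", {
  df <- make_rating_df(2)
  df$valence <- c(70, 50)
  df$others_valence <- c(60L, 55L)
  trials <- rating_trials(df)
  # diff: rating minus own others-estimate
  d <- compute_differences(trials, "diff", "valence")
  expect_equal(d$difference, c(10, -5))
  # diff2: rating minus rescaled database norm (db 5 -> 50, labels supplied)
  md <- make_meta_df(2, db_valence = c(7, 5))
  md$valence_class <- c("high", "low")
  meta <- stimulus_meta(md)
  d2 <- compute_differences(trials, "diff2", "valence", meta = meta)
  expect_equal(d2$difference, c(70 - 75, 50 - 50))
  # oavg: rating minus group mean of others-estimates
  do <- compute_differences(trials, "oavg", "valence")
  expect_equal(do$difference, c(70 - 60, 50 - 55))  # single participant
})

test_that("oavg against a supplied group mean matches direct subtraction", {
  df <- make_rating_df(1)
  df$valence <- 20
  trials <- rating_trials(df)
  gm <- c(s01 = 35)
  d <- compute_differences(trials, "oavg", "valence", group_means = gm)
  expect_equal(d$difference, -15)
})

test_that("missing normative values are reported by stimulus and condition", {
  trials <- rating_trials(make_rating_df(3))
  meta <- stimulus_meta(make_meta_df(2))
  expect_error(compute_differences(trials, "diff2", "valence", meta = meta),
               "s03.*diff2")
  expect_error(compute_differences(trials, "diff2", "valence"), "metadata")
})

test_that("consensus raters have identically zero avg/oavg differences", {
  # all participants give identical ratings -> group mean equals each rating
  rows <- do.call(rbind, lapply(c("p1", "p2", "p3"), function(p) {
    df <- make_rating_df(4, participant = p)
    df$valence <- c(30, 60, 20, 80)
    df$others_valence <- c(35L, 55L, 25L, 75L)
    df
  }))
  trials <- rating_trials(rows)
  expect_equal(compute_differences(trials, "avg", "valence")$difference,
               rep(0, 12))
  expect_equal(compute_differences(trials, "oavg", "valence")$difference,
               rep(c(-5, 5, -5, 5), 3))
})

test_that("differences are linear in the participant's ratings", {
  df <- make_rating_df(5)
  df$valence <- c(10, 40, 60, 30, 80)
  trials <- rating_trials(df)
  shifted <- df
  shifted$valence <- shifted$valence + 7
  strials <- rating_trials(shifted)
  for (cond in c("diff", "oavg")) {
    d0 <- compute_differences(trials, cond, "valence")$difference
    d1 <- compute_differences(strials, cond, "valence")$difference
    expect_equal(d1, d0 + 7, tolerance = 1e-12)
  }
})

test_that("leave-one-out group means drop the target participant", {
  p1 <- make_rating_df(2, participant = "p1")
  p2 <- make_rating_df(2, participant = "p2")
  p1$valence <- c(40, 30)
  p2$valence <- c(60, 50)
  trials <- rating_trials(rbind(p1, p2))
  d <- compute_differences(trials, "avg", "valence", leave_one_out = TRUE)
  # p1's norm for s01 is p2's rating alone (60)
  expect_equal(d$difference[d$participant_id == "p1"], c(40 - 60, 30 - 50))
  expect_equal(d$difference[d$participant_id == "p2"], c(60 - 40, 50 - 30))
})
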