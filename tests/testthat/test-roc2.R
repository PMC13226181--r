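test_that("confusion counts follow the correct/confidence quadrants", {
  cc <- confusion_at_criterion(c(TRUE, TRUE, FALSE, FALSE),
                               c(80, 60, 60, 20), 65)
  expect_equal(cc[, c("tp", "fp", "tn", "fn")],
               data.frame(tp = 1L, fp = 0L, tn = 2L, fn = 1L))
  # X = 1: every trial counts as high confidence
  c1 <- confusion_at_criterion(c(TRUE, FALSE), c(1, 100), 1)
  expect_equal(c1$fn + c1$tn, 0L)
  # all-correct input: fp = tn = 0 at any criterion
  ac <- confusion_at_criterion(rep(TRUE, 5), c(10, 30, 50, 70, 90), 50)
  expect_equal(ac$fp + ac$tn, 0L)
  # totals always sum to the trial count
  expect_equal(sum(cc[, c("tp", "fp", "tn", "fn")]), 4L)
})

test_that("ROC points sweep the grid with the TPR/FPR formulas", {
  curve <- roc_points(c(TRUE, TRUE, FALSE, FALSE), c(80, 60, 60, 20))
  expect_s3_class(curve, "roc2_curve")
  expect_equal(nrow(curve$points), 20)
  distinct <- unique(curve$points[, c("fpr", "tpr")])
  expect_setequal(paste(distinct$fpr, distinct$tpr),
                  paste(c(1, 0.5, 0, 0), c(1, 1, 0.5, 0)))
  # rates non-increasing as the criterion rises
  expect_true(all(diff(curve$points$tpr) <= 0))
  expect_true(all(diff(curve$points$fpr) <= 0))
  # constant confidence 50: (1,1) for X <= 50, (0,0) above
  flat <- roc_points(c(TRUE, FALSE), c(50, 50))
  expect_true(all(flat$points$tpr[flat$points$criterion <= 50] == 1))
  expect_true(all(flat$points$tpr[flat$points$criterion > 50] == 0))
  expect_error(roc_points(c(TRUE, TRUE), c(10, 20)), "incorrect")
})

test_that("AUROC2 integrates the anchored curve", {
  # hand enumeration over {(0,0),(0,0.5),(0.5,1),(1,1)} gives 0.875
  expect_equal(auroc2(c(TRUE, TRUE, FALSE, FALSE), c(80, 60, 60, 20),
                      min_n = 1), 0.875)
  # perfect separation
  expect_equal(auroc2(rep(c(TRUE, FALSE), each = 5),
                      rep(c(100, 1), each = 5)), 1.0)
  # confidence independent of accuracy at large n is near chance
  set.seed(202)
  n <- 4000
  expect_equal(auroc2(sample(c(TRUE, FALSE), n, replace = TRUE),
                      sample(1:100, n, replace = TRUE)), 0.5,
               tolerance = 0.03)
})

test_that("too few trials in a class yields NaN with a warning", {
  expect_warning(res <- auroc2(c(TRUE, TRUE, TRUE, FALSE),
                               c(90, 80, 70, 10)), "minimum")
  expect_true(is.nan(res))
})

test_that("trapezoid AUROC2 equals exhaustive pairwise enumeration", {
  set.seed(303)
  for (i in 1:300) {
    n <- sample(4:20, 1)
    correct <- c(TRUE, FALSE,
                 sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    conf <- sample(1:100, n, replace = TRUE)
    expect_equal(auroc2(correct, conf, min_n = 1),
                 oracle_auroc2(correct, conf), tolerance = 1e-12)
  }
})

test_that("AUROC2 is invariant to bin-preserving confidence transforms and
           flips under label swap", {
  set.seed(404)
  correct <- sample(c(TRUE, FALSE), 60, replace = TRUE, prob = c(0.6, 0.4))
  conf <- sample(1:100, 60, replace = TRUE)
  a <- auroc2(correct, conf)
  # snapping each confidence to the top of its grid bin preserves bins
  snapped <- pmin(5 * floor(conf / 5) + 4, 100)
  expect_equal(auroc2(correct, snapped), a, tolerance = 1e-12)
  expect_equal(auroc2(!correct, conf), 1 - a, tolerance = 1e-12)
})

test_that("the per-participant composition is deterministic and matches the
           manual pipeline", {
  cfg <- sim_config(n_participants = 2, n_stimuli = 40, seed = 77)
  sim <- simulate_rating_experiment(cfg)
  one <- sim$trials[sim$trials$participant_id == "P001", ]
  v1 <- auroc2_for_participant(one, "diff", "valence", min_n = 1)
  v2 <- auroc2_for_participant(one, "diff", "valence", min_n = 1)
  expect_identical(v1, v2)
  ser <- compute_differences(one, "diff", "valence")
  acc <- participant_accuracy(ser)
  expect_equal(v1, auroc2(acc$correct, acc$confidence, min_n = 1))
})

test_that("the AUROC2 table covers every participant-condition cell", {
  cfg <- sim_config(n_participants = 3, n_stimuli = 20, seed = 88)
  sim <- simulate_rating_experiment(cfg)
  tab <- auroc2_table(sim$trials, meta = sim$meta)
  expect_equal(nrow(tab), 3 * 2 * 4)  # participants x dimensions x conditions
  expect_true(all(tab$n_correct + tab$n_incorrect == 20))
  expect_true(all(is.finite(tab$auroc2) | is.nan(tab$auroc2)))
})
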