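test_that("d-prime follows the z-difference closed form", {
  meta <- stimulus_meta(make_meta_df(4))  # valence classes: high,low,high,low
  # symmetric rates: HR = 0.841, FAR = 0.159 gives d' ~ 2, c ~ 0 -- check
  # the formula on an arbitrary 2x2 table instead of engineering rates
  trials <- afc_trials(make_afc_df(
    4, valence_response = c("pleasant", "pleasant", "unpleasant", "unpleasant")))
  d <- type1_dprime_2afc(trials, meta, "valence")
  # HR = 1/2, FAR = 1/2 with n=2 per class -> corrected stays 0.5
  expect_equal(d$d_prime, 0)
  expect_equal(d$criterion_c, 0)
  # hand-check against qnorm on a larger table
  resp <- c(rep("pleasant", 9), "unpleasant",      # 9/10 hits
            rep("pleasant", 2), rep("unpleasant", 8))  # 2/10 false alarms
  cls <- rep(c("high", "low"), each = 10)
  df <- make_afc_df(20, valence_response = resp)
  meta20 <- stimulus_meta(data.frame(
    stimulus_id = sprintf("s%02d", 1:20), database = "IAPS",
    db_valence = ifelse(cls == "high", 7, 3), db_arousal = 6,
    stringsAsFactors = FALSE))
  d2 <- type1_dprime_2afc(afc_trials(df), meta20, "valence")
  expect_equal(d2$d_prime, qnorm(0.9) - qnorm(0.2), tolerance = 1e-12)
  expect_equal(d2$criterion_c, -0.5 * (qnorm(0.9) + qnorm(0.2)),
               tolerance = 1e-12)
})

test_that("extreme rates are corrected by the 1/(2N) rule", {
  expect_equal(correct_extreme_rate(1, 20), 0.975)
  expect_equal(correct_extreme_rate(0, 20), 0.025)
  expect_equal(correct_extreme_rate(0.25, 20), 0.25)
  # corrected d-prime: HR 1.0 -> 0.975 with 20 trials/class, FAR 0.25
  expect_equal(qnorm(correct_extreme_rate(1, 20)) - qnorm(0.25),
               qnorm(0.975) - qnorm(0.25))
})

test_that("confidence bins map edge values upward", {
  expect_equal(bin_confidence(c(10, 25, 49, 50, 75, 100)),
               c(1L, 2L, 2L, 3L, 4L, 4L))
  expect_equal(bin_confidence(1), 1L)
  expect_error(bin_confidence(5, edges = c(50, 20)), "increasing")
  expect_error(bin_confidence(0), "1..100")
})

test_that("sdt counts preserve class totals", {
  cts <- sdt_counts(c("s1", "s1", "s2", "s2"), c("r1", "r2", "r2", "r2"),
                    c(1, 3, 4, 2), K = 4)
  expect_equal(sum(cts["s1", , ]), 2)
  expect_equal(sum(cts["s2", , ]), 2)
  expect_error(sdt_counts("sx", "r1", 1), "s1")
})

test_that("meta-d-prime recovers the generating sensitivity for an ideal
           observer and degrades monotonically with confidence noise", {
  cts <- ideal_observer_counts(n = 1e4, d_true = 1.5, sigma_m = 0, seed = 11)
  fit <- fit_meta_d(cts)
  expect_true(fit$converged)
  expect_equal(fit$d_prime, 1.5, tolerance = 0.05)
  expect_gt(fit$m_ratio, 0.9)
  expect_lt(fit$m_ratio, 1.1)
  expect_equal(fit$m_ratio * fit$d_prime, fit$meta_d, tolerance = 1e-9)
  # second-order noise strictly lowers fitted meta-d
  noisy <- fit_meta_d(ideal_observer_counts(1e4, 1.5, sigma_m = 1, seed = 11))
  expect_lt(noisy$meta_d, fit$meta_d)
  expect_lt(noisy$m_ratio, 1)
})

test_that("degenerate count tables are rejected", {
  one_resp <- sdt_counts(rep(c("s1", "s2"), each = 3), rep("r2", 6),
                         rep(1:3, 2), K = 4)
  expect_error(fit_meta_d(one_resp), "both responses")
})

test_that("the 2AFC wrapper reproduces a direct fit", {
  cfg <- sim_config(n_participants = 1, n_stimuli = 60, sigma_m = 0.3,
                    seed = 19)
  sim <- simulate_2afc_experiment(cfg)
  fit <- fit_meta_d_2afc(sim$trials, sim$meta, "valence")
  expect_s3_class(fit, "sdt_result")
  expect_true(is.finite(fit$meta_d))
  d1 <- type1_dprime_2afc(sim$trials, sim$meta, "valence")
  expect_equal(fit$d_prime, d1$d_prime, tolerance = 1e-12)
})

test_that("rating-task d-prime tracks the rank alignment of ratings and norms", {
  norms <- stats::setNames(seq(10, 90, length.out = 60),
                           sprintf("s%02d", 1:60))
  df <- make_rating_df(60)
  df$valence <- round(seq(10, 90, length.out = 60))  # perfectly aligned
  aligned <- type1_dprime_rating(rating_trials(df), norms, "valence")
  expect_gt(aligned$d_prime, 2)
  df$valence <- rev(df$valence)                      # anti-ordered
  anti <- type1_dprime_rating(rating_trials(df), norms, "valence")
  expect_lt(anti$d_prime, 0)
  set.seed(31)
  df$valence <- sample(0:100, 60, replace = TRUE)    # independent
  indep <- type1_dprime_rating(rating_trials(df), norms, "valence")
  expect_lt(abs(indep$d_prime), 0.8)
  expect_error(type1_dprime_rating(rating_trials(df),
                                   stats::setNames(rep(50, 60), names(norms)),
                                   "valence"), "identical")
})
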