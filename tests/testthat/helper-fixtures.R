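# Builders for small valid trial tables, and independent oracles.

make_rating_df <- function(n = 4, participant = "p1", session = 1L,
                           valence = NULL, confidence = NULL,
                           others = NULL, familiarity = NULL) {
  data.frame(
    participant_id = rep(participant, n),
    session = rep(session, n),
    stimulus_id = sprintf("s%02d", seq_len(n)),
    valence = if (is.null(valence)) seq(10, by = 10, length.out = n) %% 101 else valence,
    arousal = seq(5, by = 7, length.out = n) %% 101,
    valence_confidence = if (is.null(confidence)) rep(50L, n) else confidence,
    arousal_confidence = rep(60L, n),
    others_valence = if (is.null(others)) rep(40L, n) else others,
    others_arousal = rep(45L, n),
    familiarity = if (is.null(familiarity)) rep(70L, n) else familiarity,
    stringsAsFactors = FALSE
  )
}

make_afc_df <- function(n = 4, participant = "p1", session = 1L,
                        valence_response = NULL, arousal_response = NULL,
                        confidence = NULL) {
  data.frame(
    participant_id = participant,
    session = session,
    stimulus_id = sprintf("s%02d", seq_len(n)),
    valence_response = if (is.null(valence_response)) {
      rep(c("pleasant", "unpleasant"), length.out = n)
    } else valence_response,
    arousal_response = if (is.null(arousal_response)) {
      rep(c("high", "low"), length.out = n)
    } else arousal_response,
    valence_confidence = if (is.null(confidence)) rep(50L, n) else confidence,
    arousal_confidence = rep(55L, n),
    familiarity = rep(60L, n),
    stringsAsFactors = FALSE
  )
}

make_meta_df <- function(n = 4, db_valence = NULL, db_arousal = NULL) {
  data.frame(
    stimulus_id = sprintf("s%02d", seq_len(n)),
    database = "IAPS",
    db_valence = if (is.null(db_valence)) rep(c(7, 2), length.out = n) else db_valence,
    db_arousal = if (is.null(db_arousal)) rep(c(6, 3), length.out = n) else db_arousal,
    stringsAsFactors = FALSE
  )
}

# difference series wrapper for direct accuracy-rule tests
make_series <- function(differences, confidence = rep(50L, length(differences)),
                        participant = "p1", session = 1L) {
  res <- data.frame(
    participant_id = participant, session = session,
    stimulus_id = sprintf("s%03d", seq_along(differences)),
    condition = "diff", dimension = "valence",
    difference = differences, confidence = as.integer(confidence),
    stringsAsFactors = FALSE
  )
  class(res) <- c("difference_series", "data.frame")
  res
}

# Independent AUROC2 oracle: probability that a random correct trial's
# grid-binned confidence exceeds a random incorrect trial's, ties counting
# one half, by exhaustive pairwise enumeration.
oracle_auroc2 <- function(correct, confidence, grid = seq(5L, 100L, by = 5L)) {
  bin <- vapply(confidence, function(cc) sum(grid <= cc), numeric(1))
  cs <- bin[correct]
  is <- bin[!correct]
  tot <- 0
  for (ci in cs) tot <- tot + sum(ci > is) + 0.5 * sum(ci == is)
  tot / (length(cs) * length(is))
}

# Ideal-observer 2AFC generator: confidence is a deterministic monotone map
# of |decision variable| plus optional second-order Gaussian noise.
ideal_observer_counts <- function(n, d_true, sigma_m = 0, seed = 11, K = 4L) {
  set.seed(seed)
  x <- c(stats::rnorm(n, -d_true / 2), stats::rnorm(n, d_true / 2))
  stim <- rep(c("s1", "s2"), each = n)
  resp <- ifelse(x > 0, "r2", "r1")
  xt <- abs(x) + stats::rnorm(2 * n, 0, sigma_m)
  conf <- pmin(pmax(round(1 + 99 * pmin(pmax(xt, 0), 3) / 3), 1), 100)
  sdt_counts(stim, resp, bin_confidence(conf), K = K)
}
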