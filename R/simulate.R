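#' Configuration for the synthetic-experiment simulator
#'
#' Defaults mirror the study conditions of the slider-rating design: 60
#' stimuli (15 per affective category), 58 participants, one trial per
#' stimulus per session. Noise parameters are on the 0-100 response scale:
#' `sigma_b` is the SD of a participant's stable rating bias, `sigma_1` the
#' first-order (trial-to-trial) rating noise, `sigma_o` the noise on the
#' participant's estimate of what others feel, and `sigma_m` the
#' metacognitive (second-order) noise corrupting the internal readout of
#' the trial's rating-norm difference — the single dial that degrades
#' metacognitive sensitivity without touching first-order behavior.
#' `sigma_m_sd` spreads `sigma_m` across participants (each participant
#' draws a private metacognitive noise level once, stable across sessions),
#' which is what gives AUROC2 test-retest structure. `d_true` is the type-1
#' sensitivity of the forced-choice observer.
#'
#' @param n_stimuli number of stimuli, a multiple of 4 (balanced over
#'   HVHA/HVLA/LVLA/LVHA); default 60.
#' @param n_participants number of participants; default 58.
#' @param sessions 1 or 2.
#' @param mu optional data.frame of supplied stimulus means (columns
#'   `stimulus_id`, `mu_valence`, `mu_arousal` on 0-100); drawn
#'   category-stratified uniform when `NULL`.
#' @param sigma_b participant bias SD; default 10.
#' @param sigma_1 first-order rating noise SD; default 15.
#' @param sigma_o others-estimate noise SD; default 10.
#' @param sigma_m metacognitive noise SD, in the units of the confidence
#'   evidence for the chosen design: 0-100 response-scale points for the
#'   rating design, decision-variable (unit-variance) units for the
#'   forced-choice design. The default 10 suits the rating design; values
#'   around 0.5-2 are comparable degradations for forced-choice runs.
#' @param sigma_m_sd across-participant SD of the metacognitive noise
#'   level; default 0.
#' @param d_true forced-choice type-1 sensitivity; default 1.5.
#' @param seed integer seed; mandatory, no silent entropy.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_stimuli = 60L, n_participants = 58L, sessions = 1L,
                       mu = NULL, sigma_b = 10, sigma_1 = 15, sigma_o = 10,
                       sigma_m = 10, sigma_m_sd = 0, d_true = 1.5, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (n_stimuli < 4 || n_stimuli %% 4 != 0) {
    stop("n_stimuli must be a positive multiple of 4", call. = FALSE)
  }
  if (n_participants < 1) stop("need at least one participant", call. = FALSE)
  if (!sessions %in% c(1L, 2L)) stop("sessions must be 1 or 2", call. = FALSE)
  for (s in c(sigma_b, sigma_1, sigma_o, sigma_m, sigma_m_sd)) {
    if (is.na(s) || s < 0) stop("all SDs must be >= 0", call. = FALSE)
  }
  if (d_true < 0) stop("d_true must be >= 0", call. = FALSE)
  structure(list(
    n_stimuli = as.integer(n_stimuli),
    n_participants = as.integer(n_participants),
    sessions = as.integer(sessions), mu = mu,
    sigma_b = sigma_b, sigma_1 = sigma_1, sigma_o = sigma_o,
    sigma_m = sigma_m, sigma_m_sd = sigma_m_sd,
    d_true = d_true, seed = as.integer(seed)
  ), class = "sim_config")
}

# deterministic per-(participant, session, stream) seed below 2^31
.derive_seed <- function(seed, p, s = 0L, stream = 0L) {
  m <- 2147483647
  x <- (as.numeric(seed) %% m)
  x <- (x * 69069 + p * 104729 + s * 7919 + stream * 15485863 + 1) %% m
  as.integer(x)
}

#' Simulate a balanced affective stimulus set
#'
#' Draws per-stimulus normative means on the 0-100 scale, stratified so
#' that each of the four categories (HVHA/HVLA/LVLA/LVHA) gets a quarter of
#' the stimuli: "high" dimensions are uniform on (57.5, 90), "low" on
#' (10, 42.5), keeping a margin around the category boundary as curated
#' picture sets do. Database ratings are the means mapped back to the
#' 9-point scale.
#'
#' @param n_stimuli multiple of 4.
#' @param seed integer seed.
#' @return list with `meta` (a [stimulus_meta] table) and `mu` (data.frame
#'   `stimulus_id`, `mu_valence`, `mu_arousal`).
#' @export
simulate_stimuli <- function(n_stimuli = 60L, seed) {
  set.seed(.derive_seed(seed, 0L, 0L, 1L))
  per <- n_stimuli %/% 4L
  cats <- rep(c("HVHA", "HVLA", "LVLA", "LVHA"), each = per)
  hi <- function(n) stats::runif(n, 57.5, 90)
  lo <- function(n) stats::runif(n, 10, 42.5)
  n <- length(cats)
  muv <- ifelse(substr(cats, 1, 2) == "HV", hi(n), lo(n))
  mua <- ifelse(substr(cats, 3, 4) == "HA", hi(n), lo(n))
  ids <- sprintf("stim%03d", seq_len(n))
  meta <- stimulus_meta(data.frame(
    stimulus_id = ids,
    database = "IAPS",
    db_valence = 1 + muv / 100 * 8,
    db_arousal = 1 + mua / 100 * 8,
    stringsAsFactors = FALSE
  ))
  list(meta = meta,
       mu = data.frame(stimulus_id = ids, mu_valence = muv, mu_arousal = mua,
                       stringsAsFactors = FALSE))
}

.clip_round <- function(x, lo, hi) as.integer(round(pmin(pmax(x, lo), hi)))

#' Simulate a slider-rating experiment
#'
#' Generative model per trial and dimension: internal evidence
#' e = mu_s + b_p + eps with eps ~ N(0, sigma_1); the recorded rating is e
#' clipped to 0-100 and rounded. The others-estimate is mu_s + zeta,
#' zeta ~ N(0, sigma_o). Confidence is built from second-order access to
#' the quantity the accuracy rule scores: the trial's recorded rating-norm
#' difference d (rating minus others-estimate) is corrupted by
#' N(0, sigma_m_p) and compared with the participant's running mean of past
#' differences; confidence = 100 - 2 |d_tilde - running_mean|, clipped into
#' 1-100 and rounded. With sigma_m = 0 confidence is a deterministic
#' monotone readout of the accuracy statistic; as sigma_m grows confidence
#' decouples from accuracy and AUROC2 falls to chance.
#'
#' Participant traits (bias per dimension, private metacognitive noise
#' level) are drawn once and shared across sessions, so two-session runs
#' carry genuine test-retest structure.
#'
#' @param cfg a [sim_config()].
#' @return list with `trials` (a [rating_trials] table), `meta` (the
#'   [stimulus_meta] table), and `truth` (list: `mu`, `participants`,
#'   `clip_rate`).
#' @export
simulate_rating_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  stim <- if (is.null(cfg$mu)) {
    simulate_stimuli(cfg$n_stimuli, cfg$seed)
  } else {
    list(meta = NULL, mu = cfg$mu)
  }
  mu <- stim$mu

  set.seed(.derive_seed(cfg$seed, 0L, 0L, 2L))
  pid <- sprintf("P%03d", seq_len(cfg$n_participants))
  traits <- data.frame(
    participant_id = pid,
    bias_valence = stats::rnorm(cfg$n_participants, 0, cfg$sigma_b),
    bias_arousal = stats::rnorm(cfg$n_participants, 0, cfg$sigma_b),
    sigma_m = abs(stats::rnorm(cfg$n_participants, cfg$sigma_m, cfg$sigma_m_sd)),
    stringsAsFactors = FALSE
  )

  n_clip <- 0L
  n_vals <- 0L
  rows <- vector("list", cfg$n_participants * cfg$sessions)
  i <- 0L
  for (p in seq_len(cfg$n_participants)) {
    for (s in seq_len(cfg$sessions)) {
      set.seed(.derive_seed(cfg$seed, p, s, 3L))
      ord <- sample.int(nrow(mu))
      n <- nrow(mu)
      one_dim <- function(mus, bias, sm) {
        e <- mus + bias + stats::rnorm(n, 0, cfg$sigma_1)
        rating <- .clip_round(e, 0, 100)
        others <- .clip_round(mus + stats::rnorm(n, 0, cfg$sigma_o), 0, 100)
        d <- rating - others
        d_tilde <- d + stats::rnorm(n, 0, sm)
        run_mean <- c(0, cumsum(d)[-n] / seq_len(n - 1))
        conf <- .clip_round(100 - 2 * abs(d_tilde - run_mean), 1, 100)
        n_clip <<- n_clip + sum(e < 0 | e > 100)
        n_vals <<- n_vals + n
        list(rating = rating, others = others, conf = conf, e = e)
      }
      v <- one_dim(mu$mu_valence[ord], traits$bias_valence[p], traits$sigma_m[p])
      a <- one_dim(mu$mu_arousal[ord], traits$bias_arousal[p], traits$sigma_m[p])
      fam <- .clip_round(stats::rnorm(n, 70, 20), 0, 100)
      i <- i + 1L
      rows[[i]] <- data.frame(
        participant_id = pid[p], session = s,
        stimulus_id = mu$stimulus_id[ord],
        valence = v$rating, arousal = a$rating,
        valence_confidence = v$conf, arousal_confidence = a$conf,
        others_valence = v$others, others_arousal = a$others,
        familiarity = fam, stringsAsFactors = FALSE
      )
    }
  }
  trials <- rating_trials(do.call(rbind, rows))
  list(trials = trials, meta = stim$meta,
       truth = list(mu = mu, participants = traits,
                    clip_rate = n_clip / n_vals))
}

#' Simulate a two-alternative forced-choice experiment
#'
#' Standard equal-variance SDT per trial and dimension: the decision
#' variable x ~ N(+d_true/2, 1) for high-class stimuli and N(-d_true/2, 1)
#' for low-class ones; the response is the signal label iff x > 0
#' (criterion at 0). Confidence reads out |x| corrupted by N(0, sigma_m_p)
#' and is mapped affinely (|x| of 3 spans the scale) into 1-100. Stimulus
#' classes are balanced across the four affective categories.
#'
#' @param cfg a [sim_config()] with `d_true > 0`.
#' @return list with `trials` (an [afc_trials] table), `meta`, and `truth`
#'   (list: `mu`, `participants`, per-trial decision variables omitted for
#'   size).
#' @export
simulate_2afc_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  stim <- simulate_stimuli(cfg$n_stimuli, cfg$seed)
  meta <- stim$meta

  set.seed(.derive_seed(cfg$seed, 0L, 0L, 4L))
  pid <- sprintf("P%03d", seq_len(cfg$n_participants))
  traits <- data.frame(
    participant_id = pid,
    sigma_m = abs(stats::rnorm(cfg$n_participants, cfg$sigma_m, cfg$sigma_m_sd)),
    stringsAsFactors = FALSE
  )

  rows <- vector("list", cfg$n_participants * cfg$sessions)
  i <- 0L
  for (p in seq_len(cfg$n_participants)) {
    for (s in seq_len(cfg$sessions)) {
      set.seed(.derive_seed(cfg$seed, p, s, 5L))
      ord <- sample.int(nrow(meta))
      n <- length(ord)
      one_dim <- function(cls, sig_label, noise_label) {
        x <- stats::rnorm(n, ifelse(cls == "high", cfg$d_true / 2,
                                    -cfg$d_true / 2), 1)
        resp <- ifelse(x > 0, sig_label, noise_label)
        x_tilde <- abs(x) + stats::rnorm(n, 0, traits$sigma_m[p])
        conf <- .clip_round(1 + 99 * pmin(pmax(x_tilde, 0), 3) / 3, 1, 100)
        list(resp = resp, conf = conf, x = x)
      }
      v <- one_dim(meta$valence_class[ord], "pleasant", "unpleasant")
      a <- one_dim(meta$arousal_class[ord], "high", "low")
      fam <- .clip_round(stats::rnorm(n, 70, 20), 0, 100)
      i <- i + 1L
      rows[[i]] <- data.frame(
        participant_id = pid[p], session = s,
        stimulus_id = meta$stimulus_id[ord],
        valence_response = v$resp, arousal_response = a$resp,
        valence_confidence = v$conf, arousal_confidence = a$conf,
        familiarity = fam, stringsAsFactors = FALSE
      )
    }
  }
  trials <- afc_trials(do.call(rbind, rows))
  list(trials = trials, meta = meta,
       truth = list(mu = stim$mu, participants = traits))
}
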