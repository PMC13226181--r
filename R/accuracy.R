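#' Score rating trials with the participant-based accuracy interval
#'
#' For each participant-session, the mean (Avg) and standard deviation (SD)
#' of that participant's rating-norm differences are computed over all their
#' trials, and a trial is scored correct iff its difference lies within
#' Avg +/- k*SD (boundaries inclusive). The default multiplier k = 0.675 is
#' the Gaussian quartile factor: under a Gaussian distribution of
#' differences approximately half the trials fall inside the interval, so
#' each participant is scored against their own internal variability with a
#' balanced correct/incorrect split.
#'
#' @param series a `difference_series` from [compute_differences()].
#' @param k interval half-width in SD units; default `0.675`.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return an `accuracy_vector` data.frame with columns `participant_id`,
#'   `session`, `stimulus_id`, `correct` (logical), `confidence`, plus an
#'   `"intervals"` attribute: one row per participant-session with
#'   `avg_diff`, `sd_diff`, `k`, `lower`, `upper`.
#' @export
participant_accuracy <- function(series, k = 0.675,
                                 sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  grp <- interaction(series$participant_id, series$session, drop = TRUE)
  correct <- logical(nrow(series))
  ints <- NULL
  for (g in levels(grp)) {
    in_g <- grp == g
    d <- series$difference[in_g]
    if (length(d) < 2) {
      stop(sprintf("participant '%s' session %d has fewer than 2 trials; SD undefined",
                   series$participant_id[in_g][1], series$session[in_g][1]),
           call. = FALSE)
    }
    avg <- mean(d)
    s <- stats::sd(d)
    if (sd_type == "population") s <- s * sqrt((length(d) - 1) / length(d))
    lower <- avg - k * s
    upper <- avg + k * s
    correct[in_g] <- d >= lower & d <= upper
    ints <- rbind(ints, data.frame(
      participant_id = series$participant_id[in_g][1],
      session = series$session[in_g][1],
      avg_diff = avg, sd_diff = s, k = k, lower = lower, upper = upper,
      stringsAsFactors = FALSE
    ))
  }
  res <- data.frame(
    participant_id = series$participant_id,
    session = series$session,
    stimulus_id = series$stimulus_id,
    correct = correct,
    confidence = series$confidence,
    stringsAsFactors = FALSE
  )
  attr(res, "intervals") <- ints
  class(res) <- c("accuracy_vector", "data.frame")
  res
}

#' Score forced-choice trials against database stimulus categories
#'
#' A valence trial is correct iff the response "pleasant" was given to a
#' stimulus whose database valence class is high (and "unpleasant" to a low
#' one); an arousal trial is correct iff the response "high" matches a
#' high-arousal class (and "low" a low one).
#'
#' @param trials an [afc_trials] table.
#' @param meta a [stimulus_meta] table covering every stimulus in `trials`.
#' @param dimension `"valence"` or `"arousal"`.
#' @return an `accuracy_vector` data.frame (no interval attribute).
#' @export
afc_accuracy <- function(trials, meta, dimension = c("valence", "arousal")) {
  dimension <- match.arg(dimension)
  idx <- match(trials$stimulus_id, meta$stimulus_id)
  if (anyNA(idx)) {
    stop(sprintf("stimulus '%s' missing from metadata",
                 trials$stimulus_id[which(is.na(idx))[1]]), call. = FALSE)
  }
  cls <- meta[[paste0(dimension, "_class")]][idx]
  resp <- trials[[paste0(dimension, "_response")]]
  correct <- if (dimension == "valence") {
    (resp == "pleasant") == (cls == "high")
  } else {
    (resp == "high") == (cls == "high")
  }
  res <- data.frame(
    participant_id = trials$participant_id,
    session = trials$session,
    stimulus_id = trials$stimulus_id,
    correct = correct,
    confidence = as.integer(trials[[paste0(dimension, "_confidence")]]),
    stringsAsFactors = FALSE
  )
  class(res) <- c("accuracy_vector", "data.frame")
  res
}

#' Split trials by familiarity
#'
#' Trials with familiarity at or above the cutoff go to the high-familiarity
#' partition, the rest to the low one; the split is exhaustive and disjoint.
#'
#' @param trials a trial table with a `familiarity` column.
#' @param cutoff familiarity threshold; default 50 (`>= 50` is high).
#' @return list with `high` and `low` trial tables.
#' @export
familiarity_split <- function(trials, cutoff = 50) {
  hi <- trials$familiarity >= cutoff
  list(high = trials[hi, , drop = FALSE], low = trials[!hi, , drop = FALSE])
}
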