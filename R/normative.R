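#' Per-stimulus group means of self- or others-ratings
#'
#' For the sample-average normative standards, each stimulus gets the
#' arithmetic mean over all kept participants of either their own ratings
#' (`self_rating`) or their estimates of what others would feel
#' (`others_rating`). Means are computed within session, since different
#' sessions may use different stimulus sets.
#'
#' @param trials a [rating_trials] table (typically after exclusion).
#' @param dimension `"valence"` or `"arousal"`.
#' @param source `"self_rating"` for the mean of participants' own ratings,
#'   `"others_rating"` for the mean of their others-estimates.
#' @param session session to average within; defaults to all rows present.
#' @return named numeric vector, stimulus_id -> mean rating on the 0-100
#'   scale.
#' @export
stimulus_group_means <- function(trials,
                                 dimension = c("valence", "arousal"),
                                 source = c("self_rating", "others_rating"),
                                 session = NULL) {
  dimension <- match.arg(dimension)
  source <- match.arg(source)
  if (!is.null(session)) trials <- trials[trials$session == session, , drop = FALSE]
  if (nrow(trials) == 0) stop("no trials to average", call. = FALSE)
  col <- if (source == "self_rating") dimension else paste0("others_", dimension)
  m <- tapply(trials[[col]], trials$stimulus_id, mean)
  stats::setNames(as.numeric(m), dimnames(m)[[1]])[unique(trials$stimulus_id)]
}

#' Per-trial differences between a participant's ratings and a normative
#' standard
#'
#' Four normative standards are supported per dimension, mirroring the
#' nomenclature V_diff/V_diff2/V_avg/V_oavg (and the A_* analogues):
#' \describe{
#'   \item{diff}{rating minus the participant's own estimate of what others
#'     would feel for that stimulus.}
#'   \item{diff2}{rating minus the affective-database norm, rescaled from the
#'     9-point database scale to 0-100 via [rescale_db_rating()].}
#'   \item{avg}{rating minus the sample average of all participants' own
#'     ratings of that stimulus.}
#'   \item{oavg}{rating minus the sample average of all participants'
#'     others-estimates of that stimulus.}
#' }
#'
#' @param trials a [rating_trials] table (one or more participants/sessions).
#' @param condition one of `"diff"`, `"diff2"`, `"avg"`, `"oavg"`.
#' @param dimension `"valence"` or `"arousal"`.
#' @param meta a [stimulus_meta] table; required for `condition = "diff2"`.
#' @param group_means named vector from [stimulus_group_means()]; required
#'   for `avg`/`oavg`. When `NULL` it is computed from `trials` within each
#'   session (including each participant's own rating in the mean; set
#'   `leave_one_out = TRUE` to drop the target participant's contribution).
#' @param leave_one_out drop the participant's own rating from the group
#'   mean used for their trials (only meaningful when `group_means` is
#'   computed internally). Default `FALSE`.
#' @return a `difference_series` data.frame with columns `participant_id`,
#'   `session`, `stimulus_id`, `condition`, `dimension`, `difference`, and
#'   `confidence` (the matching confidence rating, carried along for the
#'   type-2 analysis).
#' @export
compute_differences <- function(trials,
                                condition = c("diff", "diff2", "avg", "oavg"),
                                dimension = c("valence", "arousal"),
                                meta = NULL, group_means = NULL,
                                leave_one_out = FALSE) {
  condition <- match.arg(condition)
  dimension <- match.arg(dimension)
  rating <- trials[[dimension]]
  conf <- trials[[paste0(dimension, "_confidence")]]

  norm <- switch(condition,
    diff = trials[[paste0("others_", dimension)]],
    diff2 = {
      if (is.null(meta)) {
        stop("condition 'diff2' requires stimulus metadata", call. = FALSE)
      }
      idx <- match(trials$stimulus_id, meta$stimulus_id)
      if (anyNA(idx)) {
        stop(sprintf("no database norm for stimulus '%s' (condition diff2)",
                     trials$stimulus_id[which(is.na(idx))[1]]), call. = FALSE)
      }
      rescale_db_rating(meta[[paste0("db_", dimension)]][idx])
    },
    # avg / oavg: session-wise group means
    {
      src <- if (condition == "avg") "self_rating" else "others_rating"
      col <- if (condition == "avg") dimension else paste0("others_", dimension)
      out <- numeric(nrow(trials))
      for (s in unique(trials$session)) {
        in_s <- trials$session == s
        if (is.null(group_means)) {
          gm_n <- tapply(trials[[col]][in_s], trials$stimulus_id[in_s], length)
          gm <- tapply(trials[[col]][in_s], trials$stimulus_id[in_s], mean)
        } else {
          gm <- group_means
          gm_n <- NULL
        }
        idx <- match(trials$stimulus_id[in_s], names(gm))
        if (anyNA(idx)) {
          stop(sprintf("no group mean for stimulus '%s' (condition %s)",
                       trials$stimulus_id[in_s][which(is.na(idx))[1]],
                       condition), call. = FALSE)
        }
        m <- unname(gm[idx])
        if (leave_one_out) {
          if (is.null(gm_n)) {
            stop("leave_one_out requires internally computed group means",
                 call. = FALSE)
          }
          n <- unname(gm_n[idx])
          if (any(n < 2)) {
            stop("leave-one-out mean undefined for a stimulus rated once",
                 call. = FALSE)
          }
          m <- (m * n - trials[[col]][in_s]) / (n - 1)
        }
        out[in_s] <- m
      }
      out
    }
  )

  res <- data.frame(
    participant_id = trials$participant_id,
    session = trials$session,
    stimulus_id = trials$stimulus_id,
    condition = condition,
    dimension = dimension,
    difference = as.numeric(rating) - as.numeric(norm),
    confidence = as.integer(conf),
    stringsAsFactors = FALSE
  )
  class(res) <- c("difference_series", "data.frame")
  res
}
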