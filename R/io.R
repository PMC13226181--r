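#' Column schemas for the two trial designs
#'
#' Trial tables are long-format (one trial per row), UTF-8 CSV with a header
#' row. The rating design carries continuous 0-100 valence/arousal ratings,
#' the participant's estimate of what others would feel on the same scales,
#' 1-100 confidence in each rating, and 0-100 familiarity. The forced-choice
#' design replaces the continuous ratings with binary responses
#' (pleasant/unpleasant, high/low).
#'
#' @keywords internal
#' @name trial_schemas
NULL

.rating_cols <- c("participant_id", "session", "stimulus_id",
                  "valence", "arousal",
                  "valence_confidence", "arousal_confidence",
                  "others_valence", "others_arousal", "familiarity")

.afc_cols <- c("participant_id", "session", "stimulus_id",
               "valence_response", "arousal_response",
               "valence_confidence", "arousal_confidence", "familiarity")

.meta_cols <- c("stimulus_id", "database", "db_valence", "db_arousal")

# closed-range checks per column; confidence scales start at 1, the rating
# scales at 0 (the sliders had 101 points, 0..100)
.rating_ranges <- list(
  valence = c(0, 100), arousal = c(0, 100),
  valence_confidence = c(1, 100), arousal_confidence = c(1, 100),
  others_valence = c(0, 100), others_arousal = c(0, 100),
  familiarity = c(0, 100)
)

.afc_ranges <- list(
  valence_confidence = c(1, 100), arousal_confidence = c(1, 100),
  familiarity = c(0, 100)
)

.check_ranges <- function(df, ranges) {
  for (col in names(ranges)) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      stop(sprintf("column '%s' must be numeric", col), call. = FALSE)
    }
    bad <- which(is.na(v) | v < ranges[[col]][1] | v > ranges[[col]][2])
    if (length(bad)) {
      stop(sprintf(
        "column '%s' out of range [%g, %g] in row(s) %s",
        col, ranges[[col]][1], ranges[[col]][2],
        paste(utils::head(bad, 10), collapse = ", ")
      ), call. = FALSE)
    }
  }
  invisible(df)
}

.check_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

.check_unique_trials <- function(df) {
  key <- paste(df$participant_id, df$session, df$stimulus_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop(sprintf("duplicate trial for (participant, session, stimulus) = (%s)",
                 gsub("\r", ", ", dup)), call. = FALSE)
  }
  invisible(df)
}

#' Construct and validate a table of slider-rating trials
#'
#' Validates the rating-design schema: all rating fields within their closed
#' ranges (0-100 for ratings and familiarity, 1-100 for confidence), sessions
#' coded 1 or 2, and one row per (participant, session, stimulus).
#'
#' @param df a data.frame with columns `participant_id`, `session`,
#'   `stimulus_id`, `valence`, `arousal`, `valence_confidence`,
#'   `arousal_confidence`, `others_valence`, `others_arousal`, `familiarity`.
#' @return `df` with class `rating_trials` prepended.
#' @export
rating_trials <- function(df) {
  .check_cols(df, .rating_cols, "rating trial table")
  df$participant_id <- as.character(df$participant_id)
  df$stimulus_id <- as.character(df$stimulus_id)
  df$session <- as.integer(df$session)
  if (any(!df$session %in% c(1L, 2L))) {
    stop("session must be 1 or 2", call. = FALSE)
  }
  .check_ranges(df, .rating_ranges)
  .check_unique_trials(df)
  class(df) <- c("rating_trials", "data.frame")
  df
}

#' Construct and validate a table of two-alternative forced-choice trials
#'
#' @param df a data.frame with columns `participant_id`, `session`,
#'   `stimulus_id`, `valence_response` (`"pleasant"`/`"unpleasant"`),
#'   `arousal_response` (`"high"`/`"low"`), `valence_confidence`,
#'   `arousal_confidence`, `familiarity`.
#' @return `df` with class `afc_trials` prepended.
#' @export
afc_trials <- function(df) {
  .check_cols(df, .afc_cols, "forced-choice trial table")
  df$participant_id <- as.character(df$participant_id)
  df$stimulus_id <- as.character(df$stimulus_id)
  df$session <- as.integer(df$session)
  if (any(!df$session %in% c(1L, 2L))) {
    stop("session must be 1 or 2", call. = FALSE)
  }
  bad_v <- which(!df$valence_response %in% c("pleasant", "unpleasant"))
  if (length(bad_v)) {
    stop(sprintf("valence_response must be 'pleasant' or 'unpleasant' (row %d)",
                 bad_v[1]), call. = FALSE)
  }
  bad_a <- which(!df$arousal_response %in% c("high", "low"))
  if (length(bad_a)) {
    stop(sprintf("arousal_response must be 'high' or 'low' (row %d)",
                 bad_a[1]), call. = FALSE)
  }
  .check_ranges(df, .afc_ranges)
  .check_unique_trials(df)
  class(df) <- c("afc_trials", "data.frame")
  df
}

#' Construct and validate stimulus metadata
#'
#' Stimulus norms come from affective picture databases (IAPS, NAPS) on a
#' 9-point scale. High/low class labels per dimension, and the combined
#' category (HVHA/HVLA/LVLA/LVHA), are derived from the database ratings when
#' absent: a rating above 5 is "high", below 5 is "low"; a rating of exactly
#' 5 has no class and is rejected. Supplied labels are checked for
#' consistency with that rule's category composition.
#'
#' @param df a data.frame with columns `stimulus_id`, `database`
#'   (`"IAPS"`/`"NAPS"`), `db_valence`, `db_arousal` (both in `[1, 9]`);
#'   optionally `valence_class`, `arousal_class`, `category`.
#' @return `df` with class `stimulus_meta` prepended and all label columns
#'   filled in.
#' @export
stimulus_meta <- function(df) {
  .check_cols(df, .meta_cols, "stimulus metadata")
  df$stimulus_id <- as.character(df$stimulus_id)
  if (anyDuplicated(df$stimulus_id)) {
    stop("duplicate stimulus_id in metadata", call. = FALSE)
  }
  if (any(!df$database %in% c("IAPS", "NAPS"))) {
    stop("database must be 'IAPS' or 'NAPS'", call. = FALSE)
  }
  for (col in c("db_valence", "db_arousal")) {
    v <- df[[col]]
    if (!is.numeric(v) || any(is.na(v) | v < 1 | v > 9)) {
      stop(sprintf("%s must lie in [1, 9]", col), call. = FALSE)
    }
  }
  classify <- function(x, col) {
    if (any(x == 5)) {
      stop(sprintf("%s of exactly 5 has no high/low class (stimulus %s)",
                   col, df$stimulus_id[which(x == 5)[1]]), call. = FALSE)
    }
    ifelse(x > 5, "high", "low")
  }
  if (is.null(df$valence_class)) {
    df$valence_class <- classify(df$db_valence, "db_valence")
  }
  if (is.null(df$arousal_class)) {
    df$arousal_class <- classify(df$db_arousal, "db_arousal")
  }
  if (any(!df$valence_class %in% c("high", "low")) ||
      any(!df$arousal_class %in% c("high", "low"))) {
    stop("class labels must be 'high' or 'low'", call. = FALSE)
  }
  cat_of <- function(v, a) {
    paste0(ifelse(v == "high", "HV", "LV"), ifelse(a == "high", "HA", "LA"))
  }
  implied <- cat_of(df$valence_class, df$arousal_class)
  if (is.null(df$category)) df$category <- implied
  bad <- which(df$category != implied)
  if (length(bad)) {
    stop(sprintf("category inconsistent with class labels for stimulus %s",
                 df$stimulus_id[bad[1]]), call. = FALSE)
  }
  class(df) <- c("stimulus_meta", "data.frame")
  df
}

#' Read a trial table from CSV
#'
#' @param path path to a UTF-8 CSV file with a header row.
#' @param design `"rating"` for the slider-rating design, `"afc"` for the
#'   two-alternative forced-choice design.
#' @return a validated [rating_trials] or [afc_trials] table.
#' @export
load_trials <- function(path, design = c("rating", "afc")) {
  design <- match.arg(design)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (design == "rating") rating_trials(df) else afc_trials(df)
}

#' Write a trial table (or stimulus metadata) to CSV
#'
#' Writers emit RFC-4180-style quoting with a header row, so that
#' `load_trials(save_trials(x))` round-trips exactly.
#'
#' @param trials a `rating_trials`, `afc_trials` or `stimulus_meta` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_trials <- function(trials, path) {
  utils::write.csv(as.data.frame(trials), path, row.names = FALSE,
                   quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read stimulus metadata from CSV
#'
#' @param path path to a CSV with columns `stimulus_id`, `database`,
#'   `db_valence`, `db_arousal` and optional class/category labels.
#' @return a validated [stimulus_meta] table.
#' @export
load_stimulus_meta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  stimulus_meta(utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8"))
}

#' Rescale a 9-point database rating onto the 0-100 response scale
#'
#' Affine map pinning the endpoints: 1 maps to 0, 9 maps to 100, so the
#' scale midpoint 5 maps to 50. Needed to compare database norms with
#' 0-100 slider ratings.
#'
#' @param x numeric vector of ratings on the 9-point scale.
#' @return ratings on the 0-100 scale.
#' @export
#' @examples
#' rescale_db_rating(c(1, 5, 9))
rescale_db_rating <- function(x) {
  if (any(is.na(x) | x < 1 | x > 9)) {
    stop("database ratings must lie in [1, 9]", call. = FALSE)
  }
  (x - 1) / 8 * 100
}

#' Exclude participants who gave an invariant response
#'
#' A participant whose trials in a session carry an identical value for any
#' rated parameter (valence, arousal, either confidence, either
#' others-rating, familiarity, or a forced-choice response) did not engage
#' with that scale, so that participant-session is removed. With
#' `per_session = FALSE` a participant invariant in any session is dropped
#' from all sessions.
#'
#' @param trials a `rating_trials` or `afc_trials` table.
#' @param per_session if `TRUE` (default), exclusion applies only to the
#'   offending participant-session; if `FALSE`, to the whole participant.
#' @return a list with `kept` (the filtered table, original class retained)
#'   and `excluded` (data.frame of `participant_id`, `session`, `parameter`
#'   naming each invariant scale; zero rows when nothing is excluded).
#' @export
exclude_invariant_participants <- function(trials, per_session = TRUE) {
  params <- setdiff(names(trials),
                    c("participant_id", "session", "stimulus_id"))
  excluded <- data.frame(participant_id = character(), session = integer(),
                         parameter = character(), stringsAsFactors = FALSE)
  if (nrow(trials) == 0) {
    return(list(kept = trials, excluded = excluded))
  }
  grp <- interaction(trials$participant_id, trials$session, drop = TRUE)
  for (g in levels(grp)) {
    rows <- trials[grp == g, , drop = FALSE]
    for (p in params) {
      if (length(unique(rows[[p]])) == 1L) {
        excluded <- rbind(excluded, data.frame(
          participant_id = rows$participant_id[1],
          session = rows$session[1],
          parameter = p, stringsAsFactors = FALSE
        ))
      }
    }
  }
  if (nrow(excluded) == 0) {
    return(list(kept = trials, excluded = excluded))
  }
  if (per_session) {
    bad <- paste(excluded$participant_id, excluded$session)
    drop <- paste(trials$participant_id, trials$session) %in% bad
  } else {
    drop <- trials$participant_id %in% excluded$participant_id
  }
  kept <- trials[!drop, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, excluded = excluded)
}
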