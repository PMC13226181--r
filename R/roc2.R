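#' Confusion counts at a single confidence criterion
#'
#' At criterion X a trial's confidence is "high" iff confidence >= X. The
#' four cells are: TP = correct & high, FN = correct & low, FP = incorrect &
#' high, TN = incorrect & low.
#'
#' @param correct logical vector of trial accuracies.
#' @param confidence integer vector of 1-100 confidence ratings.
#' @param X criterion, `1 <= X <= 100`.
#' @return data.frame with one row: `criterion`, `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_at_criterion <- function(correct, confidence, X) {
  stopifnot(length(correct) == length(confidence), X >= 1, X <= 100)
  hi <- confidence >= X
  data.frame(
    criterion = X,
    tp = sum(correct & hi),
    fp = sum(!correct & hi),
    tn = sum(!correct & !hi),
    fn = sum(correct & !hi)
  )
}

#' Type-2 ROC points over the criterion grid
#'
#' Sweeps the criterion over the grid (default 5, 10, ..., 100), computing
#' at each criterion TPR = TP/(TP+FN) and FPR = FP/(FP+TN). Requires at
#' least one correct and one incorrect trial, otherwise the rates are
#' undefined.
#'
#' @inheritParams confusion_at_criterion
#' @param grid integer criteria to sweep; default `seq(5, 100, by = 5)`.
#' @return a `roc2_curve` object: list with `confusions` (data.frame over
#'   the grid), `points` (data.frame `fpr`, `tpr` per criterion),
#'   `n_correct`, `n_incorrect`.
#' @export
roc_points <- function(correct, confidence, grid = seq(5L, 100L, by = 5L)) {
  stopifnot(length(correct) == length(confidence))
  n_c <- sum(correct)
  n_i <- sum(!correct)
  if (n_c == 0 || n_i == 0) {
    stop("type-2 ROC undefined: need at least one correct and one incorrect trial",
         call. = FALSE)
  }
  conf <- rbind_list(lapply(grid, function(X)
    confusion_at_criterion(correct, confidence, X)))
  pts <- data.frame(
    criterion = conf$criterion,
    fpr = conf$fp / (conf$fp + conf$tn),
    tpr = conf$tp / (conf$tp + conf$fn)
  )
  structure(list(confusions = conf, points = pts,
                 n_correct = n_c, n_incorrect = n_i),
            class = "roc2_curve")
}

# minimal rbind over a list of homogeneous data.frames
rbind_list <- function(x) do.call(rbind, x)

#' @export
print.roc2_curve <- function(x, ...) {
  cat(sprintf("Type-2 ROC curve: %d correct, %d incorrect trials, %d criteria\n",
              x$n_correct, x$n_incorrect, nrow(x$points)))
  if (!is.null(x$auroc2)) cat(sprintf("AUROC2 = %.4f\n", x$auroc2))
  invisible(x)
}

#' Area under the type-2 ROC curve
#'
#' Trapezoidal area over the curve's (FPR, TPR) points augmented with the
#' anchors (0,0) and (1,1), after de-duplication and sorting. AUROC2 is the
#' non-parametric measure of metacognitive sensitivity: 0.5 is chance
#' (confidence carries no information about accuracy), 1 is perfect
#' second-order access.
#'
#' `auroc2()` accepts either a `roc2_curve` from [roc_points()] or raw
#' `correct`/`confidence` vectors. With raw vectors, if either accuracy
#' class has fewer than `min_n` trials the curve is treated as unreliable
#' and `NaN` is returned with a warning (mirroring the practice of not
#' analyzing cells with too few trials).
#'
#' @param x a `roc2_curve`, or a logical vector of accuracies.
#' @param confidence integer confidence ratings (when `x` is a vector).
#' @param grid criterion grid (when `x` is a vector).
#' @param min_n minimum trials per accuracy class for a valid curve
#'   (when `x` is a vector); default 5.
#' @return the area, a scalar in `[0, 1]`, or `NaN` when undefined.
#' @export
auroc2 <- function(x, confidence = NULL, grid = seq(5L, 100L, by = 5L),
                   min_n = 5L) {
  if (inherits(x, "roc2_curve")) {
    return(.auroc2_from_points(x$points))
  }
  correct <- x
  n_c <- sum(correct)
  n_i <- sum(!correct)
  if (n_c < min_n || n_i < min_n) {
    warning(sprintf(
      "type-2 ROC not computed: %d correct / %d incorrect trials (minimum %d each)",
      n_c, n_i, min_n), call. = FALSE)
    return(NaN)
  }
  .auroc2_from_points(roc_points(correct, confidence, grid)$points)
}

.auroc2_from_points <- function(points) {
  fpr <- c(0, points$fpr, 1)
  tpr <- c(0, points$tpr, 1)
  keep <- !duplicated(cbind(fpr, tpr))
  fpr <- fpr[keep]
  tpr <- tpr[keep]
  ord <- order(fpr, tpr)
  fpr <- fpr[ord]
  tpr <- tpr[ord]
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' AUROC2 for one participant-session, from trials to area
#'
#' Convenience composition of the full pipeline for a single
#' participant-session: compute rating-norm differences for the requested
#' normative condition, score trials with the participant-based interval
#' rule, sweep the criterion grid, and integrate the curve.
#'
#' @param trials [rating_trials] rows of a single participant-session.
#' @param condition normative condition (`"diff"`, `"diff2"`, `"avg"`,
#'   `"oavg"`).
#' @param dimension `"valence"` or `"arousal"`.
#' @param meta stimulus metadata (needed for `diff2`).
#' @param group_means group means (needed for `avg`/`oavg` when `trials`
#'   holds only one participant).
#' @param k interval multiplier; default 0.675.
#' @param grid criterion grid.
#' @param min_n minimum trials per accuracy class.
#' @return AUROC2 scalar (possibly `NaN` with a warning).
#' @export
auroc2_for_participant <- function(trials, condition, dimension,
                                   meta = NULL, group_means = NULL,
                                   k = 0.675, grid = seq(5L, 100L, by = 5L),
                                   min_n = 5L) {
  ser <- compute_differences(trials, condition, dimension,
                             meta = meta, group_means = group_means)
  acc <- participant_accuracy(ser, k = k)
  auroc2(acc$correct, acc$confidence, grid = grid, min_n = min_n)
}

#' Per-participant AUROC2 table for a whole dataset
#'
#' Runs the normative -> accuracy -> type-2 ROC pipeline for every
#' participant-session over the requested conditions and dimensions.
#' Group means for the `avg`/`oavg` standards are computed from all kept
#' participants within each session.
#'
#' @param trials a [rating_trials] table (after exclusion).
#' @param meta stimulus metadata (required when `"diff2"` is among
#'   `conditions`).
#' @param conditions normative conditions to run.
#' @param dimensions dimensions to run.
#' @inheritParams auroc2_for_participant
#' @return data.frame with one row per participant x session x dimension x
#'   condition: `n_correct`, `n_incorrect`, `auroc2`.
#' @export
auroc2_table <- function(trials, meta = NULL,
                         conditions = c("diff", "diff2", "avg", "oavg"),
                         dimensions = c("valence", "arousal"),
                         k = 0.675, grid = seq(5L, 100L, by = 5L),
                         min_n = 5L) {
  if (is.null(meta)) conditions <- setdiff(conditions, "diff2")
  out <- list()
  for (dim in dimensions) {
    for (cond in conditions) {
      ser <- compute_differences(trials, cond, dim, meta = meta)
      acc <- participant_accuracy(ser, k = k)
      grp <- interaction(acc$participant_id, acc$session, drop = TRUE)
      for (g in levels(grp)) {
        a <- acc[grp == g, , drop = FALSE]
        val <- suppressWarnings(
          auroc2(a$correct, a$confidence, grid = grid, min_n = min_n))
        out[[length(out) + 1L]] <- data.frame(
          participant_id = a$participant_id[1], session = a$session[1],
          dimension = dim, condition = cond,
          n_correct = sum(a$correct), n_incorrect = sum(!a$correct),
          auroc2 = val, stringsAsFactors = FALSE
        )
      }
    }
  }
  res <- rbind_list(out)
  rownames(res) <- NULL
  res
}
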