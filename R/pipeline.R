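#' Per-participant SDT results for a forced-choice dataset
#'
#' d-prime, meta-d-prime and M-ratio for every participant-session and
#' dimension, plus the forced-choice AUROC2 from the criterion sweep.
#'
#' @param trials an [afc_trials] table.
#' @param meta a [stimulus_meta] table.
#' @param dimensions dimensions to analyze.
#' @param edges confidence bin edges for the meta-d-prime fit.
#' @param grid criterion grid for AUROC2.
#' @param min_n minimum trials per accuracy class for AUROC2.
#' @return data.frame with one row per participant x session x dimension:
#'   `d_prime`, `criterion_c`, `meta_d`, `m_ratio`, `converged`, `auroc2`.
#' @export
sdt_table <- function(trials, meta, dimensions = c("valence", "arousal"),
                      edges = c(25L, 50L, 75L),
                      grid = seq(5L, 100L, by = 5L), min_n = 5L) {
  out <- list()
  grp <- interaction(trials$participant_id, trials$session, drop = TRUE)
  for (dim in dimensions) {
    for (g in levels(grp)) {
      tr <- trials[grp == g, , drop = FALSE]
      d1 <- type1_dprime_2afc(tr, meta, dim)
      fit <- tryCatch(fit_meta_d_2afc(tr, meta, dim, edges = edges),
                      error = function(e) NULL)
      acc <- afc_accuracy(tr, meta, dim)
      a2 <- suppressWarnings(
        auroc2(acc$correct, acc$confidence, grid = grid, min_n = min_n))
      out[[length(out) + 1L]] <- data.frame(
        participant_id = tr$participant_id[1], session = tr$session[1],
        dimension = dim,
        d_prime = d1$d_prime, criterion_c = d1$criterion_c,
        meta_d = if (is.null(fit)) NA_real_ else fit$meta_d,
        m_ratio = if (is.null(fit)) NA_real_ else fit$m_ratio,
        converged = if (is.null(fit)) FALSE else fit$converged,
        auroc2 = a2, stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Between-session reliability report
#'
#' For a per-participant results table holding two sessions, computes for
#' every dimension x condition cell the ICC(3,1) with its 95% CI, the
#' Bland-Altman bias and limits of agreement, and the between-session
#' correlation (auto Pearson/Spearman), over participants with a finite
#' value in both sessions.
#'
#' @param tab a results table such as from [auroc2_table()] or
#'   [sdt_table()], with columns `participant_id`, `session`, `dimension`,
#'   and the measure.
#' @param measure name of the measure column; default `"auroc2"`.
#' @return data.frame with one row per dimension (x condition if present):
#'   `n`, `icc`, `icc_ci_low`, `icc_ci_high`, `bias`, `loa_low`,
#'   `loa_high`, `cor`, `cor_method`, `cor_p`.
#' @export
reliability_report <- function(tab, measure = "auroc2") {
  if (!all(c(1L, 2L) %in% tab$session)) {
    stop("reliability report requires two sessions", call. = FALSE)
  }
  cells <- if ("condition" %in% names(tab)) {
    unique(tab[, c("dimension", "condition")])
  } else {
    data.frame(dimension = unique(tab$dimension))
  }
  out <- list()
  for (r in seq_len(nrow(cells))) {
    sel <- tab$dimension == cells$dimension[r]
    if (!is.null(cells$condition)) sel <- sel & tab$condition == cells$condition[r]
    sub <- tab[sel, , drop = FALSE]
    s1 <- sub[sub$session == 1L, c("participant_id", measure)]
    s2 <- sub[sub$session == 2L, c("participant_id", measure)]
    mrg <- merge(s1, s2, by = "participant_id", suffixes = c("_1", "_2"))
    a <- mrg[[paste0(measure, "_1")]]
    b <- mrg[[paste0(measure, "_2")]]
    keep <- is.finite(a) & is.finite(b)
    a <- a[keep]
    b <- b[keep]
    row <- data.frame(cells[r, , drop = FALSE], n = length(a),
                      stringsAsFactors = FALSE)
    if (length(a) >= 4) {
      icc <- icc3_1(cbind(a, b))
      ba <- bland_altman(a, b)
      ct <- tryCatch(correlate(a, b, "auto"), error = function(e) NULL)
      row$icc <- icc$icc
      row$icc_ci_low <- icc$ci_low
      row$icc_ci_high <- icc$ci_high
      row$bias <- ba$bias
      row$loa_low <- ba$loa_low
      row$loa_high <- ba$loa_high
      row$cor <- if (is.null(ct)) NA_real_ else ct$statistic
      row$cor_method <- if (is.null(ct)) NA_character_ else ct$method
      row$cor_p <- if (is.null(ct)) NA_real_ else ct$p_value
    } else {
      row[c("icc", "icc_ci_low", "icc_ci_high", "bias", "loa_low",
            "loa_high", "cor")] <- NA_real_
      row$cor_method <- NA_character_
      row$cor_p <- NA_real_
    }
    out[[length(out) + 1L]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the full analysis on trial files and write result tables
#'
#' Loads trials (and stimulus metadata when given), applies the
#' invariant-participant exclusion, runs the per-participant AUROC2
#' pipeline (rating design) or the SDT + AUROC2 pipeline (forced-choice
#' design), writes the tables plus a reliability report when two sessions
#' are present, and a JSON manifest echoing the configuration, package
#' version, and exclusion log.
#'
#' @param trial_path path to the trial CSV.
#' @param design `"rating"` or `"afc"`.
#' @param out_dir output directory (created if absent).
#' @param meta_path optional path to the stimulus-metadata CSV.
#' @param conditions normative conditions (rating design).
#' @param dimensions dimensions to analyze.
#' @param k accuracy-interval multiplier.
#' @param grid criterion grid.
#' @param edges confidence bin edges (forced-choice design).
#' @param min_n minimum trials per accuracy class.
#' @return invisibly, a list with the computed tables (`results`,
#'   `reliability` or `NULL`, `excluded`).
#' @export
run_analysis <- function(trial_path, design = c("rating", "afc"), out_dir,
                         meta_path = NULL,
                         conditions = c("diff", "diff2", "avg", "oavg"),
                         dimensions = c("valence", "arousal"),
                         k = 0.675, grid = seq(5L, 100L, by = 5L),
                         edges = c(25L, 50L, 75L), min_n = 5L) {
  design <- match.arg(design)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  trials <- load_trials(trial_path, design)
  meta <- if (!is.null(meta_path)) load_stimulus_meta(meta_path) else NULL
  excl <- exclude_invariant_participants(trials)
  if (nrow(excl$excluded)) {
    message(sprintf("excluded %d participant-session(s): %s",
                    length(unique(paste(excl$excluded$participant_id,
                                        excl$excluded$session))),
                    paste(unique(excl$excluded$participant_id), collapse = ", ")))
  }
  kept <- excl$kept

  if (design == "rating") {
    results <- auroc2_table(kept, meta = meta, conditions = conditions,
                            dimensions = dimensions, k = k, grid = grid,
                            min_n = min_n)
  } else {
    if (is.null(meta)) {
      stop("the forced-choice design requires stimulus metadata", call. = FALSE)
    }
    results <- sdt_table(kept, meta, dimensions = dimensions, edges = edges,
                         grid = grid, min_n = min_n)
  }
  utils::write.csv(results, file.path(out_dir, "results.csv"),
                   row.names = FALSE)

  rel <- NULL
  if (all(c(1L, 2L) %in% kept$session)) {
    rel <- reliability_report(results, measure = "auroc2")
    utils::write.csv(rel, file.path(out_dir, "reliability.csv"),
                     row.names = FALSE)
  }

  manifest <- list(
    package = "emoroc",
    version = as.character(utils::packageVersion("emoroc")),
    design = design, trial_path = trial_path, meta_path = meta_path,
    conditions = conditions, dimensions = dimensions,
    k = k, grid = grid, edges = edges, min_n = min_n,
    excluded = excl$excluded
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(results = results, reliability = rel,
                 excluded = excl$excluded))
}

#' Simulate an experiment and write its files
#'
#' Writes the trial CSV (per the [load_trials()] schema), the stimulus
#' metadata CSV, the hidden-truth record as JSON, and a manifest echoing
#' the configuration and seed.
#'
#' @param cfg a [sim_config()].
#' @param design `"rating"` or `"afc"`.
#' @param out_dir output directory (created if absent).
#' @return invisibly, the simulation output list (with `paths` added).
#' @export
run_simulation <- function(cfg, design = c("rating", "afc"), out_dir) {
  design <- match.arg(design)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- if (design == "rating") {
    simulate_rating_experiment(cfg)
  } else {
    simulate_2afc_experiment(cfg)
  }
  trial_path <- file.path(out_dir, sprintf("trials_%s.csv", design))
  save_trials(sim$trials, trial_path)
  meta_path <- NULL
  if (!is.null(sim$meta)) {
    meta_path <- file.path(out_dir, "stimuli.csv")
    save_trials(sim$meta, meta_path)
  }
  jsonlite::write_json(sim$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- c(unclass(cfg)[setdiff(names(cfg), "mu")],
                list(design = design, package = "emoroc",
                     version = as.character(utils::packageVersion("emoroc"))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  sim$paths <- list(trials = trial_path, meta = meta_path)
  invisible(sim)
}
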