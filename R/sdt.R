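#' Type-1 d-prime and criterion for the forced-choice task
#'
#' Equal-variance Gaussian SDT on the 2AFC data: the "signal" class is the
#' high database category for the dimension, the "signal" response is
#' "pleasant" (valence) or "high" (arousal). Hit and false-alarm rates of
#' exactly 0 or 1 are corrected by the 1/(2N) rule before the z-transform
#' (0 -> 1/(2N), 1 -> 1 - 1/(2N), N the class trial count).
#'
#' @param trials an [afc_trials] table (a single participant-session for a
#'   per-participant estimate).
#' @param meta a [stimulus_meta] table.
#' @param dimension `"valence"` or `"arousal"`.
#' @return list with `d_prime`, `criterion_c`, `hr`, `far`, `n_signal`,
#'   `n_noise`.
#' @export
type1_dprime_2afc <- function(trials, meta, dimension = c("valence", "arousal")) {
  dimension <- match.arg(dimension)
  idx <- match(trials$stimulus_id, meta$stimulus_id)
  if (anyNA(idx)) {
    stop(sprintf("stimulus '%s' missing from metadata",
                 trials$stimulus_id[which(is.na(idx))[1]]), call. = FALSE)
  }
  cls <- meta[[paste0(dimension, "_class")]][idx]
  resp <- trials[[paste0(dimension, "_response")]]
  sig_resp <- if (dimension == "valence") "pleasant" else "high"
  n_s <- sum(cls == "high")
  n_n <- sum(cls == "low")
  if (n_s == 0 || n_n == 0) {
    stop("both stimulus classes must be present to compute d-prime", call. = FALSE)
  }
  hr <- correct_extreme_rate(sum(cls == "high" & resp == sig_resp) / n_s, n_s)
  far <- correct_extreme_rate(sum(cls == "low" & resp == sig_resp) / n_n, n_n)
  list(d_prime = stats::qnorm(hr) - stats::qnorm(far),
       criterion_c = -0.5 * (stats::qnorm(hr) + stats::qnorm(far)),
       hr = hr, far = far, n_signal = n_s, n_noise = n_n)
}

#' 1/(2N) correction for extreme hit/false-alarm rates
#'
#' @param p an observed rate in `[0, 1]`.
#' @param n the number of trials behind the rate.
#' @return `p`, with 0 replaced by `1/(2n)` and 1 by `1 - 1/(2n)`.
#' @export
correct_extreme_rate <- function(p, n) {
  pmin(pmax(p, 1 / (2 * n)), 1 - 1 / (2 * n))
}

#' Discretize 1-100 confidence ratings into K levels
#'
#' Fixed-edge binning: level = 1 + number of edges at or below the rating,
#' so a rating equal to an edge maps to the higher level. The default edges
#' 25/50/75 give K = 4 levels.
#'
#' @param conf integer confidence ratings in 1..100.
#' @param edges strictly increasing cut points within 1..100.
#' @return integer levels in `1..(length(edges) + 1)`.
#' @export
bin_confidence <- function(conf, edges = c(25L, 50L, 75L)) {
  if (length(edges) < 1 || any(diff(edges) <= 0) ||
      any(edges < 1) || any(edges > 100)) {
    stop("edges must be strictly increasing within 1..100", call. = FALSE)
  }
  if (any(conf < 1 | conf > 100)) {
    stop("confidence must lie in 1..100", call. = FALSE)
  }
  1L + rowSums(outer(conf, edges, ">="))
}

#' Assemble stimulus x response x confidence-level counts for meta-d-prime
#'
#' @param stimulus factor-like vector: `"s1"` (noise/low class) or `"s2"`
#'   (signal/high class) per trial.
#' @param response `"r1"` or `"r2"` per trial (`"r2"` is the signal
#'   response).
#' @param level integer confidence level in `1..K` per trial (see
#'   [bin_confidence()]).
#' @param K number of confidence levels.
#' @return an `sdt_counts` object: a `2 x 2 x K` integer array indexed by
#'   stimulus, response, level.
#' @export
sdt_counts <- function(stimulus, response, level, K = 4L) {
  stopifnot(length(stimulus) == length(response),
            length(response) == length(level))
  if (any(!stimulus %in% c("s1", "s2")) || any(!response %in% c("r1", "r2"))) {
    stop("stimulus must be 's1'/'s2' and response 'r1'/'r2'", call. = FALSE)
  }
  if (any(level < 1 | level > K)) stop("levels must lie in 1..K", call. = FALSE)
  counts <- array(0L, dim = c(2, 2, K),
                  dimnames = list(c("s1", "s2"), c("r1", "r2"), NULL))
  for (i in seq_along(stimulus)) {
    counts[stimulus[i], response[i], level[i]] <-
      counts[stimulus[i], response[i], level[i]] + 1L
  }
  structure(counts, class = c("sdt_counts", class(counts)))
}

#' Maximum-likelihood meta-d-prime
#'
#' Fits the equal-variance Gaussian meta-d-prime model: the type-1
#' sensitivity an SDT-ideal observer would need in order to produce the
#' observed response-conditional confidence counts. Type-1 d-prime and
#' criterion c are fixed at their empirical values; at the meta level the
#' type-1 criterion is scaled as c' = c * meta_d / d', and K-1 type-2
#' criteria per response side are fitted jointly with meta_d by maximizing
#' the multinomial likelihood of the confidence counts conditional on each
#' (stimulus, response) cell. M-ratio = meta_d / d_prime is the measure of
#' metacognitive efficiency (1 for an ideal observer).
#'
#' @param counts an [sdt_counts()] array.
#' @param padding value added to every confidence cell before likelihood
#'   evaluation to avoid empty-cell degeneracies; default `1/(2K)`.
#' @param starts multipliers of the empirical d-prime used as meta_d
#'   starting points for the bounded multi-start search.
#' @return an `sdt_result` list: `d_prime`, `criterion_c`, `meta_d`,
#'   `m_ratio`, `t2_criteria_r1`, `t2_criteria_r2`, `neg_log_lik`,
#'   `converged`.
#' @export
fit_meta_d <- function(counts, padding = NULL,
                       starts = c(0.5, 1, 1.5)) {
  stopifnot(inherits(counts, "sdt_counts") || (is.array(counts) &&
            length(dim(counts)) == 3 && all(dim(counts)[1:2] == 2)))
  K <- dim(counts)[3]
  if (is.null(padding)) padding <- 1 / (2 * K)

  n_s1 <- sum(counts["s1", , ])
  n_s2 <- sum(counts["s2", , ])
  if (n_s1 == 0 || n_s2 == 0) {
    stop("both stimulus classes must have trials", call. = FALSE)
  }
  resp_r2_s1 <- sum(counts["s1", "r2", ])
  resp_r2_s2 <- sum(counts["s2", "r2", ])
  if (sum(counts[, "r1", ]) == 0 || sum(counts[, "r2", ]) == 0) {
    stop("both responses must occur at least once", call. = FALSE)
  }
  far <- correct_extreme_rate(resp_r2_s1 / n_s1, n_s1)
  hr <- correct_extreme_rate(resp_r2_s2 / n_s2, n_s2)
  d_prime <- stats::qnorm(hr) - stats::qnorm(far)
  c_emp <- -0.5 * (stats::qnorm(hr) + stats::qnorm(far))

  padded <- counts + padding

  # negative log-likelihood of the response-conditional confidence counts.
  # theta = c(meta_d, log-gaps below c' (r1 side), log-gaps above c' (r2 side))
  nll <- function(theta) {
    meta_d <- theta[1]
    g1 <- exp(theta[2:K])              # K-1 gaps, r1 side
    g2 <- exp(theta[(K + 1):(2 * K - 1)])
    cprime <- if (abs(d_prime) > 1e-12) c_emp * meta_d / d_prime else c_emp
    # boundaries: r1 side descending from c', r2 side ascending from c'
    b1 <- cprime - cumsum(g1)          # t2 criteria for levels 2..K (r1)
    b2 <- cprime + cumsum(g2)
    mu <- c(s1 = -meta_d / 2, s2 = meta_d / 2)
    ll <- 0
    for (s in c("s1", "s2")) {
      # r1 response: x < c'; level k occupies (b1[k], b1[k-1]] with b1[0] = c'
      edges1 <- c(cprime, b1)          # upper edges for levels 1..K
      p_r1 <- stats::pnorm(edges1 - mu[[s]]) -
        stats::pnorm(c(b1, -Inf) - mu[[s]])
      edges2 <- c(cprime, b2)          # level k in [edges2[k], edges2[k+1])
      p_r2 <- stats::pnorm(c(b2, Inf) - mu[[s]]) -
        stats::pnorm(edges2 - mu[[s]])
      tot1 <- stats::pnorm(cprime - mu[[s]])
      tot2 <- 1 - tot1
      p_r1 <- pmax(p_r1 / tot1, 1e-12)
      p_r2 <- pmax(p_r2 / tot2, 1e-12)
      ll <- ll + sum(padded[s, "r1", ] * log(p_r1)) +
        sum(padded[s, "r2", ] * log(p_r2))
    }
    -ll
  }

  upper_md <- 5 * abs(d_prime) + 1
  best <- NULL
  ok <- FALSE
  for (m in starts) {
    init <- c(min(max(m * d_prime, 0.01), upper_md - 0.01),
              rep(log(0.5), 2 * (K - 1)))
    fit <- try(stats::optim(
      init, nll, method = "L-BFGS-B",
      lower = c(0, rep(-10, 2 * (K - 1))),
      upper = c(upper_md, rep(5, 2 * (K - 1))),
      control = list(maxit = 500)
    ), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) {
      best <- fit
      ok <- TRUE
    }
  }
  if (!ok) {
    warning("meta-d-prime optimization failed from all starting points",
            call. = FALSE)
    return(structure(list(
      d_prime = d_prime, criterion_c = c_emp, meta_d = NA_real_,
      m_ratio = NA_real_, t2_criteria_r1 = rep(NA_real_, K - 1),
      t2_criteria_r2 = rep(NA_real_, K - 1),
      neg_log_lik = NA_real_, converged = FALSE
    ), class = "sdt_result"))
  }
  conv <- best$convergence == 0
  if (!conv) {
    warning("meta-d-prime optimizer did not report convergence", call. = FALSE)
  }
  meta_d <- best$par[1]
  cprime <- if (abs(d_prime) > 1e-12) c_emp * meta_d / d_prime else c_emp
  structure(list(
    d_prime = d_prime, criterion_c = c_emp, meta_d = meta_d,
    m_ratio = meta_d / d_prime,
    t2_criteria_r1 = cprime - cumsum(exp(best$par[2:K])),
    t2_criteria_r2 = cprime + cumsum(exp(best$par[(K + 1):(2 * K - 1)])),
    neg_log_lik = best$value, converged = conv
  ), class = "sdt_result")
}

#' @export
print.sdt_result <- function(x, ...) {
  cat(sprintf("SDT fit: d' = %.3f, c = %.3f, meta-d' = %.3f, M-ratio = %.3f%s\n",
              x$d_prime, x$criterion_c, x$meta_d, x$m_ratio,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Meta-d-prime for a forced-choice participant-session
#'
#' Wrapper that classifies stimuli (high class = s2), codes responses
#' (signal response = r2), bins confidence, and fits the meta-d-prime model.
#'
#' @inheritParams type1_dprime_2afc
#' @param edges confidence bin edges for [bin_confidence()].
#' @param ... passed to [fit_meta_d()].
#' @return an `sdt_result`.
#' @export
fit_meta_d_2afc <- function(trials, meta, dimension = c("valence", "arousal"),
                            edges = c(25L, 50L, 75L), ...) {
  dimension <- match.arg(dimension)
  idx <- match(trials$stimulus_id, meta$stimulus_id)
  if (anyNA(idx)) {
    stop(sprintf("stimulus '%s' missing from metadata",
                 trials$stimulus_id[which(is.na(idx))[1]]), call. = FALSE)
  }
  cls <- meta[[paste0(dimension, "_class")]][idx]
  resp <- trials[[paste0(dimension, "_response")]]
  sig_resp <- if (dimension == "valence") "pleasant" else "high"
  counts <- sdt_counts(
    stimulus = ifelse(cls == "high", "s2", "s1"),
    response = ifelse(resp == sig_resp, "r2", "r1"),
    level = bin_confidence(trials[[paste0(dimension, "_confidence")]], edges),
    K = length(edges) + 1L
  )
  fit_meta_d(counts, ...)
}

#' Type-1 d-prime for the continuous rating task (median-split convention)
#'
#' The continuous task has no predefined signal class, so a median-split
#' convention is used: a stimulus is "signal" iff its normative value lies
#' above the participant-session median of normative values, and the
#' response is "signal" iff the participant's rating lies above their own
#' median rating. d-prime is then z(HR) - z(FAR) with the 1/(2N) correction.
#' This convention is explicit and not a claim about any particular prior
#' analysis; it yields a low d-prime when ratings carry no information about
#' the norms and a large one when they are rank-aligned.
#'
#' @param trials [rating_trials] rows of a single participant-session.
#' @param normative named numeric vector, stimulus_id -> normative value on
#'   the 0-100 scale (e.g. from [stimulus_group_means()] or rescaled
#'   database norms).
#' @param dimension `"valence"` or `"arousal"`.
#' @return list with `d_prime`, `criterion_c`, `hr`, `far`.
#' @export
type1_dprime_rating <- function(trials, normative,
                                dimension = c("valence", "arousal")) {
  dimension <- match.arg(dimension)
  idx <- match(trials$stimulus_id, names(normative))
  if (anyNA(idx)) {
    stop(sprintf("no normative value for stimulus '%s'",
                 trials$stimulus_id[which(is.na(idx))[1]]), call. = FALSE)
  }
  nv <- unname(normative[idx])
  if (length(unique(nv)) < 2) {
    stop("all normative values identical; stimulus classes undefined",
         call. = FALSE)
  }
  sig <- nv > stats::median(nv)
  resp <- trials[[dimension]] > stats::median(trials[[dimension]])
  n_s <- sum(sig)
  n_n <- sum(!sig)
  hr <- correct_extreme_rate(sum(sig & resp) / n_s, n_s)
  far <- correct_extreme_rate(sum(!sig & resp) / n_n, n_n)
  list(d_prime = stats::qnorm(hr) - stats::qnorm(far),
       criterion_c = -0.5 * (stats::qnorm(hr) + stats::qnorm(far)),
       hr = hr, far = far)
}
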