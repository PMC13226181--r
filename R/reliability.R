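#' Intraclass correlation ICC(3,1): two-way mixed, consistency, single rater
#'
#' The McGraw-Wong C,1 coefficient: raters (here, sessions) are fixed,
#' targets random, and agreement is up to a constant shift. From the
#' two-way ANOVA decomposition, ICC = (MS_R - MS_E) / (MS_R + (k-1) MS_E)
#' with MS_R the between-target and MS_E the residual mean square. The 95%
#' confidence interval follows from F-distribution bounds on MS_R/MS_E.
#'
#' @param scores an n x k numeric matrix (or data.frame), one row per
#'   target (participant), one column per session/rater; rows with any
#'   missing cell are dropped.
#' @param conf_level confidence level for the interval; default 0.95.
#' @return an `icc_result` list: `icc`, `ci_low`, `ci_high`, `f_value`,
#'   `df1`, `df2`, `n`, `k`.
#' @export
icc3_1 <- function(scores, conf_level = 0.95) {
  m <- as.matrix(scores)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m)
  k <- ncol(m)
  if (n < 3) stop("ICC requires at least 3 complete cases", call. = FALSE)
  if (k < 2) stop("ICC requires at least 2 columns", call. = FALSE)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  grand <- mean(m)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  ms_r <- ss_rows / (n - 1)
  ms_e <- ss_err / ((n - 1) * (k - 1))
  icc <- if (ms_r + (k - 1) * ms_e == 0) {
    1  # no variance anywhere: columns identical constants
  } else {
    (ms_r - ms_e) / (ms_r + (k - 1) * ms_e)
  }
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  alpha <- 1 - conf_level
  if (ms_e > 0) {
    f_obs <- ms_r / ms_e
    fl <- f_obs / stats::qf(1 - alpha / 2, df1, df2)
    fu <- f_obs * stats::qf(1 - alpha / 2, df2, df1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  } else {
    f_obs <- Inf
    ci <- c(1, 1)
  }
  structure(list(icc = icc, ci_low = ci[1], ci_high = ci[2],
                 f_value = f_obs, df1 = df1, df2 = df2, n = n, k = k),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(3,1) = %.3f (95%% CI %.3f, %.3f), F(%d, %d) = %.3f, n = %d\n",
              x$icc, x$ci_low, x$ci_high, x$df1, x$df2, x$f_value, x$n))
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Bias is the mean of the paired differences a - b; the limits of
#' agreement are bias +/- 1.96 times the sample SD of the differences
#' (the two-sided 95% standard-normal band).
#'
#' @param a,b equal-length numeric vectors of paired measurements.
#' @param multiplier LoA half-width in SD units; default 1.96.
#' @return a `bland_altman` list: `bias`, `sd_diff`, `loa_low`, `loa_high`,
#'   `n`, plus `means` and `differences` for plotting.
#' @export
bland_altman <- function(a, b, multiplier = 1.96) {
  if (length(a) != length(b)) stop("vectors must have equal length", call. = FALSE)
  if (length(a) < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- a - b
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias = bias, sd_diff = s,
                 loa_low = bias - multiplier * s,
                 loa_high = bias + multiplier * s,
                 n = length(d), means = (a + b) / 2, differences = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias = %.4f, LoA [%.4f, %.4f], n = %d\n",
              x$bias, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' Correlation with automatic Pearson/Spearman selection
#'
#' With `method = "auto"`, Spearman's rank correlation is used when either
#' margin fails a Shapiro-Wilk normality check at alpha = 0.05, and
#' Pearson's otherwise — the conventional normality-conditional choice.
#'
#' @param a,b equal-length numeric vectors.
#' @param method `"auto"`, `"pearson"`, or `"spearman"`.
#' @param tails `"two"` (default) or `"one"` (positive association).
#' @return a `comparison_result` list: `statistic` (r or rho), `df`,
#'   `p_value`, `method`, `n`.
#' @export
correlate <- function(a, b, method = c("auto", "pearson", "spearman"),
                      tails = c("two", "one")) {
  method <- match.arg(method)
  tails <- match.arg(tails)
  if (length(a) != length(b)) stop("vectors must have equal length", call. = FALSE)
  if (length(a) < 4) stop("need at least 4 pairs", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  if (method == "auto") {
    normal <- stats::shapiro.test(a)$p.value >= 0.05 &&
      stats::shapiro.test(b)$p.value >= 0.05
    method <- if (normal) "pearson" else "spearman"
  }
  alt <- if (tails == "two") "two.sided" else "greater"
  ct <- suppressWarnings(
    stats::cor.test(a, b, method = method, alternative = alt, exact = FALSE))
  structure(list(statistic = unname(ct$estimate),
                 df = length(a) - 2L,
                 p_value = ct$p.value,
                 method = method, n = length(a)),
            class = "comparison_result")
}

#' Paired comparison with Cohen's d
#'
#' Paired t-test on the differences a - b, with the effect size reported as
#' Cohen's d = t / sqrt(n) (the paired-design convention in which d is the
#' standardized mean difference of the paired differences).
#'
#' @param a,b equal-length numeric vectors of paired observations.
#' @param tails `"two"` (default) or `"one"`.
#' @return a `comparison_result` list: `statistic` (t), `df`, `p_value`,
#'   `effect_size` (Cohen's d), `n`.
#' @export
paired_comparison <- function(a, b, tails = c("two", "one")) {
  tails <- match.arg(tails)
  if (length(a) != length(b)) stop("vectors must have equal length", call. = FALSE)
  if (length(a) < 2) stop("need at least 2 pairs", call. = FALSE)
  if (stats::sd(a - b) == 0) {
    stop("paired t undefined: differences have zero variance", call. = FALSE)
  }
  alt <- if (tails == "two") "two.sided" else "greater"
  tt <- stats::t.test(a, b, paired = TRUE, alternative = alt)
  n <- length(a)
  structure(list(statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_value = tt$p.value,
                 effect_size = unname(tt$statistic) / sqrt(n),
                 n = n),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  if (!is.null(x$effect_size)) {
    cat(sprintf("t(%d) = %.3f, p = %.4g, Cohen's d = %.3f\n",
                x$df, x$statistic, x$p_value, x$effect_size))
  } else {
    cat(sprintf("%s correlation = %.3f (n = %d), p = %.4g\n",
                x$method, x$statistic, x$n, x$p_value))
  }
  invisible(x)
}

#' Density of the sample correlation coefficient
#'
#' Exact sampling density of Pearson's r from n bivariate-normal pairs with
#' population correlation rho, via the Gaussian hypergeometric series.
#'
#' @param r evaluation points in `(-1, 1)`.
#' @param n sample size (>= 4).
#' @param rho population correlation in `(-1, 1)`.
#' @return density values at `r`.
#' @export
dsamplecor <- function(r, n, rho) {
  stopifnot(n >= 4, abs(rho) < 1)
  hyp <- vapply(r, function(ri) {
    x <- (1 + rho * ri) / 2
    term <- 1
    s <- 1
    k <- 0
    repeat {
      k <- k + 1
      term <- term * (0.5 + k - 1)^2 / ((2 * n - 1) / 2 + k - 1) * x / k
      s <- s + term
      if (abs(term) < 1e-14 * abs(s) || k > 10000) break
    }
    s
  }, numeric(1))
  (n - 2) * exp(lgamma(n - 1) - lgamma(n - 0.5)) *
    (1 - rho^2)^((n - 1) / 2) * (1 - r^2)^((n - 4) / 2) /
    sqrt(2 * pi) * (1 - rho * r)^(-(n - 1.5)) * hyp
}

#' Power of the test of zero correlation at sample size n
#'
#' Exact power under the bivariate-normal model: the critical r solves the
#' t-threshold t = r sqrt(n-2)/sqrt(1-r^2), and power integrates the exact
#' sampling density of r beyond it. The Fisher-z method uses the normal
#' approximation atanh(r) ~ N(atanh(rho), 1/(n-3)).
#'
#' @param n sample size (>= 4).
#' @param rho population correlation under the alternative, in `(0, 1)`.
#' @param alpha significance level.
#' @param tails `"one"` or `"two"`.
#' @param method `"exact"` or `"fisher"`.
#' @return achieved power, a scalar in `(0, 1)`.
#' @export
correlation_power <- function(n, rho, alpha = 0.05,
                              tails = c("one", "two"),
                              method = c("exact", "fisher")) {
  tails <- match.arg(tails)
  method <- match.arg(method)
  stopifnot(n >= 4, rho > 0, rho < 1, alpha > 0, alpha < 1)
  a <- if (tails == "one") alpha else alpha / 2
  if (method == "fisher") {
    za <- stats::qnorm(1 - a)
    return(stats::pnorm(atanh(rho) * sqrt(n - 3) - za))
  }
  tcrit <- stats::qt(1 - a, df = n - 2)
  rcrit <- tcrit / sqrt(n - 2 + tcrit^2)
  stats::integrate(dsamplecor, rcrit, 1, n = n, rho = rho,
                   rel.tol = 1e-9)$value
}

#' Minimum sample size for detecting a correlation
#'
#' Smallest n at which the test of H0: rho = 0 reaches the target power,
#' under either the exact bivariate-normal sampling distribution of r
#' (default) or the Fisher-z approximation. Power is monotone in n, so a
#' linear scan from the minimal admissible n suffices.
#'
#' @param rho expected population correlation, in `(0, 1)`.
#' @param alpha significance level; default 0.05.
#' @param power target power; default 0.8.
#' @param tails `"one"` or `"two"`; default one-tailed.
#' @param method `"exact"` (default) or `"fisher"`.
#' @param n_max search bound; an error is raised if the target power is not
#'   reached by `n_max`.
#' @return the minimum sample size, an integer.
#' @export
#' @examples
#' required_n_correlation(0.35, alpha = 0.05, power = 0.8, tails = "one")
required_n_correlation <- function(rho, alpha = 0.05, power = 0.8,
                                   tails = c("one", "two"),
                                   method = c("exact", "fisher"),
                                   n_max = 10000L) {
  tails <- match.arg(tails)
  method <- match.arg(method)
  stopifnot(rho > 0, rho < 1, alpha > 0, alpha < 1, power > 0, power < 1)
  for (n in 4:n_max) {
    if (correlation_power(n, rho, alpha, tails, method) >= power) {
      return(as.integer(n))
    }
  }
  stop(sprintf("target power not reached by n = %d", n_max), call. = FALSE)
}
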