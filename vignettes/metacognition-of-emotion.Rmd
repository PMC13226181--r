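---
title: "Measuring metacognition of emotional valence and arousal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring metacognition of emotional valence and arousal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emoroc)
```

## The measurement model

`emoroc` measures metacognitive sensitivity — second-order access to the
quality of one's own first-order judgments — for the valence and arousal
dimensions of emotional experience. The type-1 task is reporting one's
feeling about an affective picture (a 0–100 slider rating, or a binary
pleasant/unpleasant or high/low choice); the type-2 task is a 1–100
confidence rating about that report.

The obstacle specific to emotion is defining type-1 accuracy. The package
scores a continuous rating against a *normative* value for the stimulus
and against the participant's own variability:

* Per trial, the difference d = V − V_n between the rating and the
  normative value is computed. The four normative standards (`diff`,
  `diff2`, `avg`, `oavg`) differ in where V_n comes from: the
  participant's own estimate of what others feel, the picture database
  norm, or sample averages of either across all kept participants. They
  deliberately span "private theory of mind" to "inter-subjective
  consensus" benchmarks.
* Per participant-session, the interval Avg(d) ± k·SD(d) is formed with
  k = 0.675, the standard-normal quartile. A trial is correct iff its
  difference lies inside the interval (boundaries inclusive). Under a
  Gaussian distribution of differences this classifies ~50% of trials
  correct, which (a) anchors accuracy to the participant's own internal
  variability rather than to population spread, and (b) keeps type-1
  performance roughly constant across participants so that AUROC2
  differences are interpretable as metacognitive rather than first-order
  effects.

Confidence is then swept over the fixed criterion grid X ∈ {5, 10, …,
100}; at each criterion, confidence ≥ X counts as a high-confidence
report, yielding TP/FP/TN/FN counts, TPR = TP/(TP+FN) and
FPR = FP/(FP+TN). AUROC2 is the trapezoidal area over the resulting
points augmented with the anchors (0,0) and (1,1). This equals the
probability that a randomly chosen correct trial carries higher
grid-binned confidence than a randomly chosen incorrect one (ties ½) —
the property the test suite verifies by exhaustive enumeration.

For the forced-choice design, accuracy is category matching (response
"pleasant" is correct iff the database valence class is high, and
likewise for arousal), and the same criterion sweep yields AUROC2. The
package additionally fits meta-d′: the equal-variance SDT model asks what
type-1 sensitivity an ideal observer would need so that its
response-conditional confidence distributions reproduce the observed
ones, holding the type-1 criterion fixed at its empirical value (scaled
as c′ = c·meta-d′/d′ at the meta level). K−1 type-2 criteria per response
side are fitted jointly with meta-d′ by maximizing the multinomial
likelihood of the confidence counts conditional on each
(stimulus, response) cell.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 0.675 | interval half-width in SD units; 0.675 gives the Gaussian 50/50 split |
| `grid` | 5, 10, …, 100 | confidence criteria for the ROC sweep |
| `min_n` | 5 | minimum correct and incorrect trials for a valid curve; below it AUROC2 is `NaN` with a warning |
| `edges` | 25/50/75 | fixed confidence-bin edges (K = 4) for the meta-d′ fit |
| `padding` | 1/(2K) | added to every confidence cell before likelihood evaluation |
| familiarity cutoff | 50 | familiarity ≥ 50 is "high" in `familiarity_split` |
| `sd_type` | sample | n−1 denominator for the interval SD |

## Decisions made where the design was open

* **Database-scale mapping.** Database norms live on a 9-point scale,
  ratings on 0–100. `rescale_db_rating` uses the affine map with pinned
  endpoints (1→0, 9→100, hence 5→50) — the only order- and
  midpoint-preserving affine choice. It is a package convention, exposed
  as a function so an alternative mapping can be substituted.
* **Boundary trials.** A difference exactly on the interval edge counts
  as correct (inclusive reading of "lay within"). This only matters on a
  measure-zero set for continuous data and on integer-boundary ties.
* **Zero-SD series.** If a participant's differences are constant, the
  interval has zero width and trials are correct iff they equal the mean
  exactly, rather than erroring.
* **Sample vs population SD.** Sample SD (n−1) is the default for
  estimating a participant's spread from a finite trial set; a flag
  switches to the population convention.
* **Group means include the participant.** The `avg`/`oavg` standards
  average over *all* kept participants, own rating included; a
  `leave_one_out` flag removes it. Means are computed after the
  invariant-participant exclusion and within session, since sessions may
  use different stimulus sets.
* **Exclusion granularity.** A participant invariant on any rated
  parameter is excluded per offending session by default (the least
  destructive reading); `per_session = FALSE` forces whole-participant
  exclusion.
* **High/low stimulus classes.** Database ratings above 5 are "high",
  below 5 "low"; a rating of exactly 5 has no class and is a metadata
  error unless labels are supplied explicitly.
* **Confidences 1–4.** The grid starts at 5, so ratings 1–4 are
  below-criterion at every criterion; they are not given a criterion of
  their own.
* **Meta-d′ numerics.** Confidence is binned with fixed edges for
  determinism and comparability across participants (quantile binning
  would tie criteria to each participant's marginal distribution).
  The likelihood is maximized with bounded L-BFGS-B, meta-d′ ∈
  [0, 5·d′+1], multi-started from {0.5, 1, 1.5}·d′ to avoid local optima
  without randomness; non-convergence is flagged, never silent. Extreme
  hit/false-alarm rates are corrected by the 1/(2N) rule.
* **Cohen's d convention.** For paired tests d = t/√n, the convention
  uniquely consistent with published (t, df, d) triples for this design.
* **Correlation method choice.** "Auto" uses Shapiro–Wilk at α = 0.05 on
  both margins; any failure selects Spearman.
* **Exact power.** `required_n_correlation` integrates the exact sampling
  density of the correlation coefficient (hypergeometric-series form)
  rather than the Fisher-z approximation; at ρ = 0.35, one-tailed
  α = 0.05, power 0.8 the exact model needs n = 49 while Fisher-z gives
  50. The density integrates to 1 to numerical precision (tested).

## What the simulator emulates

`simulate_rating_experiment` draws per-stimulus normative means on the
0–100 scale, stratified over the four affective categories (HVHA, HVLA,
LVLA, LVHA) with "high" dimensions uniform on (57.5, 90) and "low" on
(10, 42.5) — balanced categories with a margin around the boundary, as in
curated picture sets. Defaults are 60 stimuli, 58 participants, one trial
per stimulus per session. Per trial and dimension:

* internal evidence e = μ_s + b_p + ε with participant bias
  b_p ~ N(0, σ_b = 10) and first-order noise ε ~ N(0, σ_1 = 15); the
  recorded rating is e clipped to [0, 100] and rounded (clipping rate is
  reported in the truth record, ~10% at defaults);
* the others-estimate is μ_s + ζ, ζ ~ N(0, σ_o = 10) — participants know
  approximately what others feel, with idiosyncratic error;
* confidence reads out the quantity the accuracy rule scores: the trial's
  recorded rating–norm difference, corrupted by metacognitive noise
  N(0, σ_m), compared against the participant's running mean of past
  differences, and mapped affinely (2 scale points of deviation per
  confidence point) into 1–100. With σ_m = 0, confidence is a
  deterministic monotone readout of the accuracy statistic and AUROC2
  approaches 1; as σ_m grows, AUROC2 falls to 0.5. `sigma_m_sd` spreads
  σ_m across participants (drawn once, stable across sessions), which is
  what produces positive between-session ICC of AUROC2.

The noise scales were fixed once at values giving realistic behavior on
the 0–100 scale — ratings spanning most of the scale with occasional
clipping, rating–norm difference SDs around 15–20 points, and AUROC2
values spanning the 0.5–0.95 range across σ_m settings, comparable to the
spread seen in human data.

`simulate_2afc_experiment` is a standard equal-variance SDT observer:
decision variable x ~ N(±d_true/2, 1) by stimulus class, response by sign
against a criterion at 0, confidence an affine map of |x| corrupted by
N(0, σ_m) (here in decision-variable units; |x| = 3 spans the scale).
With σ_m = 0 this is the ideal observer, and the meta-d′ fit recovers
M-ratio ≈ 1 — the parameter-recovery check in the test suite.

All randomness flows from a single mandatory seed through per-participant
derived streams, so runs are bit-reproducible and participant-level
output does not depend on participant order.

What the simulator does **not** emulate: stimulus-specific variance
structure (all pictures share the same noise scales), response heaping or
slider anchoring effects, familiarity-dependent accuracy, serial
dependence beyond the running-mean confidence reference, and any
relationship between valence and arousal (dimensions are generated
independently). Passing pipeline tests on simulated data therefore shows
the estimator chain is correct under the assumed generative structure,
not that human data meet those assumptions.

## Problem sizes used in the checks

The packaged checks use 100,000 Gaussian differences for the half-split
property; 10,000 trials per class for meta-d′ recovery (fitted counts,
so runtime is independent of n); 200 simulated participants per point of
the metacognitive-noise grid {0, 0.5, 1, 2} for the AUROC2 degradation
curve; and 60 participants × 2 sessions for the reliability structure.
These sizes keep Monte-Carlo error well inside the asserted bounds.

## Known limitations

* The rating-task d′ (`type1_dprime_rating`) needs a binary class
  structure that the continuous task does not naturally have; the
  median-split convention used here is explicit but not canonical.
* Meta-d′ from 1–100 confidence requires discretization; results depend
  mildly on the bin edges, which is why fixed edges are the default.
* ICC confidence intervals use the F-distribution bounds of the two-way
  consistency model and assume no missing cells (incomplete pairs are
  dropped).
* AUROC2 on few trials (< ~10 per class) is coarse because the empirical
  curve has few distinct points; the `min_n` guard refuses clearly
  unusable cells but cannot make small cells informative.
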