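---
title: "Trial-history behavior and neural population analysis for interval categorization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trial-history behavior and neural population analysis for interval categorization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intertrial)
library(dplyr)
```

## The task and why trial history matters

`intertrial` analyses a two-alternative interval categorization task. On
each trial the subject hears two identical 50 ms tones separated by an
inter-tone interval (ITI) drawn from eight values — 50, 100, 150, 200 ms
(short) or 350, 400, 450, 500 ms (long) — and must categorize the interval
relative to a 275 ms boundary (the midpoint between the longest short and
shortest long interval). The 150/200/350/400 ms intervals sit close to the
boundary and are difficult; the outer four are easy.

The defining feature of the design is that the stimulus sequence is coupled
to the subject's outcomes: after an incorrect response the same ITI is
repeated, while after a correct response the next ITI is drawn uniformly
from all eight values. An observer that tracks the previous outcome `R`
and the *second-order prior* `X = C × R` (the product of previous choice
and previous outcome, which on completed trials always equals the previous
stimulus category) can therefore anticipate the upcoming stimulus after
errors and improve its performance. The package provides the full analysis
chain for this situation — behavioral strategy metrics, psychometric
fitting, single-neuron encoding models and population decoding — plus a
synthetic-data layer that generates behavior and spike counts from known
ground truth so that every stage can be validated by parameter recovery
and calibration rather than by eye.

All user-facing functions take data frames first and return tibbles, so
analyses chain with the pipe; fitted objects support `tidy()`, `glance()`
and `autoplot()`.

## The task simulator and its agent

`simulate_session()` plays the outcome-coupled chain with a parametric
agent. The agent's choice rule is a logistic decision on noisy evidence
plus a history bias:

- the ITI is perceived with additive Gaussian noise (`sensory_sd_ms`,
  default 80 ms; a multiplicative Weber-noise option exists via
  `weber = TRUE`);
- the decision value is `sensitivity × (boundary − perceived) + b`, with
  `sensitivity` = 0.035 / ms by default;
- the bias `b` pulls toward the previous trial's second-order prior:
  `b = bias_after_error × X_prev` after an error (default 1.5) and
  `b = bias_after_correct × X_prev` after a correct response (default
  0.3); the first trial of a session has no bias;
- with probability `lapse_rate` (default 0.05) the choice is uniformly
  random.

The bias structure is the minimal mechanism by which an agent can exploit
the stimulus repetition: because `X_prev = −C_prev` after an error, a
positive post-error bias simultaneously produces lose-switch behavior and
a steeper post-error psychometric curve. The defaults were chosen once to
give rat-like behavior — roughly 10 percentage points higher accuracy on
easy than difficult trials, a clearly positive post-error slope change,
and lose-switch stronger than win-stay — and are not tuned to any specific
numeric target. The agent is a generative stand-in: no claim is made that
it matches the internal decision model of a real subject beyond these
qualitative phenomena.

Timestamps (center poke, two tone onsets, side poke) are simulated for
realism with a uniform 50–300 ms pre-tone delay and a fixed 50 ms tone;
only completed trials are emitted — early withdrawals and timeout
punishments are out of scope. The side mapping of choices is recorded as
an attribute only; all analyses use category codes.

```{r}
trials <- simulate_session(2000, seed = 1)
head(trials, 3)
```

## Psychometric curves and behavioral statistics

`psychometric_points()` tabulates the fraction of long choices per ITI,
optionally restricted to trials after correct or after error responses
(the first trial of a session belongs to neither). `fit_psychometric()`
fits the four-parameter lapse-logistic curve

$$p_\mathrm{long}(x) = \gamma + (1 - \gamma - \lambda)\,
  \sigma\!\left(\frac{x - \mu}{\sigma_\mathrm{inv}}\right)$$

by maximizing the binomial likelihood. Lapse parameters are bounded to
[0, 0.5), the inverse slope to (1, 1000) ms; because lapse models are
multimodal at small n, the optimizer uses at least five bounded L-BFGS-B
starts over a log-spaced slope grid. Cells with zero trials contribute
zero log-likelihood terms; estimates landing on a box bound are flagged
(`boundary = TRUE`) rather than silently accepted.

```{r}
fit <- fit_psychometric(psychometric_points(trials))
tidy(fit)
```

`compare_inverse_slopes()` reports the percent change of the inverse slope
between the after-correct and after-error curves. The sign convention is
`(σ_correct − σ_error) / σ_correct × 100`, so a steeper (more sensitive)
post-error curve is a *positive* change — this matches the direction of
the effect the analysis is designed to detect, and is stated here because
the convention is otherwise ambiguous. Significance uses a one-tailed
non-parametric bootstrap: all k trials are resampled with replacement,
both conditioned curves are refitted (warm-started at the point
estimates), and p is the fraction of bootstrap changes on the null side of
zero. Trials are the default resampling unit, mirroring a pooled-session
analysis; `resample_unit = "session"` treats sessions as units instead.
Bootstrap replicates that fail to fit are redrawn and counted
(`n_redrawn`). `performance_easy_vs_difficult()` applies the same bootstrap
to the accuracy difference between easy and difficult trials.

`wsls()` computes win-stay and lose-switch probabilities over consecutive
completed-trial pairs within sessions; a session contributes only if it
has at least one post-correct and one post-error pair. One-tailed
bootstrap p-values test each probability against the 0.5 no-strategy point
and their difference against zero.

```{r}
glance(wsls(trials, n_boot = 500, seed = 2))
```

## The synthetic neural layer

`make_population()` draws a population of log-linear neurons: baseline
log-rates `ω₀ ~ N(log 8, 0.6)` (a few to ~20 spikes/s), and per regressor
a tuning weight that is zero with probability `1 − tuned_fraction` and
`N(0, weight_sd)` otherwise (defaults 0.3 and 0.4). All regressors are
coded ±1, so a weight `ω` means a firing-rate ratio `exp(2ω)` between
conditions. Neurons are grouped into simultaneously recorded ensembles
whose sizes follow a discretized truncated normal on 1–8 calibrated to a
mean of exactly 2.9 (sd 1.6) — the recorded-ensemble statistics of the
motivating dataset.

`generate_counts()` draws Poisson counts with mean
`exp(ω₀ + Σ ω_k z_k) × duration` for one of the three 150 ms analysis
periods (trial initiation at the center poke; stimulus offset from 100 ms
before the second tone to tone offset; choice at the side poke — all
half-open windows). A negative-binomial `dispersion` option exists to
stress-test robustness to over-dispersion. `generate_spike_times()` embeds
the same rates in a piecewise-constant inhomogeneous Poisson process with
a constant baseline outside the analysis windows, so windowed counts are
distributed exactly as the count generator — this feeds the PSTH and
spike-time IO paths. Conditional on the regressors, neurons are
independent: no noise correlations are simulated, which means tests built
on this generator cannot detect analysis errors that only matter under
correlated noise.

## Design matrices and the encoding model

`build_design()` constructs the ±1 design with the task's collinearity
rules. In `all_trials` mode the 16 regressors are the current-trial
variables `S_0, R_0, C_0, EV_0` (current difficulty read as expected
value) and, for each of lags 1–3, `R, D, C, X`. The lagged stimulus is
excluded because it equals the lagged second-order prior on completed
trials, and `X_0` is excluded because it equals `S_0`; the first three
trials are dropped so all lags exist. Conditioned modes implement the
exact aliases created by the outcome filter: after correct responses
`C_−1 = X_−1` (merged, lag-1 only, `R_−1` constant and dropped); after
errors `X_−1 = −C_−1 = S_0` and `EV_0 = D_−1` (each group kept as its
current-trial representative). The passive mode uses stimulus-only
regressors with lagged stimuli standing in for the undefined second-order
prior. Alias maps are stored as attributes.

`fit_loglinear()` is the maximum-likelihood Poisson log-link regression of
spike counts on this design (via `stats::glm.fit`). The count distribution
of the model is a modelling choice — only the log link is intrinsic to the
analysis — which is why per-regressor significance does not come from the
likelihood: `permutation_pvalues()` shuffles the neuron's counts across
trials, refits on each shuffle, and doubles the one-sided exceedance
(ties counted as exceedances, p floored at `2/n_perm`, capped at 1). The
permutation null preserves the regressor correlation structure and is
agnostic to the count family, so mild over-dispersion affects power but
not validity. The shuffle refits use a lean IRLS that reproduces the
`glm.fit` MLE (tested to 10⁻⁶) at a fraction of the overhead, falling
back to `glm.fit` when it fails; shuffles that still fail are redrawn and
counted, and a neuron aborts if more than 5% fail. No multiple-testing
correction is applied across regressors, because all variables enter one
joint model rather than separate tests.

Population-level inference uses `population_fractions()`: the fraction of
neurons significant per regressor with an exact one-tailed binomial tail
against the 5% chance level, and `difference_binomial_test()` for
comparing two fractions — a Monte-Carlo null of two binomial processes at
the pooled rate. Neurons with mean rates below 1 Hz are excluded by
`neuron_filter()` before any fitting (a neuron at exactly 1 Hz is kept).

For weight-correlation analyses across periods the log link is unusable
(z-scored rates are negative), so `fit_linear_zscored()` fits OLS on
z-scored counts with the same design; on weakly tuned Poisson data its
weights track the GLM weights closely. `weight_stability()` correlates one
regressor's weights across two periods over neurons, with a permutation
null that shuffles each neuron's z-scored rates within each period.
`conditioned_weight()` and `cross_variable_weight_correlation()` estimate
weights while holding a correlated variable fixed (mean of the two
within-level fits); conditioning can create new exact aliases (with the
upcoming choice fixed, the current outcome equals ± the current stimulus),
which are resolved by dropping the later duplicate column while always
retaining the target.

## Population decoding

`balanced_decode()` implements the linear decoder: a logistic decision
variable `DV = ω₀ + Σ ωᵢ rᵢ` thresholded at zero, trained and tested by
stratified 5-fold cross-validation. Class imbalance inflates apparent
accuracy even without information, so before each fit the larger class is
randomly subsampled to the smaller one; the subsampling is repeated 20
times and the reported decoding performance (DP) is the mean held-out
fraction correct, making 0.5 the chance level at any imbalance. No
regularization is applied by default (the decoder is plain logistic
likelihood); separable micro-datasets are handled by capping the
iteration count and using only the sign of DV, which is all the
classification needs. Whether folds should be stratified by class is an
open choice; stratification is used because it guarantees both classes in
every training fold at small n.

`null_test()` shuffles the trial labels and recomputes the full
subsampled cross-validated DP `n_null` times (default 1000); the
one-tailed p is the fraction of null DPs at or above the observed one,
floored at `1/n_null`. `conditioned_decode()` decodes a target within
each level of a correlated conditioner and averages the two DPs — the
decoding analogue of the conditioned weights, separating genuine encoding
from inherited correlation. `rank_variables()` maps the decoder over all
(variable, ensemble) pairs with ensemble sizes 1–3, summarising mean DP
per variable and size over all ensembles and over the 10% most
informative ensembles. The top-fraction selection uses the same DP
estimate that is reported (so it inherits a selection bias, as any
best-of curve does) and is performed within each ensemble size so that
size curves compare like with like. Ensembles never pool neurons across
sessions.

```{r, eval = FALSE}
cfg <- decode_config(seed = 1)
rk <- rank_variables(counts, labels, cfg)
autoplot(rk)
```

## Single-neuron characterization

`roc_auc()` is the Mann-Whitney pair-counting probability that a rate
drawn from the +1 class exceeds one from the -1 class, with ties counted
as half pairs; values below 0.5 are reported reversed with a `flipped`
flag. `psth()` computes trial-averaged rates with a causal rectangular
window (rate at `t` = count in `(t−100, t]` / 0.1 s, stepped every
50 ms), optionally split by a trial variable; the standard error is taken
across trials and reported as missing for single-trial curves.

## Numerical choices and problem sizes

Reproducibility is seed-based throughout: every stochastic function takes
a `seed` argument and leaves the global RNG untouched (`withr`); nested
procedures derive independent sub-seeds. Defaults follow the reference
procedure (10,000 bootstrap replicates and permutations, 1000 decoding
nulls); the package's own test suite runs the same machinery at reduced
scale — e.g. 999-shuffle permutation calibration over 200 neurons,
200-ensemble decoder-null batches, 199-replicate bootstrap intervals —
sizes chosen to keep Monte-Carlo error comfortably inside each assertion's
tolerance band while the full suite stays fast enough for routine use.

Known limitations: the agent is a phenomenological stand-in, not a fitted
behavioral model; synthetic neurons are conditionally independent and
exactly log-linear, so calibration results certify the analysis code, not
the adequacy of the GLM for any particular real dataset; and the
after-error design collapses several task variables into one regressor by
construction, which is a property of the task, not of the package — the
encoding fractions fitted in different conditioning modes are therefore
not directly comparable.
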