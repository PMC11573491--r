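---
title: "Methods: task simulation, discounting metrics and ensemble trajectory analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: task simulation, discounting metrics and ensemble trajectory analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddtraj)
library(dplyr)
```

`ddtraj` implements a complete analysis chain for within-session
adjusting-amount delay discounting (DD) experiments with simultaneous
multi-neuron recordings: simulation of the behavioral task, discounting and
choice-strategy metrics, segmentation of choice sequences into runs, peri-
choice spike-train processing, and principal-component state-space analysis
of ensemble trajectories. Because raw animal data for this paradigm are
rarely deposited, the package ships seeded synthetic generators for both
behavior and spikes, so every stage of the pipeline can be validated against
known ground truth. This vignette documents the models, the parameters that
matter, the numerical conventions, and the limits of what the synthetic
validation shows.

## The task and its simulator

In the adjusting-amount DD task, a rat chooses between a *delay* lever that
always delivers `a = 6` sucrose pellets after a fixed delay `d` (0, 1, 2, 4,
8 or 16 s across conditions) and an *immediate* lever whose payout — the
*i-value* — adjusts with behavior: it starts each session at 3 pellets,
increases by one after every delay choice and decreases by one after every
immediate choice, clamped to 0–6. Two consecutive same-lever choices trigger
a *forced* trial on the other lever; forced trials leave the i-value
unchanged and reset the consecutive-choice counter, and an omitted forced
trial repeats. A session ends after 30 choice trials or 35 min (the longer
recording variant uses 40 trials / 45 min). These rules are implemented in
`update_i_value()`, `next_trial_kind()` and `simulate_session()` and are
tested exhaustively against brute-force state-machine oracles.

Whether forced trials should alter the i-value is genuinely open — empirical
reports only state that no effect of forced trials was found. We model them
as mechanically inert (no i-value update) because that is the reading
consistent with the adjusting-amount logic: the i-value tracks *choices*.

The simulated agent values the immediate option at its current payout,
`v_imm = i`, and the delayed option hyperbolically,

$$ v_{del} = \frac{a}{1 + k\,d}, $$

and chooses the delay lever with probability
`plogis(temperature * (v_del - v_imm))`. `k` (1/s) is the agent's true
discount rate; `temperature` (1/pellets) is the softmax inverse-noise. At
`temperature = Inf` the agent is greedy, and exact value ties break toward
the delay lever, matching the delay-lever bias observed at short delays in
this paradigm. Choice latencies are drawn from a log-normal whose median
scales as `1 / (|v_del - v_imm| + 0.25)` seconds: close-value (hard)
decisions are slow. This is deliberately minimal plumbing — it exists so that
latency-contrast analyses have realistically skewed input, not as a model of
rodent reaction times.

## Discounting and strategy metrics

**Indifference points.** The mean i-value over the last 10 choice trials of
a session (`indifference_point()`); forced trials are excluded. In real
designs the first two sessions of a newly introduced delay are discarded as
unstable before averaging — that is a data-selection step upstream of this
package's functions.

**Hyperbolic fit.** `fit_mazur()` minimizes
$\sum_d (ip_d - a/(1+k d))^2$ over `k >= 0` with a deterministic
log-spaced-grid + golden-section refinement on `[0, k_max]`. We constrain
`k` to be nonnegative: a negative rate makes the hyperbola *increase* with
delay, which contradicts the construct being measured; published negative
values of small magnitude are treated as sign-convention artifacts. The fit
is exact on noiseless input and is validated against a fine grid-search
oracle and by parameter-recovery simulations (median recovered `k` converges
to the true rate as noise shrinks).

**AUC.** `auc_discounting()` uses the Myerson–Green normalization (delays
divided by the maximum delay, indifference points by `a`), giving a unitless
area in [0, 1]. The normalization is a design choice; sources describing
this task rarely state one.

**Curve comparison.** `compare_curves_ess_f()` is the extra-sum-of-squares
F test: with one parameter per curve (`a` fixed), `df_pooled = N - 1`,
`df_separate = N - 2`, and
`F = (SSE_pooled - SSE_sep) / (SSE_sep / (N - 2))`. A perfect separate fit
with remaining pooled error is reported as an infinite F with an explicit
flag rather than an error. Monte-Carlo calibration under a shared-`k` null
(1,000 replicates in the acceptance suite) keeps the type-I error at the
nominal level.

**Choice-type runs.** Choice trials are stratified by lever and i-value
level (*low* `< 4`, *high* `> 3`); `consecutive_choice_pdf()` extracts
maximal same-type run lengths, their empirical probability density, and a
gamma fit by maximum likelihood with method-of-moments initialization (runs
of length 1 included). Gamma is a pragmatic choice for positive skewed
lengths; with fewer than two runs, or degenerate (all-equal) lengths, the
fit is skipped with a warning rather than fabricated.

**Latency contrasts.** `latency_rank_contrast()` rank-transforms pooled
third- and fourth-trial latencies (ranks limit the positive skew of reaction
times), reports mean ranks, and tests pairs with the Wilcoxon signed-rank
test — exact null distribution below n = 25 when there are no ties or zero
differences, normal approximation with tie correction otherwise. All
differences zero returns `z = 0, p = 1` by contract.

## Runs and the eight trial types

A *run* is three or more consecutive same-lever choice trials; forced trials
are invisible to run continuity. Each maximal streak of length ≥ 3
contributes exactly one run anchored at its first three choices
(`segment_runs()`). The run's third trial is the streak's third choice; its
*fourth trial* is the next choice trial, even when forced trials intervene.
If that fourth choice switches lever the run is a *Change* run, otherwise
*Fail-to-Change*; a run reaching the end of the session unclassified is
dropped with a message. Lever × outcome × trial position gives the eight
trial types (`trial_types()`).

The anchored-maximal convention is a deliberate choice: sources defining
runs do not say whether a 3+1 window slides along longer streaks. Anchoring
once per maximal streak is the simplest reading that keeps runs
non-overlapping (a property the test suite checks), and the segmenter is
verified against a brute-force scan on *every* lever sequence up to length
12.

## Peri-choice spike processing

Spike trains are aligned to the choice press and binned at 200 ms with an
inclusive-endpoint convention: a window of (−15, +15) s yields 151 bins and
(−19, +1) s yields 101 bins (`bin_count()`). Counts are converted to rates
(Hz). Smoothing (`smooth_rates()`) is per neuron along time, either a 5-bin
moving average (the default for binned population analyses) or Gaussian
convolution with σ = 10 ms on the 200 ms grid; the two are exposed as
configurable stages because published descriptions attach them to different
analyses. Edges use reflected padding, so constant series pass through
unchanged; the whole align–bin–smooth chain is linear until z-scoring, which
the suite verifies directly.

`zscore_rates()` standardizes each neuron over its concatenated bins using
the population SD (`ddof = 0`, configurable); zero-variance neurons carry no
signal and are dropped with a message. `condition_averages()` produces
grand-average traces per choice condition (IM/DEL × low/high i-value) and
per-timepoint paired t tests across neurons with Benjamini–Yekutieli FDR
correction across bins — BY because per-bin tests on smoothed data are
strongly dependent, and BY is valid under arbitrary dependence.

Population analyses include only neurons that fire at least one spike in the
peri-choice window of the third and fourth trials of *every* run type
present (`filter_firing_neurons()`); `retention_table()` carries the
starting/excluded/retained bookkeeping.

## State spaces and trajectory distances

For each of the eight trial types the trial-averaged 101-bin × neuron matrix
is computed; the eight matrices are concatenated (808 rows), z-scored per
neuron, and decomposed by PCA (`build_state_space()`, via SVD on the
already-centered matrix). PCA's sign ambiguity is resolved by forcing each
component's largest-magnitude loading positive, making results
deterministic. The trial-type matrices are trial-averaged *before*
concatenation — the 101-rows-per-type structure implies this — and
single-trial variants can be built by passing per-trial matrices, though
that mode is not the default anywhere.

Trajectories are the top-3 component scores over bins. The distance between
a run type's third- and fourth-trial trajectories is the *diagonal* of their
full pairwise Euclidean distance matrix — the per-bin norm of the coordinate
difference (`trajectory_distance()`, verified against the full matrix). The
mean over bins summarizes each run type. `per_session_distances()` runs this
recipe per session: exclusion, alignment (−19..+1 s), 5-bin moving average,
trial-type averaging, session-level PCA (z-scored over that session's
concatenated bins only), distances per run type. Run types absent from a
session are reported absent, never imputed. Group-level contrasts on the
resulting distance series (time × run repeated-measures ANOVA with
Greenhouse–Geisser correction, per-bin BY-FDR t tests) use `rm_anova_gg()`
and `fdr_by()` on the tidy output.

`rm_anova_gg()` implements the classical univariate repeated-measures F for
one within-subject factor with Greenhouse–Geisser epsilon computed from the
double-centered covariance matrix; with two levels epsilon is exactly 1 and
the statistic equals the squared paired t. It is cross-checked in the test
suite against the multivariate-model implementation in `car`. Published
fractional ANOVA degrees of freedom (e.g. df < 1 paired with large error
df) cannot be reproduced by any standard epsilon correction and are treated
as reporting artifacts; the package reports conventional epsilon-scaled dfs.

## Synthetic data: what it emulates and what it does not

`synth_spec()` fixes the study conditions for both generators in one seeded
object. Defaults, chosen once: agent `k = 0.3 /s` and `temperature = 3`
(values that put the 8 s delay near indifference, the regime of interest);
40 neurons at 5 Hz mean baseline, gamma-distributed across neurons (shape 4)
for realistic rate heterogeneity; parameter-recovery curves use
`k_true = 0.25` with Gaussian noise σ = 0.2 pellets on six delays.

`generate_spikes()` draws inhomogeneous-Poisson spikes around run events
under one of two condition templates: *stable* (constant pre-choice drive —
the short-delay, procedural regime) or *ramping* (linear rise from −8 s to
the choice — the long-delay, deliberative regime). A planted
Change-versus-Fail-to-Change signal adds `delta` Hz to a fixed random 30% of
neurons on the fourth trial of the targeted run types: constant under the
stable template, growing from zero at ramp onset to `delta` at the choice
under the ramping template. This construction gives the two regimes their
qualitative signatures — flat elevated distance profiles (stable) versus
distance rising toward the choice (ramping) — and makes the recovered
contrast monotone in `delta`, which the acceptance suite checks at
`delta ∈ {0, 1.5, 3}` Hz with 4 runs per type and 3 seeds.

What passing these tests shows: the pipeline detects, localizes in time, and
scales with a known population-level signal under Poisson noise, and every
deterministic stage matches an independent oracle. What it does not show:
recovery of the original study's effect sizes or statistics — those depend
on undeposited animal data; real spike trains are bursty, non-Poisson and
nonstationary; real run compositions are unbalanced; and real ensembles mix
signal correlations that a rate-offset model does not emulate. Synthetic
problem sizes (tens of neurons, a few runs per type) are chosen as the
smallest scale at which the planted effects are unambiguous.

## Numerical conventions and degenerate inputs

* Bin counts: `round((end - start)/width) + 1` (inclusive endpoints).
* z-scores: population SD; zero-variance neurons dropped, reported.
* PCA: SVD on the z-scored matrix; sign fixed by largest-|loading|;
  explained variance over *all* components sums to 1.
* `fit_mazur()`: `k` bounded to `[0, 100]`; boundary `k = 0` compared
  explicitly so flat curves return exactly 0.
* `compare_curves_ess_f()`: `SSE_sep = 0` with pooled error → `F = Inf`,
  flagged; both zero → `F = 0, p = 1`.
* Wilcoxon: zero differences removed; all-zero case returns `p = 1`.
* Smoothing: kernel longer than the series is an error, not silent
  truncation; spans must be odd.
* Serialization: trial/spike tables as CSV or JSON; aligned tensors as tidy
  CSV plus a JSON metadata sidecar (`write_aligned_tensor()`), keeping all
  artifacts plain text.

## Known limitations

The simulator does not model omissions, satiation or session-level drift;
the agent has no learning (its `k` is stationary within a session). Only the
anchored-maximal run convention is implemented. The Gaussian smoothing
kernel at its 10 ms default is nearly a delta function on a 200 ms grid —
it is provided for fidelity to the described processing chain and matters
only at finer bin widths. `rm_anova_gg()` handles one within-subject factor;
factorial repeated-measures designs should be composed from it per factor
level or delegated to `car`.
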