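---
title: "Attentional fluctuations and shared variability: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attentional fluctuations and shared variability: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(attnvar)
```

## The scientific problem

Neurons in visual cortex respond variably to repeated presentations of an
identical stimulus, and this variability is correlated across simultaneously
recorded cells ("noise correlation", r~sc~). Two very different accounts of
how spatial attention shapes these correlations make the same prediction in
classical cued-attention designs: attention may *suppress a common noise
source*, or the subject's *attentional state may fluctuate* from trial to
trial, with the fluctuations themselves generating shared variability. The
paradigm this package implements dissociates the two by manipulating how
*variable* the attentional state is, not just how strong it is: two dynamic
orientation-noise stimuli are shown left and right of fixation, and a cue
makes either one stimulus behaviorally relevant ("Attend In" toward the
recorded receptive fields, or "Attend Out") or both ("Attend Both"). If the
attentional state switches between the two stimuli when both are relevant,
correlations should be *highest* in Attend Both at long timescales, whereas
the noise-suppression account predicts intermediate correlations there.

`attnvar` provides (i) a generator for the complete task — stimulus
sequences, session schedules, behavioral outcomes, spiking populations under
a latent switching attention state, eye traces and laminar LFPs — and
(ii) the full analysis chain used to evaluate such experiments. Because the
generator embodies the attentional-fluctuation model explicitly, every
analysis stage can be validated against known ground truth.

## The task generator

The stimulus is a pair of Gabor patches whose orientation changes every
10 ms frame, drawn from 36 orientations spaced 5° apart. During the
zero-coherence period (ZCP) the stream is a concatenation of random
permutations of the 36 orientations, so each orientation appears once
before any repeats; consequently a 300 ms window can contain a given
orientation at most twice by chance. ZCP durations follow an exponential
distribution bounded to [0.01 s, 5 s] with mean 2.17 s. We treat the
printed statistics as describing the *truncated* distribution the subject
experiences and calibrate the underlying rate by root finding
(`zcp_rate()`); a rate of 1/2.17 would produce a truncated mean of only
about 1.62 s. The coherent period (CP) lasts 300 ms, during which
`coherence` of the 30 frames show the signal orientation (135° left, 45°
right), placed uniformly at random; non-signal CP frames continue the
background stream and are resampled away from the signal orientation so the
designed signal count is exact. A 200 ms ZCP tail gives time to respond.

Five repeatable stimulus seeds per session make identical-stimulus
repetitions available for correlation analysis. Streams are prefix-stable
deterministic functions of `(session_seed, seed_id, side)`. Attention is
blocked: blocks are randomized in triples so each condition appears before
any repeats, a block ends after 60 counted hit-or-miss trials (false alarms
and catch trials do not count), 10% of trials are catch trials with no CP,
and the Attend Both condition uses coherences one frame higher to balance
difficulty.

## The attention model

Attention enters as a population-wide latent variable $a(t)$ (0 = neutral).
Each unit couples to it multiplicatively (gain units), additively (offset
units), or both, in proportions of roughly 32% / 20% / 48%, mirroring the
heterogeneity of attentional modulation in V1. Unit rates are

$$\lambda_i(t) = d_b\,\bigl[\,b_i + o_i\,a(t) + (1 + g_i\,a(t))\,A_i
  \exp\{\kappa_i(\cos(2(\theta(t - \ell_i) - \phi_i)) - 1)\} + c_i z(t)\bigr]_+,$$

with per-block slow drift $d_b$, baseline $b_i$, tuned amplitude $A_i$, von
Mises tuning on the doubled angle with preference $\phi_i$ and concentration
$\kappa_i$, response latency $\ell_i$ (50 ms), and an optional fast shared
noise $z(t)$ (AR(1), ~20 ms correlation time). Spikes are an inhomogeneous
Poisson process, exact for the frame-wise constant rate (Poisson counts per
frame, uniform times within the frame).

Two aspects of the attentional state are parameterized separately, and this
is the central modeling decision of the package:

* **Condition mean gains** (`gain_attended` = 1.03, `gain_unattended` =
  0.98). Their gap sets the mean firing-rate difference between Attend In
  and Attend Out (a few percent, as observed in V1).
* **State separation in Attend Both** (`ab_state_separation` = 0.5). When
  both stimuli are relevant, the latent state switches between an
  attend-RF and an attend-away state placed symmetrically about the AI/AO
  midpoint, with exponential dwell times at `within_trial_switch_hz` = 4 Hz
  (mean dwell 250 ms, the rate at which attention has been reported to
  alternate between two candidate targets).

A single gain parameter cannot play both roles: mean-rate modulation of a
few percent implies a state gap far too small to generate the observed
correlation differences, while a gap large enough for the correlations
would imply implausibly large rate differences. Empirically the two effects
dissociate — rates differ between AI and AO while correlations do not —
which is precisely the signature of a mean/variance decomposition of the
attentional state. Setting `ab_state_separation = gain_attended -
gain_unattended` recovers the single-parameter model exactly, and with
switching disabled and a degenerate state prior the AB condition then
reduces to AI or AO; the property suite checks this reduction.

Trial-to-trial jitter of the state (`focused_state_sd` = 0.12, shared by
the population) is present in every condition; it is what gives AI and AO
their nonzero baseline correlations. The probability `p_attend_both` that
an AB trial is spent covering both stimuli at the midpoint gain (no
switching) decreases linearly with stimulus eccentricity in
`session_config()`: nearby stimuli fit inside one attentional field,
distant stimuli force switching. This one mechanism simultaneously produces
the elevated AB psychometric threshold, the elevated AB correlations, and
the growth of the AB correlation contrast with eccentricity.

Behavior: detection of a coherence change is Bernoulli with logistic
probability in coherence; the logistic location is 3.5 frames when the
changed stimulus is attended at CP onset and 5.5 when it is not. False
alarms arise from a constant 0.22 Hz hazard during the ZCP. Reaction times
are Beta-distributed on the legal response window (100 ms after CP onset to
200 ms after CP end); `behavior_rt_median()` gives the generative median
used as a recovery oracle.

## Analysis chain

**Spike detection** (`detect_spikes()`) thresholds at five times the robust
noise SD, $\hat\sigma = \mathrm{median}(|x|)/0.6745$, and aligns each event
to the center of mass of the rectified waveform above half the peak.
Negative-going polarity is the default (extracellular convention;
configurable). Detection is scale equivariant.

**Tuning** (`estimate_tuning()`) regresses 10 ms binned counts on a one-hot
encoding of the 15 stimulus frames preceding each bin (36 × 15 design,
solved sparsely with a tiny ridge because each lag's indicators sum to
one). The optimal latency is the lag with the largest across-orientation
weight variance (ties toward the smaller lag); the curve is re-estimated at
that lag with an intercept, equivalent to per-orientation means reported as
sum-to-zero weights. Significance (`tuning_significance()`) projects the
weight vector onto a one-cycle complex exponential and compares against a
permutation null. The null *replays the entire pipeline* — joint fit,
latency selection, refit — for every shuffle; a fixed-lag null is
anti-conservative because latency selection maximizes over 15 lags. The
permuted joint fits reuse a precomputed hat matrix so each permutation is a
single matrix-vector product. P-values use the add-one correction
$(1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{\text{perm}})$.

**Condition-wise von Mises fits** (`fit_von_mises()`,
`fit_condition_modulation()`). Tuning curves are fit with
$Y = w_1 + \exp(w_2 + w_3\cos(x - w_4))$ on the doubled angle (so the 180°
periodicity of orientation matches the von Mises period; the doubling is
isolated in one transform). The fit multi-starts over eight $w_4$ values
with Levenberg-Marquardt refinement and $w_3 \ge 0$; flat curves are
flagged degenerate with $w_4$ unidentifiable. Shape and preference are then
frozen and per-orientation responses of two conditions are regressed on
$\theta_i = \exp(w_3\cos(x_i - w_4))$ with a condition indicator and
interaction; an F-test against the offset+basis-only model gates t-tests on
the offset (β2) and gain (β3) terms that classify units as gain, offset, or
mixed (α = 0.05 per coefficient, no further correction). The shared shape
should be fit on the curve from *all* trials: basis error from a
single-condition fit leaks into spurious "mixed" classifications.

**Correlations** (`blockwise_zscore()`, `pairwise_rsc()`,
`fano_factor()`). Counts are taken in the first 1000 ms (or 200 ms) after
stimulus onset, on correct trials whose ZCP covers the window — a single
shared mask (`select_analysis_trials()`) so every module sees identical
trials. Z-scoring is block-wise with cells `(unit, condition, seed,
block)`; cells with fewer than 3 trials fall back to `(unit, condition,
seed)` statistics, and zero-variance cells are dropped. Variances are
unbiased (n−1). Fano factors use the same cells, combined by trial-count
weighting.

**Correlation timescale** (`cross_correlogram()`, `cumulative_r_ccg()`).
Raw cross-correlograms at 1 ms lags are corrected with a seed-matched shift
predictor — the cross-correlation of the two units' trial-averaged rate
profiles, computed per stimulus seed because different seeds show different
stimuli. The auto-correlogram keeps its zero-lag spike-count term, and the
cumulative integral uses unnormalized coincidence counts (the triangular
lag-overlap factor shown in the display correlogram is undone); these two
choices make $r_{\mathrm{CCG}}(T) = A_{jk}(T)/\sqrt{A_{jj}(T)A_{kk}(T)}$
equal the Pearson correlation of the $T$-window counts exactly, which the
suite verifies to machine precision. Session curves average pairs within
session, then sessions.

**Behavior, eyes, layers, statistics.** Psychometric curves are
maximum-likelihood logistic fits of hit/(hit+miss) against coherence with
50% thresholds at $-\beta_0/\beta_1$ and bootstrap percentile CIs (2000
resamples). Microsaccades are detected with the 0.1° per 10 ms (10°/s)
displacement criterion, merged over ≤5 ms gaps, binned into eight 45°
sectors centered on the cardinal/oblique axes. Current source density is
the negative second spatial difference across 60 µm-spaced channels with
edge replication and Gaussian smoothing; sinks are negative, and the
earliest post-onset sink channel is the default layer 4–5 boundary
heuristic, with depths labeled supragranular / granular / infragranular by
the 400 µm band superficial to the first layer-5 channel (the −400 µm edge
counts as granular; labels use stated depths, snapping only the reported
channel). Session-level inference uses hand-decomposed repeated-measures
ANOVAs (session as random factor, no sphericity correction, Tukey-Kramer
post hoc on the error mean square), a one-tailed t-test on the planned
contrast $AB - (AI + AO)/2$, and a Bonferroni helper for families of rate
comparisons; `stats::aov` with `Error()` strata is the independent oracle
in the tests.

## Problem sizes and numerical choices

The default simulated study is 30 sessions of 10 units and six 60-trial
blocks (roughly 600 trials per session), with eccentricities spanning
3.7–8.9°, chosen so a complete batch with correlation, behavior and
timescale analyses runs in about a minute while leaving the session-level
tests well powered. Heavier fits use: ridge 10⁻⁶ (relative to the mean
design diagonal) in the joint tuning solve; Levenberg-Marquardt with
f-tolerance 10⁻¹⁰ and 200 iterations per start; 1 ms binning for
correlograms with FFT cross-correlation. Spike counts per frame are exact
Poisson draws; eye traces are generated at 1 kHz (the detector operates on
10 ms displacements, so any rate above ~100 Hz is equivalent).

## What the generator does and does not emulate

The generator reproduces the statistical structure the analyses assume:
identical-stimulus repetitions, block structure with slow drift, latent
attention states with condition-dependent variability, heterogeneous
gain/offset coupling, logistic psychophysics with a state-dependent
threshold, sub-threshold fixational jitter with planted microsaccades, and
dipolar stimulus-locked LFPs. It does not emulate: non-Poisson spiking
(refractoriness, bursting), rate adaptation within trials, saccade
main-sequence kinematics, biophysical LFP generation, or reward and
learning dynamics. Passing tests therefore demonstrate correctness of the
estimators under the model's assumptions, not robustness to every departure
real data can show.

Two further limitations are worth stating. First, with exponential 4 Hz
switching the attention-state autocovariance decays with time constant
1/(2 × 4 Hz) = 125 ms, so the Attend-Both elevation of
$r_{\mathrm{CCG}}(\tau)$ grows smoothly from short lags rather than
appearing abruptly beyond 200 ms as in real data; the sharper empirical
knee suggests dwell-time distributions with a refractory floor rather than
exponential ones. We keep the exponential telegraph because it is the
stated model, and test the timescale signature as: separation significantly
positive at 1000 ms, significantly larger at 1000 ms than at 50 ms, and
rising from 50 to 200 ms. Second, planted microsaccade durations are capped
so the peak 10 ms displacement exceeds the detection criterion with margin
(amplitude/duration combinations below 10°/s are invisible to any
velocity-threshold detector, so uncapped draws would bound recall away
from 1).

## A small worked run

```{r example, eval = FALSE}
cfg <- session_config(session_seed = 1)
bundle <- simulate_session(cfg)
res <- run_session_analysis(bundle, window_ms = 1000)
res$rsc            # mean pairwise correlation per condition
res$contrast       # r_AB - (r_AI + r_AO) / 2
res$psychometric   # 50% thresholds per condition
```

A multi-session study with session-level statistics:

```{r study, eval = FALSE}
st <- run_session_study(n_sessions = 30, base_seed = 7)
ab_contrast_test(st$rsc)              # one-tailed planned contrast
eccentricity_trend(st$contrast, st$eccentricity_deg)
```
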