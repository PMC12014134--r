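---
title: "Methods: ROC selectivity, multisensory integration and decoding in avspike"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ROC selectivity, multisensory integration and decoding in avspike}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avspike)
```

avspike analyses trial-aligned spike trains from a two-alternative
forced-choice (2AFC) audiovisual discrimination task: an animal triggers one
of six target cues — two tones (`A3k`, `A10k`), two light bars (`Vhz`,
`Vvt`), and their trained pairings (`A3kVhz`, `A10kVvt`) — plus, optionally,
two "unmatched" pairings whose components indicate opposite reward ports.
This vignette explains the statistical machinery, its assumptions, the
tunable parameters, and the design choices made where the methods literature
leaves the details open.

## Data model

A session is two long tables. `spikes.csv` has one row per spike
(`neuron_id`, `trial_id`, `spike_time_ms` relative to cue onset; negative =
pre-cue). `trials.csv` has one row per trial (`trial_id`, `cue`, `choice`,
`correct`, `reaction_time_ms`). Times are real-valued milliseconds and all
analysis windows are half-open `[start, end)`, so a boundary spike is never
counted twice by adjacent windows. `correct` is `"yes"`/`"no"`, with a third
state `"either"` for unmatched pairings, where either port is rewarded and
correctness is undefined; analyses that restrict to correct trials keep
`"either"` trials, because excluding them would discard every trial of those
cues. Missing reaction times are empty fields, distinct from zero.

## PSTHs, baseline normalisation and responsiveness

PSTHs use 10 ms bins smoothed with a Gaussian kernel of sd 50 ms, truncated
at ±3 sd and renormalised at the epoch edges so that smoothing preserves the
time-integral of the rate (edge bins would otherwise droop). Baseline
statistics (mean and SD of the binned rate) come from the 400 ms window
before cue onset and convert the smoothed rate to a z-score. Two details are
deliberate:

* the baseline mean/SD are taken from the **raw** binned rates, not the
  smoothed series — the 50 ms kernel leaks post-onset activity ~150 ms back
  into the baseline, and a completely silent baseline must surface as a
  degenerate flag (SD = 0), not as an infinite z-score;
* a unit enters analysis only if its whole-epoch mean rate reaches 2
  spikes/s. Whether that inclusion rate should be measured over the baseline
  or the whole session is ambiguous in the methods literature; the
  whole-epoch mean is used because it is well-defined without recording
  metadata.

A cue counts as *responsive* when the baseline-subtracted evoked rate in the
0–300 ms window exceeds 2 spikes/s **and** a paired Wilcoxon signed-rank
test against the baseline-window rates gives p < 0.05 (α per cue, no
multiple-testing correction — the criterion is conjunctive, so a highly
significant 1 spikes/s response does not qualify). All-zero paired
differences leave the signed-rank test undefined; such cues are called
non-responsive and flagged. Neurons are then categorised as auditory-only,
visual-only, both (`AV`), `AV-only` (responsive to a pairing but to neither
modality alone), or unresponsive.

## ROC selectivity and the multisensory interactive index

Cue selectivity between conditions a and b is `SI = 2·(auROC − 0.5)`,
where the auROC compares the per-trial spike counts in the analysis window
(default 0–150 ms, where the early evoked response lives; a late 150–300 ms
window is configured for the corresponding control analyses). Two auROC
estimators are provided:

* `exact_rank` (default): `(wins + 0.5·ties) / (n_a·n_b)` over all cross
  pairs, computed from midranks. It is deterministic, handles ties exactly,
  and is the limit of any criterion-sweep construction as the grid refines.
* `discretized12`: the classical sweep over 12 criterion levels linearly
  spanning the pooled range (endpoints included, strict exceedance),
  trapezoidal area with anchors (0,0) and (1,1). The spacing rule for the
  12 levels is not standardised; linear spacing is used here. The two
  estimators agree exactly when the samples take ≤ 12 distinct values
  spanning the grid, and empirically within 0.05 for ≥ 20 trials per side
  (the test suite asserts both).

Significance uses a two-tailed permutation test: trial labels are
reassigned (2000 permutations by default; one figure legend in the
literature quotes 5000, so the count is exposed as `n_perm`), and the
p-value is the add-one tail estimator `min(1, 2·min(p_lo, p_hi))` with
`p = (r + 1)/(n + 1)`, which cannot return p = 0. For the rank estimator
the pooled ranks are permutation-invariant, so each permutation statistic
is a sum over a random rank subset — this is what keeps 2000-neuron
calibration runs cheap.

The multisensory interactive index (MSI) is the same ROC statistic with the
pairing's trials as condition a and the trials of the **stronger unisensory
component** — the component cue with the higher mean analysis-window rate,
ties broken toward auditory, the dominant modality in auditory cortex — as
condition b. MSI > 0 with a significant permutation test is *multisensory
enhancement*, MSI < 0 *inhibition*. Permutations reassign labels between
the pairing and the stronger component only; the third condition plays no
role in the null. Selectivity and MSI use correct trials only, matching how
such analyses are reported.

The choice-split variant computes the MSI separately on correct-choice and
incorrect-choice subsets (both the pairing's and the stronger component's
trials are split). The stronger component is fixed from correct trials so
that both subsets compare against the same cue. Neurons are analysed only
when every involved cue has ≥ 9 trials of each choice; below that the rows
are flagged excluded with the recorded reason rather than silently dropped.

## The bootstrap additive-model test

For a pairing, per-trial *evoked* rates are baseline-subtracted analysis
window rates — the additive model is applied to evoked rates so the
baseline is not summed twice. Each bootstrap iteration resamples
`min(n_AV, pool)` auditory and visual trials and records
`coefficient·(mean_A + mean_V)`; 5000 iterations (default) give the
predicted distribution. Two design points deserve emphasis:

* **Resampling is with replacement.** A literal "same number of trials,
  without replacement" draw is degenerate whenever the draw size equals the
  pool — every draw returns the full pool and the predicted SD is zero.
  With-replacement draws of size `min(n_AV, pool)` make the predicted SD a
  bootstrap estimate of the standard error of the predicted sum (slightly
  conservative when the unisensory pools are larger than `n_AV`).
* **The z-score denominator combines both error sources.**
  `z = (obs_mean − pred_mean) / sqrt(pred_SD² + obs_SE²)`, where `obs_SE`
  is the standard error of the observed multisensory mean. Dividing by the
  predicted SD alone looks natural but is mis-calibrated: the numerator
  carries the sampling noise of *both* the observed mean and the predicted
  mean, so under truly additive responses the ratio has variance ≈ 2 and
  |z| ≥ 1.96 would flag ~16% of additive neurons. With the combined
  denominator the additive-generation false-positive rate sits at the
  nominal ~5% (the acceptance suite measures it), and the reported
  `predicted_sd`/`observed_se` columns let a user reconstruct the raw ratio
  if they want it.

Classification is superadditive (z ≥ 1.96), subadditive (z ≤ −1.96), else
additive; a zero-variance predicted distribution is flagged degenerate. The
companion scaling coefficient `c_hat = AV / (A + V)` (evoked means) is the
natural effect-size; re-running the test with `coefficient = c_hat`
recentres z at ~0. Because `c_hat` is a ratio of noisy means it carries a
small positive Jensen bias of order `Var(A+V)/E[A+V]²` (~1% at 40 trials
and the rates used in the test suite) — visible if you push sample sizes.

## Pseudo-population decoding

Decoding uses a linear-kernel SVM (`e1071::svm`, cost 1, no feature
scaling — raw window counts are the features) trained and tested
independently per sliding window (100 ms, stepped 10 ms) under stratified
10-fold cross-validation. Neurons with ≥ 30 usable trials per class are
eligible; each of 100 resamples draws 30 trials per class per neuron and
pairs them randomly within class across neurons, which destroys
(non-existent, see below) noise correlations, as pseudo-population practice
assumes. The mean ± SD across resamples is reported per window. The
shuffled-label null (1000 shuffles by default) is computed at the most
informative window and reported as a constant band: for a balanced binary
problem the null distribution is window-independent, and per-window nulls
would multiply the dominant cost by the window count (a flag re-enables
them). The `first_crossing_time()` convention is the earliest window
*center* at or above the level, no interpolation. The 8×8 all-pairs matrix
uses a single 0–150 ms window, is symmetric by construction, and fixes its
diagonal at 0.5 by convention.

## The synthetic-session generator

The generator exists so that every stage can be tested against known ground
truth. Each neuron is an inhomogeneous Poisson process, piecewise constant
in time: a gamma-distributed baseline rate over the whole epoch
(mean 5 spikes/s, shape 2), plus an evoked gain from modality latency to
latency + duration (auditory 20 ms, visual 50 ms — auditory slightly
earlier, as observed in that cortex — duration 130 ms; all configurable
since no exact values are printed anywhere). Multisensory trials use

```
rate(t) = baseline + c_pair · (evoked_A(t) + evoked_V(t))
```

with a pairing-specific interaction factor `c_pair` (1 = additive, > 1
enhancement, < 1 suppression) drawn per neuron from a truncated normal. On
incorrect-choice trials `c_pair − 1` is multiplied by `incorrect_shrink`
(default 0.5): the minimal mechanism that weakens multisensory interaction
on errors while leaving unisensory responses untouched. Poisson (rather
than renewal/gamma) spiking is the simplest process consistent with the
analyses, which only ever use window counts. Behaviour draws correct
choices per modality (multisensory 0.90, unisensory 0.82) and shifted
lognormal reaction times targeting means of 367/426/417 ms (multisensory /
auditory / visual; sdlog 0.35, shift 150 ms) — the qualitative pattern of a
well-trained animal: more accurate and ~50 ms faster on multisensory
trials.

`preset_scenario()` bundles parameters for the five study conditions. The
trained presets draw evoked gains from gamma distributions with modest
means (preferred tone 8 spikes/s, non-preferred 2.5; preferred light bar 6)
— chosen so that single-neuron selectivity is clear but not saturated, as
in real cortex — with an 85% bias toward the contralateral-choice cues and
85% auditory–visual congruence. The non-preferred light bar is nearly
silent (mean 0.5 spikes/s, 80% exactly zero): with an additive interaction
(`c = 1`) any residual visual drive would make the non-preferred pairing's
combined response systematically exceed its stronger component, i.e. look
"enhanced", whereas the condition these presets emulate shows *balanced*
enhancement and inhibition for the non-preferred pairing and almost no
neurons preferring that light bar. Interaction factors are `c ~ N(1.5,
0.25)` for the preferred pairing and `N(1.0, 0.1)` elsewhere (truncated at
0); the free-choice preset pins every factor at exactly 1 and symmetrises
all preferences; the unisensory-trained preset keeps auditory preference
but removes visual preference and interaction.

What the generator deliberately does **not** emulate: across-neuron noise
correlations (none are reported for this preparation, and pseudo-population
decoding assumes their absence — adding an invented correlation structure
would fabricate a property no analysis here estimates), non-Poisson
dispersion, spike-sorting artifacts, slow drift, and any dependence of
unisensory responses on choice. Passing tests therefore validate the
*estimators* under the model's assumptions; they cannot certify behaviour
on data that violate them (e.g. strongly correlated populations would
inflate pseudo-population decoding relative to simultaneous decoding).

Note that the generator's interaction factor conflates two phenomena the
real data dissociate: a `c` of 0.83 reproduces sub-additive summation,
while enhancement relative to the *stronger component* requires
`c·(A+V) > max(A, V)`. A single pairing cannot show both strong
sub-additivity and strong enhancement in this model unless both components
drive the neuron; in real cortex the two coexist because responses are not
additive-Poisson. The presets encode enhancement (`c = 1.5`); the
additivity analyses are validated with dedicated `c = 0.83` configurations.

## Numerical choices and degenerate inputs

* Permutation p-values use add-one estimators; z thresholds are ±1.96.
* Identical pooled samples give auROC 0.5, flagged degenerate.
* A zero baseline SD flags the z-PSTH and the responsiveness call rather
  than producing infinities; all-zero paired differences flag the
  signed-rank and normality-gated comparisons ("no difference").
* The normality gate (Shapiro–Wilk at α = 0.05 on paired differences)
  selects paired-t vs signed-rank; both the gate p and the chosen test are
  reported.
* The 2×2 proportion chi-square uses no continuity correction by default
  (a flag enables Yates); expected cells below 1 are flagged.
* Master seeds derive per-stage sub-seeds by a fixed counter scheme
  (`(seed·1009 + 9973·k) mod 2^31-ish`), so pipeline stages can be re-run
  in isolation and full runs are byte-reproducible.

## Problem sizes used in the shipped tests

The package's own validation runs at sizes chosen to make sampling error
small relative to the asserted effects while keeping the suite quick:
1000 sample pairs for the auROC oracle; 2000 equal-rate neurons × 500
permutations for null calibration; 50 neurons per point on a 0–15 spikes/s
gain grid; 1000 additive and 400 sub-additive neurons (1000 bootstrap
iterations) for the additivity calibration; 30–50 neurons, 20 resamples and
200 shuffles for decoding; 200 audiovisual neurons for the
trained-condition and choice-split patterns. `scripts/acceptance.R`
recomputes the same quantities from scratch at comparable sizes.

## Known limitations

* Selectivity/MSI trial pools are shared across neurons within a session,
  so per-neuron trial-count eligibility is effectively per-session; with
  multiple sessions each contributes its own pool.
* The decoding SD across resamples mixes trial-sampling and fold-assignment
  variability; it is a spread, not a standard error of the mean accuracy.
* `AV-only` neurons are modelled as weak unisensory gains lifted by a large
  interaction factor — one of several mechanisms compatible with that
  response class.
* The discretized12 estimator inherits the coarseness of its 12-level grid
  for wide count ranges with small samples; use `exact_rank` (the default)
  unless sweep-fidelity is specifically wanted.
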