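---
title: "spinescope: methods and design notes"
author: "spinescope authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spinescope: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

spinescope analyses dendritic-spine calcium signals from longitudinal
two-photon imaging of awake mice. The pipeline starts at extracted ROI
fluorescence traces (one circular ROI per spine, one on the adjacent
parent dendrite) and ends at population-level homeostasis statistics. It
does not perform image registration, ROI segmentation, or pupil/whisker
tracking; a generic behavioral-regressor correlation hook is provided
instead of the tracking itself.

The package also contains a first-class synthetic-recording generator
with known ground truth. Every analysis stage is validated by parameter
recovery against that ground truth, because the corresponding in vivo
quantities cannot be re-derived at desk scale from raw data.

# The analysis model

## Spine-specific signal extraction

Raw fluorescence `F(t)` per ROI is converted to a drift-corrected
\(\Delta F/F_0\) in two steps:

1. **Slow-drift removal.** The 8th-percentile value of the fluorescence
   distribution in a ±15 s window centred on each sample is subtracted
   from the raw trace (`removeSlowDrift()`). Windows shrink at the trace
   ends; no data are fabricated by padding. At 15 Hz the full window
   spans 451 samples.
2. **Normalisation.** \(\Delta F/F_0(t) = (F(t) - F_0(t)) / \max(F_0(t),
   \varepsilon)\) with \(F_0\) the rolling 8th percentile and
   \(\varepsilon\) = 1% of the trace's median fluorescence
   (`computeDff()`). The percentile filter defines only the subtraction;
   the denominator convention is a package decision (documented here
   because the upstream method leaves it open), chosen so that
   \(\Delta F/F_0\) is invariant under rescaling of the raw trace.

Spine ROIs contain a dendritic component from back-propagating action
potentials (bAPs) invading the dendrite. It is removed by robust
regression: \(\Delta F/F_{0,\mathrm{spine\_specific}} =
\Delta F/F_{0,\mathrm{spine}} - \alpha\, \Delta F/F_{0,\mathrm{dendrite}}\),
where \(\alpha\) is the slope of an iteratively reweighted least-squares
fit with Tukey bisquare weights, tuning constant 4.685 times the
MAD-based residual scale, an intercept that is estimated and discarded,
at most 50 iterations, and convergence when the slope moves by less than
1e-8 (`robustSlope()`). The regression is run on the full session;
per-epoch fitting is possible by subsetting but is not the default,
since nothing in the source method indicates epoch-wise slopes.

## Event detection and activity metrics

Response events are maximal runs of samples above a threshold
(`detectEvents()`): onset is the first supra-threshold sample, peak the
argmax, offset the last supra-threshold sample; single-sample events are
allowed and there is no refractory period. Event amplitude is the
trapezoidal area of the trace above the threshold across the event span
(\(\Delta F/F_0 \cdot s\)). Frequency is events per second over the whole
session; the activity integral is the summed area; a spine is *active*
in a session if it has at least one event, *inactive* if it has none,
and *persistent* if active at every timepoint.

Two practical points deserve emphasis:

* **Threshold.** The canonical rule is `max(0.15, 3.5 * RMS)`: a 15%
  \(\Delta F/F_0\) floor combined with 3.5x the trace RMS. Whole-trace
  RMS, however, includes the calcium transients themselves; on a trace
  with realistic event rates, `3.5 * RMS` exceeds most event peaks, and
  taken literally the rule detects almost nothing. The pipeline
  (`detectSessionEvents()`) therefore defaults to a robust noise scale -
  the 25th percentile of the absolute first differences, scaled to the
  Gaussian standard deviation - which stays noise-dominated even when
  transients occupy much of the trace (the median first difference is
  already contaminated at realistic duty cycles); the floor and the
  3.5x multiplier are retained. All pure variants remain available
  (`eventThreshold(method=)`).
* **Peak resolution.** GCaMP6s transients decay over seconds, so
  successive events often overlap into one supra-threshold run. The
  pipeline resolves peaks within a run by splitting at internal valleys
  at least 0.06 \(\Delta F/F_0\) deep relative to both flanking maxima
  (peak detection); the run-as-one-event definition is kept as the
  low-level default of `detectEvents()`. Before detection the
  spine-specific trace is smoothed with a short causal boxcar (0.2 s);
  at a noise SD of ~0.015 \(\Delta F/F_0\) this suppresses
  noise-induced fragmentation of single transients while delaying
  detected onsets by less than ~0.15 s. These two settings were
  calibrated so that the detected event-onset rate on
  background-only synthetic spines is unbiased (within a few percent)
  with respect to the generative Poisson rate - the property on which
  the dummy-stimulus false-positive analysis rests.

## Functional classification

Classification uses baseline (pre-deprivation) sessions only:

* **Stimulus correlation.** Pearson correlation of the spine-specific
  trace with a binarized stimulus track (1 during presentations), with
  the conventional two-sided parametric p-value; "significantly
  positive" means r > 0 and p < 0.05.
* **Time-locked responses.** A presentation is time-locked when at least
  one detected event onset falls within 500 ms of its onset. The
  percentage is taken over all presentations of the modality (not only
  preferred-direction ones; this aggregation is an assumption, flagged
  here).
* **Chance level.** Each spine's chance of time-locking is estimated
  from its dark-epoch events against dummy presentation layouts with the
  real inter-onset statistics (`falsePositiveThreshold()`). The pipeline
  averages 20 dummy layouts: a single layout gives a per-spine estimate
  with a standard error of several percentage points, which would
  dominate the sensory criterion; averaging layouts shrinks it without
  touching the procedure itself. "Above chance" then means the real
  time-locked count is significantly above the spine's chance rate
  (one-sided binomial test at the 0.5% level) *and* the raw percentage
  exceeds the chance percentage. The strict level reflects that
  thousands of spines are tested without multiplicity correction while
  genuine responders sit far above chance.
* **Sparse-noise responsiveness.** Per sparse-noise frame, the response
  features are the \(\Delta F/F_0\) derivative (one-frame forward
  difference) immediately after the frame and ~100 ms later; at 15 Hz
  the 100 ms sample does not fall on a frame, and the nearest frame (+2
  frames, 133 ms) is used. A bivariate Gaussian is fitted to the trial
  cloud *robustly*: coordinatewise median/MAD initialisation followed by
  iterative trimming at the 99% chi-square contour.
  A plain sample-covariance fit cannot work here: with a fraction f of
  genuinely responsive trials, the largest attainable Mahalanobis
  distance is ~1/sqrt(f) (2.8 SD at f = 12.5%), so a 4-SD cut on the
  sample fit would flag nothing regardless of response size. Trials
  beyond 4 SD of the trimmed fit are responsive, and a spine is a
  sparse-noise responder when its responsive-trial count exceeds a
  one-sided binomial bound whose null combines the Gaussian tail
  (P(chi-square_2 > 16)) with the spine's chance rate of a spontaneous
  event onset hitting the 4-frame feature window - spontaneous
  transients produce genuine derivative outliers, and ignoring them
  makes every active spine "responsive".
* **Network correlation.** The network signal is the unweighted mean of
  all other spines' spine-specific traces over all conditions
  (stimulation and darkness), leave-one-out (`networkSignal()`). Because
  calcium traces are strongly autocorrelated, the parametric p-value for
  this test is anticonservative by an order of magnitude; the pipeline
  default is an exact circular-shift permutation test
  (`networkCorrelation(method = "shift")`): the null distribution is the
  correlation at every circular lag outside a ±5 s guard band, computed
  for all lags at once by FFT cross-correlation, and the reported p is
  two-sided, matching the conventional criterion "positive and
  significant (p < 0.05)". The parametric option remains available and
  is the default of the low-level `stimCorrelation()`.
* **Decision order** (`classifySpine()`): (1) visually responsive if the
  gratings correlation is significantly positive and time-locking is
  above chance, or the spine is sparse-noise responsive; (2) auditory
  responsive (multimodal regions) by the same rule on the auditory
  track; (3) network-correlated if the network correlation is
  significantly positive; (4) unclassified otherwise; (5) a non-sensory
  spine with above-chance time-locking but no significant stimulus
  correlation is excluded from further analysis.

## Longitudinal and population analyses

Baseline labels are fixed; sessions are aligned by spine id
(`alignLongitudinal()`). Percent changes are normalized to the mean of
the baseline sessions, so the baseline maps to 0% exactly
(`normalizedPctChange()`). Inactive fractions, per-class group changes
(mean ± SEM), within-spine frequency(12 h)/amplitude(48 h) coupling
(Pearson when both changes pass a Shapiro-Wilk check, Spearman
otherwise), dendritic clustering with a within-branch position-shuffle
null (1000 shuffles, fixed logged seed, distances reported up to the
90th percentile of branch lengths), an orientation selectivity index,
and global dendritic response correlations complete the battery. The
OSI folds the eight directions into four orientations (averaging
opposite directions) and contrasts the preferred orientation with its
orthogonal: OSI = (R_pref - R_orth) / (R_pref + R_orth) - the standard
contrast, adopted because the exact upstream variant is not spelled
out. Global dendritic responses are quantified as the mean event area
within stimulus windows on the dendrite-ROI \(\Delta F/F_0\) trace
(evoked-window area; whole-session quantification is a possible
alternative that is deliberately not used). Group statistics are limited
to means ± SEM and the correlations above; a full ANOVA/post-hoc battery
is out of scope.

A caveat on amplitude changes: the measured event amplitude is the area
*above the threshold*, which is convex in the underlying transient peak.
A multiplicative scaling s of true peak amplitudes therefore produces a
measured group amplitude change larger than (s - 1): with the default
kernel and threshold the elasticity is roughly 1.5-2. Recovery tests of
deprivation scaling compare against the identity (no change) case, where
the nonlinearity vanishes, and against the qualitative per-class
pattern; the numeric elasticity is a property of the metric, not a bug.

# The synthetic-recording generator

`simulateSession()` renders, for each spine, a raw fluorescence trace
F = F0_true (1 + own + alpha x dendrite + drift + noise) and a paired
dendrite-ROI trace, at 15 Hz (inferred from "15 frames per second"
framing of the upstream acquisition; configurable).

Event trains per session:

* every spine has Poisson background events (default 0.113 Hz - the
  rate at which a 0.5 s window is hit by chance 5.5% of the time,
  matching the reported population false-positive level);
* a session-wide latent network train (default 0.15 Hz) is inherited by
  each coupled spine with probability `couplingWeight` (0.6); visually
  and auditory responsive spines are coupled too, so that sensory
  spines also correlate with the network signal;
* responsive spines emit an evoked event after each preferred
  presentation with probability 0.8 and a uniform 0-250 ms latency.
  Visual spines carry an orientation tuning curve (response probability
  1 / 0.75 / 0.25 of maximum at 0 / 45 / 90 degrees from the preferred
  orientation) - spine tuning is broad, and a tuning curve, rather than
  a single preferred direction, is what makes an orientation
  selectivity index meaningful;
* the branch-level global (bAP) train is *independent* of the latent
  train (default 0.15 Hz, amplitudes 2x spine events): the dendritic
  signal reflects the cell's output, not the shared input. This also
  keeps the bleed slope alpha identifiable - if a spine's inherited
  events coincided sample-for-sample with its dendrite's events, no
  regression could separate bleed from co-activity.

Amplitudes are lognormal (mean 0.45 dF/F, CV 0.3); evoked events are 2x
larger (stimulus-driven synchronous input). The transient kernel is a
difference of exponentials (rise 0.18 s, decay 1.8 s, unit peak) with a
smooth shoulder subtraction that returns it to baseline within ~4 s: the
ideal double exponential overstates tail persistence, and sub-noise
tails otherwise bias low-percentile baseline estimates. Noise is white
Gaussian (SD 0.015 dF/F); slow drift is sinusoidal (amplitude 0.2
relative to baseline, period drawn per ROI pair from 120-360 s) and
shared between a spine and its adjacent dendrite ROI, which share the
optical micro-locus. The bleed slope alpha is uniform on 0.2-0.8 per
spine. Event rates, amplitudes and noise levels are not reported
quantities; they were chosen once so that the analytic false-positive
check (1 - exp(-lambda/2)), the bleed-slope recovery, and the
silent-spine definition are all simultaneously meaningful, and they are
documented here rather than claimed as measured values.

Deprivation is modelled per class: at 12 h after onset a class-dependent
fraction of spines is silenced (all events removed; V1 defaults 0.35 /
0.17 / 0.15 for visual / network-only / unclassified, about 20% of the
population). The silenced fraction per class is exact (largest-remainder
count over a latent per-spine draw), like the class mixture itself, so
population fractions reflect the configured values rather than an extra
layer of binomial noise. Silenced spines reactivate with probability 0.5 at 24 h and
0.75 at 48 h; irreversible deprivation (enucleation) removes the
deprived modality's evoked events from the deprivation onset onward;
reversible paradigms (dark exposure, ear plugging) do not, since imaging
happens after restoration; network-only spines scale their amplitudes
(1.1 / 1.2 / 1.3 at 12 / 24 / 48 h) unless TNF-alpha signalling is
blocked, in which case all scalings are identity. Sham implies no
silencing, no scaling, no evoked removal (enforced by validity).

Study presets (`buildConfig()`) bundle these choices; the V1 and RSC
baseline mixtures encode the published population proportions, which is
what makes classifier recovery a meaningful end-to-end check.

## What the generator does and does not emulate

Emulated: paired spine/dendrite ROIs with bleed-through; stimulus
schedules (gratings in 8 directions, 3 s on / 3 s gray, five blocks;
sparse-noise frames every 250 ms with 8-12 non-overlapping 8-degree
squares; auditory bursts at 3-5 s intervals; a 6 min dark epoch);
Poisson background, shared network events, tuned evoked responses;
drift, noise, deprivation-induced silencing, reactivation and
TNF-dependent scaling.

Not emulated: pixel-level movies and motion artifacts, locomotion
(analysis is restricted to stationary periods by construction), z-drift
and ROI mis-segmentation, bleaching trends beyond the sinusoidal wander,
spatially organised (clustered) functional classes - positions are
assigned independently of class, matching the reported absence of
clustering - and any behavioral covariates. Passing recovery tests
therefore demonstrates correctness of the analysis pipeline under the
stated generative assumptions, not robustness to every pathology of
real recordings.

# Numerical and reproducibility choices

* All generator output is a pure function of the configuration,
  including its seed; sub-streams (plan, schedule, events, rendering,
  dummy layouts, shuffles) derive fixed offsets from it, and RNG state
  is always restored afterwards.
* Problem sizes: recovery fixtures use 2000 spines (1000 for the
  sparse/gratings overlap), one 660 s session (V1) or 780 s (RSC) at
  15 Hz; the deprivation fixture spans five sessions. Unit and property
  tests use 40-500 spines.
* Rolling percentiles are exact (C++ sliding sorted window, type-7
  quantiles), matched sample-for-sample against a brute-force oracle.
* Degenerate inputs error early and name the offending quantity:
  constant regressors and tracks, missing dark epochs, too-short traces,
  fewer than 3 spines for a network reference, under 50 sparse trials.
* Ties and edges: the event-onset window is closed ([onset, onset +
  0.5]); the 100 ms derivative sample rounds to the nearest frame; a
  single-sample event contributes a one-sample rectangle so every event
  has positive area; run splitting keeps the total area of a run.

# Known limitations

* The rolling-percentile baseline inflates slightly on traces with high
  transient duty cycle; this compresses \(\Delta F/F_0\) and biases the
  bleed slope downward by a few hundredths under the default activity
  levels (the recovery tests bound this).
* The parametric stimulus-correlation p-value shares the upstream
  method's anticonservatism under autocorrelation; it is deliberately
  retained for the sensory tests (paired with the above-chance
  time-locking requirement, which carries the specificity), while the
  network test uses the shift permutation.
* The sparse-noise test identifies responsiveness only; receptive-field
  positions are out of scope.
* Measured amplitude changes inherit the area-above-threshold
  elasticity discussed above.
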