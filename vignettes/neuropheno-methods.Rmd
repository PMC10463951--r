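---
title: "NeuroPheno methods: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{NeuroPheno methods: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(NeuroPheno)
```

NeuroPheno packages the quantitative procedures used to phenotype an
optogenetic early-life-pain (ELP) mouse model across four data modalities:
extracellular multi-electrode-array (MEA) recordings of cortical slices,
Fura-2 ratiometric calcium imaging of DRG neurons, IntelliCage home-cage
behavior, and lipidomic feature tables. Each stage has a matching seeded
synthetic-data generator with exhaustive ground-truth bookkeeping, so the
whole pipeline is testable end to end without animal data. This vignette
explains the models, the tunable parameters, the numerical conventions, and
what validation on synthetic data does and does not establish.

## MEA stage: multi-unit-activity detection

Raw voltages are highpass-filtered with a causal second-order Butterworth
filter (cutoff 200 Hz), mirroring the single-pass behavior of online
acquisition software; a zero-phase forward-backward variant is available
behind the `zeroPhase` flag for offline re-analysis. Events are threshold
crossings of the filtered trace at five times the noise standard deviation,
collected over 5-minute traces; channels with fewer than 100 events in
5 minutes are classified inactive (exactly 100 is active, and the count
threshold scales linearly for other durations). The two slice-level readouts
are the number of active channels and the multi-unit-activity (MUA)
frequency, the event count divided by the duration.

Three details of the detection rule are deliberate choices rather than
protocol statements:

* **Noise estimator.** The "standard deviation of the noise" is estimated
  robustly as `median(|x|)/0.6745` (the MAD estimator, consistent for
  Gaussian noise). A plain SD would be inflated by the very spikes being
  detected; robust estimation is the standard practice in threshold spike
  detection. On simulated noise with 10-sigma spikes the estimate stays
  within a few percent of the true sigma while the plain SD drifts upward.
* **Polarity and dead time.** Thresholding is applied to `|x|` (both
  polarities) because extracellular spike polarity depends on electrode
  placement. Crossings within 1 ms are merged into a single event (the
  multiphasic waveform would otherwise be double-counted), and the event
  time is the largest absolute deflection of the excursion.
* **Per-channel thresholds.** Noise varies per electrode, so the noise SD
  and threshold are estimated independently per channel; this also makes
  all readouts invariant to rescaling the whole trace.

The MEA generator inserts a biphasic 1 ms waveform - a dominant negative
phase with a 40% positive rebound, the typical extracellular morphology -
at Poisson event times into Gaussian noise, with amplitude expressed in
multiples of the noise SD. The ground-truth event time is the waveform
trough, matching the extremum convention of the detector. At the emulated
regime (50 kHz, 300 s, threshold 5 SD) the expected false-positive count
from Gaussian noise alone is about 8.6 events per channel
(`2 * pnorm(-5) * 1.5e7`); with 8-SD spikes at 1 Hz this bounds attainable
precision near 0.97, and recall is essentially 1. Because a channel's
realized spike count is Poisson (SD about 17 on a mean of 300), per-channel
MUA error is assessed as the mean relative error across channels rather
than a strict per-channel band, which random Poisson fluctuation alone
would violate.

A full 60-channel, 300 s, 50 kHz recording occupies ~7 GB as a double
matrix, so `validateSpikeDetection()` simulates and scores one channel at a
time with derived per-channel seeds.

## Calcium stage: run-length peak calling

Traces are F340/380 ratios sampled every 2 s. The protocol records baseline
for 0-200 s, perfuses capsaicin at 200-220 s and KCl (high K+) at
780-825 s. Each trace is normalized to the mean of its baseline window
(fold change); the per-neuron baseline mean, not a running baseline, is the
reference throughout.

A capsaicin response is the first run of at least 5 consecutive samples
strictly greater than 10% above baseline whose start lies in [200, 780) s;
a KCl response requires at least 5 consecutive samples strictly greater
than 20% above baseline starting strictly after 780 s. The capsaicin search
window is closed at 780 s so depolarization responses are never
mis-attributed to capsaicin. "First peak" is the maximum fold within the
first qualifying excursion, not the global maximum, since the rule ties the
peak to the first qualifying run.

The response magnitude is quantified as the trapezoidal integral of
(fold - 1) over the above-baseline excursion containing the qualifying run,
extended by one flanking sample on each side with the integrand clipped at
zero. The excursion bound makes the area zero for non-responders, and the
flank extension makes the integral exact for transients that touch baseline
on the grid: a piecewise-linear excursion rising 1 to 1.2 and back over
20 s integrates to exactly 0.5 x 20 s x 0.2 = 2.0 fold-seconds. For smooth
kernels the 2 s grid trapezoid agrees with a 100x finer integral of the
generating kernel within 2%.

The generator adds alpha-function transients
(`k(t) = (t/tp) exp(1 - t/tp)`, peak exactly 1 at `tp = 10` s, placed on
the sample grid) on a constant baseline (default 0.8, a typical F340/380
resting ratio) with additive Gaussian noise (default SD 0.01). The
capsaicin responder fraction defaults to 0.7 and the KCl (viability)
fraction to 0.95, the neighborhood reported for healthy DRG preparations.
Noise-free configurations make peak maxima exact, which the tests exploit.

## IntelliCage stage: behavioral features

The visit table is the unit of analysis: one row per corner visit with
nosepoke and lick aggregates. The task schedule is free adaptation (FA,
14 d), nosepoke adaptation with three correct corners (NP3c, 14 d), place
preference learning (PPL, 10 d) and its reversal (PPLrev, 10 d). Corner
assignments are round-robin (about four mice per corner); the PPLrev corner
is the opposite-side corner of the PPL corner, implemented as the diagonal
partner (1-3, 2-4), and the NP3c correct set excludes exactly that future
reversal corner.

Conventions shared by all metrics:

* Time 0 is lights-on; the cycle is 12 h light / 12 h dark. Binned time
  courses use half-open bins `[t, t + 12 h)` aligned to lights-on; a visit
  belongs to the bin containing its start, so binned counts always sum to
  stream totals.
* The inter-visit interval (IVI) is the gap from the end of one visit to
  the start of the next by the same animal (re-entry semantics), not
  start-to-start.
* A *fast re-entry* is a return to the same corner with IVI strictly below
  60 s (an IVI of exactly 60 s does not count). The 60 s bound
  operationalizes "early return" for both the re-entry counts and the
  repetitiveness statistic.
* Nosepokes per visit are total pokes over total visits within the unit;
  units with no visits are missing, never zero.

**Repetitiveness** is the log2 ratio of observed early returns to their
expectation under a shuffle null: the corner-label sequence is permuted
(default 1000 seeded shuffles) while all timestamps stay fixed, preserving
each corner's visit count and the empirical IVI distribution. An analytic
1/4 null would ignore unequal corner preferences; the shuffle null does
not. A pseudo-count of 0.5 enters both numerator and denominator only when
either is zero (flagged), and units with fewer than 10 visits are flagged
undefined. Under a uniform Markov generator (stay probability 0.25) the
statistic is centred at 0; its expectation grows as roughly
`log2(stay / expected-stay)`, about 1.26 at stay 0.6. Because the shuffle
preserves marginal corner counts, slow drifts in corner preference (e.g. a
learning curve) can inflate the statistic slightly; calibration runs
therefore use the pure-Markov generator.

**Feature matrix.** Thirteen per-day parameters (visit rates by phase,
nosepoke, licking and correctness metrics, visit durations, IVIs, door
latency) are averaged per task and over the whole observation, yielding
exactly five task-level values per parameter per animal, matching the
per-task scatter layout of home-cage multivariate analyses. Repetitiveness
is the one exception: it is computed per task directly rather than per day,
because a shuffle statistic on a single day's ~100 visits is dominated by
Monte-Carlo and sampling noise.

The generator draws visit onsets from a piecewise-constant day/night
Poisson process sampled exactly by thinning (default 4 visits/h by day,
10 by night - the nocturnal activity pattern), gamma visit durations (mean
20 s), Markov corner choices, negative-binomial nosepoke counts (real
per-visit counts are over-dispersed; dispersion 4), and Poisson lick counts
that attach only to door-opening visits in door-controlled tasks (licking
in FA is unconstrained). Group defaults are 15 vs 16 animals with nosepoke
means 2 vs 3 and lick rates 8 vs 16 per visit, the direction and size of
the contrasts the emulated study reports. The IVI and lick-duration
distributions are generator conventions, not protocol claims. An optional
logistic learning curve biases non-stay corner choices toward the correct
set over task days (chance floor, ceiling 0.9, midpoint day 4, slope 1 -
a typical week-scale acquisition curve); it is disabled in null
calibrations.

## Statistics layer

Two-group comparisons use the pooled-variance Student's t-test (Welch
behind a flag); Mann-Whitney U is the nonparametric alternative, exact by
enumeration up to a combined n of 12 without ties and a tie-corrected
normal approximation otherwise. Time courses and task profiles use a
two-way mixed ANOVA (between factor crossed with a within factor, subject
error stratum), restricted to balanced complete designs - per-day values
are averaged first, and no imputation is performed. Degrees of freedom are
uncorrected for sphericity, and the output notes this. Posthoc adjustments
are Sidak (`1 - (1 - p)^m`) and Dunnett many-to-one, the latter evaluated
by seeded Monte-Carlo from the equicorrelated multivariate-t distribution
(default 1e5 draws, correlation `n_i/(n_i + n_0)`), which works for any
number of contrasts and degrees of freedom; the Monte-Carlo standard error
is reported and adjusted p-values are floored at the raw p. Feature tables
are normalized by Auto scaling (unit variance) or Range scaling before
multivariate display; constant columns are flagged rather than silently
dropped.

## Lipid screen

The volcano stage takes a samples x species table of area ratios to
class-specific internal standards (AUC/IS). Per species it reports the log2
fold change of group means (test over reference; positive = higher in the
test group) and a two-sided pooled t-test computed on log2-transformed
intensities - the lipidomics convention, since area-ratio noise is
approximately log-normal - plus Benjamini-Hochberg q-values. With the
study-sized design (15/16 samples, CV 0.1) a planted one-log2 shift is
recovered with essentially full sensitivity at q < 0.05 while the empirical
false-discovery proportion stays below the nominal level. A
`rangeNormForPlots()` helper rescales species to [0, 1] for overlay
scatters.

## Determinism and problem sizes

Every generator and every Monte-Carlo procedure takes an explicit integer
seed; repeat runs are bit-identical. Pipelines fan one master seed out to
stage seeds through a fixed integer derivation (`childSeed()`), so stages
are independently reproducible. The validation suite runs the full MEA
regime (60 channels x 300 s x 50 kHz, streamed), 50-seed repetitiveness
calibrations at >= 5000 visits per animal, 1000 null ANOVA replicates, and
20-seed volcano screens; these sizes give Monte-Carlo standard errors
comfortably inside the asserted tolerances.

## What synthetic validation does not show

The generators emulate the statistical structure of each modality, not its
biophysics. Gaussian noise omits line artifacts, electrode drift and
correlated network events that real MEA recordings contain; alpha-kernel
transients omit photobleaching, baseline drift and desensitization;
Markov corner choices with a logistic learning curve cannot reproduce
social dynamics among co-housed animals (the generator draws animals
independently); log-normal lipid noise omits batch effects and
class-correlated quantification error. Passing tests therefore establish
that the implementations compute their definitions correctly and recover
planted effects under the stated noise models - not that the rules are
optimal for any particular preparation. Parameters that a given laboratory
measures differently (thresholds, run lengths, IVI bound, bin anchor) are
exposed as arguments with the protocol values as defaults.
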