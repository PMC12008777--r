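---
title: "tapbeta: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tapbeta: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

tapbeta implements the complete analysis chain of a cued finger-tapping
(sensorimotor synchronization, SMS) EEG experiment: deterministic cue
schedules, accelerometer-based tap detection, behavioural and circular
statistics, movement-locked beta-band (12–30 Hz) time–frequency analysis,
and hierarchical Bayesian factorial inference. This vignette documents the
models, the tunable parameters, the numerical choices, and what the
synthetic-data generator does and does not emulate.

## The experimental design the package models

Eight cue conditions cross three two-level characteristics: frequency
(slow = 1 Hz, fast = 3.2 Hz), modality (auditory, visual) and rhythmicity
(isorhythmic, polyrhythmic with a 2:3 secondary rhythm). The fast
auditory-polyrhythmic condition runs at 3.0 Hz, mirroring a quirk of the
stimulus set this design is modelled on. Every condition starts with a
15-s resting baseline and continues with five tapping sequences of 16
(slow) or 51 (fast) cues, separated by 5-s breaks.

Two deliberate conventions where the design leaves room:

* **Sequence duration is defined by the beat count**, not a nominal "~16
  s": a sequence spans `(cues - 1) * isi` seconds (15 s at 1 Hz, 15.625 s
  at 3.2 Hz), because the cue counts are exact design constants.
* **The secondary rhythm is phase-anchored to the sequence start**, so its
  first beat coincides with the first main beat, and secondary beats are
  emitted only up to the last main beat. The anchoring is not dictated by
  the design; coincident first beats is the simplest reading of a 2:3
  "subdivision" and makes every second main beat coincide with every third
  secondary beat. At 16 main beats this yields 23 secondary beats.

## Tap detection

The accelerometer magnitude (pointwise L2 norm of the three axes) is
band-passed 0.5–70 Hz with a zero-phase second-order Butterworth filter at
the native rate, then converted to 256 Hz. Detection uses a sliding window
one ISI long: the first window is centred on the first cue; the largest
local maximum above a threshold is a tap; after a detection the next
window is `[tap + isi/2, tap + 1.5 isi]`, so the windows track the
performed rhythm rather than the cue train, and the rule itself enforces a
minimum inter-tap gap of half an ISI.

Choices worth knowing:

* The original procedure corrects missed/misidentified taps by visual
  inspection; that cannot be reproduced deterministically, so "no peak"
  is defined by an explicit amplitude threshold, default **5 × the median
  absolute deviation** of the processed trace. Ties between equal-height
  peaks go to the earliest.
* When a window after a detection contains no peak, detection falls back
  to the next cue beyond the failed window — the deterministic analogue of
  re-anchoring on the stimulus.
* Retention: a sequence is kept iff its **raw** tap count (before start-up
  trimming) lies in `[ceil(0.7 C), floor(1.3 C)]` — 12–20 taps for C = 16,
  36–66 for C = 51; a condition is dropped when 4 of its 5 sequences fail;
  the first two taps of each retained sequence are removed before any
  metric.
* Rate conversion is Fourier-domain resampling. It is exact for
  band-limited signals — every call site band-passes below the target
  Nyquist first — and the Nyquist bin is zeroed so downsampling cannot
  alias. (The polyphase resampler in the `signal` package shows ~15 %
  passband ripple with its default filter, which is why it is not used.)

## Behavioural and circular statistics

ITI-D is the mean inter-tap interval divided by the ISI; ITI-CV is the
sample (n − 1) standard deviation of the intervals over their mean, in
percent. Intervals are computed within sequences only — breaks are not
tapping intervals — and pooled across a condition's retained sequences.

Each tap's phase is `360° (tap − preceding cue) / (successive − preceding
cue)`; the denominator is the actual bracketing interval, which equals the
nominal ISI for exact schedules but stays correct for jittered event logs.
The circular median minimizes the summed circular absolute deviation
(ties resolved by the circular mean of the minimizers; candidates are the
data points and pairwise circular midpoints, which provably contain the
minimizer). Quartiles are taken after rotating the median to 180° to avoid
wrap ambiguity. Signed asynchronies map phases ≤ 180° to positive
(late) and phases > 180° to negative (early) milliseconds, rounded to the
nearest ms: 330° at a 1-s ISI is −83 ms.

Hypothesis tests:

* **Rayleigh** (Z = nR², standard series p) when a **Watson goodness-of-fit
  test** does not reject a von Mises distribution at α = 0.05, **Rao's
  spacing test** otherwise; the routing is recorded in the result.
* Watson's U² p-value is a seeded **parametric bootstrap** from the fitted
  von Mises (refitting per replicate), exact up to Monte-Carlo error;
  Rao's p-value is a seeded Monte-Carlo under the uniform null. Shipping
  interpolated critical-value tables would add transcription risk without
  adding accuracy at these sample sizes.
* **Moore's paired test** ranks the magnitudes of the pairwise difference
  vectors and tests their directional alignment (R* = R'/n^{3/2}).
  The primary p-value is a seeded pair-flip randomization — under the
  null each difference vector's direction is exchangeable with its
  reverse — which is exactly calibrated at any n, including the study
  scale n = 17; the large-sample chi-square form is also reported. Pairs
  with zero-length difference vectors are dropped (their direction is
  undefined) with n reduced.
* Bonferroni for the 12 planned comparisons uses the exact division
  α/m = 0.05/12 = 0.0041667 with a strict inequality.

## EEG conditioning

EEG is band-passed 1–35 Hz (zero-phase, 2nd order) and converted to 256
Hz, filtering at the native rate first. Channels are flagged when their
whole-recording mean absolute amplitude is above 50 µV or below 1 µV (the
window of the amplitude statistic is not pinned down by the original
description; whole-recording is the most conservative deterministic
reading) and replaced by Perrin-style spherical-spline interpolation
(stiffness m = 4). Two reference schemes are produced: the average
reference, used to identify artefactual epochs, and the spherical-spline
surface Laplacian (m = 4, ridge λ = 1e-5, Legendre series to order 50,
head radius 0.09 m; V/m²), used for all power analyses because of its
spatial specificity. The Laplacian parameters are standard Perrin-type
defaults and are exposed as arguments. Ocular-artefact ICA is out of
scope: the pipeline accepts recordings cleaned elsewhere (the synthetic
data carry no ocular artefacts), and a pass-through point exists between
band-pass and re-referencing.

The montage is an idealized spherical 10-10 layout of the 30 scalp
channels of a 32-electrode cap without the two mastoids (ring and midline
electrodes at their exact 10-20 angles, intermediate electrodes as
spherical midpoints); it is a synthetic geometry, not a digitized head
shape, and is also shipped as
`inst/extdata/montage_1010_idealized.json`. The default blacklist of edge
electrodes excluded from inference is the outer ring (Fp1, Fpz, Fp2, F7,
F8, T7, T8, P7, P8, O1, Oz, O2).

## Time–frequency analysis of the beta band

Eleven complex Morlet wavelets span 12–32 Hz with 3–5 cycles, both
geometrically spaced and paired index-wise
(`f_i = 12 (32/12)^{i/10}`, `c_i = 3 (5/3)^{i/10}`); kernels are
unit-energy normalized and power is the squared magnitude of the
convolution coefficients. Samples within one kernel half-length (4
Gaussian SDs) of either recording edge are flagged invalid and epochs
touching them are dropped rather than padded.

Baselines are split into 0.5-s epochs after trimming one second at each
end (26 candidates from 15 s). Tap epochs span `[tap − isi, tap + isi]`.
Artefact rejection computes, per channel, three per-epoch statistics over
baseline and condition epochs jointly — mean absolute amplitude, maximum
absolute amplitude, maximum time–frequency power — and rejects an epoch if
any channel exceeds that statistic's across-epoch mean + 2, 10 or 20 SD
respectively. Anchoring each rule on its own statistic's distribution is
the only reading under which all three rules are tail events: thresholding
an epoch's *maximum* against the mean-absolute statistic's spread would
reject essentially every clean Gaussian epoch. With many statistically
independent channels the 2-SD rule still rejects a union of ~2.3 % tails
per channel; on real EEG the strong across-channel correlation keeps the
rejected fraction far lower. The mask is computed on the average-reference
dataset and applied to the Laplacian dataset.

Normalization is `POW(t, f) = 10 log10(tap(t, f) / baseline(f))` with
`baseline(f)` the per-channel mean power across retained baseline epochs.
One numerical point deserves emphasis: the **window averages are dB of the
mean linear ratio**, not the mean of per-sample dB. Single-trial wavelet
power at one time–frequency point is approximately exponentially
distributed, and `E[ln X] = ln E[X] − γ`, so averaging raw per-sample dB
is biased low by ~2.5 dB; dB-of-the-mean makes the baseline's own
normalized average 0 dB and lets planted effects read out at face value.
(The per-epoch dB maps themselves are still available for display.)

Epochs are trimmed to one ISI with 30 % before and 70 % after the tap;
the around-tap window is `[−0.3, 0.2) · isi` and the after-tap window
`[0.2, 0.7) · isi` (half-open, so the boundary sample is counted once).
The band average uses the wavelets with centre frequency ≤ 30 Hz — the
family extends to 32 Hz but the analysed band is 12–30 Hz, so the 32-Hz
wavelet is excluded (including it is a one-line change).

## The hierarchical factorial model

One observation per participant × condition (× electrode × window) cell
enters a Gaussian hierarchical model in the Kruschke ANOVA style:

μ_cell = β0 + Σ_families β_family[level(cell)]

with one effect family per non-empty subset of the factors — frequency F
(2), modality M (2), rhythmicity R (2), electrode E (30) and participant P
(17), i.e. 31 families up to the five-way interaction for power (Model 1)
and 15 families without E for ITI-D and ITI-CV (Model 2), each model
fitted separately per window or metric. Each family's deflections are
exchangeable N(0, σ_f²); every σ_f and the noise scale have half-Gaussian
priors, and β0 a broad Gaussian — widths default to 5 (scales) and 10
(β0) times the observations' SD, a vague, data-scaled choice (the precise
hyperprior widths were an open design point; they are arguments of
`fit_model()`). Missing cells (excluded participant-conditions) are simply
absent rows; the hierarchical prior imputes them implicitly.

Estimation is a blocked Gibbs sampler written in C++ (Rcpp):

* Within a family the indicator columns are orthogonal, so the
  conditional update is a vector of independent normal draws.
* Scales are slice-sampled on the log scale; each family also gets an
  interweaved non-centered update (with η = β/σ_f fixed, the scale enters
  the likelihood linearly and its conditional is Gaussian), which breaks
  the funnel between a family's scale and its deflections.
* An exact Gaussian "recentring" move shifts mass along the
  likelihood-invariant direction shared by β0 and each family's common
  mean, removing the random-walk behaviour of the raw parameterization.
* The saturated family (at most one observation per level — the five-way
  interaction in the full design) identifies only σ² + σ_f². A partially
  collapsed move integrates its coefficients out, updates the pair
  jointly as (total variance v, split ρ) — v by slice, ρ by an exact grid
  draw from its prior-induced conditional — and redraws the coefficients
  from their exact conditional. Without this move two chains can sit at
  different splits for thousands of iterations, and the split is not
  inert: it controls how strongly cell posteriors are shrunk.

Sum-to-zero identifiability follows the Kruschke convention: the raw
draws are not constrained, but all reported quantities are either
invariant to recentring (predicted cell values, hence all contrasts) or
explicitly recentred (`effect_draws()` reconstructs classical ANOVA
deflections of any participant-free family from the participant-averaged
cell-mean draws). The fit object stores β0, the noise scale, all family
scales and the condition × electrode cell means averaged over
participants; full coefficient draws are kept only when the design is
small (< 2000 coefficients), since the saturated Model 1 would otherwise
store ~15,000 parameters per draw.

Convergence is assessed on the reported quantities (β0 and the cell
means) by split R-hat and a Geyer-type bulk ESS; the strict contract
(R-hat < 1.05, ESS > 1000) is recorded in `diagnostics$converged`, and a
warning is raised when R-hat exceeds 1.1. The noise scale's own R-hat is
reported separately because σ is only jointly identified with the
saturated family's scale.

Posterior summaries use the mean and the 99 % highest-density interval
(shortest sorted window containing the mass). A power contrast is
significant iff its 99 %-HDI excludes 0 dB **and** the absolute posterior
mean exceeds the 0.4-dB floor **and** the electrode is not blacklisted; a
behavioural contrast needs only the HDI rule. `comparisons_of_interest()`
returns the 12 planned pairs — four per cue characteristic, each pair
differing in exactly one characteristic.

## The synthetic-data generator

The generator is first-class, tested code; it defines the conditions
under which the package's claims are verified.

* **Taps**: each cue spawns a tap with probability 1 − miss_prob at the
  cue time plus a von Mises phase offset scaled by the ISI (the
  distribution of real asynchronies is unspecified; von Mises is the
  canonical unimodal circular choice). A target ITI-CV can be given
  instead of a concentration and is converted via the circular-SD
  relation (independent per-tap jitter makes interval variance twice the
  tap variance). A refractory rule drops taps closer than 0.1 ISI.
* **Accelerometer**: 60-ms biphasic transients (peak centred on the tap
  time) with axis weights (1, 0.6, 0.3), plus white noise at a
  configurable transient-to-noise ratio (default 10; detection accuracy
  is asserted down to 5).
* **EEG**: per channel, a 1/f background (default exponent 1) plus a
  12–30 Hz band-limited noise component (default SD 5 µV) whose amplitude
  envelope equals baseline except in the tap-locked windows, where the
  planted dB values apply. Two calibration choices make "planted dB"
  exactly the measurable quantity: (i) the component is band-limited
  noise rather than a single sinusoid, because a narrowband carrier
  modulates only the wavelets near it and the band-averaged dB would
  dilute ~3-fold (a sinusoidal carrier remains available as an option);
  (ii) the envelope gain compensates for the unmodulated background's
  share of band power, `g² = (10^{d/10}(r+1) − 1)/r` with r the
  band-power ratio of component to background (default 10), so the
  planted d is the change in *total* band power. Topographic spread is a
  Gaussian weight in spherical angle around a focus electrode (default
  C3, mirroring the contralateral motor focus of right-handed tapping);
  an optional spike injector exists solely to exercise the rejection
  rules.

What the generator does **not** emulate: ocular and muscle artefacts,
volume conduction and realistic cross-channel covariance (channels are
independent), 1/f nonstationarity, modality- or rhythmicity-specific
behavioural signatures unless planted. Passing the closed-loop tests
therefore demonstrates that the measurement chain is unbiased and the
inference calibrated under the stated statistical structure — not that
real recordings satisfy that structure.

A practical measurement note: the baseline spectrum is estimated from a
15-s rest, which carries ~0.3 dB of sampling noise per channel per
recording at these bandwidths. Closed-loop checks therefore average the
recovered values over replicate recordings (six in the test suite) and
over identically planted electrodes — exactly as the study design averages
over participants.

## Problem sizes and scope choices

The test suite exercises the full 2 × 2 × 2 × 30 × 17 power design (4080
cells) in single fits and 50 seeded replicates at reduced draw counts
(2 chains × 200 warm-up + 500 draws) for coverage and null calibration;
circular calibration uses 2000 null replicates at n = 17; closed-loop
beta recovery uses five-sequence recordings (70–255 retained epochs) with
six replicates per case; the end-to-end pipeline test runs three
participants × two conditions with a six-electrode model. These sizes are
the package's verification conditions; larger runs only tighten the same
estimates.

Two interface decisions: recordings are serialized as a documented
plain-text bundle (JSON header + TSV data + TSV events) rather than EDF —
no EDF reader/writer exists among the package's dependencies, and the
bundle keeps every artefact human-readable; and the pipeline is exposed as
R functions (`run_pipeline()`, `make_report()`) rather than a shell
command, the natural interface for an R analysis package.

## Known limitations

* The Gibbs sampler assumes a Gaussian likelihood with a single noise
  scale; heavy-tailed observation models would need a different sampler.
* Electrode-adjacency-informed priors are deliberately not implemented;
  electrodes are exchangeable in the prior.
* The surface Laplacian attenuates spatially broad signals by design;
  closed-loop dB calibration at a focal electrode under focal planting is
  conservative (neighbouring channels carry attenuated envelopes).
* Phase statistics assume taps bracketed by cues; taps outside the cue
  train are dropped and counted, not extrapolated.
* The cross-correlogram is illustrative (as in the original analysis);
  phase statistics are the primary synchronization measure.
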