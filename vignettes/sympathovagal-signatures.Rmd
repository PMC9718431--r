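---
title: "Detecting autonomic dysreflexia from sympathovagal signatures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting autonomic dysreflexia from sympathovagal signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Autonomic dysreflexia (AD) in spinal cord injury above T6 is a reflex
cascade: a noxious trigger below the lesion drives uninhibited sympathetic
discharge, systolic blood pressure rises rapidly (>= 15 mmHg, with mean
arterial pressure up >= 10 mmHg), and the baroreflex answers with a
compensatory vagal surge and bradycardia. Cuff-based monitoring samples far
too slowly to catch onset; this package analyzes continuous ECG and skin
sympathetic nerve activity (skNA) instead, and asks whether the
sympathetic-then-vagal signature suffices to detect AD and to distinguish it
from other sympathetic stressors (acoustic startle above the lesion, tail
pinch below it).

Because no public recordings of this preparation exist, the package carries
a first-class synthetic-data generator; all quantitative statements below
are properties of that generator as computed by the test suite and
`scripts/acceptance.R`, not claims about animal data.

## The synthetic cohort

`sim_config()` fixes the study conditions: 13 animals tested on post-injury
days 7, 9, 11 and 14; per day, three 1-minute colorectal distensions (CRD)
with 10-minute recoveries plus one startle and one tail-pinch trial in
seeded random order after a 120-s baseline. Channels follow the recording
array: ECG and skNA at 10 kHz, tail-cuff blood pressure every 30 s (systolic,
diastolic and mean pressure columns), skin temperature at 2 Hz (simulated as
slow noise around 34 °C and never used in features).

Ground truth is generated at the event level and rendered to waveforms on
demand:

- **Beats.** NN intervals follow `60000/HR + e(t)`, with animal-level heart
  rate ~ N(400, 20) bpm and AR(1) beat-to-beat noise (innovation SD 3 ms,
  coefficient 0.5), giving a baseline RMSSD near 3.5 ms and pnn5 near 15% —
  plausible restrained-rat values. During the AD vagal phase (onset lag 30 s)
  the NN mean lengthens by 15% (bradycardia) and the variability multiplier
  ramps 1 → 3 toward the end of the episode, then decays back over the first
  60 s of recovery, so heart rate and HRV return to pre-AD levels after the
  stimulus. Startle raises heart rate 10% with doubled variability; tail
  pinch halves variability (vagal inhibition) at unchanged rate.
- **Bursts.** Sympathetic bursts are a piecewise-constant Poisson process:
  2/min at baseline; during CRD 20/min for the first half-minute then a
  quarter of that (the discharge concentrates within seconds of the
  trigger); 15/min during startle; baseline rate but doubled amplitude
  during tail pinch (tonic iskNA rises without extra burst counts). Packets
  last 0.1–1 s, are kept >= 150 ms apart so they remain resolvable events,
  and render as Hann-enveloped 500–1000 Hz noise riding on broadband noise
  (SD 1 µV).
- **Blood pressure.** Each stimulus adds a linear ramp peaking at its end
  and decaying with a 90-s time constant; peak SBP deltas default to +20
  (AD), +7 (startle) and +5 (tail pinch) mmHg with proportional diastolic
  changes, plus 1.5 mmHg cuff noise. With probability 0.7 a distension is a
  "success" (ΔSBP >= 15.5); failures keep the full sympathetic surge but an
  attenuated BP ramp (ΔSBP 4–12 mmHg) and a 0.3-scaled vagal response, giving
  the labeling stage realistic negatives.
- **ECG rendering** places a stylized PQRST template (R apex exactly on the
  beat sample) over baseline wander and white noise (SD 0.05 mV).

Two fidelity levels keep the analysis tractable: waveform-level operations
(filtering, R-peak and burst detection) are validated on short rendered
recordings, while cohort-scale feature extraction consumes truth-derived
beat and iskNA series directly (`truth_beat_series()`,
`truth_skna_series()`). The iskNA envelope is reconstructed analytically —
rectified-noise floor `σ·sqrt(in-band share)·sqrt(2/π)` plus each burst's
Hann contribution — which the folded-normal tests tie back to the waveform
path. Cohort problem sizes (52 recordings, ~3,400 s each, subsampled to
2,200 windows) were chosen to mirror the data-point count the classifier
protocol expects while keeping full runs in tens of seconds.

What the generator does **not** emulate: movement artifacts, electrode
noise bursts, spontaneous arousal episodes or drifting baseline physiology.
Its non-stimulus windows are therefore cleaner than real ones — see
"Limitations".

## Signal conditioning

- **Zero-phase filtering.** ECG is band-passed 0.5–100 Hz, skNA 500–1000 Hz
  (the neuECG convention separating stellate-ganglion spike energy from
  cardiac content). Rather than forward–backward IIR passes, the package
  applies the Butterworth squared-magnitude response on the FFT grid of the
  mirror-padded signal: identical passband shape, exactly zero phase, and
  exactly symmetric under time reversal, so burst and beat timestamps are
  unbiased — which matters when feature windows are only 15 s. Padding is
  symmetric and grown to a 2-3-5-smooth FFT length.
- **R peaks** (`detect_r_peaks()`): squared-derivative energy, 30-ms
  integration window, adaptive threshold, 100-ms refractory period — the
  classic QRS-energy recipe re-parameterized for 400-bpm rat hearts — with
  the R time refined to the local ECG maximum. On default-noise synthetic
  ECG it recovers >= 99% of truth beats within ±5 ms.
- **NN cleaning** (`clean_nn()`): RR intervals deviating > 20% from an
  11-beat running median are rejected; successive-difference statistics
  never span a rejected interval. The 20%/11-beat rule is the standard
  ectopic filter; both values are arguments.
- **iskNA and bursts**: the 100-ms moving average of rectified skNA;
  baseline location/scale are median and MAD (×1.4826) over stimulus-free
  time, robust to the bursts themselves. A burst is a maximal excursion
  above mean + 3·MAD, with excursions < 100 ms apart merged and merged
  excursions < 50 ms discarded. The threshold multiplier, merge gap and
  minimum duration are exposed; a zero-MAD baseline falls back to an
  absolute floor with a warning.

## Features, scaling, selection

The five features are computed on non-overlapping half-open windows
`[t, t+15)` aligned to recording start (stride is an argument; no overlap by
default). A window's HRV features use NN intervals whose terminating beat
lies in the window; windows with fewer than 3 NN intervals are flagged and
excluded. pnn5 is interpreted as the percentage of successive NN
*differences* exceeding 5 ms, the rat-scale analogue of pNN50 and, like
RMSSD, a vagal index.

Min-max scaling is fitted per (animal, trial day) — normalization "from the
same day" needs no cross-day calibration, but it uses each day's full data
and therefore leaks scaling statistics across any later split. The package
reproduces that protocol by default and offers `scaling = "train-only"`,
with `audit_scaling()` quantifying how often held-out values fall outside
the fitted [0, 1].

Window labels: a window takes a stimulus class when >= 50% of it overlaps
the stimulus epoch; distension windows are labeled `ad` only when the trial
passes the BP criteria below; failed distensions and all other time are
`none`. `select_features()` ranks any candidate bank (an extended
HRV/burst-morphology bank ships for this purpose) by the chi-squared
statistic of quartile-bin × class tables.

## AD labeling

`label_trial()` operationalizes the clinical criteria with choices the
criteria themselves leave open: baseline is the mean of BP samples in the
120 s before onset; "rapid" rise means the peak occurs within the stimulus
minute plus 120 s; bradycardia is a vagal-phase mean heart rate below the
baseline mean minus two standard errors; sympathetic precedence requires a
detected burst between onset and the SBP peak. The SBP and MAP thresholds
are inclusive and conjunctive by default; `map_mode = "audit"` reports the
MAP delta without requiring it, since it is ambiguous whether the MAP
criterion was universally enforced or verified post hoc. The full breakdown
is always returned so threshold sensitivity can be audited. On the default
cohort the labels agree with generator truth in > 95% of trials,
disagreements sitting near the thresholds.

## Classifier protocol

"Five-layer" is read as input + three hidden + output; the hidden sizes
default to 32-16-8 (any sizes can be passed — no reproducible rule exists
for auto-sized hidden layers). Training is full-batch Adam (learning rate
0.01, L2 1e-4, up to 300 epochs) with He initialization, seeded end to end.
The data are split 70/15/15 by largest-remainder stratification (global
sizes exactly `round(n·frac)`, per-class counts within one window of exact);
the validation set drives early stopping (patience 30); the test set is
reported; 10-fold stratified cross-validation gauges stability. This
CV-on-all/early-stop-on-val/report-on-test protocol is this package's
resolution of how the three sets and the 10 folds interact, which the
original description leaves open. Binary decisions threshold the sigmoid
output at 0.5; multiclass takes the argmax. AUC is computed by `pROC` and
cross-checked in tests against a brute-force pairwise oracle.

## Statistical battery

Welch t-tests (the unequal-variance default is this package's choice)
compare each feature between AD and non-AD windows at α = 0.01; one-way
ANOVA compares the three stimuli, with per-stimulus vs-baseline t-tests and
directions reported alongside (tail pinch *lowers* pnn5 while AD and startle
raise it). Outliers are removed in a single pass — per feature, per group —
at |z| > 3 with the group's own mean and SD; with five values and one
extreme the z-score cannot exceed 3, so small-group outliers survive by
construction. No multiple-testing correction is applied; reports carry the
test count so one can be applied externally.

## Numerical choices and degenerate inputs

Seeds derive from one global seed through a deterministic mixer, so a fixed
configuration reproduces every artifact byte for byte (`run_pipeline()`
manifests are MD5-checksummed). Degenerate cases are explicit: constant
features scale to 0 with a warning; empty burst or beat sets propagate as
flagged windows rather than errors; single-class test sets leave
sensitivity/specificity `NA` with a warning; an all-rejected RR sequence is
an error advising a signal-quality check.

## Limitations

- The generator's non-stimulus windows are clean. Consequently the
  multiclass confusion concentrates at the AD/none boundary (failed
  distensions carry a full sympathetic surge yet are labeled `none`; the
  vagal tail decays into recovery windows), and the `ad` and `none` classes
  end up essentially tied as the most-misclassified class — on real data,
  where baseline physiology wanders, the non-stimulus class would be
  expected to absorb clearly the most confusion. Passing classifier tests
  show the pipeline recovers the signature it was built to detect at the
  generator's effect sizes; they do not certify performance on real
  recordings.
- BP is sampled every 30 s, as with a tail cuff; short SBP spikes between
  samples are invisible to the labeling stage, exactly as in the
  corresponding experiment.
- No frequency-domain HRV features, no temperature features, no
  arrhythmia handling beyond the NN-interval filter, and no mixed-effects
  modeling of the repeated-measures structure (each window is treated as
  independent in the battery).
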