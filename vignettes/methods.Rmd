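---
title: "Room-level beacon localization and frailty assessment: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Room-level beacon localization and frailty assessment: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frailhome)
```

## The monitoring problem

Frailty in older adults correlates with how people move around their own
home: how often they change rooms and how long they dwell in each. The
pipeline in this package estimates a subject's room from BLE beacon RSSI,
logs room transitions, and classifies frailty status from dwell-time
statistics. This vignette records the models, the tunable parameters and
every place where the design was genuinely open, together with the choice
made and why.

## Fingerprinting and the training walk

A room's fingerprint is the per-beacon mean RSSI over a 30-s walk through
the room: samples fall into one-second half-open bins $[t, t+1)$, each bin
contributes its within-bin mean, and the fingerprint entry is the mean of
the bin means. Binning first makes the entry robust to bursts (a beacon
advertising faster than its peers does not dominate its own average).

Real scans drop packets, so empty bins are skipped rather than treated as
zeros. Two guard rails reject a walk outright: a beacon never heard at all
(the fingerprint would be undefined), and a beacon heard in fewer than half
of the bins (the mean would rest on too little data). Both errors name the
offending beacon, since the fix — move the beacon or redo the walk — is
physical.

The step detector validates that the trainer kept moving: a step fires when
$|a - g|$ crosses a threshold upward ($g = 9.81\ \mathrm{m/s^2}$), with a
refractory period against double counting, and the walk passes only if each
of the six 5-s windows contains a step. Threshold 1.5 m/s² and refractory
0.3 s are conventional pedometer-scale values; only the *existence* of a
threshold detector is prescribed by the method, so both are arguments.

## Online localization

Three mechanisms turn a raw RSSI stream into a stable room estimate.

**Per-beacon 2σ filtering.** Each beacon keeps a sliding window of its last
$W = 10$ raw values. With window mean $m$ and *population* standard
deviation $s$, values with $|x - m| > 2s$ (strictly) are discarded and the
survivors' mean is the beacon's filtered value. Two conventions had to be
fixed: the divisor of $s$ (we use $n$; the outcome of the 2σ rule depends
on it) and the strictness of the comparison. A consequence worth knowing:
for a window of $n = 5$ with a single dominant outlier, the outlier's
deviation approaches $0.8\,D = 2s$ from below and is therefore *never*
discarded — the 2σ rule needs either a longer window or repeated evidence.
With $W = 10$ a single outlier is comfortably rejected. $W$ is short enough
to track movement at typical ~1 Hz advertising and is configurable. Beacons
with an empty window are imputed at −100 dBm, below the practical BLE
reception floor, so silence reads as maximal distance. If every value is
discarded (impossible under the 2σ rule, but guarded) or $s = 0$, the plain
mean is returned.

**Nearest fingerprint.** The instantaneous room minimises the Euclidean
distance between the filtered vector and the stored fingerprints. The
argmax/argmin tie-breaks (here and in the vote) use database insertion
order, making the whole pipeline deterministic. The smoothing vote ranges
over *rooms* — in a house where the beacon count differs from the room
count only the per-room appearance frequencies are meaningful.

**Majority vote and the outside rule.** A second buffer holds the last
$L = 800$ instantaneous estimates (one per arriving measurement, so its
wall-clock span depends on the aggregate scan rate — at 5 beacons × 4 Hz,
800 instants ≈ 40 s). The reported room changes only when some room's count
strictly exceeds $0.8 L$; below that the previous room is retained, and
before the buffer first fills the state is `Unknown`. "Strictly" is a
literal reading of *above* 80 %: at $L = 800$, 640 votes do not switch, 641
do. The outside rule is collective: when no roster beacon has broadcast for
strictly more than 4 s, an `Outside` transition is emitted, timestamped at
silence start + 4 s (the earliest moment the rule could have fired).
Re-entry clears all windows and the vote buffer — stale pre-exit estimates
should not vote on the post-entry room. Tests and the desk-scale examples
use scaled-down $L$ (30–40); the decision rule is identical at any $L$.

## The simulator

The propagation model is standard log-distance path loss:
$P_0 - 10 n \log_{10} d$, with $P_0$ the received power at 1 m, plus three
effects the field evaluation identified: per-wall attenuation along the
sight line (default 3 dB/wall; the default floorplan deliberately has no
wall on the open-plan kitchen/living boundary), a human-body attenuation
ramping as $(1 - \cos\theta)/2$ from 0 (beacon ahead) to 6 dB (beacon
directly behind) — a smooth interpolation consistent with the 1–6 dB
non-line-of-sight attenuation range measured for BLE — and zero-mean
Gaussian shadowing (default σ = 2 dB). An optional per-session interference
offset drawn from 1–5 dB models WiFi coexistence and is off by default.
Defaults $n = 2.2$ and 3 dB/wall are mid-range single-floor residential
values. The model is deliberately not a ray tracer: no multipath fading, no
3-D geometry, no device calibration — so passing tests demonstrate the
*algorithmic* pipeline, not radio realism.

Distances are clamped at 0.1 m to keep the law finite on top of a beacon.
Rooms are closed on lower/left edges, open on upper/right, so every point
maps to exactly one room. Every generator is a pure function of
(parameters, seed) and restores the caller's RNG state.

The behaviour model is semi-Markov: the next room comes from a
zero-diagonal transition matrix (uniform by default), the dwell from a
three-part mixture — fast (uniform on 2–15 s), slow (600 s + a lognormal
with mean ≈ 250 s), and a lognormal body with class-specific mean. The
default class profiles (non-frail 70 s body dwell, 25 % fast / 1 % slow;
pre-frail 110 s, 15 % / 5 %; frail 300 s, 3 % / 22 %) were calibrated once
against the published cohort-level segment moments — about 21 ± 17
transitions per segment of about 2040 ± 290 s, pooled over classes — and
the pooled simulated moments (≈ 17 transitions, ≈ 2010 s) sit inside those
bands. What the simulator does *not* emulate: circadian structure, room
semantics (kitchen at mealtimes), inter-subject variability beyond the
class profiles, and the fuzziness of real transition logs produced by an
imperfect localizer. Classification accuracy on this synthetic cohort
therefore shows that the feature/classifier machinery recovers
class-separated dwell statistics, not that those accuracies transfer to
field data.

## Segmentation and features

The dwell-interval signal is the successive difference of a subject's
transition timestamps; `Outside` episodes split it into independent
sub-signals (outside dwell is not indoor behaviour and must not leak into
dwell statistics). Segmentation is a greedy running sum: a segment closes
when the sum reaches 1800 s, *including* the closing interval in full, so
segment durations overshoot by part of one dwell; a trailing remainder
below 1800 s is discarded from the feature set but preserved in an
attribute, keeping segmentation reconstruction-lossless (a tested
invariant, together with last-interval minimality).

The nine features use: sample standard deviation ($n-1$; defined as 0 for a
single interval), fast = dwell ≤ 15 s (inclusive), slow = dwell > 600 s
(exclusive), and normalised counts divided by (number of rooms × number of
transitions) where the room count is a *house* property (the registered
rooms), not the rooms visited in one segment.

## Classification and evaluation

The five classifiers are the established implementations — `e1071` naive
Bayes, `class` 10-NN, `nnet` (one hidden layer of 16 units, decay 0.01),
`rpart` with information-gain splits and cost-complexity pruning as the
C4.5-style tree, and `randomForest` with 100 trees; hyperparameters beyond
$k = 10$ neighbours were open and these are ordinary defaults, all seeded.
kNN and the network standardise features with training-fold statistics
(zero-variance guards to 1).

Cross-validation is stratified 10-fold with a seeded shuffle; out-of-fold
predictions are pooled into a single confusion matrix from which all
metrics derive. Pooling (rather than averaging per-fold metrics) was chosen
because it is the convention under which published per-class confusion
row sums equal the class counts. Sensitivity is diagonal/row-sum, PPV
diagonal/column-sum, macro averages unweighted; the misclassification
breakdown expresses each off-diagonal cell as a share of its true class's
errors and of all errors. Metrics are labelled by their mathematical
definition throughout: on the reference random-forest matrices shipped with
the package, the recomputed macro sensitivity and macro PPV match the
published values with the two column headers interchanged, so trusting the
definitions rather than the headers is the reproducible choice. One further
bookkeeping note: the reference 3-class matrix totals 528 samples while the
stated cohort has 530; the package reports matrix-derived metrics
(accuracy 440/528 = 83.33 %) and leaves the two-sample discrepancy as a
property of the source tables.

## Problem sizes

The test suite and acceptance script run everything at desk scale, chosen
to exercise each property with comfortable margins: 30-s training walks at
4 Hz per beacon; tracking sessions of 1–3 minutes with vote windows of
30–40 instants; the full 48-point × 4-heading grid survey (192 stationary
trials of 20 s each); behaviour cohorts of a few simulated days giving
~200 segments per class for parameter-recovery runs and ~400 pooled
segments for moment checks; 10 000 dwell draws for marginal-moment
verification. The noise-free recovery property (grid accuracy exactly 1.0
and exact room-sequence recovery up to the smoothing latency) is evaluated
with shadowing, interference *and* the body ramp at zero: the body term is
deterministic but heading-dependent, and near a room boundary a 6 dB
rear-facing drop can legitimately move a point's nearest fingerprint — that
is a property of the radio geometry, not an algorithmic defect, so it is
excluded from the *exactness* test and retained in the moderate-noise bound
(σ ≤ 4 dB, accuracy ≥ 0.90).

## Known limitations

Rectangular rooms and 2-D geometry only; no multipath or device-specific
calibration; behaviour profiles are stationary in time; the localizer's
`Unknown` warm-up state means very short streams produce no transitions;
and classifier accuracies quoted on synthetic cohorts measure the pipeline,
not clinical performance.
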