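---
title: "Recognising equine training activities from leg accelerometers: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognising equine training activities from leg accelerometers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(equigait)
```

This vignette explains the models implemented in **equigait**, the
assumptions behind the synthetic-data generator, the tunable parameters and
their defaults, and the numerical decisions a user or reviewer may want to
audit. Nothing here reports a number that the test suite or
`scripts/acceptance.R` does not itself compute.

## The problem

A horse in dressage or jumping training performs a sequence of activities:
the basic gaits (4-beat walk, 2-beat diagonal trot, 3-beat canter with a
left or right lead), pace variants of each gait (collected, working,
extended), gait variations (passage, piaffe, flying change), lateral
movements (shoulder-in, haunches-in, leg yield, half pass, pirouette),
jumps, and halts. Two tri-axial accelerometers on the front tendon boots
(x toward the ground, y forward, z into the leg; 50 Hz) record enough
structure to recognise these activities and to estimate velocity and stride
mechanics. The package implements that full pipeline: windowing and
features, a hybrid convolutional classifier arranged as a multi-phase
hierarchy, an autocorrelation stride-duration estimator, a per-gait velocity
regressor, and quadratic-discriminant pace regions.

Raw recordings from such studies are usually restricted, so the package
generates its own labeled data. Everything the models "prove" is therefore
relative to the generator's assumptions, which this vignette makes explicit.

## The synthetic signal model

Each activity window is a sum of three deterministic components plus
Gaussian noise on every channel:

* **Impacts (x-axis).** Each leg contributes a train of Gaussian-windowed
  pulses at its footfall phase of the stride cycle: walk = lateral sequence
  at quarter-cycle spacing; trot = diagonal pairs half a cycle apart with a
  suspension gap; canter = three beats with the lead-side foreleg landing
  last and carrying the largest impact (ratio 1.30). A sensor sees its own
  leg at weight 1 and the other legs attenuated (other foreleg 0.12,
  ipsilateral hind 0.20, diagonal hind 0.15), so the x-channel repeats
  exactly once per stride and its autocorrelation peaks at the stride
  duration. The footfall pattern is anchored on the movement's side, which
  makes swapping the left and right sensors map a left-sided window exactly
  onto its right-sided counterpart (the mirror property is by construction,
  and is tested).
* **Forward oscillation (y-axis).** A stride-frequency sinusoid (plus a 0.4
  second harmonic) whose amplitude grows linearly with velocity. This
  carries the periodicity robustly even after sub-sampling to 10 Hz, and it
  gives piaffe its signature: piaffe advances at almost no forward speed
  (0.15-0.30 m/s) while passage moves on (1.4-1.7 m/s), so the piaffe
  y-variance is a small fraction of passage's at an equal impact cadence.
* **Lateral structure (z-axis).** Sided movements put a constant offset plus
  a small oscillation on the side sensor: 0.3 m/s^2 for the hand of an
  ordinary pace, 0.8 for the canter lead, 1.5 / 2.5 / 3.5 for shoulder-in /
  haunches-in / half pass and leg yield, and 5.0 (with 70% on the outside
  sensor) for pirouettes. Lateral movements additionally scale the side
  legs' impacts by 1.3 (`lateral_ratio`, configurable): large enough to
  learn, small enough that the phase-3 blocks are not trivially separable.

Jumps superimpose one high-magnitude transient (4.5 g, sigma 0.10 s) on a
canter base; flying changes splice the opposite-lead pattern onto the first
part of the window with a switch point drawn in the middle fifth; halt is
pure noise around gravity.

Velocities are drawn uniformly within mean +/- 1 SD of the published
locomotion-parameter table per (horse type, gait, pace); the impact peak
amplitude is calibrated to 9.81 x v / 1.6 m/s^2, i.e. about 1 g at a typical
walk speed and monotone in velocity. Within a table row the stride duration
is deterministically coupled to the drawn velocity
(dT = mean_dT - sd_dT x (v - mean_v)/sd_v), so faster draws take shorter
strides and a draw at the row mean reproduces the row's stride duration
exactly. The impact pulse width is max(0.04 x dT, 20 ms) so pulses are still
resolvable after 50 -> 10 Hz sub-sampling. The default channel noise is
sd = 0.3 m/s^2 (no noise floor is published; configurable).

**What the generator does not emulate:** real hoof-impact waveforms (no
published waveforms exist to fit, only a qualitative passage/piaffe
contrast), soft-tissue resonances, surface and shoeing effects, sensor
drift, rider-to-rider variation, transitions inside a window, and
mislabeled or out-of-view intervals. Perfect synthetic accuracies therefore
demonstrate that the pipeline recovers the structure it assumes — not that
the same accuracy would be reached on new field data.

## Windowing and features

Fixed-size (optionally overlapping) windows are cut inside annotation
spans; a window must lie entirely within one annotation, so boundary
windows are dropped rather than label-noised. The handcrafted features per
channel are mean, variance, peak-to-peak amplitude, and the mean interval
between crossings of the channel mean ("horizontal axis" is read as the
signal mean; a window with no crossings reports the window duration).
Sub-sampling 50 -> r Hz keeps every (50/r)-th sample starting at the first,
and requires r to divide 50.

## The hybrid CNN

Raw windows (channels x samples, scaled to g units) pass through conv(32
filters, kernel 5, ReLU) -> zero-padding back to the input length ->
conv(64, kernel 5, ReLU) -> per-segment pooling (4 temporal segments; both
the max and the mean of each feature map per segment) -> flatten -> fusion
with the handcrafted features (z-scored on the training split) -> dense(64,
ReLU) -> softmax. Dropout 0.55 is applied to the pooled convolutional
features during training. The mean-pool channel exists because a short
impact transient's sampled maximum varies with its phase relative to the
sampling grid, while its area (the mean) does not; amplitude read-out is
what the velocity model needs. Layer counts and widths are package
defaults, not published values, and are configurable per node.

Training: adaptive-moment optimizer (lr 1e-3, batch 32), up to 100 epochs
with early stopping (patience 8) on an internal 15% validation split, plus
a convergence stop when the validation loss falls below `min_loss`
(default 1e-3). Weight initialization, the stratified 66/34 train/test
split, batch shuffling and dropout masks are all driven by R's RNG, so a
given (data, seed) pair reproduces bit-identical weights and accuracies.
Backpropagation through every layer was verified against central finite
differences during development. Prediction returns the argmax of the
softmax posterior with ties broken toward the lowest class index. Models
serialize to a directory of plain-text files (17 significant digits), which
round-trips predictions bit-exactly.

The velocity regressor is the same network with a linear output trained for
mean squared error on eight channels — the six accelerations plus the
autocorrelation function of each leg's x-axis signal (length-matched to the
window) — and height at withers as the only fused feature, one model per
gait. Two regression-specific defaults differ from the classifier, both
deliberate: no dropout (multiplicative noise on the pooled amplitude
features directly limits the precision of a continuous readout, and the
small early-stopped network does not need it), and a longer budget (150
epochs, patience 15) because a small validation MSE is noisier than a
validation cross-entropy.

## The classification hierarchy

Phase 1 (2 s windows) routes halt/walk/trot/canter. Phase 2 holds per-gait
side classifiers (4 s / 1 s / 2 s for walk / trot / canter). Phase 3
refines: walk into pirouette vs other (2.4 s), then lateral movements vs
paces (1.2 s), then the individual laterals (0.64 s); trot into paces vs
variations vs laterals (0.8 s), passage vs piaffe (0.5 s), the laterals
(2 s sliding by 0.5 s) and leg yield vs half pass (0.8 s); canter into
flying change vs pirouette vs the rest (2 s) and its refinement (0.64 s).
The jumping model is one 6-class node at 2 s / 10 Hz. Differing window
sizes across nodes are handled by re-segmenting the raw stream per node,
never by resizing windows. A span's decision at each node is the majority
vote over its windows (ties to the node's first class), and the cascade
descends into the voted child; spans voted into a pace superclass are
flagged for phase 4.

Side context: shoulder-in and haunches-in are ridden on the hand the horse
is already on, so those spans inherit the side estimate of the most recent
preceding trot-pace span — across intervening spans, which extends the
stated immediate-succession rule; "unknown" when no trot pace precedes.
Fine labels coarsen to five modes of specialization (4 superclasses
including halt; superclasses with side; 7 pace/movement groups; 11 movement
families; all 25 labels), and the mode tables are total and nested — every
finer mode refines the coarser one (tested). The proportion-weighted
overall accuracy renormalizes the published class proportions over the
classes actually evaluated; whether halt should instead be excluded is not
specified, and renormalization was chosen.

## Stride mechanics and pace regions

The autocorrelation uses the biased normalized estimator (divisor n at all
lags, via `stats::acf`), which tapers large lags and stabilizes peak
picking on short windows; it is checked against a direct O(n^2) oracle at
1e-9. The stride duration is the highest local maximum between 0.2 s and
2.5 s — the published stride-duration range padded by about 25% — and a
window with no local maximum there raises a typed "aperiodic" error (halt,
for instance). Estimates are exact to one sample period on generated
windows covering at least two strides; for walk, whose strides reach about
1.5 s, use windows of 3-4 s. Stride length is L = v x dT and step frequency
f = 1/dT.

The pace classifier is quadratic discriminant analysis on the two features
(height at withers, velocity), implemented directly (class means, class
covariances, uniform priors); a singular class covariance is ridge-
regularized with a warning. Posteriors agree with brute-force Gaussian
densities to 1e-9 and with an independent QDA implementation in tests;
exact ties resolve to the earlier pace in (collected, working, extended).
Trot and canter use one pooled model across ponies and horses (the
decision-region figure of the source analysis pools them; a per-type split
is a caller-side option via the samples it passes). Walk uses one model per
group velocity profile: ponies (height <= 1.48 m), slow horses, and fast
horses (minimum collected-walk speed >= 1.6 m/s); how that minimum speed is
obtained in deployment is user input, as in the source analysis.

Two structural facts about the published velocity bands matter when
interpreting synthetic pace accuracies. Canter bands are disjoint within
and across horse types wherever it matters, so the canter model reaches
100% held-out accuracy. Trot bands are not: pony collected and working
trot overlap (2.68-2.78 vs 2.74-3.12 m/s), and pony extended trot overlaps
horse working trot in a pooled model — so synthetic trot accuracy sits
below 100% by construction, and the package does not claim otherwise. For
walk, population bands of different paces overlap outright; this is exactly
why group velocity profiles exist. The walk sampler therefore works per
subject: each roster subject carries a fixed offset within the band (tied
to its minimum collected-walk speed for horses), with a small within-
subject jitter. Within a group the pace supports then separate and the
group models reach full accuracy on the study-style roster.

## Problem sizes and reproducibility

The shipped acceptance script uses 200 windows per class for the phase-1
gait superclassifier (4 classes, 2 s at 50 Hz), 150 per class for the
6-class jumping model (2 s at 10 Hz), 100 windows per pace for each
velocity regressor, and 50 velocity draws per (pace, horse type) for the
canter QDA — sizes at which each result is stable across seeds while a full
run stays within a few minutes on one CPU. The test suite uses smaller
configurations of the same models (8/16 filters) for unit-level checks.
Every random quantity — generator draws, splits, initialization, dropout —
flows from a single integer seed.

## Known limitations

* The generator is a statistical stand-in, not horse biomechanics; see the
  list of non-emulated effects above. Accuracies on it are upper bounds on
  field performance.
* Exact convolutional depths and widths per hierarchy node are package
  defaults; the source analysis tuned per-node shapes that were never
  published.
* The fast-horse walk group depends, in the original data, on a single
  misclassified sample; the package reproduces the group mechanism, not
  that artifact.
* The "medium" pace variant is out of scope, as is decoding any vendor's
  binary sensor format: recordings enter as delimited text.
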