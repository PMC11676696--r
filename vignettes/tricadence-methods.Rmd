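---
title: "Cadence counting and cycling-task recognition from a trunk IMU"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cadence counting and cycling-task recognition from a trunk IMU}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tricadence)
```

## The measurement problem

A triathlete's movement cadence — swimming strokes, cycling pedal strokes
and running strides per minute — and the alternation between in-saddle and
out-of-saddle riding carry information about pacing, fatigue and response
to terrain. Video analysis resolves these but does not scale; multi-sport
watches average over long windows and locate position poorly. A single
trunk-mounted IMU (100 Hz accelerometer and gyroscope, 10 Hz GPS) records
enough signal to recover both, if the analysis respects the biomechanics of
how trunk motion reflects limb action.

This vignette documents the models and the design decisions behind the
package: the peak-counting cadence estimator, the window-spectral task
classifier, the synthetic session generator used to validate both, and the
numerical choices in between.

## Data model and conventions

A recording holds six uniformly sampled channels plus an optional GPS
sub-track. The axis convention is fixed project-wide: **x forward, y
mediolateral, z vertical** (gravity-aligned at rest). Acceleration is
stored in g and angular velocity in °/s, matching the ±16 g / ±2000 °/s
sensor ranges; the validator rejects samples outside those ranges, naming
the offending row.

Task label intervals are **half-open** `[start, end)`: a boundary instant
belongs to the later interval. Gaps are allowed and surface as `unlabelled`
rather than as errors, because field recordings have unlabelled transitions.
`coasting` is defined as riding without turning the pedals for **more than
one second**; the validator enforces the duration rule. Pedalling pauses of
a second or less are not coasting.

## Band-pass peak counting

Cadence events are extrema of a band-pass-filtered trunk channel. The
filter is a Butterworth band-pass — maximally flat passband, monotone
roll-off — of order six; we interpret "order" as the order of the band-pass
realisation itself, not of an underlying low-pass prototype (conventions
differ, so this is stated explicitly; the `signal::butter` prototype order
is therefore 3). Cutoffs are 2–3 Hz for cycling and running and
0.5–1.4 Hz for swimming, whose stroke-driven trunk roll is far slower.

Filtering is applied **zero-phase** (forward–backward), because event
timestamps must line up with externally synchronised video; a causal pass
would lag events by a band-dependent group delay. Two caveats are
documented rather than hidden: the double pass squares the magnitude
response, sharpening the effective roll-off beyond a single sixth-order
pass; and edges need care. Each pass starts from the steady state of a
constant input equal to the first sample (so a gravity offset leaves no
start-up transient) and the signal is extended by odd reflection over three
periods of the lower cutoff before filtering.

Channel and polarity defaults encode trunk biomechanics, since a trunk
sensor cannot observe limbs directly:

| discipline | band (Hz) | min interval | channel | polarity |
|---|---|---|---|---|
| swim | 0.5–1.4 | 0.5 s | mediolateral acc | peaks and troughs |
| cycle | 2–3 | 0.3 s | vertical acc | peaks only |
| run | 2–3 | 0.25 s | vertical acc | peaks only |

Swimming counts both extrema of the trunk roll because left and right arm
entries alternate with the roll; cycling and running produce one vertical
trunk oscillation per pedal stroke or stride. All defaults are overridable
per profile. Candidate extrema closer together than the minimum interval
are thinned greedily by magnitude — the larger extremum wins a conflict —
which is also how ties against noise ripples resolve deterministically. No
amplitude or prominence threshold is applied by default (only the minimum
interval is part of the method's definition); an optional prominence
parameter exists for noisy field data.

Cadence over an epoch is `count × 60 / epoch_s` with half-open binning.
Count accuracy is `100·(1 − |detected − truth|/truth)` floored at zero — the
published description does not print a formula, so this symmetric form is a
package choice. RMSE between detected and true cadence uses 60 s
non-overlapping epochs by default (cadence units are per minute); a final
partial epoch is excluded from the RMSE because its cadence extrapolates a
short count, while totals keep those events.

The five-strike video synchronisation signature is located on the forward
axis: the first run of five spikes above a configurable threshold (default
4 g, minimum gap 0.3 s) anchors the sensor clock to the video clock. The
strikes are only described qualitatively in the field protocol, so both
parameters are configurable rather than fixed.

## Window-spectral features and the task classifier

All six channels are combined and filtered with the same band-pass as
cycling peak counting (this pre-filter follows the pipeline's description;
it is configurable, and turning it off widens the spectral contrast
available to the classifier — an experiment left to the user). Windows of
250 samples (2.5 s) with no overlap are transformed with a rectangular
window to one-sided magnitude spectra: 126 bins per channel, 756 features
per window. The rectangular window makes the bin count and hop arithmetic
exact; no taper is part of the method's definition.

Features are z-scored per feature with means and population SDs fitted on
**training windows only**; features constant in training map to zero rather
than dividing by zero (synthetic silence makes this reachable). Labels on a
0.1 s grid are assigned to windows by majority vote — 25 fine steps per
window; `unlabelled` steps abstain, and an exact tie goes to the label
occurring earliest within the window, a deterministic, dictionary-order-free
rule.

The classifier is a gradient-boosted decision-tree ensemble (XGBoost,
softmax objective) at library defaults — 100 rounds, depth 6, learning rate
0.3, fixed seed, one thread — deliberately untuned: the pipeline is a proof
of concept and tuning is out of scope. Evaluation uses a participant-level
hold-out: the training participants' windows are split 80/20, and all
windows of the remaining participants form a generalisation set never seen
in training. The 80/20 split is by **contiguous blocks of windows**
(default 8 windows = 20 s, seeded random block order), not window-level
sampling, because adjacent windows are nearly identical and a random
window split would leak test information into training.

Binary scoring treats `out_of_saddle` as the positive class and excludes
coasting truth windows: distinguishing coasting from seated pedalling from
trunk signals is unreliable (the trunk barely differentiates soft-pedalling
from freewheeling), so the coasting label exists in the data model and the
generator but carries no performance claim.

## The synthetic session generator

Field recordings with video ground truth are not redistributable, so the
package validates against a seeded generator whose defaults are the study
conditions the pipeline targets.

**Single-discipline sessions** place a fundamental at the cadence frequency
on the discipline's primary channel — swim: mediolateral roll at
`cadence/120` Hz so peaks plus troughs give the stroke count; cycle/run:
vertical at `cadence/60` Hz — plus phase-locked harmonics (weights 1, 0.25,
0.08), a gravity baseline and Gaussian noise (default 0.05 g accelerometer,
5 °/s gyroscope). Ground-truth event times are the analytic extrema of the
fundamental, so event counts are exact integers. Default cadences follow
typical race values: swim 79, cycle 157.5, run 172 events/min; amplitudes
are order-of-magnitude trunk-acceleration choices (0.4–0.8 g primary
channel), since per-discipline trunk amplitude scales are not published.

**Scheduled cycling sessions** add per-block task regimes: seated pedalling
(vertical oscillation at the session cadence), standing efforts (lower
cadence — factor 0.84 — raised amplitude, vertical baseline shift, and
~1.3 Hz mediolateral rocking as the bike sways under the standing rider;
the rocking frequency is a biomechanical modelling choice, not a measured
fact), and coasting (road noise only). Three realism terms matter for what
the tests can show:

* **per-block variation** — each pedalling block draws its own cadence
  (CV 8 %) and amplitude (CV 15 %), so seated and standing cadence
  distributions nearly abut instead of being separable by a single
  frequency threshold;
* **within-block drift** — instantaneous cadence follows a mean-reverting
  random walk (stationary SD 4 %, ~5 s relaxation), spreading pedalling
  energy over neighbouring bins as real riders do; ground-truth events
  remain exact as phase crossings of the drifting phase track;
* **transitions** — the standing regime ramps in and out over 1.5 s
  (standing up is not instantaneous), so a 2–4 s surge never reaches a
  clean steady state.

Schedules come in two styles: balanced 20 s blocks (controlled protocol,
classes roughly equally represented) and race-style schedules (~92 %
in-saddle, out-of-saddle efforts of 2–4 s by default at jittered offsets,
coasting ≥ 3 s). Both are built from the same schedule type. With these
defaults the classifier recognises long efforts at high accuracy, yet
sensitivity to brief race-style efforts drops sharply — the 2.5 s windows
blur sub-window efforts into mostly-seated mixtures. The test suite asserts
this contrast (strict inequality on matched seeds) rather than hiding it,
because it is the main practical limitation of fixed 2.5 s windows.

**GPS tracks** follow an elongated rectangle (5 km perimeter, 8:1 aspect)
or an out-and-back line at constant speed on a local-plane lat/lon
conversion, with optional Gaussian position jitter; fixes land on the
inertial time grid.

What the generator does *not* emulate: soft-tissue and mounting artefacts,
braking and terrain-induced broadband transients, bilateral asymmetry,
fatigue drift, open-water conditions, GPS multipath. Passing the bundled
experiments therefore demonstrates correctness of the pipeline under the
stated signal model and the stated class-contrast assumptions — not field
accuracy on real athletes, which requires video-truthed recordings.

## Numerical choices and degenerate inputs

* Filter stability is checked at design time (all poles strictly inside the
  unit circle); inverted or Nyquist-violating cutoffs raise a design error.
* A flat signal yields an empty event series, not an error; recordings
  shorter than twice the minimum interval (or than one STFT window) raise
  argument errors.
* Time-grid validation tolerates 1 µs of spacing error; IO round-trips are
  lossless to well below 1e-9 via full-precision CSV writing.
* Single-class training data and single-window standardizer fits are
  errors, not silent degeneracies.
* Schedule durations snap to the 0.1 s label grid so window counts and
  label counts always agree.

## Problem sizes in the bundled experiments

The unit and property tests run on sessions of 10–400 s. The reference
experiment (`scripts/acceptance.R`) uses six 8-minute swim sessions
(cadences 71–87), five 15-minute cycling sessions (150–165), six 10-minute
run sessions (166–178), and twelve ~20-minute riders (six balanced, six
race-style with 20 s efforts; six riders train with an 80/20 block split,
all twelve are evaluated). These sizes give stable means while keeping the
whole experiment comfortably within a coffee break on a laptop.
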