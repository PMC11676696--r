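# tricadence

Triathlon performance analysis from a **single trunk-mounted IMU** (100 Hz
tri-axial accelerometer ±16 g and gyroscope ±2000 °/s, optional 10 Hz GPS).
The package is aimed at sport scientists and performance analysts who want
movement cadence and cycling-task information over short, contextually
relevant epochs — something multi-sport watches cannot provide — without
merging data from several sensors.

Two analysis paths are implemented:

1. **Peak counting.** A trunk channel is band-pass filtered with a
   sixth-order zero-phase Butterworth filter (2–3 Hz for cycling and
   running; 0.5–1.4 Hz for the slower swimming cadence) and propulsive
   events are the filtered-signal extrema subject to a minimum event
   interval (swim 0.5 s, cycle 0.3 s, run 0.25 s; when two candidates
   conflict the larger-magnitude extremum wins). Events become per-epoch
   cadence, `cadence = count × 60 / epoch_s`, and are scored against ground
   truth with count accuracy `100·(1 − |d − t|/t)`, per-epoch RMSE and
   relative error `100·|d − t|/t`.
2. **Cycling-task classification.** All six inertial channels are filtered,
   cut into 2.5 s windows (250 samples, no overlap) and transformed to
   one-sided spectral magnitudes — 126 frequency bins per channel, 756
   features per window. Features are z-scored with a standardizer fitted on
   training windows only; task labels on a 0.1 s grid are assigned to
   windows by majority vote; a gradient-boosted tree ensemble (XGBoost,
   library defaults, fixed seed) classifies `in_saddle` / `out_of_saddle` /
   `coasting`. Evaluation follows a participant-level hold-out: 80/20
   contiguous-block split of the training participants, all other
   participants entirely held out. Windows are scored with accuracy,
   sensitivity and specificity (positive class `out_of_saddle`; coasting
   windows excluded from the binary report).

A seeded synthetic session generator (`simulate_discipline`,
`simulate_cycling_session`, `simulate_gps_track`) produces recordings with
exact ground truth, and GeoJSON map exports draw task intervals and rolling
cadence along the GPS track.

## Worked example

```r
library(tricadence)

# a 5-minute synthetic run at 172 strides/min, default noise
sim <- simulate_discipline(synthetic_session_spec("run", duration_s = 300,
                                                  cadence_per_min = 172,
                                                  seed = 7))
ev <- detect_events(sim$recording, discipline_profile("run"))
cs <- cadence_series(ev, epoch_s = 60, duration_s = 300)
print(cs)
#> <cadence_series> 5 epochs of 60 s, 860 events, mean 172.0 /min
count_accuracy(length(ev$event_times_s), sim$truth$n_events)
#> [1] 100
cadence_rmse(cs, cadence_series(sim$truth$event_times_s, 60, 300))
#> [1] 0
```

The detector recovered all 860 ground-truth strides (accuracy 100 %), and
the per-minute cadence matches the ground truth in every epoch (RMSE 0
strides/min at this noise level).

A command-line interface wraps the same functions
(`inst/scripts/tricadence`): `simulate`, `count-cadence`, `classify-train`,
`classify-predict`, `evaluate`, `map`. Every run logs its seed and config
hash so results are replayable.

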