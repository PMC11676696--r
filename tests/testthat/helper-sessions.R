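# Shared fixture builders: all synthetic, generated at test time.

# small random but valid recording for IO round-trip checks
random_recording <- function(n = 200, seed = 42, with_gps = FALSE) {
  set.seed(seed)
  gps <- NULL
  if (with_gps) {
    tg <- seq(0, (n - 1) / 100, by = 0.1)
    gps <- data.frame(t = tg, lat = -31.95 + cumsum(rnorm(length(tg), 0, 1e-6)),
                      lon = 115.85 + cumsum(rnorm(length(tg), 0, 1e-6)))
  }
  imu_recording(rnorm(n, 0, 0.5), rnorm(n, 0, 0.5), 1 + rnorm(n, 0, 0.5),
                rnorm(n, 0, 20), rnorm(n, 0, 20), rnorm(n, 0, 20),
                sample_rate_hz = 100, gps = gps,
                meta = list(participant = "T1"))
}

# recording with a single pure sinusoid on one channel, zeros elsewhere
sinusoid_recording <- function(freq_hz, duration_s, channel = "acc_z",
                               amplitude = 1, sample_rate_hz = 100) {
  n <- round(duration_s * sample_rate_hz)
  t <- (seq_len(n) - 1L) / sample_rate_hz
  chans <- stats::setNames(rep(list(numeric(n)), 6),
                           c("acc_x", "acc_y", "acc_z",
                             "gyr_x", "gyr_y", "gyr_z"))
  chans[[channel]] <- amplitude * sin(2 * pi * freq_hz * t)
  imu_recording(chans$acc_x, chans$acc_y, chans$acc_z,
                chans$gyr_x, chans$gyr_y, chans$gyr_z,
                sample_rate_hz = sample_rate_hz)
}

# scheduled synthetic rider: STFT features + window labels
make_rider <- function(seed, kind = c("balanced", "race"), effort_s = 20,
                       duration_s = 600, stft = stft_config()) {
  kind <- match.arg(kind)
  set.seed(seed)
  sched <- if (kind == "balanced") {
    schedule_balanced(20, max(1L, round(duration_s / 60)))
  } else {
    schedule_race(duration_s, effort_s = effort_s)
  }
  dur <- sum(sched$duration_s)
  sim <- simulate_cycling_session(
    synthetic_session_spec("cycle", duration_s = dur, task_schedule = sched,
                           seed = seed))
  fine <- fine_grain_labels(sim$truth$label_track, 0.1, dur)
  list(features = stft_magnitudes(sim$recording, stft),
       labels = align_labels(fine, stft),
       truth = sim$truth, recording = sim$recording)
}

# label_track constructed without validation (unit fixtures that deliberately
# bypass e.g. the coasting-duration rule)
raw_label_track <- function(start_s, end_s, label) {
  df <- data.frame(start_s = start_s, end_s = end_s, label = label,
                   stringsAsFactors = FALSE)
  class(df) <- c("label_track", "data.frame")
  df
}
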