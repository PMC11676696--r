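#' Specification for a synthetic trunk-IMU session
#'
#' Describes a seeded synthetic session with exact ground truth: a cyclic
#' locomotion signal (fundamental at the cadence frequency plus phase-locked
#' harmonics plus Gaussian noise) on the discipline's primary trunk channel,
#' and — for cycling — an optional schedule of task blocks with distinct
#' signal regimes. Default cadences follow typical triathlon race values
#' (swim 79 strokes/min, cycle 157.5 pedal strokes/min, run 172 strides/min);
#' amplitudes are order-of-magnitude trunk-acceleration choices (0.1-1.5 g).
#'
#' For swimming the primary channel is the mediolateral (roll) axis and the
#' fundamental runs at `cadence / 120` Hz so that peaks and troughs together
#' — left and right arm entries — yield the stroke count. For cycling and
#' running it is the vertical axis at `cadence / 60` Hz, one oscillation per
#' pedal stroke / stride.
#'
#' @param discipline `"swim"`, `"cycle"` or `"run"`.
#' @param duration_s Session length in seconds.
#' @param cadence_per_min Propulsive events per minute (ground truth).
#' @param amplitude_g Primary-channel fundamental amplitude in g.
#' @param harmonic_weights Relative weights of harmonics 1..H of the
#'   fundamental (first entry is the fundamental and should be 1).
#' @param noise_sd Gaussian noise SD per accelerometer channel in g.
#' @param noise_sd_gyro Gaussian noise SD per gyroscope channel in deg/s.
#' @param baseline_g Static vertical acceleration (gravity projection), g.
#' @param task_schedule Optional data.frame `duration_s, label` of cycling
#'   task blocks; must be cycling, block durations sum to `duration_s`.
#' @param standing_cadence_factor Pedalling-rate multiplier for out-of-saddle
#'   blocks (standing efforts run at a lower cadence; default 0.84).
#' @param cadence_cv Coefficient of variation of the per-block pedalling
#'   cadence in scheduled rides (default 0.05): riders do not hold one exact
#'   cadence, so each pedalling block draws its own rate around the mean.
#' @param amplitude_cv Coefficient of variation of the per-block signal
#'   amplitude in scheduled rides (default 0.15), emulating effort-to-effort
#'   differences in trunk motion.
#' @param transition_s Stand-up / sit-down transition time in seconds
#'   (default 1.5): the out-of-saddle signal regime ramps in and out linearly
#'   over this span, so brief standing efforts never reach a clean steady
#'   state — the reason short efforts are intrinsically harder to classify
#'   from fixed-length windows.
#' @param cadence_drift_sd Stationary SD (as a fraction of the block cadence)
#'   of the within-block mean-reverting cadence drift in scheduled rides
#'   (default 0.04): riders do not hold a metronomic rate, which spreads
#'   pedalling energy over neighbouring frequency bins.
#' @param seed Integer RNG seed; identical specs and seeds give identical
#'   sessions.
#' @return An object of class `synthetic_session_spec`.
#' @export
synthetic_session_spec <- function(discipline = c("swim", "cycle", "run"),
                                   duration_s = 300,
                                   cadence_per_min = NULL,
                                   amplitude_g = NULL,
                                   harmonic_weights = c(1, 0.25, 0.08),
                                   noise_sd = 0.05,
                                   noise_sd_gyro = 5,
                                   baseline_g = 1,
                                   task_schedule = NULL,
                                   standing_cadence_factor = 0.84,
                                   cadence_cv = 0.08,
                                   amplitude_cv = 0.15,
                                   transition_s = 1.5,
                                   cadence_drift_sd = 0.04,
                                   seed = 1L) {
  discipline <- match.arg(discipline)
  defaults <- list(swim = list(cadence = 79, amp = 0.5),
                   cycle = list(cadence = 157.5, amp = 0.4),
                   run = list(cadence = 172, amp = 0.8))[[discipline]]
  if (is.null(cadence_per_min)) cadence_per_min <- defaults$cadence
  if (is.null(amplitude_g)) amplitude_g <- defaults$amp
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop_argument("duration_s must be positive")
  if (any(cadence_per_min <= 0)) stop_argument("cadence_per_min must be positive")
  if (noise_sd < 0 || noise_sd_gyro < 0) stop_argument("noise SDs must be >= 0")
  if (!is.null(task_schedule)) {
    if (discipline != "cycle")
      stop_argument("task_schedule only applies to cycling sessions")
    if (!all(c("duration_s", "label") %in% names(task_schedule)))
      stop_argument("task_schedule needs columns duration_s, label")
    if (abs(sum(task_schedule$duration_s) - duration_s) > 1e-6)
      stop_argument("task_schedule durations must sum to duration_s")
    bad <- setdiff(unique(task_schedule$label), TASK_LABELS)
    if (length(bad))
      stop_format(sprintf("unknown schedule label(s): %s",
                          paste(bad, collapse = ", ")))
  }
  structure(list(discipline = discipline, duration_s = duration_s,
                 cadence_per_min = cadence_per_min, amplitude_g = amplitude_g,
                 harmonic_weights = harmonic_weights, noise_sd = noise_sd,
                 noise_sd_gyro = noise_sd_gyro, baseline_g = baseline_g,
                 task_schedule = task_schedule,
                 standing_cadence_factor = standing_cadence_factor,
                 cadence_cv = cadence_cv, amplitude_cv = amplitude_cv,
                 transition_s = transition_s,
                 cadence_drift_sd = cadence_drift_sd,
                 seed = as.integer(seed)),
            class = "synthetic_session_spec")
}

# fundamental + phase-locked harmonics, unit fundamental amplitude
harmonic_wave <- function(tau, f, weights) {
  y <- numeric(length(tau))
  for (h in seq_along(weights))
    y <- y + weights[h] * sin(2 * pi * h * f * tau)
  y
}

# instantaneous pedalling phase with a mean-reverting (OU) cadence drift:
# f_inst = f0 * (1 + w), w relaxing over ~5 s with stationary SD drift_sd,
# clamped so the phase stays strictly increasing
drifting_phase <- function(n, f0, fs, drift_sd, relax_s = 5) {
  if (drift_sd <= 0 || n < 2) return(2 * pi * f0 * seq_len(n) / fs)
  theta <- 1 / (relax_s * fs)
  eps <- stats::rnorm(n, 0, drift_sd * sqrt(2 * theta))
  w <- numeric(n)
  for (k in 2:n) w[k] <- w[k - 1] * (1 - theta) + eps[k]
  w <- pmax(pmin(w, 0.5), -0.5)
  2 * pi * cumsum(f0 * (1 + w)) / fs
}

# waveform with harmonics on an arbitrary phase track
harmonic_wave_phase <- function(phase, weights) {
  y <- numeric(length(phase))
  for (h in seq_along(weights)) y <- y + weights[h] * sin(h * phase)
  y
}

# exact ground-truth peak times of sin(phase): crossings of pi/2 + 2 pi k,
# found by inverse interpolation of the strictly increasing phase track
phase_peak_times <- function(phase, tau) {
  if (max(phase) < pi / 2) return(numeric())
  targets <- seq(pi / 2, max(phase), by = 2 * pi)
  targets <- targets[targets >= phase[1]]
  if (!length(targets)) return(numeric())
  stats::approx(phase, tau, xout = targets, ties = "ordered")$y
}

# analytic extremum times of the fundamental sin(2 pi f tau) on [0, dur):
# peaks at (k + 1/4)/f, troughs at (k + 3/4)/f
fundamental_extrema <- function(f, dur, troughs = FALSE) {
  step <- if (troughs) 0.5 else 1
  first <- 0.25 / f
  tt <- seq(first, dur, by = step / f)
  tt[tt < dur - 1e-12]
}

#' Simulate a single-discipline session with exact ground truth
#'
#' Generates an [imu_recording] whose primary channel carries the cadence
#' fundamental plus harmonics plus seeded Gaussian noise, and returns the
#' analytic event times (extrema of the fundamental) as ground truth. No task
#' schedule is involved; see [simulate_cycling_session] for scheduled rides.
#'
#' @param spec A [synthetic_session_spec] without `task_schedule`.
#' @return List with elements `recording` (an `imu_recording`) and `truth`
#'   (list: `event_times_s`, `n_events`, `cadence_per_min`).
#' @export
simulate_discipline <- function(spec) {
  if (!inherits(spec, "synthetic_session_spec"))
    stop_argument("need a synthetic_session_spec")
  if (!is.null(spec$task_schedule))
    stop_argument("spec has a task_schedule; use simulate_cycling_session")
  set.seed(spec$seed)
  fs <- 100
  n <- round(spec$duration_s * fs)
  t <- (seq_len(n) - 1L) / fs
  cad <- spec$cadence_per_min[1]
  chans <- list()
  for (ch in ACC_CHANNELS) chans[[ch]] <- stats::rnorm(n, 0, spec$noise_sd)
  for (ch in GYR_CHANNELS) chans[[ch]] <- stats::rnorm(n, 0, spec$noise_sd_gyro)
  chans$acc_z <- chans$acc_z + spec$baseline_g
  if (spec$discipline == "swim") {
    f <- cad / 120  # one roll cycle per two strokes
    chans$acc_y <- chans$acc_y +
      spec$amplitude_g * harmonic_wave(t, f, spec$harmonic_weights)
    chans$gyr_x <- chans$gyr_x + 30 * sin(2 * pi * f * t)  # trunk roll rate
    # peaks and troughs interleave: one stroke every half roll cycle
    events <- seq(0.25 / f, spec$duration_s, by = 0.5 / f)
    events <- events[events < spec$duration_s - 1e-12]
  } else {
    f <- cad / 60
    chans$acc_z <- chans$acc_z +
      spec$amplitude_g * harmonic_wave(t, f, spec$harmonic_weights)
    chans$acc_x <- chans$acc_x +
      0.15 * spec$amplitude_g * sin(2 * pi * f * t + pi / 3)
    chans$gyr_y <- chans$gyr_y + 15 * sin(2 * pi * f * t)
    events <- fundamental_extrema(f, spec$duration_s)
  }
  rec <- imu_recording(chans$acc_x, chans$acc_y, chans$acc_z,
                       chans$gyr_x, chans$gyr_y, chans$gyr_z,
                       sample_rate_hz = fs,
                       meta = list(discipline = spec$discipline,
                                   seed = spec$seed, synthetic = TRUE))
  list(recording = rec,
       truth = list(event_times_s = events, n_events = length(events),
                    cadence_per_min = cad))
}

#' Balanced block schedule (controlled-protocol style)
#'
#' Repeats the given task sequence in equal fixed-duration blocks, the
#' controlled design used to balance class representation for classifier
#' training.
#'
#' @param block_s Block duration in seconds (default 20).
#' @param n_cycles Number of repetitions of the label sequence.
#' @param labels Task sequence per cycle.
#' @return data.frame `duration_s, label` usable as a `task_schedule`.
#' @export
schedule_balanced <- function(block_s = 20, n_cycles = 10,
                              labels = TASK_LABELS) {
  data.frame(duration_s = rep(block_s, n_cycles * length(labels)),
             label = rep(labels, n_cycles), stringsAsFactors = FALSE)
}

#' Race-style schedule: long in-saddle stretches with brief efforts
#'
#' Emulates uncontrolled riding where in-saddle time dominates (roughly 90-94
#' percent) and out-of-saddle efforts are brief. Each cycle is a long
#' in-saddle stretch, an out-of-saddle effort of `effort_s`, another stretch,
#' and a short coast.
#'
#' Race efforts start at arbitrary moments, not on a metronome, so the
#' in-saddle stretch lengths are jittered (uniformly within `+/- jitter` of
#' their mean) and `effort_s` may be a length-2 range to draw each effort
#' duration from. The schedule therefore uses the current RNG state; call
#' `set.seed()` first for a reproducible schedule.
#'
#' @param duration_s Approximate total duration (rounded to whole cycles).
#' @param effort_s Out-of-saddle effort duration in seconds: a single value,
#'   or a range `c(min, max)` sampled per effort (default `c(2, 4)`, the
#'   brief surges seen in uncontrolled rides; use 20 for controlled-length
#'   efforts).
#' @param coast_s Coasting duration per cycle (must exceed 1 s; default 3).
#' @param in_saddle_fraction Target fraction of in-saddle time (default 0.92).
#' @param jitter Relative jitter of in-saddle stretch lengths (default 0.4).
#' @return data.frame `duration_s, label`.
#' @export
schedule_race <- function(duration_s = 1200, effort_s = c(2, 4), coast_s = 3,
                          in_saddle_fraction = 0.92, jitter = 0.4) {
  effort_mean <- mean(effort_s)
  other <- effort_mean + coast_s
  cycle_s <- other / (1 - in_saddle_fraction)
  in_each <- (cycle_s - other) / 2
  n_cycles <- max(1L, round(duration_s / cycle_s))
  blocks <- do.call(rbind, lapply(seq_len(n_cycles), function(i) {
    eff <- if (length(effort_s) == 2L)
      stats::runif(1, effort_s[1], effort_s[2]) else effort_s
    # durations snap to the 0.1 s label grid
    data.frame(
      duration_s = round(c(in_each * stats::runif(1, 1 - jitter, 1 + jitter),
                           eff,
                           in_each * stats::runif(1, 1 - jitter, 1 + jitter),
                           coast_s), 1),
      label = c("in_saddle", "out_of_saddle", "in_saddle", "coasting"),
      stringsAsFactors = FALSE)
  }))
  blocks
}

#' Simulate a scheduled cycling session
#'
#' Each schedule block gets its own signal regime on top of channel noise:
#' \describe{
#'   \item{in_saddle}{vertical pedalling oscillation at the session cadence
#'     (about 2.6 Hz at the default 157.5/min), moderate amplitude.}
#'   \item{out_of_saddle}{pedalling at the lower standing cadence
#'     (`standing_cadence_factor` x spec cadence, about 2.2 Hz), raised
#'     vertical amplitude and baseline shift, plus strong ~1.3 Hz
#'     mediolateral rocking as the bike sways under the standing rider.}
#'   \item{coasting}{no pedalling oscillation, road noise only.}
#' }
#' Ground-truth pedal events exist only in pedalling blocks (analytic extrema
#' of each block's fundamental); the label track mirrors the schedule
#' exactly.
#'
#' @param spec A [synthetic_session_spec] with a `task_schedule`.
#' @return List with `recording`, `truth` (list: `event_times_s`, `n_events`,
#'   `label_track`).
#' @export
simulate_cycling_session <- function(spec) {
  if (!inherits(spec, "synthetic_session_spec"))
    stop_argument("need a synthetic_session_spec")
  if (is.null(spec$task_schedule))
    stop_argument("spec has no task_schedule; use simulate_discipline")
  sched <- spec$task_schedule
  set.seed(spec$seed)
  fs <- 100
  n <- round(spec$duration_s * fs)
  t <- (seq_len(n) - 1L) / fs
  chans <- list()
  for (ch in ACC_CHANNELS) chans[[ch]] <- stats::rnorm(n, 0, spec$noise_sd)
  for (ch in GYR_CHANNELS) chans[[ch]] <- stats::rnorm(n, 0, spec$noise_sd_gyro)
  chans$acc_z <- chans$acc_z + spec$baseline_g
  f_seat <- spec$cadence_per_min[1] / 60
  f_stand <- f_seat * spec$standing_cadence_factor
  f_rock <- 1.3
  starts <- cumsum(c(0, sched$duration_s[-nrow(sched)]))
  events <- numeric()
  for (b in seq_len(nrow(sched))) {
    t0 <- starts[b]; dur <- sched$duration_s[b]
    ii <- which(t >= t0 - 1e-9 & t < t0 + dur - 1e-9)
    tau <- t[ii] - t0
    lab <- sched$label[b]
    # riders neither hold one exact cadence nor one effort amplitude:
    # every pedalling block draws its own rate and amplitude around the mean
    cad_mult <- max(0.5, 1 + stats::rnorm(1, 0, spec$cadence_cv))
    amp_mult <- max(0.2, 1 + stats::rnorm(1, 0, spec$amplitude_cv))
    if (lab == "in_saddle") {
      f_b <- f_seat * cad_mult
      ph <- drifting_phase(length(ii), f_b, fs, spec$cadence_drift_sd)
      chans$acc_z[ii] <- chans$acc_z[ii] + amp_mult *
        spec$amplitude_g * harmonic_wave_phase(ph, spec$harmonic_weights)
      chans$gyr_y[ii] <- chans$gyr_y[ii] + 10 * amp_mult * sin(ph)
      events <- c(events, t0 + phase_peak_times(ph, tau))
    } else if (lab == "out_of_saddle") {
      f_b <- f_stand * cad_mult
      ph <- drifting_phase(length(ii), f_b, fs, spec$cadence_drift_sd)
      # standing up / sitting down is not instantaneous: the regime ramps in
      # and out, so brief efforts never reach a clean steady state
      env <- pmin(1, tau / spec$transition_s, (dur - tau) / spec$transition_s)
      env <- pmax(env, 0)
      # trunk motion blends out of the seated regime through the transition
      seat_env <- 1 - env
      chans$acc_z[ii] <- chans$acc_z[ii] + 0.2 * amp_mult * env +
        env * 1.3 * amp_mult * spec$amplitude_g *
          harmonic_wave_phase(ph, spec$harmonic_weights) +
        seat_env * spec$amplitude_g *
          harmonic_wave(tau, f_seat * cad_mult, spec$harmonic_weights)
      chans$acc_y[ii] <- chans$acc_y[ii] +
        0.6 * amp_mult * env * sin(2 * pi * f_rock * tau)
      chans$gyr_x[ii] <- chans$gyr_x[ii] + 30 * amp_mult * env * sin(2 * pi * f_rock * tau)
      events <- c(events, t0 + phase_peak_times(ph, tau))
    } else {  # coasting: road noise only
      chans$acc_z[ii] <- chans$acc_z[ii] + stats::rnorm(length(ii), 0, 0.3 * spec$noise_sd)
    }
  }
  track <- label_track(starts, starts + sched$duration_s, sched$label)
  rec <- imu_recording(chans$acc_x, chans$acc_y, chans$acc_z,
                       chans$gyr_x, chans$gyr_y, chans$gyr_z,
                       sample_rate_hz = fs,
                       meta = list(discipline = "cycle", seed = spec$seed,
                                   synthetic = TRUE, scheduled = TRUE))
  list(recording = rec,
       truth = list(event_times_s = sort(events), n_events = length(events),
                    label_track = track))
}

#' Simulate a 10 Hz GPS track along a course
#'
#' Moves at the given speed along an elongated rectangle (perimeter =
#' `course_length_m`, long:short side 8:1) or an out-and-back line, converts
#' local metres to lat/lon around the origin and adds seeded Gaussian
#' position jitter. Fix times land on the inertial 100 Hz grid.
#'
#' @param duration_s Track duration in seconds.
#' @param course `"rectangle"` or `"out_and_back"`.
#' @param speed_mps Speed in m/s (scalar, default 10).
#' @param jitter_m Gaussian position jitter SD in metres (default 0).
#' @param course_length_m Rectangle perimeter / out-and-back total length, m.
#' @param origin `c(lat, lon)` of the course origin in decimal degrees.
#' @param seed RNG seed for the jitter.
#' @return data.frame `t, lat, lon` at 10 Hz, suitable as a GPS sub-track.
#' @export
simulate_gps_track <- function(duration_s, course = c("rectangle", "out_and_back"),
                               speed_mps = 10, jitter_m = 0,
                               course_length_m = 5000,
                               origin = c(lat = -31.95, lon = 115.85),
                               seed = 1L) {
  course <- match.arg(course)
  if (duration_s <= 0 || speed_mps <= 0)
    stop_argument("duration_s and speed_mps must be positive")
  set.seed(seed)
  tt <- seq(0, duration_s - 1e-9, by = 0.1)
  s <- (speed_mps * tt) %% course_length_m
  if (course == "rectangle") {
    aspect <- 8
    long_side <- course_length_m * aspect / (2 * (aspect + 1))
    short_side <- course_length_m / (2 * (aspect + 1))
    x <- numeric(length(s)); y <- numeric(length(s))
    seg1 <- s < long_side
    seg2 <- !seg1 & s < long_side + short_side
    seg3 <- !seg1 & !seg2 & s < 2 * long_side + short_side
    seg4 <- !(seg1 | seg2 | seg3)
    x[seg1] <- s[seg1];                      y[seg1] <- 0
    x[seg2] <- long_side;                    y[seg2] <- s[seg2] - long_side
    x[seg3] <- long_side - (s[seg3] - long_side - short_side)
    y[seg3] <- short_side
    x[seg4] <- 0
    y[seg4] <- short_side - (s[seg4] - 2 * long_side - short_side)
  } else {
    half <- course_length_m / 2
    x <- ifelse(s < half, s, course_length_m - s)
    y <- numeric(length(s))
  }
  if (jitter_m > 0) {
    x <- x + stats::rnorm(length(x), 0, jitter_m)
    y <- y + stats::rnorm(length(y), 0, jitter_m)
  }
  m_per_deg_lat <- 111320
  m_per_deg_lon <- 111320 * cos(origin[["lat"]] * pi / 180)
  data.frame(t = tt,
             lat = origin[["lat"]] + y / m_per_deg_lat,
             lon = origin[["lon"]] + x / m_per_deg_lon)
}
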