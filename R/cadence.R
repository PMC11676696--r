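#' Per-discipline event-detection parameters
#'
#' Bundles the band-pass edges, minimum event interval, input channel and
#' extremum polarity used to count propulsive movement events. Defaults follow
#' the trunk-sensor pipeline: swimming 0.5-1.4 Hz with a 0.5 s minimum
#' interval, cycling 2-3 Hz with 0.3 s, running 2-3 Hz with 0.25 s.
#'
#' Channel defaults reflect trunk biomechanics: swimming uses the mediolateral
#' accelerometer with peaks and troughs (trunk roll alternates with left/right
#' arm entry, so each extremum is one stroke); cycling and running use the
#' vertical accelerometer with peaks only (one trunk oscillation per pedal
#' stroke / one impact per stride).
#'
#' @param name One of `"swim"`, `"cycle"`, `"run"`.
#' @param band Length-2 numeric, band-pass cutoffs in Hz.
#' @param min_interval_s Minimum spacing between retained events in seconds.
#' @param channel Channel name, one of the six inertial channels.
#' @param polarity `"peaks_only"` or `"peaks_and_troughs"`.
#' @param prominence Optional minimum prominence (in filtered-signal units) a
#'   candidate extremum must have; `NULL` (default) disables the check.
#' @return An object of class `discipline_profile`.
#' @export
discipline_profile <- function(name = c("swim", "cycle", "run"),
                               band = NULL, min_interval_s = NULL,
                               channel = NULL, polarity = NULL,
                               prominence = NULL) {
  name <- match.arg(name)
  defaults <- list(
    swim  = list(band = c(0.5, 1.4), min_interval_s = 0.5,
                 channel = "acc_y", polarity = "peaks_and_troughs"),
    cycle = list(band = c(2, 3), min_interval_s = 0.3,
                 channel = "acc_z", polarity = "peaks_only"),
    run   = list(band = c(2, 3), min_interval_s = 0.25,
                 channel = "acc_z", polarity = "peaks_only"))[[name]]
  band <- if (is.null(band)) defaults$band else band
  min_interval_s <- if (is.null(min_interval_s)) defaults$min_interval_s else min_interval_s
  channel <- if (is.null(channel)) defaults$channel else channel
  polarity <- if (is.null(polarity)) defaults$polarity else polarity
  if (!polarity %in% c("peaks_only", "peaks_and_troughs"))
    stop_argument("polarity must be 'peaks_only' or 'peaks_and_troughs'")
  if (!channel %in% IMU_CHANNELS)
    stop_argument(sprintf("unknown channel '%s'", channel))
  if (!is.numeric(min_interval_s) || min_interval_s <= 0)
    stop_argument("min_interval_s must be positive")
  if (length(band) != 2 || band[1] >= band[2])
    stop_with("tricadence_design_error", "band must be (low, high) with low < high")
  structure(list(name = name, band = band, min_interval_s = min_interval_s,
                 channel = channel, polarity = polarity,
                 prominence = prominence),
            class = "discipline_profile")
}

#' @export
print.discipline_profile <- function(x, ...) {
  cat(sprintf("<discipline_profile> %s: %g-%g Hz on %s, min interval %g s, %s\n",
              x$name, x$band[1], x$band[2], x$channel, x$min_interval_s,
              x$polarity))
  invisible(x)
}

# local maxima indices of a numeric vector (interior strict sign changes)
local_maxima_idx <- function(x) {
  if (length(x) < 3L) return(integer())
  which(diff(sign(diff(x))) < 0) + 1L
}

# greedy minimum-distance thinning: keep candidates in decreasing magnitude
# order, discarding any candidate closer than min_dist samples to one already
# kept (the larger-magnitude extremum wins a conflict)
thin_by_distance <- function(idx, mag, min_dist) {
  k <- length(idx)
  if (k == 0L) return(integer())
  ord <- order(mag, decreasing = TRUE)
  removed <- logical(k)
  keep <- logical(k)
  for (j in ord) {
    if (removed[j]) next
    keep[j] <- TRUE
    lo <- j
    while (lo > 1L && idx[j] - idx[lo - 1L] < min_dist) lo <- lo - 1L
    hi <- j
    while (hi < k && idx[hi + 1L] - idx[j] < min_dist) hi <- hi + 1L
    if (lo < hi) removed[lo:hi] <- TRUE
    removed[j] <- TRUE
  }
  idx[keep]
}

#' Detected movement events
#'
#' @param event_times_s Strictly increasing event times in seconds.
#' @param discipline Discipline name.
#' @param profile The generating [discipline_profile] (optional).
#' @return An object of class `event_series`.
#' @export
event_series <- function(event_times_s, discipline, profile = NULL) {
  event_times_s <- as.numeric(event_times_s)
  if (length(event_times_s) > 1L && any(diff(event_times_s) <= 0))
    stop_validation("event times must be strictly increasing")
  structure(list(event_times_s = event_times_s, discipline = discipline,
                 profile = profile),
            class = "event_series")
}

#' @export
print.event_series <- function(x, ...) {
  cat(sprintf("<event_series> %s: %d events", x$discipline,
              length(x$event_times_s)))
  if (length(x$event_times_s))
    cat(sprintf(" over %.1f s", diff(range(x$event_times_s))))
  cat("\n")
  invisible(x)
}

#' Detect movement events (strokes, pedal strokes, strides)
#'
#' Band-pass filters the profile's channel (zero phase) and takes local maxima
#' — and minima, when the polarity is `peaks_and_troughs` — subject to the
#' profile's minimum event interval. When two candidate extrema fall closer
#' than the minimum interval, the larger-magnitude one is retained. A flat
#' signal yields an empty series, not an error.
#'
#' @param rec An [imu_recording].
#' @param profile A [discipline_profile].
#' @return An `event_series`.
#' @export
detect_events <- function(rec, profile) {
  validate_imu_recording(rec)
  if (!inherits(profile, "discipline_profile"))
    stop_argument("profile must be a discipline_profile")
  if (rec_duration(rec) <= 2 * profile$min_interval_s)
    stop_argument("recording shorter than twice the minimum event interval")
  spec <- bandpass_spec(6, profile$band[1], profile$band[2],
                        rec$sample_rate_hz)
  y <- apply_zero_phase(rec[[profile$channel]], spec)
  pk <- local_maxima_idx(y)
  pk <- pk[y[pk] > 0]
  idx <- pk
  if (profile$polarity == "peaks_and_troughs") {
    tr <- local_maxima_idx(-y)
    tr <- tr[y[tr] < 0]
    idx <- sort(c(pk, tr))
  }
  if (!is.null(profile$prominence) && length(idx))
    idx <- idx[abs(y[idx]) >= profile$prominence]
  min_dist <- profile$min_interval_s * rec$sample_rate_hz
  idx <- sort(thin_by_distance(idx, abs(y[idx]), min_dist))
  event_series(rec$t[idx], profile$name, profile)
}

#' Per-epoch cadence from detected events
#'
#' Counts events in consecutive half-open epochs `[k e, (k+1) e)` covering
#' `[0, duration_s)` and converts counts to events per minute
#' (`count * 60 / epoch_s`). Events at or beyond `duration_s` are dropped.
#'
#' @param ev An [event_series] (or a numeric vector of event times).
#' @param epoch_s Epoch length in seconds.
#' @param duration_s Total covered duration; defaults to the last event time.
#' @return An object of class `cadence_series` with fields `epoch_starts_s`,
#'   `counts`, `cadence_per_min`, `epoch_s`, `duration_s`.
#' @export
cadence_series <- function(ev, epoch_s, duration_s = NULL) {
  times <- if (inherits(ev, "event_series")) ev$event_times_s else as.numeric(ev)
  if (!is.numeric(epoch_s) || epoch_s <= 0)
    stop_argument("epoch_s must be positive")
  if (is.null(duration_s))
    duration_s <- if (length(times)) max(times) + 1e-9 else epoch_s
  n_epochs <- as.integer(ceiling(duration_s / epoch_s - 1e-9))
  n_epochs <- max(n_epochs, 1L)
  starts <- (seq_len(n_epochs) - 1L) * epoch_s
  times <- times[times >= 0 & times < duration_s]
  counts <- tabulate(floor(times / epoch_s) + 1L, nbins = n_epochs)
  structure(list(epoch_starts_s = starts, counts = as.integer(counts),
                 cadence_per_min = counts * (60 / epoch_s),
                 epoch_s = epoch_s, duration_s = duration_s),
            class = "cadence_series")
}

#' @export
print.cadence_series <- function(x, ...) {
  cat(sprintf("<cadence_series> %d epochs of %g s, %d events, mean %.1f /min\n",
              length(x$counts), x$epoch_s, sum(x$counts),
              mean(x$cadence_per_min)))
  invisible(x)
}

#' @export
as.data.frame.cadence_series <- function(x, ...) {
  data.frame(epoch_start_s = x$epoch_starts_s, count = x$counts,
             cadence_per_min = x$cadence_per_min)
}

#' @export
plot.cadence_series <- function(x, ...) {
  graphics::plot(x$epoch_starts_s + x$epoch_s / 2, x$cadence_per_min,
                 type = "s", xlab = "time (s)", ylab = "cadence (events/min)",
                 ...)
  invisible(x)
}

#' Locate the five-strike video synchronisation signature
#'
#' The sensor is struck several times in view of the video camera before the
#' race, producing distinct spikes on the forward accelerometer axis. This
#' finds the first run of `n_taps` supra-threshold spikes (threshold on
#' |acc_x - median|, spikes separated by at least `min_gap_s`) and returns the
#' time of the last one, the anchor for aligning sensor and video clocks.
#'
#' @param rec An [imu_recording].
#' @param n_taps Number of strikes expected (default 5).
#' @param min_gap_s Minimum separation between distinct strikes (default 0.3 s).
#' @param threshold_g Spike threshold in g (default 4).
#' @return Sync time in seconds.
#' @export
detect_sync_taps <- function(rec, n_taps = 5, min_gap_s = 0.3,
                             threshold_g = 4) {
  validate_imu_recording(rec)
  x <- abs(rec$acc_x - stats::median(rec$acc_x))
  above <- which(x > threshold_g)
  if (!length(above))
    stop_detection(sprintf("found 0 spikes, expected %d", n_taps), found = 0L)
  gap_samples <- min_gap_s * rec$sample_rate_hz
  grp <- cumsum(c(1L, as.integer(diff(above) > gap_samples)))
  spike_t <- vapply(split(above, grp), function(ii) {
    rec$t[ii[which.max(x[ii])]]
  }, numeric(1))
  if (length(spike_t) < n_taps)
    stop_detection(sprintf("found %d spikes, expected %d",
                           length(spike_t), n_taps),
                   found = length(spike_t))
  unname(spike_t[n_taps])
}

#' Count-level accuracy of event detection
#'
#' `100 * (1 - |detected - truth| / truth)`, floored at zero.
#'
#' @param detected,truth Integer event counts; `truth` must be positive.
#' @return Percent accuracy.
#' @export
count_accuracy <- function(detected, truth) {
  if (!is.numeric(truth) || truth <= 0) stop_argument("truth must be > 0")
  max(0, 100 * (1 - abs(detected - truth) / truth))
}

#' RMSE between two per-epoch cadence series
#'
#' Root mean squared per-epoch difference in events/min. The two series must
#' share the same epoch grid. A final partial epoch (duration not a multiple
#' of the epoch length) is excluded, since its cadence extrapolates a short
#' count; totals elsewhere still include those events.
#'
#' @param detected,truth [cadence_series] objects on the same grid.
#' @return RMSE in events per minute.
#' @export
cadence_rmse <- function(detected, truth) {
  if (!inherits(detected, "cadence_series") || !inherits(truth, "cadence_series"))
    stop_argument("need two cadence_series")
  if (abs(detected$epoch_s - truth$epoch_s) > 1e-9 ||
      length(detected$counts) != length(truth$counts))
    stop_argument("cadence series are on different epoch grids")
  keep <- seq_along(detected$counts)
  n_full <- floor(detected$duration_s / detected$epoch_s + 1e-9)
  if (n_full >= 1 && n_full < length(keep)) keep <- seq_len(n_full)
  d <- detected$cadence_per_min[keep] - truth$cadence_per_min[keep]
  sqrt(mean(d^2))
}

#' Relative error of total event counts
#'
#' `100 * |detected - truth| / truth` percent; symmetric in sign.
#'
#' @param detected_total,truth_total Total event counts; `truth_total` > 0.
#' @return Percent relative error.
#' @export
relative_error <- function(detected_total, truth_total) {
  if (!is.numeric(truth_total) || truth_total <= 0)
    stop_argument("truth_total must be > 0")
  100 * abs(detected_total - truth_total) / truth_total
}
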