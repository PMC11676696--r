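#' Short-time Fourier transform configuration
#'
#' Defaults give 2.5 s windows (250 samples at 100 Hz) with no overlap, so an
#' even window yields `window_samples / 2 + 1` one-sided frequency bins per
#' channel — 126 bins at the defaults, 756 features per window over the six
#' inertial channels. A rectangular window (no taper) is used so the bin
#' count and hop arithmetic are exact.
#'
#' @param window_samples Window length in samples (default 250).
#' @param overlap_samples Overlap between consecutive windows (default 0).
#' @param sample_rate_hz Sampling rate (default 100).
#' @return An object of class `stft_config`.
#' @export
stft_config <- function(window_samples = 250L, overlap_samples = 0L,
                        sample_rate_hz = 100) {
  window_samples <- as.integer(window_samples)
  overlap_samples <- as.integer(overlap_samples)
  if (window_samples < 2L || window_samples %% 2L != 0L)
    stop_argument("window_samples must be an even integer >= 2")
  if (overlap_samples < 0L || overlap_samples >= window_samples)
    stop_argument("need 0 <= overlap_samples < window_samples")
  structure(list(window_samples = window_samples,
                 overlap_samples = overlap_samples,
                 sample_rate_hz = sample_rate_hz),
            class = "stft_config")
}

#' @export
print.stft_config <- function(x, ...) {
  cat(sprintf("<stft_config> %d-sample windows (%.2f s), overlap %d, %d bins/channel\n",
              x$window_samples, x$window_samples / x$sample_rate_hz,
              x$overlap_samples, x$window_samples / 2L + 1L))
  invisible(x)
}

stft_hop <- function(cfg) cfg$window_samples - cfg$overlap_samples

stft_n_windows <- function(n_samples, cfg) {
  if (n_samples < cfg$window_samples) 0L
  else (n_samples - cfg$window_samples) %/% stft_hop(cfg) + 1L
}

#' Per-window spectral-magnitude features
#'
#' Combines the six inertial channels, optionally band-pass pre-filters each
#' (zero phase, cycling band 2-3 Hz by default, matching the peak-counting
#' filter), and computes the one-sided magnitude spectrum of consecutive
#' windows. Each channel contributes `window/2 + 1` bins; features are
#' ordered channel-major (`acc_x_bin000 ...`).
#'
#' @param rec An [imu_recording].
#' @param cfg An [stft_config].
#' @param prefilter A [bandpass_spec] applied to every channel before the
#'   transform, or `NULL` to disable. The default follows the pipeline's
#'   text: the same 2-3 Hz filter as cycling peak counting.
#' @param channels Channels to include (default all six).
#' @return An object of class `feature_matrix`: list with `values`
#'   (windows x features matrix), `window_starts_s`, `channels`, `bin_hz`,
#'   `cfg`.
#' @export
stft_magnitudes <- function(rec, cfg = stft_config(),
                            prefilter = bandpass_spec(6, 2, 3, rec$sample_rate_hz),
                            channels = IMU_CHANNELS) {
  validate_imu_recording(rec)
  n <- length(rec$t)
  if (n < cfg$window_samples)
    stop_argument(sprintf("recording (%d samples) shorter than one window (%d)",
                          n, cfg$window_samples))
  hop <- stft_hop(cfg)
  n_win <- stft_n_windows(n, cfg)
  w <- cfg$window_samples
  n_bins <- w %/% 2L + 1L
  starts <- (seq_len(n_win) - 1L) * hop
  vals <- matrix(0, n_win, n_bins * length(channels))
  fnames <- character(n_bins * length(channels))
  for (ci in seq_along(channels)) {
    x <- rec[[channels[ci]]]
    if (!is.null(prefilter)) x <- apply_zero_phase(x, prefilter)
    seg <- matrix(0, w, n_win)
    for (k in seq_len(n_win)) seg[, k] <- x[starts[k] + seq_len(w)]
    spec <- Mod(stats::mvfft(seg))[seq_len(n_bins), , drop = FALSE]
    cols <- (ci - 1L) * n_bins + seq_len(n_bins)
    vals[, cols] <- t(spec)
    fnames[cols] <- sprintf("%s_bin%03d", channels[ci], seq_len(n_bins) - 1L)
  }
  colnames(vals) <- fnames
  structure(list(values = vals,
                 window_starts_s = starts / cfg$sample_rate_hz + rec$t[1],
                 channels = channels,
                 bin_hz = (seq_len(n_bins) - 1L) * cfg$sample_rate_hz / w,
                 cfg = cfg),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d windows x %d features (%d channels x %d bins)\n",
              nrow(x$values), ncol(x$values), length(x$channels),
              length(x$bin_hz)))
  invisible(x)
}

#' Fit a feature standardizer (z-scoring state)
#'
#' Stores the per-feature mean and (population) standard deviation of the
#' training windows, to be applied to any later matrix. Fitting on the
#' training split only keeps test and generalisation data out of the scaling.
#'
#' @param training A [feature_matrix] or plain matrix with >= 2 rows.
#' @return An object of class `feature_standardizer`.
#' @export
fit_standardizer <- function(training) {
  x <- if (inherits(training, "feature_matrix")) training$values else training
  if (is.null(dim(x)) || nrow(x) < 2L)
    stop_argument("need at least 2 training windows to fit a standardizer")
  mu <- colMeans(x)
  sd_ <- sqrt(colMeans(sweep(x, 2, mu)^2))
  structure(list(mean = mu, sd = sd_, n_features = ncol(x)),
            class = "feature_standardizer")
}

#' Apply a fitted standardizer
#'
#' Maps each feature to `(x - mean) / sd`; features that were constant in
#' training (sd = 0) map to 0 rather than dividing by zero.
#'
#' @param state A `feature_standardizer` from [fit_standardizer].
#' @param features A [feature_matrix] or plain matrix with matching columns.
#' @return Same type as `features`, standardized.
#' @export
apply_standardizer <- function(state, features) {
  is_fm <- inherits(features, "feature_matrix")
  x <- if (is_fm) features$values else features
  if (ncol(x) != state$n_features)
    stop_argument(sprintf("feature dimension %d does not match standardizer (%d)",
                          ncol(x), state$n_features))
  sd_safe <- ifelse(state$sd > 0, state$sd, 1)
  z <- sweep(sweep(x, 2, state$mean), 2, sd_safe, "/")
  z[, state$sd == 0] <- 0
  if (is_fm) { features$values <- z; features } else z
}

#' Align fine-step labels to STFT windows by majority vote
#'
#' Each window receives the most frequent label among the fine steps (0.1 s by
#' default) that fall inside its half-open span; `unlabelled` steps do not
#' vote, and a window whose steps are all unlabelled stays `unlabelled`. An
#' exact tie goes to the label occurring earliest within the window, a
#' deterministic rule independent of label ordering.
#'
#' @param fine Character vector of fine-step labels (see [fine_grain_labels]).
#' @param cfg An [stft_config].
#' @param step_s Fine step size in seconds (default 0.1).
#' @return Character vector, one label per STFT window.
#' @export
align_labels <- function(fine, cfg = stft_config(), step_s = 0.1) {
  if (!length(fine)) stop_argument("empty fine label sequence")
  n_samples <- as.integer(round(length(fine) * step_s * cfg$sample_rate_hz))
  n_win <- stft_n_windows(n_samples, cfg)
  hop <- stft_hop(cfg)
  out <- character(n_win)
  for (k in seq_len(n_win)) {
    t0 <- (k - 1L) * hop / cfg$sample_rate_hz
    t1 <- t0 + cfg$window_samples / cfg$sample_rate_hz
    i0 <- as.integer(floor(t0 / step_s + 1e-9)) + 1L
    i1 <- min(as.integer(ceiling(t1 / step_s - 1e-9)), length(fine))
    votes <- fine[i0:i1]
    votes <- votes[votes != UNLABELLED]
    if (!length(votes)) { out[k] <- UNLABELLED; next }
    counts <- table(factor(votes, levels = unique(votes)))
    out[k] <- names(counts)[which.max(counts)]
  }
  out
}
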