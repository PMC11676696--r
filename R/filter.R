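#' Band-pass filter specification
#'
#' Describes the Butterworth band-pass used throughout the pipeline: a
#' sixth-order band-pass (the order of the band-pass filter itself, not of an
#' underlying low-pass prototype) with 2-3 Hz cutoffs for cycling and running
#' and 0.5-1.4 Hz for the slower swimming cadence.
#'
#' @param order Even filter order of the band-pass realisation (default 6).
#' @param low_hz,high_hz Lower/upper cutoff frequencies in Hz.
#' @param sample_rate_hz Sampling rate in Hz.
#' @return An object of class `bandpass_spec`.
#' @export
bandpass_spec <- function(order = 6, low_hz, high_hz, sample_rate_hz = 100) {
  if (!is.numeric(order) || order < 2 || order %% 2 != 0)
    stop_argument("order must be an even integer >= 2")
  if (!(is.numeric(low_hz) && is.numeric(high_hz) &&
        low_hz > 0 && low_hz < high_hz && high_hz < sample_rate_hz / 2))
    stop_with("tricadence_design_error",
              sprintf("cutoffs must satisfy 0 < low (%g) < high (%g) < Nyquist (%g)",
                      low_hz, high_hz, sample_rate_hz / 2))
  structure(list(order = as.integer(order), low_hz = low_hz,
                 high_hz = high_hz, sample_rate_hz = sample_rate_hz),
            class = "bandpass_spec")
}

#' @export
print.bandpass_spec <- function(x, ...) {
  cat(sprintf("<bandpass_spec> order %d Butterworth, %g-%g Hz @ %g Hz\n",
              x$order, x$low_hz, x$high_hz, x$sample_rate_hz))
  invisible(x)
}

#' Design the digital Butterworth band-pass filter
#'
#' Returns the transfer-function coefficients of a maximally flat band-pass
#' of the stated order (r-signal's `butter(n)` band-pass has order 2n, so the
#' prototype order is `spec$order / 2`). The realisation is checked for
#' stability (all poles strictly inside the unit circle).
#'
#' @param spec A [bandpass_spec].
#' @return An object of class `bandpass_filter` with elements `b`, `a`, `spec`.
#' @export
design_bandpass <- function(spec) {
  if (!inherits(spec, "bandpass_spec")) stop_argument("need a bandpass_spec")
  w <- c(spec$low_hz, spec$high_hz) * 2 / spec$sample_rate_hz
  bt <- signal::butter(spec$order / 2L, w, type = "pass")
  poles <- polyroot(rev(bt$a))
  if (any(Mod(poles) >= 1))
    stop_with("tricadence_design_error",
              "designed filter is unstable at these cutoffs")
  structure(list(b = bt$b, a = bt$a, spec = spec), class = "bandpass_filter")
}

#' Frequency response magnitude of a designed filter
#'
#' Evaluates |H(e^{i 2 pi f / fs})| at the requested frequencies. For
#' zero-phase (forward-backward) application the effective magnitude is this
#' value squared.
#'
#' @param filt A `bandpass_filter` (or a [bandpass_spec], designed on the fly).
#' @param freq_hz Frequencies in Hz.
#' @return Numeric vector of gains.
#' @export
bandpass_gain <- function(filt, freq_hz) {
  if (inherits(filt, "bandpass_spec")) filt <- design_bandpass(filt)
  w <- 2 * pi * freq_hz / filt$spec$sample_rate_hz
  z <- exp(-1i * w)
  num <- vapply(z, function(zi) sum(filt$b * zi^(seq_along(filt$b) - 1)),
                complex(1))
  den <- vapply(z, function(zi) sum(filt$a * zi^(seq_along(filt$a) - 1)),
                complex(1))
  Mod(num / den)
}

#' Zero-phase band-pass filtering
#'
#' Applies the filter forward and backward so event times are not lagged
#' (event timestamps must line up with externally synchronised video). The
#' signal is extended by odd reflection at both ends before filtering to
#' suppress start-up transients; the pad spans three periods of the lower
#' cutoff, the slowest component the filter passes. Note the
#' forward-backward pass squares the magnitude response, sharpening the
#' effective roll-off beyond a single pass of the stated order.
#'
#' @param x Numeric signal; must be longer than 3 x filter order.
#' @param spec A [bandpass_spec] or designed `bandpass_filter`.
#' @return Filtered signal, same length as `x`.
#' @export
apply_zero_phase <- function(x, spec) {
  filt <- if (inherits(spec, "bandpass_filter")) spec else design_bandpass(spec)
  n <- length(x)
  if (n <= 3 * filt$spec$order)
    stop_argument(sprintf("signal too short (%d) for order-%d zero-phase filtering",
                          n, filt$spec$order))
  pad <- min(n - 1L,
             as.integer(round(3 * filt$spec$sample_rate_hz / filt$spec$low_hz)))
  head_pad <- 2 * x[1] - x[(pad + 1L):2L]
  tail_pad <- 2 * x[n] - x[(n - 1L):(n - pad)]
  ext <- c(head_pad, x, tail_pad)
  # start each pass in the steady state of a constant input equal to the
  # first sample, so large offsets (gravity) leave no start-up transient
  nb <- length(filt$b)
  dc_gain <- sum(filt$b) / sum(filt$a)
  run <- function(v) signal::filter(filt$b, filt$a, v,
                                    init.x = rep(v[1], nb - 1L),
                                    init.y = rep(v[1] * dc_gain, nb - 1L))
  y <- run(ext)
  y <- rev(run(rev(y)))
  as.numeric(y[(pad + 1L):(pad + n)])
}
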