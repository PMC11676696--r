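#' Cycling-task labels
#'
#' The recognised cycling tasks. `coasting` is riding without actively turning
#' the pedals for more than one second; shorter pedalling pauses are not
#' labelled as coasting, which the track validator enforces.
#' @export
TASK_LABELS <- c("in_saddle", "out_of_saddle", "coasting")

#' Sentinel for time outside any labelled interval
#' @export
UNLABELLED <- "unlabelled"

#' Ordered, non-overlapping cycling-task intervals
#'
#' Intervals are half-open `[start_s, end_s)`: a boundary instant belongs to
#' the later interval. Gaps between intervals are permitted and read back as
#' `unlabelled` when the track is rasterised.
#'
#' @param start_s,end_s Numeric vectors of interval bounds in seconds.
#' @param label Character vector of task labels (see [TASK_LABELS]).
#' @return An object of class `label_track`: a data.frame with columns
#'   `start_s`, `end_s`, `label`.
#' @export
label_track <- function(start_s = numeric(), end_s = numeric(),
                        label = character()) {
  df <- data.frame(start_s = as.numeric(start_s), end_s = as.numeric(end_s),
                   label = as.character(label), stringsAsFactors = FALSE)
  class(df) <- c("label_track", "data.frame")
  validate_label_track(df)
}

#' Validate a label track
#' @param track A `label_track`.
#' @return The track, invisibly, if valid.
#' @export
validate_label_track <- function(track) {
  if (!nrow(track)) return(invisible(track))
  bad <- setdiff(unique(track$label), TASK_LABELS)
  if (length(bad))
    stop_format(sprintf("unknown label(s): %s", paste(bad, collapse = ", ")))
  if (is.unsorted(track$start_s, strictly = FALSE))
    stop_validation("intervals not sorted by start time")
  if (any(track$end_s <= track$start_s))
    stop_validation("interval with end_s <= start_s")
  if (nrow(track) > 1L &&
      any(track$start_s[-1] < track$end_s[-nrow(track)] - 1e-9))
    stop_validation("overlapping intervals")
  coast <- track$label == "coasting"
  if (any(coast & (track$end_s - track$start_s) <= 1))
    stop_validation("coasting interval must last more than one second")
  invisible(track)
}

#' @export
print.label_track <- function(x, ...) {
  cat(sprintf("<label_track> %d interval(s), %.1f s labelled\n",
              nrow(x), sum(x$end_s - x$start_s)))
  if (nrow(x)) print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Read a cycling-task label track from CSV
#'
#' Expects a header `start_s,end_s,label`; unknown labels are rejected.
#'
#' @param path Path to the file.
#' @param delim Field delimiter.
#' @return A validated `label_track`.
#' @export
read_label_track <- function(path, delim = ",") {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  dt <- data.table::fread(path, sep = delim, header = TRUE,
                          data.table = FALSE)
  need <- c("start_s", "end_s", "label")
  missing <- setdiff(need, names(dt))
  if (length(missing))
    stop_format(sprintf("missing column(s): %s",
                        paste(missing, collapse = ", ")))
  label_track(dt$start_s, dt$end_s, dt$label)
}

#' Write a label track to CSV
#' @param track A `label_track`.
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_label_track <- function(track, path, delim = ",") {
  validate_label_track(track)
  ok <- tryCatch({
    data.table::fwrite(as.data.frame(track), path, sep = delim)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_io(sprintf("cannot write to %s", path))
  invisible(path)
}

#' Rasterise a label track to a fine label sequence
#'
#' Produces one label per step of `step_s` seconds over `[0, duration_s)`; the
#' label of step k is that of the interval containing time `k * step_s` under
#' the half-open convention (a boundary instant belongs to the later
#' interval). Steps outside every interval get [UNLABELLED].
#'
#' @param track A `label_track`.
#' @param step_s Step size in seconds (default 0.1).
#' @param duration_s Total span to rasterise.
#' @return Character vector of length `round(duration_s / step_s)`.
#' @export
fine_grain_labels <- function(track, step_s = 0.1, duration_s) {
  if (!is.numeric(step_s) || step_s <= 0)
    stop_argument("step_s must be positive")
  if (!is.numeric(duration_s) || duration_s < 0)
    stop_argument("duration_s must be non-negative")
  n <- round(duration_s / step_s)
  out <- rep(UNLABELLED, n)
  if (!nrow(track)) return(out)
  tk <- (seq_len(n) - 1L) * step_s
  for (i in seq_len(nrow(track))) {
    hit <- tk >= track$start_s[i] - 1e-9 & tk < track$end_s[i] - 1e-9
    out[hit] <- track$label[i]
  }
  out
}
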