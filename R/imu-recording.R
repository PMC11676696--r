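#' Trunk-IMU recording
#'
#' Container for a uniformly sampled six-channel inertial time series with an
#' optional 10 Hz GPS sub-track. Axis convention (fixed project-wide): x =
#' forward (direction of travel), y = mediolateral, z = vertical
#' (gravity-aligned at rest). Acceleration is stored in g, angular velocity in
#' degrees per second, matching the sensor ranges of a +/-16 g, +/-2000 deg/s
#' trunk unit.
#'
#' @param acc_x,acc_y,acc_z Numeric vectors, acceleration per axis in g.
#' @param gyr_x,gyr_y,gyr_z Numeric vectors, angular velocity per axis in deg/s.
#' @param sample_rate_hz Sampling rate in Hz (default 100).
#' @param t Optional time vector in seconds; defaults to a uniform grid from 0
#'   at `sample_rate_hz`.
#' @param gps Optional data.frame with columns `t`, `lat`, `lon` (decimal
#'   degrees), nominally at 10 Hz, with timestamps inside the recording span.
#' @param meta List of metadata (participant id, discipline tag, notes).
#' @return An object of class `imu_recording`.
#' @export
imu_recording <- function(acc_x, acc_y, acc_z, gyr_x, gyr_y, gyr_z,
                          sample_rate_hz = 100, t = NULL, gps = NULL,
                          meta = list()) {
  n <- length(acc_x)
  if (is.null(t)) t <- (seq_len(n) - 1L) / sample_rate_hz
  rec <- structure(
    list(sample_rate_hz = sample_rate_hz, t = as.numeric(t),
         acc_x = as.numeric(acc_x), acc_y = as.numeric(acc_y),
         acc_z = as.numeric(acc_z),
         gyr_x = as.numeric(gyr_x), gyr_y = as.numeric(gyr_y),
         gyr_z = as.numeric(gyr_z),
         gps = gps, meta = meta),
    class = "imu_recording")
  validate_imu_recording(rec)
}

ACC_RANGE_G <- 16
GYR_RANGE_DPS <- 2000
ACC_CHANNELS <- c("acc_x", "acc_y", "acc_z")
GYR_CHANNELS <- c("gyr_x", "gyr_y", "gyr_z")
IMU_CHANNELS <- c(ACC_CHANNELS, GYR_CHANNELS)

#' Validate an IMU recording against its invariants
#'
#' Checks channel lengths, uniform strictly increasing time (spacing within
#' 1e-6 s of 1/sample_rate), sensor ranges and GPS timestamp containment.
#' Errors (class `tricadence_validation_error`) name the offending row.
#'
#' @param rec An `imu_recording`.
#' @return The recording, invisibly unchanged, if valid.
#' @export
validate_imu_recording <- function(rec) {
  n <- length(rec$t)
  if (n < 1L) stop_validation("recording has no samples")
  for (ch in IMU_CHANNELS) {
    if (length(rec[[ch]]) != n)
      stop_validation(sprintf("channel '%s' has length %d, expected %d",
                              ch, length(rec[[ch]]), n))
  }
  if (!is.numeric(rec$sample_rate_hz) || rec$sample_rate_hz <= 0)
    stop_validation("sample_rate_hz must be a positive number")
  if (n > 1L) {
    dt <- diff(rec$t)
    expected <- 1 / rec$sample_rate_hz
    bad <- which(abs(dt - expected) > 1e-6)
    if (any(dt <= 0))
      stop_validation(sprintf("time not strictly increasing at row %d",
                              which(dt <= 0)[1] + 1L))
    if (length(bad))
      stop_validation(sprintf(
        "non-uniform time spacing at row %d (%.8f s, expected %.8f s)",
        bad[1] + 1L, dt[bad[1]], expected))
  }
  for (ch in ACC_CHANNELS) {
    bad <- which(abs(rec[[ch]]) > ACC_RANGE_G)
    if (length(bad))
      stop_validation(sprintf("%s out of range [-16, 16] g at row %d",
                              ch, bad[1]))
  }
  for (ch in GYR_CHANNELS) {
    bad <- which(abs(rec[[ch]]) > GYR_RANGE_DPS)
    if (length(bad))
      stop_validation(sprintf("%s out of range [-2000, 2000] deg/s at row %d",
                              ch, bad[1]))
  }
  if (!is.null(rec$gps)) {
    gps <- rec$gps
    if (!all(c("t", "lat", "lon") %in% names(gps)))
      stop_format("gps sub-track needs columns t, lat, lon")
    if (nrow(gps) && (min(gps$t) < rec$t[1] - 1e-9 ||
                      max(gps$t) > rec$t[n] + 1e-9))
      stop_validation("gps timestamps outside recording span")
  }
  invisible(rec)
}

#' @export
print.imu_recording <- function(x, ...) {
  n <- length(x$t)
  cat(sprintf("<imu_recording> %d samples @ %g Hz (%.1f s)\n",
              n, x$sample_rate_hz, if (n) x$t[n] - x$t[1] + 1 / x$sample_rate_hz else 0))
  if (!is.null(x$gps)) cat(sprintf("  gps: %d fixes\n", nrow(x$gps)))
  if (length(x$meta)) {
    keep <- vapply(x$meta, function(v) is.atomic(v) && length(v) == 1, TRUE)
    if (any(keep))
      cat("  meta:", paste(names(x$meta)[keep], unlist(x$meta[keep]),
                           sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Recording duration in seconds
#' @param rec An `imu_recording`.
#' @return Duration in seconds (n / sample rate).
#' @export
rec_duration <- function(rec) length(rec$t) / rec$sample_rate_hz

#' Read an IMU recording from a delimited text table
#'
#' The table must have a header row naming columns
#' `t, acc_x, acc_y, acc_z, gyr_x, gyr_y, gyr_z`, optionally followed by
#' `lat, lon`. GPS rows are those with non-missing `lat`; all other rows leave
#' lat/lon empty. The sample rate is inferred from the time grid unless given.
#'
#' @param path Path to the file.
#' @param delim Field delimiter, `","` (default) or `"\t"`.
#' @param sample_rate_hz Optional explicit sample rate; inferred from the
#'   median time step when `NULL`.
#' @param meta Metadata list attached to the recording.
#' @return A validated `imu_recording`.
#' @export
read_imu_table <- function(path, delim = ",", sample_rate_hz = NULL,
                           meta = list()) {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  dt <- data.table::fread(path, sep = delim, header = TRUE,
                          data.table = FALSE)
  need <- c("t", IMU_CHANNELS)
  missing <- setdiff(need, names(dt))
  if (length(missing))
    stop_format(sprintf("missing column(s): %s",
                        paste(missing, collapse = ", ")))
  gps <- NULL
  if (all(c("lat", "lon") %in% names(dt))) {
    keep <- !is.na(dt$lat) & !is.na(dt$lon)
    if (any(keep))
      gps <- data.frame(t = dt$t[keep], lat = dt$lat[keep], lon = dt$lon[keep])
  }
  if (is.null(sample_rate_hz)) {
    if (nrow(dt) < 2L) sample_rate_hz <- 100
    else sample_rate_hz <- 1 / stats::median(diff(dt$t))
  }
  imu_recording(dt$acc_x, dt$acc_y, dt$acc_z,
                dt$gyr_x, dt$gyr_y, dt$gyr_z,
                sample_rate_hz = sample_rate_hz, t = dt$t, gps = gps,
                meta = meta)
}

#' Write an IMU recording to a delimited text table
#'
#' Columns are written in the fixed order
#' `t, acc_x, acc_y, acc_z, gyr_x, gyr_y, gyr_z[, lat, lon]`; values keep full
#' double precision so a read/write round trip is lossless well below 1e-9.
#' A GPS sub-track is stored inline: fixes are matched to the nearest inertial
#' sample row (within half a sample), other rows get empty lat/lon. Fixes that
#' do not land on the sample grid are written to a side file `<path>` with
#' suffix `_gps`.
#'
#' @param rec An `imu_recording`.
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_imu_table <- function(rec, path, delim = ",") {
  validate_imu_recording(rec)
  df <- data.frame(t = rec$t, acc_x = rec$acc_x, acc_y = rec$acc_y,
                   acc_z = rec$acc_z, gyr_x = rec$gyr_x, gyr_y = rec$gyr_y,
                   gyr_z = rec$gyr_z)
  if (!is.null(rec$gps) && nrow(rec$gps)) {
    idx <- round((rec$gps$t - rec$t[1]) * rec$sample_rate_hz) + 1L
    on_grid <- idx >= 1L & idx <= nrow(df) &
      abs(rec$t[pmin(pmax(idx, 1L), nrow(df))] - rec$gps$t) <
      0.5 / rec$sample_rate_hz
    if (all(on_grid)) {
      df$lat <- NA_real_; df$lon <- NA_real_
      df$lat[idx] <- rec$gps$lat
      df$lon[idx] <- rec$gps$lon
    } else {
      side <- sub("(\\.[^.]+)?$", "_gps\\1", path)
      data.table::fwrite(rec$gps, side, sep = delim)
    }
  }
  ok <- tryCatch({
    data.table::fwrite(df, path, sep = delim, na = "")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_io(sprintf("cannot write to %s", path))
  invisible(path)
}
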