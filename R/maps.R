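# Map-style exports: GeoJSON FeatureCollections of styled LineStrings, a
# diff-able artifact that any web map can render. Colour scheme is fixed:
# red = out_of_saddle, green = in_saddle, grey = coasting / unlabelled.

TASK_COLOURS <- c(in_saddle = "#1a9641", out_of_saddle = "#d7191c",
                  coasting = "#808080", unlabelled = "#808080")

geojson_feature <- function(coords, properties) {
  list(type = "Feature",
       properties = properties,
       geometry = list(type = "LineString",
                       coordinates = coords))
}

write_geojson <- function(features, path) {
  fc <- list(type = "FeatureCollection", features = features)
  ok <- tryCatch({
    jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_io(sprintf("cannot write to %s", path))
  invisible(path)
}

gps_in_span <- function(gps, start_s, end_s) {
  keep <- gps$t >= start_s - 1e-9 & gps$t < end_s - 1e-9
  unname(lapply(which(keep), function(i) c(gps$lon[i], gps$lat[i])))
}

#' Export a cycling-task map as GeoJSON
#'
#' Writes one LineString per task interval, coloured red (out-of-saddle),
#' green (in-saddle) or grey (coasting), carrying `label`, `start_s`,
#' `end_s` and `duration_s` properties. An empty track produces a single
#' grey `unlabelled` segment spanning the whole GPS trace. The segment
#' coordinates are exactly the GPS fixes whose timestamps fall inside each
#' interval's half-open time span.
#'
#' @param gps GPS sub-track data.frame `t, lat, lon` (time-aligned with the
#'   label track) or an [imu_recording] carrying one.
#' @param track A [label_track].
#' @param path Output path (`.geojson`).
#' @return `path`, invisibly.
#' @export
export_task_map <- function(gps, track, path) {
  if (inherits(gps, "imu_recording")) gps <- gps$gps
  if (is.null(gps) || !nrow(gps))
    stop_with("tricadence_export_error", "no GPS sub-track to map")
  if (!nrow(track)) {
    feat <- list(geojson_feature(
      gps_in_span(gps, min(gps$t), max(gps$t) + 1),
      list(label = UNLABELLED, start_s = min(gps$t), end_s = max(gps$t),
           duration_s = max(gps$t) - min(gps$t),
           stroke = unname(TASK_COLOURS[UNLABELLED]))))
    return(write_geojson(feat, path))
  }
  feats <- lapply(seq_len(nrow(track)), function(i) {
    geojson_feature(
      gps_in_span(gps, track$start_s[i], track$end_s[i]),
      list(label = track$label[i], start_s = track$start_s[i],
           end_s = track$end_s[i],
           duration_s = track$end_s[i] - track$start_s[i],
           stroke = unname(TASK_COLOURS[track$label[i]])))
  })
  write_geojson(feats, path)
}

#' Export a rolling-cadence map as GeoJSON
#'
#' Splits the session into intervals of `interval_s` (a multiple of the
#' cadence epoch), draws each as an alternating-colour LineString and
#' annotates it with the event count in that interval and a trailing simple
#' moving average of cadence over `rolling_window` intervals.
#'
#' @param gps GPS sub-track data.frame `t, lat, lon` or an [imu_recording].
#' @param cadence A [cadence_series].
#' @param interval_s Map interval length in seconds; must be a positive
#'   multiple of the cadence epoch.
#' @param rolling_window Number of trailing intervals in the moving average
#'   (default 3; shorter at the start of the session).
#' @param path Output path (`.geojson`).
#' @return `path`, invisibly.
#' @export
export_cadence_map <- function(gps, cadence, interval_s,
                               rolling_window = 3L, path) {
  if (inherits(gps, "imu_recording")) gps <- gps$gps
  if (is.null(gps) || !nrow(gps))
    stop_with("tricadence_export_error", "no GPS sub-track to map")
  if (!inherits(cadence, "cadence_series"))
    stop_argument("cadence must be a cadence_series")
  ratio <- interval_s / cadence$epoch_s
  if (interval_s <= 0 || abs(ratio - round(ratio)) > 1e-9)
    stop_argument("interval_s must be a positive multiple of the cadence epoch")
  ratio <- as.integer(round(ratio))
  n_int <- as.integer(ceiling(cadence$duration_s / interval_s - 1e-9))
  grp <- rep(seq_len(n_int), each = ratio)[seq_along(cadence$counts)]
  counts <- as.integer(tapply(cadence$counts, grp, sum))
  cad <- counts * 60 / interval_s
  roll <- vapply(seq_len(n_int), function(i) {
    mean(cad[max(1L, i - rolling_window + 1L):i])
  }, numeric(1))
  palette <- c("#1a9641", "#2b83ba")  # alternating green / blue
  feats <- lapply(seq_len(n_int), function(i) {
    t0 <- (i - 1L) * interval_s
    geojson_feature(
      gps_in_span(gps, t0, t0 + interval_s),
      list(interval = i, start_s = t0, end_s = t0 + interval_s,
           count = counts[i], cadence_per_min = cad[i],
           rolling_cadence_per_min = roll[i],
           stroke = palette[(i - 1L) %% 2L + 1L]))
  })
  write_geojson(feats, path)
}
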