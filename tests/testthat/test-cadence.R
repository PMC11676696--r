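test_that("detect_events counts sinusoid extrema analytically", {
  # flat signal: no events, not an error
  flat <- sinusoid_recording(1, 30, amplitude = 0)
  expect_length(detect_events(flat, discipline_profile("swim"))$event_times_s,
                0L)

  # 1 Hz roll, swim profile (peaks and troughs): 2 extrema per cycle
  swim <- sinusoid_recording(1, 60, channel = "acc_y")
  n_swim <- length(detect_events(swim, discipline_profile("swim"))$event_times_s)
  expect_lte(abs(n_swim - 120), 1)

  # 2.8 Hz vertical, run profile (peaks only): 1 peak per cycle
  run <- sinusoid_recording(2.8, 60, channel = "acc_z")
  n_run <- length(detect_events(run, discipline_profile("run"))$event_times_s)
  expect_lte(abs(n_run - 168), 1)

  expect_error(detect_events(sinusoid_recording(2.8, 0.4),
                             discipline_profile("run")),
               class = "tricadence_argument_error")
})

test_that("analytic extremum counts hold across durations", {
  for (dur in c(10, 60, 300)) {
    rec <- sinusoid_recording(2.5, dur, channel = "acc_z")
    n <- length(detect_events(rec, discipline_profile("cycle"))$event_times_s)
    expect_lte(abs(n - floor(2.5 * dur)), 1)
  }
})

test_that("event spacing respects the minimum interval on noisy input", {
  for (seed in 1:5) {
    set.seed(seed)
    rec <- imu_recording(rnorm(3000, 0, 0.5), rnorm(3000, 0, 0.5),
                         rnorm(3000, 0, 0.5), rnorm(3000, 0, 50),
                         rnorm(3000, 0, 50), rnorm(3000, 0, 50))
    for (d in c("swim", "cycle", "run")) {
      prof <- discipline_profile(d)
      ev <- detect_events(rec, prof)$event_times_s
      if (length(ev) > 1)
        expect_gte(min(diff(ev)), prof$min_interval_s - 1e-9)
    }
  }
})

test_that("cadence_series bins events half-open and conserves them", {
  ev <- event_series(seq(0.25, 59.75, by = 0.5), "run")
  cs <- cadence_series(ev, 10, 60)
  expect_equal(cs$counts, rep(20L, 6))
  expect_equal(cs$cadence_per_min, rep(120, 6))

  empty <- cadence_series(event_series(numeric(), "run"), 10, 60)
  expect_equal(empty$counts, rep(0L, 6))

  # half-open binning: events at 0 and 10 land in different epochs
  cs2 <- cadence_series(event_series(c(0, 10), "run"), 10, 20)
  expect_equal(cs2$counts, c(1L, 1L))

  # conservation over random event sets
  for (seed in 1:5) {
    set.seed(seed)
    times <- sort(runif(200, 0, 97))
    cs3 <- cadence_series(times, 7, 97)
    expect_equal(sum(cs3$counts), sum(times >= 0 & times < 97))
  }
  expect_error(cadence_series(ev, -1), class = "tricadence_argument_error")
})

test_that("sync-tap detection anchors on the last of five strikes", {
  n <- 800
  acc_x <- rnorm(n, 0, 0.1)
  for (tap in 1:5) acc_x[tap * 100 + 1] <- 8
  rec <- imu_recording(acc_x, numeric(n), numeric(n),
                       numeric(n), numeric(n), numeric(n))
  expect_lt(abs(detect_sync_taps(rec) - 5.0), 0.02)

  quiet <- imu_recording(numeric(n), numeric(n), numeric(n),
                         numeric(n), numeric(n), numeric(n))
  err <- tryCatch(detect_sync_taps(quiet), condition = identity)
  expect_s3_class(err, "tricadence_detection_error")
  expect_match(conditionMessage(err), "0 spikes")

  acc3 <- numeric(n); acc3[c(101, 201, 301)] <- 8
  rec3 <- imu_recording(acc3, numeric(n), numeric(n),
                        numeric(n), numeric(n), numeric(n))
  err3 <- tryCatch(detect_sync_taps(rec3), condition = identity)
  expect_match(conditionMessage(err3), "3 spikes")
})

test_that("count metrics match their closed forms", {
  expect_equal(count_accuracy(341, 341), 100)
  expect_equal(count_accuracy(338, 341), 100 * (1 - 3 / 341))
  expect_equal(round(count_accuracy(338, 341), 2), 99.12)
  expect_equal(count_accuracy(0, 341), 0)    # floored, not negative
  expect_equal(count_accuracy(700, 341), 0)
  expect_error(count_accuracy(10, 0), class = "tricadence_argument_error")

  expect_equal(relative_error(1000, 1000), 0)
  expect_equal(relative_error(1030, 1000), 3.0)
  expect_equal(relative_error(970, 1000), 3.0)  # symmetric
  expect_error(relative_error(10, 0), class = "tricadence_argument_error")
})

test_that("cadence RMSE compares per-epoch series on a shared grid", {
  a <- cadence_series(seq(0.25, 179.75, by = 0.5), 60, 180)
  expect_equal(cadence_rmse(a, a), 0)

  mk <- function(counts) structure(
    list(epoch_starts_s = c(0, 60, 120), counts = counts,
         cadence_per_min = counts, epoch_s = 60, duration_s = 180),
    class = "cadence_series")
  # constant offset of 2 events per 60 s epoch -> RMSE 2 events/min
  expect_equal(cadence_rmse(mk(c(122, 118, 121)), mk(c(120, 116, 119))), 2)
  # hand-computed: differences (3, -4, 0) -> sqrt(25/3)
  expect_equal(cadence_rmse(mk(c(63, 56, 70)), mk(c(60, 60, 70))),
               sqrt(25 / 3))
  # a final partial epoch is excluded from the RMSE
  mk4 <- function(counts, dur) structure(
    list(epoch_starts_s = c(0, 60, 120, 180), counts = counts,
         cadence_per_min = counts, epoch_s = 60, duration_s = dur),
    class = "cadence_series")
  expect_equal(cadence_rmse(mk4(c(63, 56, 70, 99), 190),
                            mk4(c(60, 60, 70, 1), 190)),
               sqrt(25 / 3))

  mismatched <- cadence_series(1:10, 30, 300)
  expect_error(cadence_rmse(a, mismatched),
               class = "tricadence_argument_error")
})
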