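test_that("discipline simulation has exact, seeded ground truth", {
  spec <- synthetic_session_spec("run", duration_s = 60, cadence_per_min = 172,
                                 noise_sd = 0, seed = 4)
  sim <- simulate_discipline(spec)
  expect_equal(sim$truth$n_events, 172L)

  # determinism: same spec and seed -> bit-identical recordings
  sim2 <- simulate_discipline(spec)
  expect_identical(sim$recording$acc_z, sim2$recording$acc_z)
  expect_identical(sim$recording$gyr_x, sim2$recording$gyr_x)

  # every generated recording satisfies the container invariants
  for (d in c("swim", "cycle", "run")) {
    s <- simulate_discipline(synthetic_session_spec(d, duration_s = 30,
                                                    seed = 7))
    expect_s3_class(validate_imu_recording(s$recording), "imu_recording")
    # swim: stroke count is cadence * minutes (peaks + troughs of the roll)
    expected <- s$truth$cadence_per_min * 30 / 60
    expect_lte(abs(s$truth$n_events - expected), 1)
  }
  expect_error(simulate_discipline(
    synthetic_session_spec("run", duration_s = -5)),
    class = "tricadence_argument_error")
})

test_that("the peak counter recovers generated cadence across the range", {
  # cadences spanning slow swimming to fast running, default noise
  cases <- list(list("swim", 60), list("swim", 85), list("cycle", 120),
                list("cycle", 157.5), list("run", 172), list("run", 190))
  for (cs in cases) {
    sim <- simulate_discipline(synthetic_session_spec(
      cs[[1]], duration_s = 120, cadence_per_min = cs[[2]], seed = 11))
    ev <- detect_events(sim$recording, discipline_profile(cs[[1]]))
    recovered <- length(ev$event_times_s) / 2  # events per minute over 2 min
    expect_lte(abs(recovered - cs[[2]]) / cs[[2]], 0.02)
  }
})

test_that("detection recovers nearly all ground-truth events at default noise", {
  sim <- simulate_discipline(synthetic_session_spec("run", duration_s = 300,
                                                    seed = 2))
  ev <- detect_events(sim$recording, discipline_profile("run"))
  expect_gte(length(ev$event_times_s) / sim$truth$n_events, 0.99)
})

test_that("scheduled cycling sessions mirror their schedule exactly", {
  sched <- schedule_balanced(20, 20)  # 60 blocks of 20 s
  spec <- synthetic_session_spec("cycle", duration_s = sum(sched$duration_s),
                                 task_schedule = sched, seed = 3)
  sim <- simulate_cycling_session(spec)
  tr <- sim$truth$label_track
  expect_equal(nrow(tr), 60L)
  expect_equal(sum(tr$end_s - tr$start_s), 1200)
  expect_equal(tr$label, sched$label)

  # coasting blocks contain no ground-truth pedal events
  coast <- tr[tr$label == "coasting", ]
  for (i in seq_len(nrow(coast))) {
    in_block <- sim$truth$event_times_s >= coast$start_s[i] &
      sim$truth$event_times_s < coast$end_s[i]
    expect_equal(sum(in_block), 0L)
  }

  # schedule must be consistent with the stated duration
  expect_error(synthetic_session_spec("cycle", duration_s = 100,
                                      task_schedule = sched),
               class = "tricadence_argument_error")
  expect_error(synthetic_session_spec("run", duration_s = 1200,
                                      task_schedule = sched),
               class = "tricadence_argument_error")
})

test_that("out-of-saddle rocking dominates the mediolateral low band", {
  sched <- data.frame(duration_s = c(20, 20), label = c("in_saddle",
                                                        "out_of_saddle"))
  sim <- simulate_cycling_session(synthetic_session_spec(
    "cycle", duration_s = 40, task_schedule = sched, seed = 6))
  band_power <- function(x) {
    p <- Mod(stats::fft(x))^2
    f <- (seq_along(p) - 1) * 100 / length(p)
    mean(p[f >= 0.5 & f <= 2])
  }
  p_in <- band_power(sim$recording$acc_y[1:2000])
  p_out <- band_power(sim$recording$acc_y[2001:4000])
  expect_gte(p_out / p_in, 4)
})

test_that("race and balanced schedules reproduce the class-balance contrast", {
  set.seed(8)
  race <- schedule_race(1200)
  frac_in <- sum(race$duration_s[race$label == "in_saddle"]) /
    sum(race$duration_s)
  expect_gt(frac_in, 0.88)
  expect_lt(frac_in, 0.95)
  # short efforts stay in the 2-4 s band
  efforts <- race$duration_s[race$label == "out_of_saddle"]
  expect_true(all(efforts >= 2 & efforts <= 4))

  bal <- schedule_balanced(20, 10)
  frac_bal <- sum(bal$duration_s[bal$label == "in_saddle"]) /
    sum(bal$duration_s)
  expect_equal(frac_bal, 1 / 3)
})

test_that("GPS tracks follow the course at the requested speed", {
  skip_if_not_installed("geosphere")
  # constant speed, no jitter: constant inter-fix distance
  g <- simulate_gps_track(60, "rectangle", speed_mps = 10, jitter_m = 0)
  d <- geosphere::distHaversine(cbind(g$lon[-nrow(g)], g$lat[-nrow(g)]),
                                cbind(g$lon[-1], g$lat[-1]))
  straight <- d[d < 1.5]  # drop corner fixes where the path turns
  expect_lt(diff(range(straight)) / mean(straight), 1e-3)

  # haversine path length within 1% of speed * duration
  g2 <- simulate_gps_track(500, "rectangle", speed_mps = 10, jitter_m = 0)
  d2 <- geosphere::distHaversine(cbind(g2$lon[-nrow(g2)], g2$lat[-nrow(g2)]),
                                 cbind(g2$lon[-1], g2$lat[-1]))
  expect_lt(abs(sum(d2) - 10 * 500) / (10 * 500), 0.01)

  # lap closure: a full 5 km lap at 10 m/s returns near the start
  g3 <- simulate_gps_track(500.1, "rectangle", speed_mps = 10, jitter_m = 0)
  last <- nrow(g3)
  expect_lt(geosphere::distHaversine(c(g3$lon[1], g3$lat[1]),
                                     c(g3$lon[last], g3$lat[last])), 2)
  expect_error(simulate_gps_track(-1), class = "tricadence_argument_error")
})
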