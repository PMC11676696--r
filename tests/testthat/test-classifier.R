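make_sessions <- function(n_participants = 4, n_windows = 50, seed = 5) {
  set.seed(seed)
  sessions <- list()
  for (i in seq_len(n_participants)) {
    lab <- sample(c("in_saddle", "out_of_saddle"), n_windows, TRUE)
    x <- matrix(rnorm(n_windows * 8), n_windows, 8)
    sessions[[paste0("P", i)]] <- list(features = x, labels = lab)
  }
  sessions
}

test_that("split_holdout partitions windows without leakage", {
  sessions <- make_sessions(4, 50)
  sp <- split_holdout(sessions, c("P1", "P2"), seed = 9)
  total <- sum(vapply(sessions, function(s) nrow(s$features), 1))
  expect_equal(nrow(sp$train$x) + nrow(sp$test$x) + nrow(sp$general$x), total)
  # excluded participants contribute nothing to train or test
  expect_false(any(c("P3", "P4") %in% c(sp$train$participant,
                                        sp$test$participant)))
  expect_setequal(unique(sp$general$participant), c("P3", "P4"))
  expect_error(split_holdout(sessions, character()),
               class = "tricadence_argument_error")

  # 100 windows from training participants -> exactly 80 / 20
  s100 <- make_sessions(1, 100)
  sp100 <- split_holdout(s100, "P1", seed = 2)
  expect_equal(nrow(sp100$train$x), 80L)
  expect_equal(nrow(sp100$test$x), 20L)

  # partition property over randomised collections
  for (seed in 1:4) {
    sc <- make_sessions(3, 17 + seed * 13, seed = seed)
    spx <- split_holdout(sc, c("P1", "P3"), seed = seed)
    expect_equal(nrow(spx$train$x) + nrow(spx$test$x) + nrow(spx$general$x),
                 sum(vapply(sc, function(s) nrow(s$features), 1)))
  }
})

test_that("the model separates spectrally distinct classes and is deterministic", {
  # two synthetic riders: spectrally separated regimes via the generator
  r1 <- make_rider(1, "balanced", duration_s = 300)
  r2 <- make_rider(2, "balanced", duration_s = 300)
  sessions <- list(P1 = r1, P2 = r2)
  sp <- split_holdout(sessions, c("P1", "P2"), seed = 1)
  m <- task_model(sp$train$x, sp$train$y, seed = 1)

  keep <- sp$train$y != "unlabelled"
  train_acc <- mean(predict(m, sp$train$x[keep, , drop = FALSE]) ==
                      sp$train$y[keep])
  expect_equal(train_acc, 1)

  # determinism: same data and seed -> identical predictions
  m2 <- task_model(sp$train$x, sp$train$y, seed = 1)
  expect_identical(predict(m, sp$test$x), predict(m2, sp$test$x))

  # single-class data cannot be fit
  expect_error(task_model(sp$train$x, rep("in_saddle", nrow(sp$train$x))),
               class = "tricadence_training_error")

  # model bundle round-trips through a file
  path <- withr::local_tempfile(fileext = ".rds")
  save_task_model(m, path)
  m3 <- load_task_model(path)
  expect_identical(predict(m, sp$test$x), predict(m3, sp$test$x))
  expect_identical(m3$classes, m$classes)
})

test_that("permuted labels drop held-out accuracy to the majority rate", {
  r1 <- make_rider(3, "balanced", duration_s = 300)
  r2 <- make_rider(4, "balanced", duration_s = 300)  # held-out rider
  set.seed(99)
  y_perm <- sample(r1$labels)
  m <- task_model(r1$features, y_perm, seed = 1)
  acc <- 100 * mean(predict(m, r2$features) == r2$labels)
  majority <- 100 * max(table(r2$labels)) / length(r2$labels)
  expect_lte(abs(acc - majority), 10)
})

test_that("merge_windows run-length encodes window labels", {
  cfg <- stft_config()
  tr <- merge_windows(c("in_saddle", "in_saddle", "out_of_saddle",
                        "out_of_saddle", "in_saddle"), cfg)
  expect_equal(tr$start_s, c(0, 5, 10))
  expect_equal(tr$end_s, c(5, 10, 12.5))
  expect_equal(tr$label, c("in_saddle", "out_of_saddle", "in_saddle"))

  one <- merge_windows(rep("coasting", 8), cfg)
  expect_equal(nrow(one), 1L)
  expect_equal(one$end_s - one$start_s, 20)

  alt <- merge_windows(rep(c("in_saddle", "out_of_saddle"), 5), cfg)
  expect_equal(nrow(alt), 10L)
  expect_true(all(alt$end_s - alt$start_s == 2.5))

  # unlabelled runs become gaps
  gap <- merge_windows(c("in_saddle", "unlabelled", "coasting"), cfg)
  expect_equal(gap$label, c("in_saddle", "coasting"))
  expect_equal(nrow(merge_windows(character(), cfg)), 0L)
})

test_that("binary confusion report satisfies its identities", {
  perfect <- evaluate_binary(rep(c("in_saddle", "out_of_saddle"), 10),
                             rep(c("in_saddle", "out_of_saddle"), 10))
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)

  blind <- evaluate_binary(rep("in_saddle", 4),
                           c("in_saddle", "out_of_saddle",
                             "in_saddle", "in_saddle"))
  expect_equal(blind$sensitivity, 0)

  # tp=42 fn=58 tn=96 fp=4
  truth <- c(rep("out_of_saddle", 100), rep("in_saddle", 100))
  pred <- c(rep("out_of_saddle", 42), rep("in_saddle", 58),
            rep("in_saddle", 96), rep("out_of_saddle", 4))
  rep_ <- evaluate_binary(pred, truth)
  expect_equal(rep_$sensitivity, 42)
  expect_equal(rep_$specificity, 96)
  expect_equal(rep_$accuracy, 69)
  expect_equal(rep_$tp + rep_$fp + rep_$tn + rep_$fn, rep_$total)

  # coasting truth windows are excluded from the binary report
  with_coast <- evaluate_binary(c(pred, rep("in_saddle", 7)),
                                c(truth, rep("coasting", 7)))
  expect_equal(with_coast$total, 200)

  expect_error(evaluate_binary("in_saddle", character()),
               class = "tricadence_argument_error")
})
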