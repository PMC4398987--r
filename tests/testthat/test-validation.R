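test_that("safe thresholds keep all true detections with a minimal subset", {
  r <- estimate_safe_threshold(c(0.1, 0.3), c(0.2, 0.9), "reject_above", 0.1)
  expect_equal(r$threshold, 0.3)
  expect_equal(r$n_fp_rejected, 1L)     # 0.9 rejected, 0.2 kept
  # all FP beyond all TP: every FP rejected
  r2 <- estimate_safe_threshold(c(0.1, 0.2), c(0.5, 0.8), "reject_above", 0.05)
  expect_equal(r2$n_fp_rejected, 2L)
  # empty FP list: threshold at the extremal TP grid value, zero rejections
  r3 <- estimate_safe_threshold(c(0.15, 0.35), orientation = "reject_above",
                                step = 0.05)
  expect_equal(r3$threshold, 0.35)
  expect_equal(r3$n_fp_rejected, 0L)
  # reject_below walks down to the largest grid value at or below min(TP)
  r4 <- estimate_safe_threshold(c(7, 12), c(2, 9), "reject_below", step = 2)
  expect_equal(r4$threshold, 6)
  expect_equal(r4$n_fp_rejected, 1L)    # 2 rejected, 9 kept
  expect_error(estimate_safe_threshold(numeric(), 1, "reject_above", 0.1),
               "non-empty")
  expect_error(estimate_safe_threshold(1, 1, "reject_above", 0), "positive")
})

test_that("validation combines per-feature decisions with logical AND", {
  ft <- data.frame(track_id = 1:3, duration = c(20, 20, 20),
                   instability = c(0, 0, 0), shape_change = c(0.2, 0.2, 0.2),
                   edge_density = c(0.1, 0.9, 0.1),
                   texture_variation = c(0.05, 0.05, 0.5))
  rules <- list(
    estimate_safe_threshold(20, orientation = "reject_below", step = 1,
                            feature = "duration"),
    estimate_safe_threshold(0.3, orientation = "reject_above", step = 0.01,
                            feature = "shape_change"),
    estimate_safe_threshold(0.2, orientation = "reject_above", step = 0.01,
                            feature = "edge_density"),
    estimate_safe_threshold(0.1, orientation = "reject_above", step = 0.01,
                            feature = "texture_variation"))
  expect_equal(validate_tracks(ft, rules), c(TRUE, FALSE, FALSE))
  expect_true(validate_track(ft[1, ], rules))
  # a single failing feature rejects the track; empty rules accept all
  expect_equal(validate_tracks(ft, list()), rep(TRUE, 3))
  expect_error(validate_tracks(ft[, -5],
                               rules[3]), "edge_density")
  # ties at the threshold pass (strict rejection)
  at <- ft[1, ]; at$edge_density <- 0.2
  expect_true(validate_track(at, rules))
})

test_that("tightening any single threshold only shrinks the accepted set", {
  set.seed(81)
  ft <- data.frame(track_id = 1:40, duration = sample(1:30, 40, TRUE),
                   instability = runif(40), shape_change = runif(40),
                   edge_density = runif(40), texture_variation = runif(40))
  base <- list(estimate_safe_threshold(0.8, orientation = "reject_above",
                                       step = 0.01, feature = "edge_density"))
  accepted <- validate_tracks(ft, base)
  for (t in c(0.6, 0.4, 0.2)) {
    tighter <- list(estimate_safe_threshold(t, orientation = "reject_above",
                                            step = 0.01,
                                            feature = "edge_density"))
    now <- validate_tracks(ft, tighter)
    expect_true(all(which(now) %in% which(accepted)))
    accepted <- now
  }
})

test_that("rules calibrated on a labeled table reject no true positives", {
  set.seed(82)
  n <- 60
  labels <- rep(c(TRUE, FALSE), c(25, 35))
  ft <- data.frame(
    track_id = seq_len(n),
    duration = ifelse(labels, sample(15:30, n, TRUE), sample(1:30, n, TRUE)),
    instability = ifelse(labels, runif(n, 0, 0.2), runif(n)),
    shape_change = ifelse(labels, runif(n, 0, 0.4), runif(n)),
    edge_density = ifelse(labels, runif(n, 0, 0.3), runif(n)),
    texture_variation = ifelse(labels, runif(n, 0, 0.15), runif(n)))
  rules <- calibrate_rules(ft, labels)
  ok <- validate_tracks(ft, rules)
  expect_true(all(ok[labels]))          # safe-value guarantee
  expect_lt(mean(ok[!labels]), 1)       # some false detections rejected
})

test_that("the SVM validator separates separable feature clouds", {
  set.seed(83)
  n <- 80
  labels <- rep(c(TRUE, FALSE), each = n / 2)
  ft <- data.frame(
    track_id = seq_len(n), duration = sample(18:22, n, TRUE),
    instability = runif(n, 0, 0.2), shape_change = runif(n, 0.2, 0.4),
    edge_density = ifelse(labels, runif(n, 0, 0.2), runif(n, 0.6, 1)),
    texture_variation = runif(n, 0, 0.3))
  v <- train_svm_validator(ft, labels, kernel = "linear")
  expect_gte(v$cv_accuracy, 0.95)
  expect_equal(predict(v, ft), labels)
  # identical clouds: chance-level cross-validation
  ft2 <- ft; ft2$edge_density <- runif(n)
  set.seed(84)
  accs <- replicate(10, train_svm_validator(ft2, sample(labels),
                                            kernel = "linear")$cv_accuracy)
  expect_lt(abs(mean(accs) - 0.5), 0.15)
  expect_error(train_svm_validator(ft, rep(TRUE, n)), "both classes")
})

test_that("threshold rules survive a YAML round-trip", {
  rules <- list(
    duration = estimate_safe_threshold(c(10, 25), orientation = "reject_below",
                                       step = 0.5, feature = "duration"),
    edge_density = estimate_safe_threshold(c(0.1, 0.22),
                                           orientation = "reject_above",
                                           step = 0.01,
                                           feature = "edge_density"))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_rules(rules, path)
  back <- read_rules(path)
  expect_equal(names(back), c("duration", "edge_density"))
  expect_equal(back$duration$threshold, rules$duration$threshold)
  expect_equal(back$edge_density$orientation, "reject_above")
})
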