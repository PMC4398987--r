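make_samples <- function(n_fg, n_bg, fg_center = c(50, 10, 18),
                         bg_center = c(50, -22, 38), spread = 3, seed = 1) {
  set.seed(seed)
  fg <- t(replicate(n_fg, fg_center + rnorm(3, sd = spread)))
  bg <- t(replicate(n_bg, bg_center + rnorm(3, sd = spread)))
  data.frame(L = c(fg[, 1], bg[, 1]), u = c(fg[, 2], bg[, 2]),
             v = c(fg[, 3], bg[, 3]),
             label = rep(c("foreground", "background"), c(n_fg, n_bg)),
             source = "segment_mean")
}

test_that("luminance filter keeps limits semantics and background untouched", {
  s <- data.frame(L = c(5, 50, 95, 5, 95), u = 0, v = 0,
                  label = c("foreground", "foreground", "foreground",
                            "background", "background"),
                  source = "segment_mean")
  expect_equal(luminance_filter(s, 0, 100), s)            # filter off
  med <- luminance_filter(s, 10, 90)
  expect_equal(med$L[med$label == "foreground"], 50)      # 5 and 95 removed
  expect_equal(sum(med$label == "background"), 2)         # untouched
  strong <- luminance_filter(s, 20, 80)
  expect_false(95 %in% strong$L[strong$label == "foreground"])
  expect_error(luminance_filter(s, 50, 40), "lower_pct")
  # widening the limits never removes more samples
  set.seed(31)
  r <- data.frame(L = runif(200, 0, 100), u = 0, v = 0,
                  label = sample(c("foreground", "background"), 200, TRUE),
                  source = "segment_mean")
  for (k in 1:10) {
    lo <- runif(1, 0, 49); hi <- runif(1, 51, 100)
    wide <- luminance_filter(r, max(lo - 5, 0), min(hi + 5, 100))
    narrow <- luminance_filter(r, lo, hi)
    expect_gte(nrow(wide), nrow(narrow))
  }
})

test_that("training color extraction labels the two sides of the mask", {
  sq <- generate_training_images(
    scene_spec(width = 96, height = 64, n_blobs = 1, blob_axes = c(7, 10),
               occlusions = list()), n = 1, seed = 3)[[1]]
  samples <- extract_training_colors(sq$image, sq$mask, scale = 1,
                                     min_segment_size = 20)
  fg <- samples[samples$label == "foreground", ]
  bg <- samples[samples$label == "background", ]
  expect_gte(nrow(fg), 1)
  expect_gte(nrow(bg), 1)
  # the background color list is longer than the foreground list
  expect_gt(nrow(bg), nrow(fg))
  # foreground samples sit in the low-chroma gray-brown band
  expect_true(all(fg$u > 0 & fg$u < 25 & fg$L > 30 & fg$L < 70))
  # an all-background mask warns and yields only background samples
  expect_warning(
    only_bg <- extract_training_colors(sq$image, sq$mask & FALSE, scale = 1,
                                       min_segment_size = 20),
    "one class")
  expect_true(all(only_bg$label == "background"))
})

test_that("well-separated classes train to near-perfect cross-validation", {
  s <- make_samples(500, 500, seed = 41)
  set.seed(41)
  m <- train_color_model(s)
  expect_gte(m$cv_accuracy, 0.99)
})

test_that("identical class distributions train to chance accuracy", {
  set.seed(42)
  accs <- replicate(20, {
    s <- make_samples(150, 150, bg_center = c(50, 10, 18),
                      seed = sample.int(1e6, 1))
    train_color_model(s)$cv_accuracy
  })
  expect_lt(abs(mean(accs) - 0.5), 0.1)
})

test_that("a higher foreground cost ratio raises foreground recall", {
  # overlapping mixture
  s <- make_samples(200, 200, bg_center = c(50, 4, 22), spread = 6, seed = 43)
  set.seed(43)
  m1 <- train_color_model(s, cost_ratio = 1)
  set.seed(43)
  m4 <- train_color_model(s, cost_ratio = 4)
  fg <- as.matrix(s[s$label == "foreground", c("L", "u", "v")])
  expect_gt(mean(predict(m4, fg)), mean(predict(m1, fg)))
})

test_that("the two-stage vote is strictly above the threshold", {
  # rule model: positive iff L > 50
  model <- rule_model(function(L, u, v) L > 50)
  # 10-pixel segment, 7 positive -> 0.7 > 2/3 -> candidate
  L <- matrix(10, 5, 6); L[1, 1:5] <- 60; L[2, 1:2] <- 60
  f <- luv_frame(L)
  seg <- as_segment(rect_mask(5, 6, 1, 2, 1, 5), 0L, 1L, f)  # rows 1-2, 10 px
  expect_true(classify_segment(model, seg, f, mode = "two_stage"))
  # 9-pixel segment, 6 positive -> exactly 2/3, not above -> reject
  L2 <- matrix(10, 5, 6); L2[1:2, 1:3] <- 60
  f2 <- luv_frame(L2)
  seg2 <- as_segment(rect_mask(5, 6, 1, 3, 1, 3), 0L, 1L, f2)  # 9 px
  expect_false(classify_segment(model, seg2, f2, mode = "two_stage"))
  # zero positive pixels -> rejected in both modes
  f3 <- luv_frame(matrix(10, 5, 6))
  seg3 <- as_segment(rect_mask(5, 6, 1, 3, 1, 3), 0L, 1L, f3)
  expect_false(classify_segment(model, seg3, f3, mode = "two_stage"))
  expect_false(classify_segment(model, seg3, f3, mode = "one_stage"))
  expect_error(classify_segment(model, seg3, f3, mode = "nope"))
  expect_error(classify_segment(model, seg3, luv_frame(matrix(0, 9, 9)),
                                mode = "two_stage"), "belong")
})

test_that("candidate detection returns all/none for degenerate models", {
  f <- luv_frame(cbind(matrix(20, 12, 8), matrix(70, 12, 8)))
  sm <- mean_shift_segment(f, 3, 8, 5)
  expect_length(detect_candidates(accept_all_model(), sm, f), length(sm$segments))
  expect_length(detect_candidates(reject_all_model(), sm, f), 0)
  # order independence: one-stage candidates = segments passing individually
  s <- make_samples(100, 100, seed = 44)
  set.seed(44)
  m <- train_color_model(s)
  c1 <- detect_candidates(m, sm, f, mode = "one_stage")
  single <- Filter(function(sg) classify_segment(m, sg, f, "one_stage"),
                   sm$segments)
  expect_equal(vapply(c1, `[[`, integer(1), "id"),
               vapply(single, `[[`, integer(1), "id"))
})

test_that("model decisions are deterministic and survive serialization", {
  s <- make_samples(120, 240, seed = 45)
  set.seed(45); m1 <- train_color_model(s)
  set.seed(45); m2 <- train_color_model(s)
  grid <- as.matrix(expand.grid(L = seq(10, 90, 10), u = seq(-30, 30, 10),
                                v = seq(-20, 50, 10)))
  expect_identical(predict(m1, grid), predict(m2, grid))
  path <- withr::local_tempfile(fileext = ".json")
  write_color_model(m1, path)
  m3 <- read_color_model(path)
  expect_identical(predict(m3, grid), predict(m1, grid))
  expect_equal(m3$cv_accuracy, m1$cv_accuracy)
  expect_equal(m3$gamma, m1$gamma)
})

test_that("single-class input and empty filtered foreground are errors", {
  s <- make_samples(50, 50, seed = 46)
  expect_error(train_color_model(s[s$label == "background", ]), "foreground")
  dark <- s
  dark$L[dark$label == "foreground"] <- 5
  expect_error(train_color_model(dark, luminance_limits = c(10, 90)),
               "foreground")
})
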