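test_that("an isolated two-detection track yields one positive step-1 sample", {
  gt <- make_track(frames = 0:1, id = 7, track_id = 1)
  s <- generate_step1_samples(gt)
  expect_equal(nrow(s), 1)
  expect_true(s$label)
  expect_equal(s$euclidean_px, 5)
})

test_that("gating keeps distant bees out of the step-1 negatives", {
  a <- make_track(frames = 0:4, id = 1, track_id = 1, x0 = 0, y0 = 0)
  b <- make_track(frames = 0:4, id = 2, track_id = 2, x0 = 2000, y0 = 0)
  gt <- combine_tracks(a, b)
  s <- generate_step1_samples(gt, gating_radius_px = 200)
  expect_equal(nrow(s), 8) # 4 within-track pairs per bee
  expect_true(all(s$label))
})

test_that("step-1 sample enumeration matches brute force on a crossing scene", {
  # three bees crossing in the middle of a 5-frame scene
  a <- make_track(frames = 0:4, id = 10, track_id = 1, x0 = 0, y0 = 0, vx = 50)
  b <- make_track(frames = 0:4, id = 20, track_id = 2, x0 = 200, y0 = 0, vx = -50)
  c_ <- make_track(frames = 0:4, id = 30, track_id = 3, x0 = 100, y0 = 120, vy = -40)
  gt <- combine_tracks(a, b, c_)
  s <- generate_step1_samples(gt, gating_radius_px = 200)

  # oracle: exhaustive enumeration over all ordered consecutive-frame pairs
  expected <- 0L
  expected_pos <- 0L
  for (i in seq_len(nrow(gt))) {
    for (j in seq_len(nrow(gt))) {
      if (gt$frame[j] != gt$frame[i] + 1) next
      d <- sqrt((gt$x[i] - gt$x[j])^2 + (gt$y[i] - gt$y[j])^2)
      if (d > 200) next
      expected <- expected + 1L
      if (gt$truth_id[i] == gt$truth_id[j]) expected_pos <- expected_pos + 1L
    }
  }
  expect_equal(nrow(s), expected)
  expect_equal(sum(s$label), expected_pos)
  # false positives can never be part of a positive pair
  gt_fp <- gt
  gt_fp$truth_id[1] <- FALSE_POSITIVE
  s_fp <- generate_step1_samples(gt_fp, gating_radius_px = 200)
  expect_lt(sum(s_fp$label), sum(s$label))
})

test_that("a track of length two yields exactly one positive step-2 sample", {
  gt <- make_track(frames = 3:4, id = 9, track_id = 1)
  s <- generate_step2_samples(gt)
  expect_equal(nrow(s), 1)
  expect_true(all(s$label))
})

test_that("step-2 positives on short tracks match the split-enumeration oracle", {
  gt <- make_track(frames = 0:3, id = 9, track_id = 1)
  s <- generate_step2_samples(gt)
  oracle <- oracle_step2_samples(gt)
  expect_equal(nrow(s), nrow(oracle)) # 10 distinct fragment splits
  expect_equal(nrow(s), 10)
  key <- function(d) {
    do.call(paste, c(d[, c(
      "track_a", "a_start_frame", "a_end_frame",
      "track_b", "b_start_frame", "b_end_frame", "label"
    )], sep = "/"))
  }
  expect_setequal(key(s), key(oracle))
})

test_that("step-2 negatives from overlapping different-ID tracks match the oracle", {
  a <- make_track(frames = 0:6, id = 5, track_id = 1, x0 = 0)
  b <- make_track(frames = 3:9, id = 6, track_id = 2, x0 = 30, y0 = 10)
  gt <- combine_tracks(a, b)
  s <- generate_step2_samples(gt)
  oracle <- oracle_step2_samples(gt)
  key <- function(d) {
    do.call(paste, c(d[, c(
      "track_a", "a_start_frame", "a_end_frame",
      "track_b", "b_start_frame", "b_end_frame", "label"
    )], sep = "/"))
  }
  expect_setequal(key(s), key(oracle))
  expect_equal(sum(!s$label), sum(!oracle$label))
})

test_that("splits across gaps wider than the bound are not emitted", {
  frames <- c(0, 1, 2, 20, 21) # internal gap of 17 frames
  gt <- make_track(frames = frames, id = 3, track_id = 1)
  s <- generate_step2_samples(gt, max_gap = 14)
  expect_true(all(s$b_start_frame - s$a_end_frame - 1 <= 14))
  oracle <- oracle_step2_samples(gt, max_gap = 14)
  expect_equal(nrow(s), nrow(oracle))
})

test_that("sample generation on a many-track scene equals the oracle and is deterministic", {
  withr::with_seed(8, {
    tracks <- lapply(1:5, function(i) {
      f0 <- sample(0:5, 1)
      len <- sample(3:8, 1)
      make_track(
        frames = f0:(f0 + len - 1), id = i * 11, track_id = i,
        x0 = runif(1, 0, 300), y0 = runif(1, 0, 300),
        vx = runif(1, -10, 10), vy = runif(1, -10, 10)
      )
    })
  })
  gt <- do.call(combine_tracks, tracks)
  s1 <- generate_step2_samples(gt)
  s2 <- generate_step2_samples(gt)
  expect_identical(s1, s2) # pure function of ground truth
  oracle <- oracle_step2_samples(gt)
  key <- function(d) {
    do.call(paste, c(d[, c(
      "track_a", "a_start_frame", "a_end_frame",
      "track_b", "b_start_frame", "b_end_frame", "label"
    )], sep = "/"))
  }
  expect_setequal(key(s1), key(oracle))
})

test_that("step-2 sample features agree with direct recomputation from the fragments", {
  a <- make_track(frames = 0:5, id = 5, track_id = 1, x0 = 0, vy = 2)
  b <- make_track(frames = 2:8, id = 6, track_id = 2, x0 = 30, y0 = 10, vx = -3)
  gt <- combine_tracks(a, b)
  # add decode noise so the bit features are non-trivial
  withr::with_seed(9, {
    bm <- as.matrix(gt[, paste0("b", 0:11)])
    bm <- abs(bm - matrix(runif(length(bm), 0, 0.45), nrow(bm)))
    gt[, paste0("b", 0:11)] <- as.data.frame(bm)
  })
  s <- generate_step2_samples(gt)
  gt_by_track <- split(gt, gt$truth_track_id)
  for (i in seq_len(nrow(s))) {
    ta <- gt_by_track[[as.character(s$track_a[i])]]
    ta <- ta[ta$frame >= s$a_start_frame[i] & ta$frame <= s$a_end_frame[i], ]
    tb <- gt_by_track[[as.character(s$track_b[i])]]
    tb <- tb[tb$frame >= s$b_start_frame[i] & tb$frame <= s$b_end_frame[i], ]
    f <- step2_features(ta[order(ta$frame), ], tb[order(tb$frame), ])
    for (nm in names(f)) {
      expect_equal(s[[nm]][i], f[[nm]], tolerance = 1e-9)
    }
  }
})

test_that("model training separates a separable toy problem and is reproducible", {
  withr::with_seed(10, {
    n <- 400
    pos <- tibble::tibble(
      euclidean_px = runif(n, 0, 30), angular_diff_rad = runif(n, 0, 0.5),
      id_manhattan = runif(n, 0, 1), label = TRUE
    )
    neg <- tibble::tibble(
      euclidean_px = runif(n, 100, 200), angular_diff_rad = runif(n, 1, pi),
      id_manhattan = runif(n, 5, 12), label = FALSE
    )
    holdout_idx <- sample(2 * n, 200)
  })
  samples <- dplyr::bind_rows(pos, neg)
  train <- samples[-holdout_idx, ]
  test <- samples[holdout_idx, ]
  m <- fit_correspondence_model(train, "step1", seed = 3)
  p <- predict_probability(m, test)
  expect_equal(mean((p > 0.5) == test$label), 1.0)
  # determinism: refit + repredict bit-for-bit
  m2 <- fit_correspondence_model(train, "step1", seed = 3)
  expect_identical(predict_probability(m2, test), p)
  expect_identical(p, predict_probability(m, test))
})

test_that("label-shuffled samples give chance-level held-out AUC", {
  withr::with_seed(12, {
    n <- 10000
    samples <- tibble::tibble(
      id_manhattan_mean = runif(n, 0, 12), euclidean_px = runif(n, 0, 300),
      forward_error_px = runif(n, 0, 300), backward_error_px = runif(n, 0, 300),
      angular_diff_rad = runif(n, 0, pi), confidence_diff = runif(n, 0, 0.5),
      label = sample(c(TRUE, FALSE), n, replace = TRUE)
    )
    holdout <- sample(n, 2500)
  })
  m <- fit_correspondence_model(
    samples[-holdout, ], "step2",
    hyperparams = list(ntree = 100L), seed = 4
  )
  p <- predict_probability(m, samples[holdout, ])
  auc <- beetrackr:::rank_auc(p, samples$label[holdout])
  expect_gt(auc, 0.45)
  expect_lt(auc, 0.55)
})

test_that("training refuses single-class input and mismatched features", {
  s <- tibble::tibble(
    euclidean_px = runif(10), angular_diff_rad = runif(10),
    id_manhattan = runif(10), label = TRUE
  )
  expect_error(fit_correspondence_model(s, "step1"), "positive and.*negative")
  s$label[1:5] <- FALSE
  m <- fit_correspondence_model(s, "step1")
  expect_error(
    predict_probability(m, tibble::tibble(id_manhattan_mean = 1)),
    "stage"
  )
  p <- predict_probability(m, s)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("model bundles survive a save/load round trip and reject schema drift", {
  fx <- small_fixture()
  path <- withr::local_tempfile(fileext = ".rds")
  save_correspondence_model(fx$m1, path)
  back <- load_correspondence_model(path)
  probe <- tibble::tibble(
    euclidean_px = c(3, 150), angular_diff_rad = c(0.05, 2), id_manhattan = c(0.2, 8)
  )
  expect_identical(predict_probability(back, probe), predict_probability(fx$m1, probe))

  stale <- fx$m1
  stale$schema_version <- 99L
  save_correspondence_model(stale, path)
  expect_error(load_correspondence_model(path), "schema version")
})

test_that("a trained step-2 model scores a seamless continuation above threshold", {
  fx <- small_fixture()
  cont <- tibble::tibble(
    id_manhattan_mean = 0, euclidean_px = 8, forward_error_px = 0,
    backward_error_px = 0, angular_diff_rad = 0, confidence_diff = 0
  )
  expect_gt(predict_probability(fx$m2, cont), 0.5)
})

test_that("tidy and glance summarize fitted models", {
  fx <- small_fixture()
  td1 <- generics::tidy(fx$m1)
  expect_equal(nrow(td1), 4) # 3 weights + intercept
  td2 <- generics::tidy(fx$m2)
  expect_setequal(td2$term, beetrackr:::step2_feature_names())
  g <- generics::glance(fx$m2)
  expect_equal(g$stage, "step2")
  expect_lt(g$positive_fraction, 0.5) # heavily imbalanced by construction
})
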