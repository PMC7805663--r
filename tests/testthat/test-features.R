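test_that("angular difference handles identity, wraparound, and matches the brute-force oracle", {
  expect_equal(angular_difference(0.5, 0.5), 0)
  expect_equal(angular_difference(pi, -pi), 0)
  expect_equal(angular_difference(0.1, 6.2), oracle_angular_difference(0.1, 6.2),
    tolerance = 1e-12
  )
  withr::with_seed(1, {
    a <- runif(200, -10, 10)
    b <- runif(200, -10, 10)
  })
  oracle <- mapply(oracle_angular_difference, a, b)
  expect_equal(angular_difference(a, b), oracle, tolerance = 1e-10)
  # symmetry and shift invariance
  expect_equal(angular_difference(a, b), angular_difference(b, a))
  expect_equal(angular_difference(a + 1.7, b + 1.7), angular_difference(a, b),
    tolerance = 1e-10
  )
  expect_true(all(angular_difference(a, b) >= 0 & angular_difference(a, b) <= pi))
})

test_that("id_manhattan is the per-bit L1 distance and a metric", {
  p <- rep(0.5, 12)
  expect_equal(id_manhattan(p, p), 0)
  expect_equal(id_manhattan(rep(0, 12), rep(1, 12)), 12)
  p <- c(0.9, 0.1, 0.5, rep(0, 9))
  q <- c(0.7, 0.4, 0.5, rep(0, 9))
  expect_equal(id_manhattan(p, q), 0.5)
  expect_error(id_manhattan(rep(0.5, 11), rep(0.5, 11)), "12")
  withr::with_seed(2, {
    for (i in 1:100) {
      a <- runif(12)
      b <- runif(12)
      c_ <- runif(12)
      expect_lte(id_manhattan(a, c_), id_manhattan(a, b) + id_manhattan(b, c_) + 1e-12)
      expect_equal(id_manhattan(a, b), id_manhattan(b, a))
      expect_equal(id_manhattan(a, b), sum(abs(a - b)))
    }
  })
})

test_that("step-1 features compose the three sub-operations", {
  d1 <- make_det(frame = 0, x = 0, y = 0, theta = 1, bits = 100)
  d2 <- make_det(frame = 1, x = 3, y = 4, theta = 1, bits = 100)
  f <- step1_features(d1, d2)
  expect_equal(unlist(f), c(euclidean_px = 5, angular_diff_rad = 0, id_manhattan = 0))

  same <- step1_features(d1, d1)
  expect_equal(unname(unlist(same)), c(0, 0, 0))

  withr::with_seed(3, {
    a <- make_det(
      frame = rep(0, 50), x = runif(50, 0, 100), y = runif(50, 0, 100),
      theta = runif(50, -pi, pi), bits = matrix(runif(600), ncol = 12)
    )
    b <- make_det(
      frame = rep(1, 50), x = runif(50, 0, 100), y = runif(50, 0, 100),
      theta = runif(50, -pi, pi), bits = matrix(runif(600), ncol = 12)
    )
  })
  f <- step1_features(a, b)
  for (i in seq_len(50)) {
    expect_equal(f$euclidean_px[i], sqrt((a$x[i] - b$x[i])^2 + (a$y[i] - b$y[i])^2))
    expect_equal(f$angular_diff_rad[i], oracle_angular_difference(a$theta[i], b$theta[i]),
      tolerance = 1e-10
    )
    expect_equal(
      f$id_manhattan[i],
      sum(abs(unlist(a[i, paste0("b", 0:11)]) - unlist(b[i, paste0("b", 0:11)])))
    )
  }
})

test_that("extrapolation error follows constant-velocity kinematics", {
  tr <- make_det(frame = 0:1, x = c(0, 1), y = 0, bits = 1)
  target <- make_det(frame = 2, x = 2, y = 0, bits = 1)
  expect_equal(extrapolation_error(tr, target, "forward"), 0)

  # stationary source: zero-velocity fallback to plain distance
  still <- make_det(frame = 0:1, x = 5, y = 5, bits = 1)
  target <- make_det(frame = 2, x = 8, y = 9, bits = 1)
  expect_equal(extrapolation_error(still, target, "forward"), 5)

  single <- make_det(frame = 0, x = 5, y = 5, bits = 1)
  expect_equal(extrapolation_error(single, target, "forward"), 5)

  # velocity (2, 1) per frame, frame difference 3: prediction lands at (16, 8)
  tr <- make_det(frame = 4:5, x = c(8, 10), y = c(4, 5), bits = 1)
  target <- make_det(frame = 8, x = 13, y = 12, bits = 1)
  expect_equal(
    extrapolation_error(tr, target, "forward"),
    sqrt((16 - 13)^2 + (8 - 12)^2)
  )

  # backward: first motion of the later tracklet, reversed across the gap
  tr2 <- make_det(frame = 8:9, x = c(13, 15), y = c(12, 13), bits = 1)
  last_a <- make_det(frame = 5, x = 10, y = 5, bits = 1)
  # velocity (2, 1); prediction at frame 5 is (13,12) - 3*(2,1) = (7, 9)
  expect_equal(
    extrapolation_error(tr2, last_a, "backward"),
    sqrt((7 - 10)^2 + (9 - 5)^2)
  )
})

test_that("step-2 features are zero for a seamless constant-velocity continuation", {
  tA <- make_det(frame = 0:2, x = c(0, 2, 4), y = 0, theta = 0.3, bits = 99)
  tB <- make_det(frame = 3:5, x = c(6, 8, 10), y = 0, theta = 0.3, bits = 99)
  f <- step2_features(tA, tB)
  expect_equal(
    unname(unlist(f)),
    c(0, 2, 0, 0, 0, 0)
  )
})

test_that("single-detection tracklets degrade extrapolation features to plain distance", {
  tA <- make_det(frame = 0, x = 0, y = 0, bits = 5)
  tB <- make_det(frame = 3, x = 6, y = 8, bits = 5)
  f <- step2_features(tA, tB)
  expect_equal(f$forward_error_px, f$euclidean_px)
  expect_equal(f$backward_error_px, f$euclidean_px)
  expect_equal(f$euclidean_px, 10)
})

test_that("step-2 features match independent per-feature recomputation", {
  withr::with_seed(4, {
    tA <- make_det(
      frame = 0:2, x = cumsum(runif(3, 0, 5)), y = cumsum(runif(3, 0, 5)),
      theta = runif(3, -pi, pi), bits = matrix(runif(36), ncol = 12)
    )
    tB <- make_det(
      frame = 5:7, x = 20 + cumsum(runif(3, 0, 5)), y = cumsum(runif(3, 0, 5)),
      theta = runif(3, -pi, pi), bits = matrix(runif(36), ncol = 12)
    )
  })
  f <- step2_features(tA, tB)
  bitsA <- as.matrix(tA[, paste0("b", 0:11)])
  bitsB <- as.matrix(tB[, paste0("b", 0:11)])
  expect_equal(f$id_manhattan_mean, sum(abs(colMeans(bitsA) - colMeans(bitsB))))
  expect_equal(f$euclidean_px, sqrt((tA$x[3] - tB$x[1])^2 + (tA$y[3] - tB$y[1])^2))
  expect_equal(f$forward_error_px, extrapolation_error(tA, tB[1, ], "forward"))
  expect_equal(f$backward_error_px, extrapolation_error(tB, tA[3, ], "backward"))
  expect_equal(f$angular_diff_rad, oracle_angular_difference(tA$theta[3], tB$theta[1]),
    tolerance = 1e-10
  )
  confA <- min(abs(apply(bitsA, 2, median) - 0.5))
  confB <- min(abs(apply(bitsB, 2, median) - 0.5))
  expect_equal(f$confidence_diff, abs(confA - confB))
})

test_that("overlapping tracklets are rejected", {
  tA <- make_det(frame = 0:3, x = 0, y = 0, bits = 1)
  tB <- make_det(frame = 3:5, x = 1, y = 1, bits = 1)
  expect_error(step2_features(tA, tB), "overlap")
})

test_that("step-2 features are invariant to common translation and rotation of angles", {
  withr::with_seed(5, {
    for (rep in 1:20) {
      tA <- make_det(
        frame = 0:3, x = runif(4, 0, 50), y = runif(4, 0, 50),
        theta = runif(4, -pi, pi), bits = matrix(runif(48), ncol = 12)
      )
      tB <- make_det(
        frame = 6:9, x = runif(4, 0, 50), y = runif(4, 0, 50),
        theta = runif(4, -pi, pi), bits = matrix(runif(48), ncol = 12)
      )
      f0 <- step2_features(tA, tB)
      shift <- function(d, dx, dy, dth) {
        d$x <- d$x + dx
        d$y <- d$y + dy
        d$theta <- d$theta + dth
        d
      }
      f1 <- step2_features(shift(tA, 123, -45, 0.8), shift(tB, 123, -45, 0.8))
      expect_equal(unlist(f1), unlist(f0), tolerance = 1e-9)
      # declared ranges
      expect_true(f0$id_manhattan_mean >= 0 && f0$id_manhattan_mean <= 12)
      expect_true(f0$angular_diff_rad >= 0 && f0$angular_diff_rad <= pi)
      expect_true(f0$confidence_diff >= 0 && f0$confidence_diff <= 0.5)
      expect_true(all(unlist(f0[c(2, 3, 4)]) >= 0))
    }
  })
})

test_that("bulk tracklet-pair features agree with the single-pair computation", {
  fx <- small_fixture()
  det <- link_detections(fx$det, fx$m1)
  summ <- beetrackr:::tracklet_summaries(det)
  pairs <- beetrackr:::candidate_pairs_step2(summ, tracking_config())
  expect_gt(nrow(pairs), 5)
  take <- pairs[seq_len(min(25, nrow(pairs))), ]
  for (i in seq_len(nrow(take))) {
    tA <- det[det$tracklet_id == take$tid_a[i], ]
    tB <- det[det$tracklet_id == take$tid_b[i], ]
    f <- step2_features(tA, tB)
    for (nm in names(f)) {
      expect_equal(take[[nm]][i], f[[nm]], tolerance = 1e-9)
    }
  }
})
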