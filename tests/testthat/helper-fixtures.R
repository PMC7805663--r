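# Builders and shared fixtures for the test suite. Everything is generated
# in code; nothing is read from disk.

# 12 exact soft bits for an integer ID, b0 = least significant.
exact_bits <- function(id) {
  as.numeric(bitwAnd(as.integer(id), 2^(0:11)) > 0)
}

# Build a detection table row by row. `bits` may be a single ID (exact
# decoding), a length-12 vector, or an n x 12 matrix.
make_det <- function(frame, x, y, theta = 0, bits = 0, cam = 0L,
                     truth_id = NULL, truth_track_id = NULL,
                     det_id = NULL) {
  n <- length(frame)
  if (is.matrix(bits)) {
    bm <- bits
  } else if (length(bits) == 12 && n != 12) {
    bm <- matrix(bits, nrow = n, ncol = 12, byrow = TRUE)
  } else if (length(bits) == n) {
    bm <- t(vapply(bits, exact_bits, numeric(12)))
  } else if (length(bits) == 1) {
    bm <- matrix(exact_bits(bits), nrow = n, ncol = 12, byrow = TRUE)
  } else {
    stop("bad bits argument")
  }
  colnames(bm) <- paste0("b", 0:11)
  out <- tibble::tibble(
    det_id = if (is.null(det_id)) seq_len(n) else det_id,
    frame = as.integer(frame),
    timestamp = frame / 3,
    cam = as.integer(cam),
    x = as.numeric(x), y = as.numeric(y),
    theta = rep_len(as.numeric(theta), n)
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(bm))
  if (!is.null(truth_id)) out$truth_id <- as.integer(rep_len(truth_id, n))
  if (!is.null(truth_track_id)) {
    out$truth_track_id <- as.integer(rep_len(truth_track_id, n))
  }
  out
}

# A straight-line ground-truth track with exact decodings.
make_track <- function(frames, id, track_id, x0 = 0, y0 = 0,
                       vx = 5, vy = 0, theta = 0, cam = 0L,
                       det_id_start = 1L) {
  k <- seq_along(frames) - 1
  make_det(
    frame = frames, x = x0 + vx * k, y = y0 + vy * k, theta = theta,
    bits = id, cam = cam, truth_id = id, truth_track_id = track_id,
    det_id = det_id_start + seq_along(frames) - 1L
  )
}

combine_tracks <- function(...) {
  out <- dplyr::bind_rows(...)
  out$det_id <- seq_len(nrow(out))
  out
}

# --- Independent oracles -----------------------------------------------

# Brute-force optimal assignment: enumerate all injections of the smaller
# side into the larger and maximize the total score.
brute_force_assignment <- function(scores) {
  nr <- nrow(scores)
  nc <- ncol(scores)
  transposed <- nr > nc
  if (transposed) {
    scores <- t(scores)
    tmp <- nr
    nr <- nc
    nc <- tmp
  }
  best <- -Inf
  perms <- function(v, k) {
    if (k == 0) {
      return(list(integer(0)))
    }
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i], k - 1)) out <- c(out, list(c(v[i], rest)))
    }
    out
  }
  for (p in perms(seq_len(nc), nr)) {
    s <- sum(scores[cbind(seq_len(nr), p)])
    if (s > best) best <- s
  }
  best
}

# Independent angular difference: explicit minimization over wrap offsets.
oracle_angular_difference <- function(a, b) {
  min(abs(a - b + 2 * pi * (-8:8)))
}

# Step-2 sample enumeration oracle: literal nested-loop implementation of
# the three generation rules, returning deduplicated fragment extents.
oracle_step2_samples <- function(gt, max_gap = 14L) {
  gt <- dplyr::filter(gt, truth_id != beetrackr::FALSE_POSITIVE)
  tracks <- split(gt[order(gt$frame), ], gt$truth_track_id[order(gt$frame)])
  out <- list()
  emit <- function(ta, fa, tb, fb, label) {
    out[[length(out) + 1]] <<- data.frame(
      track_a = as.integer(ta), a_start_frame = min(fa), a_end_frame = max(fa),
      track_b = as.integer(tb), b_start_frame = min(fb), b_end_frame = max(fb),
      label = label
    )
  }
  # rule 1: split each track once at each time step
  for (tn in names(tracks)) {
    f <- sort(tracks[[tn]]$frame)
    n <- length(f)
    if (n >= 2) {
      for (k in 1:(n - 1)) {
        if (f[k + 1] - f[k] - 1 <= max_gap) {
          emit(tn, f[1:k], tn, f[(k + 1):n], TRUE)
        }
      }
    }
    # rule 2: every contiguous sub-track of length <= 3, split everywhere
    for (len in 2:3) {
      if (n < len) next
      for (s in 1:(n - len + 1)) {
        sub <- f[s:(s + len - 1)]
        for (k in 1:(len - 1)) {
          if (sub[k + 1] - sub[k] - 1 <= max_gap) {
            emit(tn, sub[1:k], tn, sub[(k + 1):len], TRUE)
          }
        }
      }
    }
  }
  # rule 3: same-time-step splits of every different-ID ordered track pair
  for (ta in names(tracks)) {
    for (tb in names(tracks)) {
      if (tracks[[ta]]$truth_id[1] == tracks[[tb]]$truth_id[1]) next
      fa <- sort(tracks[[ta]]$frame)
      fb <- sort(tracks[[tb]]$frame)
      for (t in min(fa, fb):max(fa, fb)) {
        pre <- fa[fa <= t]
        suf <- fb[fb > t]
        if (length(pre) == 0 || length(suf) == 0) next
        gap <- min(suf) - max(pre) - 1
        if (gap >= 0 && gap <= max_gap) emit(ta, pre, tb, suf, FALSE)
      }
    }
  }
  unique(dplyr::bind_rows(out))
}

# --- Shared model fixtures (trained once per test run) ------------------

fixture_env <- new.env(parent = emptyenv())

# Small simulated scene + models for the tracking tests.
small_fixture <- function() {
  if (!is.null(fixture_env$small)) {
    return(fixture_env$small)
  }
  sim <- simulate_colony(sim_config(
    n_bees = 12, duration_s = 60, arena_w_px = 1500, arena_h_px = 1000,
    rng_seed = 42
  ))
  det <- sim$detections
  m1 <- fit_correspondence_model(
    generate_step1_samples(det),
    stage = "step1", seed = 7
  )
  m2 <- fit_correspondence_model(
    generate_step2_samples(det),
    stage = "step2", hyperparams = list(ntree = 100L), seed = 7
  )
  fixture_env$small <- list(sim = sim, det = det, m1 = m1, m2 = m2)
  fixture_env$small
}

# Full-scale study fixture: ~50 bees over ~2,000 frames at the default
# calibration, with models trained on the first 500 frames and the
# remaining 1,500 held out for evaluation.
big_fixture <- function() {
  if (!is.null(fixture_env$big)) {
    return(fixture_env$big)
  }
  sim <- simulate_colony(sim_config(n_bees = 50, duration_s = 2000 / 3, rng_seed = 101))
  det <- sim$detections
  train <- dplyr::filter(det, frame < 500)
  eval_det <- dplyr::filter(det, frame >= 500)
  m1 <- fit_correspondence_model(generate_step1_samples(train), "step1", seed = 11)
  m2 <- fit_correspondence_model(generate_step2_samples(train), "step2", seed = 11)
  fixture_env$big <- list(
    sim = sim, det = det, train = train, eval_det = eval_det,
    m1 = m1, m2 = m2
  )
  fixture_env$big
}
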