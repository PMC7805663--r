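#' Configuration for the synthetic colony simulator
#'
#' Defaults emulate the statistical structure of the recorded hive data the
#' method targets: 3 Hz sampling, about 97.9% of consecutive same-bee
#' detections in adjacent frames (no gap), gaps of at most 14 frames
#' covering about 99.8% of gaps, a 13% binarized-ID decode error, and false
#' positives amounting to roughly 1% of detections.
#'
#' @param arena_w_px,arena_h_px Comb-plane arena size in pixels.
#' @param n_bees Number of tagged bees (at most 4096, the 12-bit ID space).
#' @param fps Frames per second.
#' @param duration_s Simulated duration in seconds.
#' @param speed_scale_px Mean per-frame step length of the correlated
#'   random walk, pixels.
#' @param turn_persistence Heading persistence in \[0, 1): 0 is an
#'   uncorrelated walk, values near 1 give nearly straight paths.
#' @param orientation_noise_rad Std. dev. of the noise between a bee's
#'   heading and its decoded tag orientation.
#' @param p_gap_start Per-frame probability that a detected bee starts a
#'   short dropout gap (occlusion); `1 - p_gap_start` is the expected
#'   fraction of gapless consecutive correspondences.
#' @param gap_length_geom Success parameter of the geometric law (support
#'   1, 2, ...) for dropout gap lengths; the default 0.35 puts 99.76% of
#'   gap mass at or below 14 frames.
#' @param absence_rate Per-frame probability that a bee leaves the hive
#'   (splitting its ground-truth track).
#' @param absence_duration_s Mean duration of an absence, seconds.
#' @param id_error_rate Target probability that binarizing a detection's
#'   corrupted soft bits yields the wrong ID (calibrated numerically).
#' @param false_positive_rate Expected false positives per genuine
#'   detection.
#' @param rng_seed Integer seed; the simulation is fully reproducible.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(arena_w_px = 3000,
                       arena_h_px = 2000,
                       n_bees = 50L,
                       fps = 3,
                       duration_s = 200,
                       speed_scale_px = 10,
                       turn_persistence = 0.85,
                       orientation_noise_rad = 0.3,
                       p_gap_start = 0.021,
                       gap_length_geom = 0.35,
                       absence_rate = 2e-5,
                       absence_duration_s = 60,
                       id_error_rate = 0.13,
                       false_positive_rate = 0.01,
                       rng_seed = 1L) {
  stopifnot(
    arena_w_px > 0, arena_h_px > 0,
    n_bees >= 1, n_bees <= 4096,
    fps > 0, duration_s > 0, speed_scale_px >= 0,
    turn_persistence >= 0, turn_persistence < 1,
    orientation_noise_rad >= 0,
    p_gap_start >= 0, p_gap_start < 1,
    gap_length_geom > 0, gap_length_geom <= 1,
    absence_rate >= 0, absence_rate < 1,
    absence_duration_s > 0,
    id_error_rate >= 0, id_error_rate <= 1,
    false_positive_rate >= 0
  )
  structure(
    list(
      arena_w_px = arena_w_px, arena_h_px = arena_h_px,
      n_bees = as.integer(n_bees), fps = fps, duration_s = duration_s,
      speed_scale_px = speed_scale_px, turn_persistence = turn_persistence,
      orientation_noise_rad = orientation_noise_rad,
      p_gap_start = p_gap_start, gap_length_geom = gap_length_geom,
      absence_rate = absence_rate, absence_duration_s = absence_duration_s,
      id_error_rate = id_error_rate,
      false_positive_rate = false_positive_rate,
      rng_seed = as.integer(rng_seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (f in names(x)) cat(sprintf("  %-22s %s\n", f, format(x[[f]])))
  invisible(x)
}

# Per-bit corruption model: with weight w a bit is drawn from a broad,
# symmetric component spanning 0.5 (confident-wrong and uncertain decodes),
# otherwise from a sharp component hugging the true value. The broad weight
# is solved so that the marginal probability of a wrong binarized 12-bit ID
# equals the configured rate.
broad_weight_for_rate <- function(id_error_rate) {
  if (id_error_rate <= 0) {
    return(0)
  }
  p_sharp_flip <- 0.5^19 # P(Beta(1, 19) > 0.5)
  per_bit <- 1 - (1 - id_error_rate)^(1 / 12)
  w <- (per_bit - p_sharp_flip) / (0.5 - p_sharp_flip)
  min(max(w, 0), 1)
}

#' Corrupt a true tag ID into noisy soft bits
#'
#' Draws soft-bit probability vectors for `n` independent decodings of a
#' true 12-bit ID under a two-component mixture per bit: a sharp component
#' concentrated near the true bit value and a broad component spanning 0.5,
#' so that both confidently wrong and uncertain decodings occur. The broad
#' component's weight is calibrated at construction so that binarizing at
#' 0.5 recovers the wrong ID with probability `id_error_rate`. With
#' `id_error_rate = 0` the bits are returned exactly 0/1.
#'
#' @param true_id Integer 0..4095.
#' @param n Number of independent decodings to draw.
#' @param id_error_rate Target binarized-ID error probability.
#' @return An `n` x 12 matrix of soft bits, column j = bit j-1 (LSB first).
#' @export
corrupt_bits <- function(true_id, n = 1, id_error_rate = 0.13) {
  stopifnot(true_id >= 0, true_id <= 4095)
  true_bits <- as.numeric(bitwAnd(true_id, 2^(0:11)) > 0)
  b <- matrix(true_bits, nrow = n, ncol = 12, byrow = TRUE)
  if (id_error_rate <= 0) {
    return(b)
  }
  w <- broad_weight_for_rate(id_error_rate)
  m <- n * 12
  broad <- matrix(runif(m) < w, nrow = n)
  x <- matrix(0, nrow = n, ncol = 12)
  x[broad] <- rbeta(sum(broad), 1.5, 1.5)
  x[!broad] <- rbeta(m - sum(broad), 1, 19)
  # fold the deviation onto the true bit: b = 0 -> x, b = 1 -> 1 - x
  b + (1 - 2 * b) * x
}

# Detected/gap run-length process for one bee over T frames. Returns an
# integer vector: 1 detected, 0 dropout gap, -1 absent (track split).
presence_sequence <- function(T, p_gap, geom_p, p_absent, absence_mean_frames) {
  state <- integer(T)
  t <- 1L
  s <- p_gap + p_absent
  while (t <= T) {
    run <- if (s > 0) 1L + rgeom(1, s) else T
    run <- min(run, T - t + 1L)
    state[t:(t + run - 1L)] <- 1L
    t <- t + run
    if (t > T) break
    if (runif(1) < p_absent / s) {
      len <- max(15L, as.integer(round(rexp(1, 1 / absence_mean_frames))))
      kind <- -1L
    } else {
      len <- 1L + rgeom(1, geom_p)
      kind <- 0L
    }
    len <- min(len, T - t + 1L)
    state[t:(t + len - 1L)] <- kind
    t <- t + len
  }
  state
}

#' Simulate a tagged colony's detection stream with ground truth
#'
#' Bees follow a correlated random walk with reflective boundaries inside a
#' rectangular comb-plane arena. Each present bee is detected once per
#' frame unless it is inside a dropout gap (occlusion) or absent from the
#' hive; detections carry soft bits corrupted by the calibrated noise model
#' of [corrupt_bits()]. False positives appear uniformly in space with
#' uniform random soft bits and `truth_id = FALSE_POSITIVE`. Ground-truth
#' tracks are split at absences (a bee returning from outside starts a new
#' truth track) but not at dropout gaps.
#'
#' @param config A [sim_config()].
#' @return A list of class `bee_sim` with elements `detections` (a
#'   validated detection tibble including `truth_id` and `truth_track_id`)
#'   and `config`.
#' @export
#' @examples
#' sim <- simulate_colony(sim_config(n_bees = 3, duration_s = 10, rng_seed = 7))
#' dplyr::count(sim$detections, truth_id)
simulate_colony <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed)
  T <- as.integer(round(config$duration_s * config$fps))
  stopifnot(T >= 1)
  ids <- sample(0:4095, config$n_bees)
  turn_sd <- (1 - config$turn_persistence) * pi
  absence_frames <- config$absence_duration_s * config$fps

  per_bee <- vector("list", config$n_bees)
  for (i in seq_len(config$n_bees)) {
    x <- numeric(T)
    y <- numeric(T)
    heading <- numeric(T)
    x[1] <- runif(1, 0, config$arena_w_px)
    y[1] <- runif(1, 0, config$arena_h_px)
    heading[1] <- runif(1, -pi, pi)
    steps <- rexp(T, 1 / max(config$speed_scale_px, 1e-9))
    turns <- rnorm(T, 0, turn_sd)
    for (t in 2:max(T, 2)) {
      if (T == 1) break
      heading[t] <- heading[t - 1] + turns[t]
      nx <- x[t - 1] + steps[t] * cos(heading[t])
      ny <- y[t - 1] + steps[t] * sin(heading[t])
      # reflect at the arena walls, flipping the heading component
      if (nx < 0 || nx > config$arena_w_px) {
        if (nx < 0) nx <- -nx else nx <- 2 * config$arena_w_px - nx
        nx <- min(max(nx, 0), config$arena_w_px)
        heading[t] <- pi - heading[t]
      }
      if (ny < 0 || ny > config$arena_h_px) {
        if (ny < 0) ny <- -ny else ny <- 2 * config$arena_h_px - ny
        ny <- min(max(ny, 0), config$arena_h_px)
        heading[t] <- -heading[t]
      }
      x[t] <- nx
      y[t] <- ny
    }
    state <- presence_sequence(
      T, config$p_gap_start, config$gap_length_geom,
      config$absence_rate, absence_frames
    )
    # truth tracks: runs between absences that contain >= 1 detection
    seg <- cumsum(c(1L, diff(state == -1L) != 0L))
    seg[state == -1L] <- NA_integer_
    det_frames <- which(state == 1L)
    if (length(det_frames) == 0) next
    bits <- corrupt_bits(ids[i], length(det_frames), config$id_error_rate)
    colnames(bits) <- bit_cols()
    per_bee[[i]] <- tibble(
      frame = det_frames - 1L,
      x = x[det_frames], y = y[det_frames],
      theta = normalize_angle(
        heading[det_frames] + rnorm(length(det_frames), 0, config$orientation_noise_rad)
      ),
      truth_id = ids[i],
      truth_track_id = i * 1000L + match(seg[det_frames], unique(seg[det_frames]))
    ) |>
      dplyr::bind_cols(as_tibble(bits))
  }
  det <- bind_rows(per_bee)

  n_fp <- stats::rpois(1, config$false_positive_rate * nrow(det))
  if (n_fp > 0) {
    fp_bits <- matrix(runif(n_fp * 12), ncol = 12)
    colnames(fp_bits) <- bit_cols()
    fp <- tibble(
      frame = sample(0:(T - 1L), n_fp, replace = TRUE),
      x = runif(n_fp, 0, config$arena_w_px),
      y = runif(n_fp, 0, config$arena_h_px),
      theta = runif(n_fp, -pi, pi),
      truth_id = FALSE_POSITIVE,
      truth_track_id = NA_integer_
    ) |>
      dplyr::bind_cols(as_tibble(fp_bits))
    det <- bind_rows(det, fp)
  }

  det <- det |>
    arrange(.data$frame, .data$truth_id) |>
    mutate(
      det_id = row_number(),
      timestamp = .data$frame / config$fps,
      cam = 0L
    ) |>
    select(
      "det_id", "frame", "timestamp", "cam", "x", "y", "theta",
      all_of(bit_cols()), "truth_id", "truth_track_id"
    )

  structure(
    list(detections = validate_detections(det), config = config),
    class = "bee_sim"
  )
}

#' @export
print.bee_sim <- function(x, ...) {
  d <- x$detections
  cat(sprintf(
    "<bee_sim> %d detections, %d frames, %d bees, %d false positives\n",
    nrow(d), n_distinct(d$frame),
    n_distinct(d$truth_id[d$truth_id != FALSE_POSITIVE]),
    sum(d$truth_id == FALSE_POSITIVE)
  ))
  invisible(x)
}

#' Measure the simulator's calibration statistics
#'
#' Empirical counterparts of the quantities the simulator is calibrated
#' against: the fraction of consecutive same-track detection pairs with no
#' gap, the fraction of gaps no longer than `max_gap` frames, the
#' binarized-ID decode error over genuine detections, and the
#' false-positive share.
#'
#' @param detections A detection table with `truth_id` and
#'   `truth_track_id` columns (e.g. from [simulate_colony()]).
#' @param max_gap Gap bound used for the coverage statistic.
#' @return A one-row tibble.
#' @export
sim_calibration_stats <- function(detections, max_gap = 14L) {
  real <- filter(detections, .data$truth_id != FALSE_POSITIVE)
  gaps <- real |>
    group_by(.data$truth_track_id) |>
    arrange(.data$frame, .by_group = TRUE) |>
    summarise(gap = list(diff(.data$frame) - 1L), .groups = "drop") |>
    pull(.data$gap) |>
    unlist()
  decode_err <- mean(decode_id(real) != real$truth_id)
  tibble(
    n_pairs = length(gaps),
    frac_gapless = mean(gaps == 0),
    frac_gaps_within_bound = if (any(gaps > 0)) mean(gaps[gaps > 0] <= max_gap) else 1,
    decode_error = decode_err,
    frac_false_positive = mean(detections$truth_id == FALSE_POSITIVE)
  )
}
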