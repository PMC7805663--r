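#' Smallest angular difference between two orientations
#'
#' Distance on the circle: the minimum over integer `k` of `|a - b + 2*pi*k|`,
#' always in `[0, pi]`. Vectorized over both arguments.
#'
#' @param a,b Angles in radians.
#' @return Numeric vector of angular differences in radians.
#' @export
#' @examples
#' angular_difference(pi, -pi) # 0: same orientation
angular_difference <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

#' Manhattan distance between two soft-bit ID vectors
#'
#' Sum of absolute per-bit probability differences; 0 for identical
#' decodings, 12 for two maximally confident, fully complementary IDs.
#'
#' @param p,q Either numeric vectors of length 12 or matrices/data frames
#'   with 12 columns (rows are compared pairwise).
#' @return Numeric vector of distances in \[0, 12\].
#' @export
id_manhattan <- function(p, q) {
  p <- to_bit_matrix(p)
  q <- to_bit_matrix(q)
  if (ncol(p) != 12 || ncol(q) != 12) {
    abort("Soft-bit vectors must have exactly 12 entries.")
  }
  rowSums(abs(p - q))
}

to_bit_matrix <- function(p) {
  if (is.data.frame(p)) {
    cols <- if (all(bit_cols() %in% names(p))) bit_cols() else names(p)
    p <- as.matrix(p[, cols, drop = FALSE])
  } else if (!is.matrix(p)) {
    p <- matrix(p, nrow = 1)
  }
  p
}

#' Detection-pair features for the first tracking step
#'
#' The three features scored by the step-1 correspondence classifier for a
#' detection and its candidate successor in the next frame: Euclidean
#' distance in pixels, angular difference of the tag orientations, and
#' Manhattan distance between the two 12-bit soft decodings.
#'
#' @param d1,d2 Detection tables of equal row count; row i of `d1` is paired
#'   with row i of `d2`.
#' @return A tibble with columns `euclidean_px`, `angular_diff_rad`,
#'   `id_manhattan`, one row per pair.
#' @export
step1_features <- function(d1, d2) {
  stopifnot(nrow(d1) == nrow(d2))
  tibble(
    euclidean_px = sqrt((d1$x - d2$x)^2 + (d1$y - d2$y)^2),
    angular_diff_rad = angular_difference(d1$theta, d2$theta),
    id_manhattan = id_manhattan(d1, d2)
  )
}

#' Constant-velocity extrapolation error
#'
#' Linear motion prediction used by the step-2 spatial features. In the
#' forward direction the last motion vector of `source` (its last two
#' detections, one frame apart) is extrapolated across the frame difference
#' to the target detection; in the backward direction the first motion
#' vector of `source` is extrapolated in reverse to a target that precedes
#' it. A single-detection source has no motion estimate and degenerates to
#' zero velocity, i.e. the plain Euclidean distance.
#'
#' @param source A tracklet: detection table sorted by frame, gapless.
#' @param target_det A single-row detection table.
#' @param direction `"forward"` (target follows source) or `"backward"`
#'   (target precedes source).
#' @return Euclidean distance in pixels between prediction and target.
#' @export
extrapolation_error <- function(source, target_det,
                                direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  stopifnot(nrow(source) >= 1, nrow(target_det) == 1)
  n <- nrow(source)
  if (direction == "forward") {
    anchor <- source[n, ]
    vx <- if (n >= 2) source$x[n] - source$x[n - 1] else 0
    vy <- if (n >= 2) source$y[n] - source$y[n - 1] else 0
    dt <- target_det$frame - anchor$frame
  } else {
    anchor <- source[1, ]
    vx <- if (n >= 2) source$x[2] - source$x[1] else 0
    vy <- if (n >= 2) source$y[2] - source$y[1] else 0
    dt <- target_det$frame - anchor$frame # negative: predict into the past
  }
  px <- anchor$x + vx * dt
  py <- anchor$y + vy * dt
  sqrt((px - target_det$x)^2 + (py - target_det$y)^2)
}

# Minimum over bits of |median - 0.5|: the confidence of the least certain
# bit of a fragment's consensus decoding. `bits` is an n x 12 matrix.
fragment_confidence <- function(bits) {
  med <- apply(bits, 2, median)
  min(abs(med - 0.5))
}

#' Tracklet-pair features for the second tracking step
#'
#' The six features scored by the step-2 correspondence classifier for an
#' ordered pair of non-overlapping tracklets:
#' \enumerate{
#'   \item Manhattan distance between the per-bit arithmetic means of the
#'     two tracklets' soft decodings.
#'   \item Euclidean distance from the last detection of the first tracklet
#'     to the first detection of the second.
#'   \item Forward error: constant-velocity extrapolation of the first
#'     tracklet's last motion to the second tracklet's first detection.
#'   \item Backward error: reverse extrapolation of the second tracklet's
#'     first motion to the first tracklet's last detection.
#'   \item Angular difference between the abutting orientations.
#'   \item Absolute difference of the two tracklets' least-certain-bit
#'     confidences (per-bit median, bit closest to 0.5).
#' }
#'
#' @param tA,tB Tracklets (detection tables sorted by frame); `tB` must
#'   start strictly after `tA` ends.
#' @return A one-row tibble with columns `id_manhattan_mean`,
#'   `euclidean_px`, `forward_error_px`, `backward_error_px`,
#'   `angular_diff_rad`, `confidence_diff`.
#' @export
step2_features <- function(tA, tB) {
  if (min(tB$frame) <= max(tA$frame)) {
    abort("Tracklets overlap in time: tB must start strictly after tA ends.")
  }
  bitsA <- as.matrix(tA[, bit_cols(), drop = FALSE])
  bitsB <- as.matrix(tB[, bit_cols(), drop = FALSE])
  lastA <- tA[nrow(tA), ]
  firstB <- tB[1, ]
  tibble(
    id_manhattan_mean = sum(abs(colMeans(bitsA) - colMeans(bitsB))),
    euclidean_px = sqrt((lastA$x - firstB$x)^2 + (lastA$y - firstB$y)^2),
    forward_error_px = extrapolation_error(tA, firstB, "forward"),
    backward_error_px = extrapolation_error(tB, lastA, "backward"),
    angular_diff_rad = angular_difference(lastA$theta, firstB$theta),
    confidence_diff = abs(fragment_confidence(bitsA) - fragment_confidence(bitsB))
  )
}

step1_feature_names <- function() {
  c("euclidean_px", "angular_diff_rad", "id_manhattan")
}

step2_feature_names <- function() {
  c(
    "id_manhattan_mean", "euclidean_px", "forward_error_px",
    "backward_error_px", "angular_diff_rad", "confidence_diff"
  )
}

# Per-tracklet summary used for bulk step-2 feature extraction: endpoint
# kinematics, per-bit means and the least-certain-bit confidence.
tracklet_summaries <- function(det, id_col = "tracklet_id") {
  det <- arrange(det, .data[[id_col]], .data$frame)
  base <- det |>
    group_by(tid = .data[[id_col]]) |>
    summarise(
      n = n(),
      start_frame = first(.data$frame),
      end_frame = last(.data$frame),
      first_x = first(.data$x), first_y = first(.data$y),
      last_x = last(.data$x), last_y = last(.data$y),
      first_theta = first(.data$theta), last_theta = last(.data$theta),
      # motion vectors at the two ends; zero for single-detection tracklets
      fwd_vx = if (n() >= 2) .data$x[n()] - .data$x[n() - 1] else 0,
      fwd_vy = if (n() >= 2) .data$y[n()] - .data$y[n() - 1] else 0,
      bwd_vx = if (n() >= 2) .data$x[2] - .data$x[1] else 0,
      bwd_vy = if (n() >= 2) .data$y[2] - .data$y[1] else 0,
      across(all_of(bit_cols()), mean, .names = "mean_{.col}"),
      across(all_of(bit_cols()), median, .names = "med_{.col}"),
      .groups = "drop"
    )
  med <- as.matrix(base[, paste0("med_", bit_cols()), drop = FALSE])
  base$confidence <- apply(abs(med - 0.5), 1, min)
  base
}

# Vectorized step-2 features for ordered pairs of tracklet summaries.
# `pairs` has columns tid_a, tid_b; returns pairs + feature columns.
step2_features_bulk <- function(pairs, summaries) {
  sa <- summaries |> rename_with_prefix("a_")
  sb <- summaries |> rename_with_prefix("b_")
  d <- pairs |>
    inner_join(sa, by = c("tid_a" = "a_tid")) |>
    inner_join(sb, by = c("tid_b" = "b_tid"))
  mean_a <- as.matrix(d[, paste0("a_mean_", bit_cols()), drop = FALSE])
  mean_b <- as.matrix(d[, paste0("b_mean_", bit_cols()), drop = FALSE])
  dt <- d$b_start_frame - d$a_end_frame
  fwd_px <- d$a_last_x + d$a_fwd_vx * dt
  fwd_py <- d$a_last_y + d$a_fwd_vy * dt
  bwd_px <- d$b_first_x - d$b_bwd_vx * dt
  bwd_py <- d$b_first_y - d$b_bwd_vy * dt
  pairs$id_manhattan_mean <- rowSums(abs(mean_a - mean_b))
  pairs$euclidean_px <- sqrt((d$a_last_x - d$b_first_x)^2 + (d$a_last_y - d$b_first_y)^2)
  pairs$forward_error_px <- sqrt((fwd_px - d$b_first_x)^2 + (fwd_py - d$b_first_y)^2)
  pairs$backward_error_px <- sqrt((bwd_px - d$a_last_x)^2 + (bwd_py - d$a_last_y)^2)
  pairs$angular_diff_rad <- angular_difference(d$a_last_theta, d$b_first_theta)
  pairs$confidence_diff <- abs(d$a_confidence - d$b_confidence)
  pairs
}

rename_with_prefix <- function(df, prefix) {
  names(df) <- paste0(prefix, names(df))
  df
}
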