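#' Column schema for detection tables
#'
#' A detection is one localized-and-decoded marker observation in one video
#' frame. Detection tables are plain tibbles with one row per detection and
#' the columns below; `truth_id` and `truth_track_id` are optional and only
#' present for ground-truth or simulated data.
#'
#' \describe{
#'   \item{det_id}{integer, unique key}
#'   \item{frame}{integer frame index, >= 0; at the nominal 3 Hz rate three
#'     frames span about one second}
#'   \item{timestamp}{seconds, real}
#'   \item{cam}{small integer camera / hive-side label}
#'   \item{x, y}{comb-plane position in pixels (already stitched upstream)}
#'   \item{theta}{orientation in radians, normalized into (-pi, pi]}
#'   \item{b0 ... b11}{soft bits: probability that bit i of the 12-bit tag ID
#'     is set, each in \[0, 1\]; b0 is the least significant bit}
#'   \item{truth_id}{optional: true tag ID 0--4095, or [FALSE_POSITIVE]}
#'   \item{truth_track_id}{optional: ground-truth track membership}
#' }
#'
#' @return A character vector of required column names.
#' @export
detection_columns <- function() {
  c("det_id", "frame", "timestamp", "cam", "x", "y", "theta", bit_cols())
}

#' Normalize an angle into (-pi, pi]
#'
#' @param theta numeric vector of angles in radians.
#' @return Angles wrapped into the half-open interval (-pi, pi].
#' @export
#' @examples
#' normalize_angle(c(0, pi, -pi, 3 * pi))
normalize_angle <- function(theta) {
  out <- theta - 2 * pi * floor((theta + pi) / (2 * pi))
  # floor maps -pi to -pi itself; fold onto the +pi end of the interval
  out[out <= -pi] <- pi
  out
}

#' Validate a table of detections
#'
#' Checks a raw detection table against the schema in [detection_columns()],
#' normalizes orientations into (-pi, pi], and returns the table sorted by
#' camera and frame (the order every downstream stage assumes). Malformed
#' rows abort with a report naming the offending `det_id` and field.
#'
#' @param det A data frame of detections (see [detection_columns()]).
#' @return A validated tibble of class `bee_detections`, sorted by
#'   `cam`, `frame`, `det_id`.
#' @export
#' @examples
#' sim <- simulate_colony(sim_config(n_bees = 2, duration_s = 3, rng_seed = 1))
#' det <- validate_detections(sim$detections)
validate_detections <- function(det) {
  det <- as_tibble(det)
  missing_cols <- setdiff(detection_columns(), names(det))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "Detection table is missing required column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }

  fail <- function(rows, field, why) {
    ids <- det$det_id[rows]
    abort(paste0(
      "Invalid detections (field `", field, "`, ", why, "): det_id ",
      paste(head(ids, 10), collapse = ", "),
      if (length(ids) > 10) paste0(" and ", length(ids) - 10, " more") else ""
    ))
  }

  dup <- duplicated(det$det_id)
  if (any(dup)) fail(which(dup), "det_id", "duplicate key")

  num_ok <- function(v) is.numeric(v) & is.finite(v)
  for (f in c("frame", "timestamp", "x", "y", "theta")) {
    bad <- !num_ok(det[[f]])
    if (any(bad)) fail(which(bad), f, "non-finite or non-numeric")
  }
  if (any(det$frame < 0)) fail(which(det$frame < 0), "frame", "negative")
  if (any(det$frame != floor(det$frame))) {
    fail(which(det$frame != floor(det$frame)), "frame", "non-integer")
  }

  for (f in bit_cols()) {
    v <- det[[f]]
    bad <- !num_ok(v) | v < 0 | v > 1
    if (any(bad)) fail(which(bad), f, "bit probability outside [0, 1]")
  }

  if ("truth_id" %in% names(det)) {
    v <- det$truth_id
    bad <- !is.na(v) & (v != FALSE_POSITIVE) & (v < 0 | v > 4095 | v != floor(v))
    if (any(bad)) fail(which(bad), "truth_id", "outside 0..4095 and not FALSE_POSITIVE")
  }

  det$frame <- as.integer(det$frame)
  det$cam <- as.integer(det$cam)
  det$theta <- normalize_angle(det$theta)
  det <- arrange(det, .data$cam, .data$frame, .data$det_id)

  # timestamps must move with the frame counter within one camera
  chk <- det |>
    group_by(.data$cam) |>
    mutate(
      bad_ts = .data$frame > lag(.data$frame, default = -1L) &
        .data$timestamp < lag(.data$timestamp, default = -Inf)
    ) |>
    ungroup()
  if (any(chk$bad_ts)) {
    fail(which(chk$bad_ts), "timestamp", "decreases while frame increases")
  }

  class(det) <- c("bee_detections", class(det))
  det
}

#' Binarize soft bits into integer tag IDs
#'
#' Thresholds each of the twelve bit probabilities at 0.5 (a bit is set iff
#' its probability is strictly greater than 0.5) and assembles the integer
#' ID with `b0` as the least significant bit.
#'
#' @param det A detection table, or any data frame with columns `b0`..`b11`.
#' @return An integer vector of decoded IDs in 0..4095, one per row.
#' @export
decode_id <- function(det) {
  bits <- as.matrix(det[, bit_cols(), drop = FALSE])
  as.integer((bits > 0.5) %*% 2^(0:11))
}

#' Tracking parameters
#'
#' Bundles the knobs shared by both tracking steps and the chunked runner.
#'
#' @param gating_radius_px Spatial gate for candidate correspondences in
#'   pixels (about 12 mm of comb at the reference optics). Step 2 scales the
#'   gate by `gap + 1` so that longer gaps admit proportionally farther
#'   candidates.
#' @param link_threshold Minimum correspondence probability for a match to
#'   be kept after assignment; matches scoring below it are discarded and
#'   the tracklet or track is closed.
#' @param max_gap_frames Largest allowed gap (missing frames between two
#'   consecutive member detections) when merging tracklets.
#' @param fps Nominal recording rate in frames per second.
#' @param chunk_seconds Length of the independently tracked intervals used
#'   by [track_chunked()].
#' @param rng_seed Integer seed governing any randomized component.
#' @return A list of class `tracking_config`.
#' @export
tracking_config <- function(gating_radius_px = 200,
                            link_threshold = 0.5,
                            max_gap_frames = 14L,
                            fps = 3,
                            chunk_seconds = 3600L,
                            rng_seed = 1L) {
  stopifnot(
    gating_radius_px > 0,
    link_threshold >= 0, link_threshold <= 1,
    max_gap_frames >= 0,
    fps > 0, chunk_seconds > 0
  )
  structure(
    list(
      gating_radius_px = gating_radius_px,
      link_threshold = link_threshold,
      max_gap_frames = as.integer(max_gap_frames),
      fps = fps,
      chunk_seconds = as.integer(chunk_seconds),
      rng_seed = as.integer(rng_seed)
    ),
    class = "tracking_config"
  )
}

#' @export
print.tracking_config <- function(x, ...) {
  cat("<tracking_config>\n")
  for (f in names(x)) cat(sprintf("  %-18s %s\n", f, format(x[[f]])))
  invisible(x)
}

# Frame gap between the end of fragment A and the start of fragment B:
# 0 means consecutive frames.
frame_gap <- function(end_frame_a, start_frame_b) {
  start_frame_b - end_frame_a - 1L
}

# Assert that a per-tracklet detection table is gapless (step-1 contract).
assert_gapless <- function(det, id_col = "tracklet_id") {
  bad <- det |>
    group_by(.data[[id_col]]) |>
    summarise(gapless = all(diff(sort(.data$frame)) == 1L) || n() == 1L) |>
    filter(!.data$gapless)
  if (nrow(bad) > 0) {
    abort(paste0(
      "Tracklet(s) violate the gapless contract: ",
      paste(head(bad[[id_col]], 5), collapse = ", ")
    ))
  }
  invisible(det)
}
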