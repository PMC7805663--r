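#' Perfect tracking: ground-truth tracks in result format
#'
#' Maps the ground-truth tracks themselves into the result representation
#' (false positives excluded). Running [assign_track_ids()] on this output
#' measures the residual error floor of the median ID rule: even with
#' flawless correspondences, some detections sit in tracks whose consensus
#' ID is wrong because their decodings were corrupted.
#'
#' @param truth A detection table with `truth_id` and `truth_track_id`.
#' @return The non-false-positive detections with `track_id` set to the
#'   ground-truth track membership.
#' @export
perfect_tracking <- function(truth) {
  truth <- as_tibble(truth)
  stopifnot(all(c("truth_id", "truth_track_id") %in% names(truth)))
  truth |>
    filter(.data$truth_id != FALSE_POSITIVE, !is.na(.data$truth_track_id)) |>
    mutate(track_id = dplyr::dense_rank(.data$truth_track_id))
}

#' Naive baseline: link detections by their decoded ID only
#'
#' The no-learning reference: each detection's soft bits are binarized at
#' 0.5 and detections sharing the same decoded integer ID are chained over
#' time, nearest frame first, ties broken by Euclidean proximity. With
#' `allow_gaps` the chain tolerates gaps up to `max_gap_frames`, otherwise
#' only consecutive frames link.
#'
#' @param det A validated detection table.
#' @param config A [tracking_config()]; only `max_gap_frames` is used.
#' @param allow_gaps Whether equal-ID chaining may bridge gaps.
#' @return The detection tibble with an added `track_id` column.
#' @export
baseline_naive_id_linking <- function(det, config = tracking_config(),
                                      allow_gaps = TRUE) {
  det <- arrange(as_tibble(det), .data$frame, .data$det_id)
  det$decoded <- decode_id(det)
  det$track_id <- NA_integer_
  next_id <- 1L
  max_gap <- if (allow_gaps) config$max_gap_frames else 0L

  for (code in unique(det$decoded)) {
    rows <- which(det$decoded == code)
    frames <- det$frame[rows]
    chains_last_frame <- integer(0)
    chains_x <- numeric(0)
    chains_y <- numeric(0)
    chains_id <- integer(0)
    for (f in unique(frames)) {
      cand <- rows[frames == f]
      alive <- which(chains_last_frame >= f - max_gap - 1L & chains_last_frame < f)
      # most recent chains choose first; each takes its nearest candidate
      alive <- alive[order(-chains_last_frame[alive], chains_id[alive])]
      taken <- rep(FALSE, length(cand))
      for (k in alive) {
        free <- which(!taken)
        if (length(free) == 0) break
        dd <- (det$x[cand[free]] - chains_x[k])^2 + (det$y[cand[free]] - chains_y[k])^2
        pick <- free[which.min(dd)]
        det$track_id[cand[pick]] <- chains_id[k]
        chains_last_frame[k] <- f
        chains_x[k] <- det$x[cand[pick]]
        chains_y[k] <- det$y[cand[pick]]
        taken[pick] <- TRUE
      }
      for (pick in which(!taken)) {
        det$track_id[cand[pick]] <- next_id
        chains_last_frame <- c(chains_last_frame, f)
        chains_x <- c(chains_x, det$x[cand[pick]])
        chains_y <- c(chains_y, det$y[cand[pick]])
        chains_id <- c(chains_id, next_id)
        next_id <- next_id + 1L
      }
    }
  }
  det$decoded <- NULL
  det
}

#' Match result tracks to ground-truth tracks
#'
#' Attributes every result track to the ground-truth individual owning the
#' majority of its detections (ties broken by the earliest-starting, then
#' lowest-numbered truth track) and classifies each member detection as a
#' correct member or an insertion (a detection of another individual, or a
#' false positive). An insertion occurring at a frame where the attributed
#' individual's true detection exists is additionally flagged as a
#' mismatch. Each truth track's corresponding result track is the
#' attributed track holding most of its detections; truth detections
#' absent from that track are deletions.
#'
#' @param result A detection table with a `track_id` membership column.
#' @param truth The ground-truth detection universe (all det_ids, with
#'   `truth_id` and `truth_track_id`).
#' @param track_col Name of the membership column in `result`.
#' @return A list of class `bee_track_matching` with elements
#'   `track_attribution`, `detection_class`, and `truth_tracks`.
#' @export
match_tracks_to_truth <- function(result, truth, track_col = "track_id") {
  result <- as_tibble(result)
  truth <- as_tibble(truth)
  stopifnot(all(c("truth_id", "truth_track_id") %in% names(truth)))
  if (!track_col %in% names(result)) {
    abort(paste0("Column `", track_col, "` not found in result."))
  }
  unknown <- setdiff(result$det_id, truth$det_id)
  if (length(unknown) > 0) {
    abort(paste0(
      "Result references det_id(s) absent from the truth universe: ",
      paste(head(unknown, 5), collapse = ", ")
    ))
  }

  mem <- result |>
    filter(!is.na(.data[[track_col]])) |>
    select(det_id = "det_id", track_id = all_of(track_col)) |>
    left_join(
      select(truth, "det_id", "frame", "truth_id", "truth_track_id"),
      by = "det_id"
    )

  truth_starts <- truth |>
    filter(.data$truth_id != FALSE_POSITIVE, !is.na(.data$truth_track_id)) |>
    group_by(.data$truth_track_id) |>
    summarise(
      truth_start = min(.data$frame), n_truth = n(),
      bee_id = first(.data$truth_id), .groups = "drop"
    )

  attribution <- mem |>
    filter(.data$truth_id != FALSE_POSITIVE) |>
    count(.data$track_id, .data$truth_track_id) |>
    left_join(truth_starts, by = "truth_track_id") |>
    group_by(.data$track_id) |>
    arrange(
      dplyr::desc(.data$n), .data$truth_start, .data$truth_track_id,
      .by_group = TRUE
    ) |>
    slice(1) |>
    ungroup() |>
    select("track_id", attributed_truth_track = "truth_track_id",
      n_majority = "n", attributed_bee_id = "bee_id"
    )
  all_tracks <- distinct(mem, .data$track_id) |>
    left_join(attribution, by = "track_id")

  det_class <- mem |>
    left_join(
      select(all_tracks, "track_id", "attributed_truth_track"),
      by = "track_id"
    ) |>
    mutate(
      class = dplyr::case_when(
        !is.na(.data$truth_track_id) &
          .data$truth_track_id == .data$attributed_truth_track ~ "correct",
        .default = "insertion"
      )
    )
  # a mismatch is an insertion sitting where the attributed individual's
  # true detection exists at that very frame
  truth_frames <- truth |>
    filter(.data$truth_id != FALSE_POSITIVE, !is.na(.data$truth_track_id)) |>
    select(attributed_truth_track = "truth_track_id", "frame") |>
    mutate(truth_has_frame = TRUE)
  det_class <- det_class |>
    left_join(
      truth_frames,
      by = c("attributed_truth_track", "frame"),
      relationship = "many-to-one"
    ) |>
    mutate(mismatch = .data$class == "insertion" &
      !is.na(.data$truth_has_frame) & .data$truth_has_frame) |>
    select(-"truth_has_frame")

  # each truth track's corresponding result track and its deletions
  correct_counts <- det_class |>
    filter(.data$class == "correct") |>
    count(.data$truth_track_id, .data$track_id, name = "n_present")
  track_sizes <- count(mem, .data$track_id, name = "track_size")
  corresponding <- correct_counts |>
    left_join(
      result |>
        filter(!is.na(.data[[track_col]])) |>
        group_by(track_id = .data[[track_col]]) |>
        summarise(result_start = min(c(.data$frame, Inf)), .groups = "drop"),
      by = "track_id"
    ) |>
    group_by(.data$truth_track_id) |>
    arrange(
      dplyr::desc(.data$n_present), .data$result_start, .data$track_id,
      .by_group = TRUE
    ) |>
    slice(1) |>
    ungroup()

  truth_tracks <- truth |>
    filter(.data$truth_id != FALSE_POSITIVE, !is.na(.data$truth_track_id)) |>
    group_by(.data$truth_track_id) |>
    summarise(
      n_truth = n(),
      max_internal_gap = if (n() > 1) max(diff(sort(.data$frame)) - 1L) else 0L,
      .groups = "drop"
    ) |>
    left_join(
      select(corresponding, "truth_track_id",
        corresponding_track = "track_id", "n_present"
      ),
      by = "truth_track_id"
    ) |>
    left_join(track_sizes, by = c(corresponding_track = "track_id")) |>
    mutate(
      n_present = dplyr::coalesce(.data$n_present, 0L),
      n_deleted = .data$n_truth - .data$n_present,
      complete = .data$n_deleted == 0L &
        dplyr::coalesce(.data$track_size, 0L) == .data$n_truth
    )

  structure(
    list(
      track_attribution = all_tracks,
      detection_class = det_class,
      truth_tracks = truth_tracks
    ),
    class = "bee_track_matching"
  )
}

#' @export
print.bee_track_matching <- function(x, ...) {
  cat(sprintf(
    "<bee_track_matching> %d result tracks vs %d truth tracks; %d insertions, %d deletions\n",
    nrow(x$track_attribution), nrow(x$truth_tracks),
    sum(x$detection_class$class == "insertion"), sum(x$truth_tracks$n_deleted)
  ))
  invisible(x)
}

#' Score a tracking result against ground truth
#'
#' Computes the full error accounting from a truth matching and the
#' per-track consensus ID assignments: the share of detections and of
#' tracks carrying a wrong ID, the share of ground-truth tracks
#' reconstructed exactly (raw, and normalized to the tracks achievable
#' under the gap bound), deletions, insertions, and mismatches.
#'
#' @param matching A [match_tracks_to_truth()] result.
#' @param id_assignments An [assign_track_ids()] table for the same result
#'   tracks.
#' @param truth The ground-truth detection universe.
#' @param max_gap Gap bound defining which truth tracks are achievable.
#' @return A one-row tibble of class `bee_metrics`.
#' @export
compute_metrics <- function(matching, id_assignments, truth, max_gap = 14L) {
  stopifnot(inherits(matching, "bee_track_matching"))
  truth <- as_tibble(truth)
  id_of_track <- select(id_assignments, track_id = 1, "assigned_id")

  real <- filter(truth, .data$truth_id != FALSE_POSITIVE)
  mem <- matching$detection_class |>
    select("det_id", "track_id") |>
    left_join(id_of_track, by = "track_id")
  per_det <- real |>
    select("det_id", "truth_id") |>
    left_join(mem, by = "det_id") |>
    mutate(wrong = is.na(.data$assigned_id) | .data$assigned_id != .data$truth_id)

  track_ids <- matching$track_attribution |>
    left_join(id_of_track, by = "track_id") |>
    mutate(wrong = is.na(.data$attributed_bee_id) |
      .data$assigned_id != .data$attributed_bee_id)

  tt <- matching$truth_tracks
  achievable <- tt$max_internal_gap <= max_gap
  ins <- sum(matching$detection_class$class == "insertion")
  mis <- sum(matching$detection_class$mismatch)

  out <- tibble(
    pct_incorrect_detection_ids = 100 * mean(per_det$wrong),
    pct_incorrect_track_ids = 100 * mean(track_ids$wrong),
    pct_complete_tracks = 100 * mean(tt$complete),
    pct_complete_of_achievable = if (any(achievable)) {
      100 * mean(tt$complete[achievable])
    } else {
      NA_real_
    },
    pct_deleted_detections = 100 * sum(tt$n_deleted) / sum(tt$n_truth),
    pct_tracks_with_deletion = 100 * mean(tt$n_deleted > 0),
    insertion_count = ins,
    mismatch_count = mis,
    n_result_tracks = nrow(matching$track_attribution),
    n_truth_tracks = nrow(tt)
  )
  class(out) <- c("bee_metrics", class(out))
  out
}

#' One-call evaluation of a tracking result
#'
#' Convenience wrapper: assigns consensus IDs, matches result tracks to
#' truth, and computes the metric report.
#'
#' @param result A detection table with a track membership column.
#' @param truth The ground-truth detection universe.
#' @param track_col Name of the membership column in `result`.
#' @param max_gap Gap bound for achievable completeness.
#' @return A one-row `bee_metrics` tibble.
#' @export
evaluate_tracking <- function(result, truth, track_col = "track_id",
                              max_gap = 14L) {
  ids <- assign_track_ids(result, id_col = track_col)
  names(ids)[1] <- "track_id"
  matching <- match_tracks_to_truth(result, truth, track_col = track_col)
  compute_metrics(matching, ids, truth, max_gap = max_gap)
}

#' Raw per-detection decode error
#'
#' Fraction of genuine detections whose binarized 12-bit decoding differs
#' from the true ID, before any tracking.
#'
#' @param truth A detection table with `truth_id`.
#' @return A proportion in \[0, 1\].
#' @export
raw_decode_error <- function(truth) {
  real <- filter(as_tibble(truth), .data$truth_id != FALSE_POSITIVE)
  mean(decode_id(real) != real$truth_id)
}
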