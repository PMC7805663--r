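#' Link detections into gapless tracklets (tracking step 1)
#'
#' Iterates through the detections frame by frame, per camera, keeping a
#' list of open tracklets. At each frame the step-1 classifier scores every
#' open tracklet's last detection against the new detections within the
#' gating radius; the Hungarian method assigns candidates to tracklets, and
#' assignments scoring below the link threshold are rejected. Tracklets
#' whose best candidate was rejected (or that received none) close;
#' unassigned detections open new tracklets. The result partitions every
#' input detection into exactly one gapless tracklet.
#'
#' @param det A validated detection table (see [validate_detections()]).
#' @param model A step-1 `correspondence_model`.
#' @param config A [tracking_config()].
#' @return The detection tibble with an added integer `tracklet_id` column.
#' @export
link_detections <- function(det, model, config = tracking_config()) {
  stopifnot(inherits(model, "correspondence_model"))
  if (model$stage != "step1") abort("link_detections() needs a step-1 model.")
  det <- arrange(as_tibble(det), .data$cam, .data$frame, .data$det_id)

  # score all gated consecutive-frame pairs in one batch
  pairs <- candidate_pairs_step1(det, config$gating_radius_px)
  if (nrow(pairs) > 0) {
    pairs$prob <- predict_probability(model, pairs)
  } else {
    pairs$prob <- numeric(0)
  }

  det$tracklet_id <- NA_integer_
  next_id <- 1L
  for (cam in unique(det$cam)) {
    in_cam <- det$cam == cam
    res <- link_one_camera(
      det[in_cam, ], pairs[pairs$cam == cam, ],
      config$link_threshold, next_id
    )
    det$tracklet_id[in_cam] <- res$tracklet_id
    next_id <- res$next_id
  }
  assert_gapless(det)
  det
}

# All gated ordered detection pairs in consecutive frames, with step-1
# features, per camera.
candidate_pairs_step1 <- function(det, gating_radius_px) {
  cols <- c("det_id", "frame", "cam", "x", "y", "theta", bit_cols())
  a <- det[, cols]
  b <- det[, cols]
  names(a) <- paste0(names(a), "_1")
  names(b) <- paste0(names(b), "_2")
  b$frame_before <- b$frame_2 - 1L
  p <- inner_join(
    a, b,
    by = c("cam_1" = "cam_2", "frame_1" = "frame_before"),
    relationship = "many-to-many"
  )
  if (nrow(p) == 0) {
    return(tibble(
      cam = integer(), frame_1 = integer(), det_id_1 = integer(),
      det_id_2 = integer(), euclidean_px = numeric(),
      angular_diff_rad = numeric(), id_manhattan = numeric()
    ))
  }
  d2 <- (p$x_1 - p$x_2)^2 + (p$y_1 - p$y_2)^2
  p <- p[d2 <= gating_radius_px^2, ]
  bits1 <- as.matrix(p[, paste0(bit_cols(), "_1"), drop = FALSE])
  bits2 <- as.matrix(p[, paste0(bit_cols(), "_2"), drop = FALSE])
  tibble(
    cam = p$cam_1, frame_1 = p$frame_1,
    det_id_1 = p$det_id_1, det_id_2 = p$det_id_2,
    euclidean_px = sqrt((p$x_1 - p$x_2)^2 + (p$y_1 - p$y_2)^2),
    angular_diff_rad = angular_difference(p$theta_1, p$theta_2),
    id_manhattan = rowSums(abs(bits1 - bits2))
  )
}

link_one_camera <- function(det, pairs, threshold, next_id) {
  tid <- rep(NA_integer_, nrow(det))
  frames <- sort(unique(det$frame))
  rows_by_frame <- split(seq_len(nrow(det)), det$frame)
  pairs_by_frame <- split(pairs, pairs$frame_1)

  open_rows <- integer(0) # det row index of each open tracklet's last detection
  prev_frame <- NA_integer_
  for (f in frames) {
    cand_rows <- rows_by_frame[[as.character(f)]] # sorted by det_id
    # gapless contract: opens survive only across a single-frame step
    if (!identical(prev_frame, f - 1L)) open_rows <- integer(0)

    matched_open <- integer(0)
    matched_cand <- integer(0)
    if (length(open_rows) > 0) {
      pf <- pairs_by_frame[[as.character(f - 1L)]]
      if (!is.null(pf) && nrow(pf) > 0) {
        s <- matrix(0, nrow = length(open_rows), ncol = length(cand_rows))
        i <- match(pf$det_id_1, det$det_id[open_rows])
        j <- match(pf$det_id_2, det$det_id[cand_rows])
        ok <- !is.na(i) & !is.na(j)
        s[cbind(i[ok], j[ok])] <- pf$prob[ok]
        m <- solve_assignment(s, threshold)
        matched_open <- m$row
        matched_cand <- m$col
      }
    }
    # extend matched tracklets, open new ones for the rest
    if (length(matched_open) > 0) {
      tid[cand_rows[matched_cand]] <- tid[open_rows[matched_open]]
    }
    new_cand <- setdiff(seq_along(cand_rows), matched_cand)
    if (length(new_cand) > 0) {
      tid[cand_rows[new_cand]] <- seq.int(next_id, length.out = length(new_cand))
      next_id <- next_id + length(new_cand)
    }
    open_rows <- cand_rows
    prev_frame <- f
  }
  list(tracklet_id = tid, next_id = next_id)
}

#' Merge tracklets into gapped tracks (tracking step 2)
#'
#' Processes tracklet start frames in temporal order, mirroring step 1 one
#' level up: tracklets beginning at a frame are candidate continuations for
#' open tracks whose tail ended at most `max_gap_frames + 1` frames
#' earlier. Candidate pairs are gated spatially at
#' `gating_radius_px * (gap + 1)` (a bee can cover more ground across a
#' longer gap), scored by the step-2 classifier on the pair of abutting
#' tracklets, and assigned with the Hungarian method; matches below the
#' link threshold are rejected. Merged tracks concatenate detections,
#' preserving the gap; unmatched starters open new tracks.
#'
#' @param det A detection table with a `tracklet_id` column from
#'   [link_detections()].
#' @param model A step-2 `correspondence_model`.
#' @param config A [tracking_config()].
#' @return The detection tibble with an added integer `track_id` column.
#' @export
merge_tracklets <- function(det, model, config = tracking_config()) {
  stopifnot(inherits(model, "correspondence_model"))
  if (model$stage != "step2") abort("merge_tracklets() needs a step-2 model.")
  if (!"tracklet_id" %in% names(det)) {
    abort("merge_tracklets() expects the `tracklet_id` column from link_detections().")
  }
  det <- arrange(as_tibble(det), .data$cam, .data$frame, .data$det_id)
  assert_gapless(det)

  summaries <- tracklet_summaries(det)
  pairs <- candidate_pairs_step2(summaries, config)
  if (nrow(pairs) > 0) {
    pairs$prob <- predict_probability(model, pairs)
  } else {
    pairs$prob <- numeric(0)
  }

  summaries <- arrange(summaries, .data$start_frame, .data$tid)
  tracklet_track <- setNames(
    rep(NA_integer_, nrow(summaries)),
    as.character(summaries$tid)
  )
  next_track <- 1L

  open <- tibble(
    track_id = integer(), tail_tid = integer(), last_frame = integer()
  )
  pairs_by_tail <- split(pairs, pairs$tid_a)
  start_frames <- sort(unique(summaries$start_frame))
  starters_by_frame <- split(summaries$tid, summaries$start_frame)
  end_by_tid <- setNames(summaries$end_frame, as.character(summaries$tid))

  for (f in start_frames) {
    open <- open[open$last_frame >= f - config$max_gap_frames - 1L, ]
    starters <- sort(starters_by_frame[[as.character(f)]])
    eligible <- which(open$last_frame < f)

    matched_open <- integer(0)
    matched_starter <- integer(0)
    if (length(eligible) > 0) {
      s <- matrix(0, nrow = length(eligible), ncol = length(starters))
      for (k in seq_along(eligible)) {
        pf <- pairs_by_tail[[as.character(open$tail_tid[eligible[k]])]]
        if (is.null(pf)) next
        j <- match(pf$tid_b, starters)
        ok <- !is.na(j)
        s[k, j[ok]] <- pf$prob[ok]
      }
      if (any(s > 0)) {
        m <- solve_assignment(s, config$link_threshold)
        matched_open <- eligible[m$row]
        matched_starter <- m$col
      }
    }

    if (length(matched_open) > 0) {
      gaps <- f - open$last_frame[matched_open] - 1L
      if (any(gaps < 0 | gaps > config$max_gap_frames)) {
        abort("Internal error: merge produced an out-of-bounds gap.")
      }
      tids <- starters[matched_starter]
      tracklet_track[as.character(tids)] <- open$track_id[matched_open]
      open$tail_tid[matched_open] <- tids
      open$last_frame[matched_open] <- as.integer(end_by_tid[as.character(tids)])
    }
    new_starters <- setdiff(starters, starters[matched_starter])
    if (length(new_starters) > 0) {
      ids <- seq.int(next_track, length.out = length(new_starters))
      tracklet_track[as.character(new_starters)] <- ids
      next_track <- next_track + length(new_starters)
      open <- bind_rows(open, tibble(
        track_id = ids, tail_tid = new_starters,
        last_frame = as.integer(end_by_tid[as.character(new_starters)])
      ))
    }
  }

  det$track_id <- unname(tracklet_track[as.character(det$tracklet_id)])
  det
}

# Ordered tracklet pairs admissible for merging: gap in [0, max_gap],
# spatial gate scaled by gap + 1, with step-2 features attached.
candidate_pairs_step2 <- function(summaries, config) {
  ends <- summaries |> select(tid_a = "tid", a_end = "end_frame")
  starts <- summaries |> select(tid_b = "tid", b_start = "start_frame")
  p <- inner_join(
    ends |> mutate(lo = .data$a_end + 1L, hi = .data$a_end + config$max_gap_frames + 1L),
    starts,
    by = join_by("lo" <= "b_start", "hi" >= "b_start")
  ) |>
    select("tid_a", "tid_b") |>
    filter(.data$tid_a != .data$tid_b)
  if (nrow(p) == 0) {
    return(dplyr::bind_cols(
      tibble(tid_a = integer(), tid_b = integer()),
      tibble(!!!setNames(rep(list(numeric()), 6), step2_feature_names()))
    ))
  }
  p <- step2_features_bulk(p, summaries)
  gap <- summaries$start_frame[match(p$tid_b, summaries$tid)] -
    summaries$end_frame[match(p$tid_a, summaries$tid)] - 1L
  p[p$euclidean_px <= config$gating_radius_px * (gap + 1), ]
}

#' Chunked two-step tracking with ID-based long-range merging
#'
#' Splits the recording into intervals of `chunk_seconds`, runs both
#' tracking steps independently within each chunk (chunk outputs depend
#' only on chunk inputs, so chunks are parallelizable in principle), and
#' then concatenates tracks across chunks whose assigned consensus IDs are
#' equal. Equal-ID candidates are joined in temporal order; when several
#' non-overlapping candidates are available, the spatially nearest abutting
#' endpoint wins. Same-ID tracks that overlap in time are kept separate and
#' reported as conflicts.
#'
#' @param det A validated detection table.
#' @param model_step1,model_step2 Fitted correspondence models.
#' @param config A [tracking_config()].
#' @return A list of class `bee_long_tracks`: `detections` (with
#'   `tracklet_id`, `track_id`, `long_track_id` columns), `tracks` (per
#'   long track: assigned ID, confidence, span), and `conflicts`.
#' @export
track_chunked <- function(det, model_step1, model_step2,
                          config = tracking_config()) {
  det <- arrange(as_tibble(det), .data$cam, .data$frame, .data$det_id)
  chunk_frames <- max(1L, as.integer(round(config$chunk_seconds * config$fps)))
  f0 <- min(det$frame)
  det$chunk <- (det$frame - f0) %/% chunk_frames

  out <- vector("list", length(unique(det$chunk)))
  offset <- 0L
  for (ci in sort(unique(det$chunk))) {
    d <- det[det$chunk == ci, , drop = FALSE]
    d <- link_detections(d, model_step1, config)
    d <- merge_tracklets(d, model_step2, config)
    d$tracklet_id <- d$tracklet_id + offset
    d$track_id <- d$track_id + offset
    offset <- offset + max(d$tracklet_id, d$track_id)
    out[[which(sort(unique(det$chunk)) == ci)]] <- d
  }
  d <- bind_rows(out)

  ids <- assign_track_ids(d, id_col = "track_id")
  spans <- d |>
    group_by(.data$track_id) |>
    summarise(
      start_frame = min(.data$frame), end_frame = max(.data$frame),
      first_x = .data$x[which.min(.data$frame)],
      first_y = .data$y[which.min(.data$frame)],
      last_x = .data$x[which.max(.data$frame)],
      last_y = .data$y[which.max(.data$frame)],
      .groups = "drop"
    ) |>
    inner_join(select(ids, "track_id", "assigned_id"), by = "track_id") |>
    arrange(.data$assigned_id, .data$start_frame, .data$track_id)

  long_of <- setNames(rep(NA_integer_, nrow(spans)), as.character(spans$track_id))
  conflicts <- list()
  next_long <- 1L
  for (aid in unique(spans$assigned_id)) {
    grp <- spans[spans$assigned_id == aid, ]
    chains <- tibble(
      long_id = integer(), end_frame = integer(),
      last_x = numeric(), last_y = numeric()
    )
    for (r in seq_len(nrow(grp))) {
      free <- which(chains$end_frame < grp$start_frame[r])
      if (length(free) > 0) {
        dist <- sqrt((chains$last_x[free] - grp$first_x[r])^2 +
          (chains$last_y[free] - grp$first_y[r])^2)
        k <- free[which.min(dist)]
        long_of[as.character(grp$track_id[r])] <- chains$long_id[k]
        chains$end_frame[k] <- grp$end_frame[r]
        chains$last_x[k] <- grp$last_x[r]
        chains$last_y[k] <- grp$last_y[r]
      } else {
        if (nrow(chains) > 0) {
          conflicts <- c(conflicts, list(tibble(
            assigned_id = aid, track_id = grp$track_id[r],
            overlaps_long_id = chains$long_id[which.max(chains$end_frame)]
          )))
        }
        long_of[as.character(grp$track_id[r])] <- next_long
        chains <- bind_rows(chains, tibble(
          long_id = next_long, end_frame = grp$end_frame[r],
          last_x = grp$last_x[r], last_y = grp$last_y[r]
        ))
        next_long <- next_long + 1L
      }
    }
  }
  d$long_track_id <- unname(long_of[as.character(d$track_id)])
  d$chunk <- NULL

  long_tracks <- assign_track_ids(d, id_col = "long_track_id")
  conflicts <- if (length(conflicts) > 0) {
    bind_rows(conflicts)
  } else {
    tibble(assigned_id = integer(), track_id = integer(), overlaps_long_id = integer())
  }
  if (nrow(conflicts) > 0) {
    warn(sprintf(
      "%d same-ID track(s) overlap in time and were kept separate.",
      nrow(conflicts)
    ))
  }
  structure(
    list(detections = d, tracks = long_tracks, conflicts = conflicts),
    class = "bee_long_tracks"
  )
}

#' @export
print.bee_long_tracks <- function(x, ...) {
  cat(sprintf(
    "<bee_long_tracks> %d detections in %d long tracks (%d conflicts)\n",
    nrow(x$detections), nrow(x$tracks), nrow(x$conflicts)
  ))
  invisible(x)
}
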