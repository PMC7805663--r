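#' Labeled detection-pair samples for the step-1 classifier
#'
#' Enumerates every ordered pair of detections in consecutive frames (same
#' camera) whose Euclidean distance is within the gating radius, labels it
#' positive when both detections carry the same ground-truth ID (and
#' neither is a false positive), and attaches the three step-1 features.
#' The enumeration is a pure function of the ground truth and the radius.
#'
#' @param gt Ground-truth detection table with a `truth_id` column.
#' @param gating_radius_px Spatial gate in pixels.
#' @return A tibble with columns `det_id_1`, `det_id_2`, the
#'   [step1_features()] columns, and `label` (logical).
#' @export
generate_step1_samples <- function(gt, gating_radius_px = 200) {
  gt <- as_tibble(gt)
  stopifnot("truth_id" %in% names(gt))
  cols <- c("det_id", "frame", "cam", "x", "y", "theta", bit_cols(), "truth_id")
  a <- gt[, cols]
  b <- gt[, cols]
  names(a) <- paste0(names(a), "_1")
  names(b) <- paste0(names(b), "_2")
  b$frame_before <- b$frame_2 - 1L
  pairs <- inner_join(
    a, b,
    by = c("cam_1" = "cam_2", "frame_1" = "frame_before"),
    relationship = "many-to-many"
  )
  if (nrow(pairs) == 0) {
    return(tibble(
      det_id_1 = integer(), det_id_2 = integer(),
      euclidean_px = numeric(), angular_diff_rad = numeric(),
      id_manhattan = numeric(), label = logical()
    ))
  }
  d2 <- (pairs$x_1 - pairs$x_2)^2 + (pairs$y_1 - pairs$y_2)^2
  pairs <- pairs[d2 <= gating_radius_px^2, ]
  bits1 <- as.matrix(pairs[, paste0(bit_cols(), "_1"), drop = FALSE])
  bits2 <- as.matrix(pairs[, paste0(bit_cols(), "_2"), drop = FALSE])
  tibble(
    det_id_1 = pairs$det_id_1,
    det_id_2 = pairs$det_id_2,
    euclidean_px = sqrt((pairs$x_1 - pairs$x_2)^2 + (pairs$y_1 - pairs$y_2)^2),
    angular_diff_rad = angular_difference(pairs$theta_1, pairs$theta_2),
    id_manhattan = rowSums(abs(bits1 - bits2)),
    label = pairs$truth_id_1 == pairs$truth_id_2 &
      pairs$truth_id_1 != FALSE_POSITIVE &
      pairs$truth_id_2 != FALSE_POSITIVE
  )
}

# Running medians of all prefixes of x (one value per prefix length),
# maintained by sorted insertion.
cumulative_median <- function(x) {
  n <- length(x)
  out <- numeric(n)
  s <- numeric(0)
  for (k in seq_len(n)) {
    i <- findInterval(x[k], s)
    s <- append(s, x[k], after = i)
    h <- k %/% 2L
    out[k] <- if (k %% 2L == 1L) s[h + 1L] else (s[h] + s[h + 1L]) / 2
  }
  out
}

# Summaries of every prefix (s = 1..n as end index) or suffix of one
# ground-truth track, in the tracklet_summaries() column format.
track_prefix_summaries <- function(det, reverse = FALSE) {
  det <- arrange(det, .data$frame)
  if (reverse) det <- det[rev(seq_len(nrow(det))), ]
  n <- nrow(det)
  bits <- as.matrix(det[, bit_cols(), drop = FALSE])
  cmean <- apply(bits, 2, cumsum) / seq_len(n)
  cmed <- apply(bits, 2, cumulative_median)
  if (n == 1) {
    cmean <- matrix(cmean, nrow = 1)
    cmed <- matrix(cmed, nrow = 1)
  }
  conf <- apply(abs(cmed - 0.5), 1, min)
  k <- seq_len(n)
  prev <- pmax(k - 1, 1)
  two_plus <- n >= 2
  if (!reverse) {
    out <- tibble(
      frag_n = k,
      start_frame = det$frame[1], end_frame = det$frame,
      first_x = det$x[1], first_y = det$y[1],
      last_x = det$x, last_y = det$y,
      first_theta = det$theta[1], last_theta = det$theta,
      fwd_vx = ifelse(k >= 2, det$x - det$x[prev], 0),
      fwd_vy = ifelse(k >= 2, det$y - det$y[prev], 0),
      bwd_vx = if (two_plus) det$x[2] - det$x[1] else 0,
      bwd_vy = if (two_plus) det$y[2] - det$y[1] else 0
    )
    # a prefix of length 1 has no motion at either end
    out$bwd_vx[1] <- 0
    out$bwd_vy[1] <- 0
  } else {
    # det is reversed: row k is the suffix starting at original index n-k+1
    out <- tibble(
      frag_n = k,
      start_frame = det$frame, end_frame = det$frame[1],
      first_x = det$x, first_y = det$y,
      last_x = det$x[1], last_y = det$y[1],
      first_theta = det$theta, last_theta = det$theta[1],
      fwd_vx = if (two_plus) det$x[1] - det$x[2] else 0,
      fwd_vy = if (two_plus) det$y[1] - det$y[2] else 0,
      bwd_vx = ifelse(k >= 2, det$x[prev] - det$x, 0),
      bwd_vy = ifelse(k >= 2, det$y[prev] - det$y, 0)
    )
    out$fwd_vx[1] <- 0
    out$fwd_vy[1] <- 0
  }
  cmean_t <- as_tibble(cmean, .name_repair = "minimal")
  names(cmean_t) <- paste0("mean_", bit_cols())
  out <- dplyr::bind_cols(out, cmean_t)
  out$confidence <- conf
  out
}

# Vectorized summaries of short fragments (length 1 or 2: the pieces the
# sub-track rule produces). `s`, `e` are row indices into the sorted track.
short_fragment_summaries <- function(det, s, e) {
  stopifnot(all(e - s <= 1L))
  bits <- as.matrix(det[, bit_cols(), drop = FALSE])
  bmean <- (bits[s, , drop = FALSE] + bits[e, , drop = FALSE]) / 2
  colnames(bmean) <- paste0("mean_", bit_cols())
  two <- e > s
  out <- tibble(
    frag_n = e - s + 1L,
    start_frame = det$frame[s], end_frame = det$frame[e],
    first_x = det$x[s], first_y = det$y[s],
    last_x = det$x[e], last_y = det$y[e],
    first_theta = det$theta[s], last_theta = det$theta[e],
    fwd_vx = ifelse(two, det$x[e] - det$x[s], 0),
    fwd_vy = ifelse(two, det$y[e] - det$y[s], 0)
  )
  out$bwd_vx <- out$fwd_vx
  out$bwd_vy <- out$fwd_vy
  out <- dplyr::bind_cols(out, as_tibble(bmean))
  # for fragments this short the per-bit median equals the mean
  out$confidence <- apply(abs(bmean - 0.5), 1, min)
  out
}

#' Labeled tracklet-pair samples for the step-2 classifier
#'
#' Builds training pairs from ground-truth tracks under three rules:
#' \enumerate{
#'   \item Positive samples: every track is split once at each time step
#'     into a (prefix, suffix) pair.
#'   \item Additional positives: every contiguous sub-track of length 3 or
#'     less is split at all possible positions, enriching the sample pool
#'     with short fragments.
#'   \item Negative samples: every ordered pair of tracks with different
#'     IDs that overlap in time (up to the gap bound) is split at each time
#'     step `t`, pairing the first track's detections up to `t` with the
#'     second track's detections after `t`.
#' }
#' Only pairs whose split gap lies in `[0, max_gap]` are emitted, and
#' samples are deduplicated on their fragment extents and label. The
#' result carries the six [step2_features()] columns.
#'
#' @param gt Ground-truth detection table with `truth_id` and
#'   `truth_track_id` columns; false positives are ignored (they belong to
#'   no track).
#' @param max_gap Largest allowed gap at the split, frames.
#' @return A tibble with fragment extent columns (`track_a`,
#'   `a_start_frame`, `a_end_frame`, `track_b`, `b_start_frame`,
#'   `b_end_frame`), the six feature columns, and `label`.
#' @export
generate_step2_samples <- function(gt, max_gap = 14L) {
  gt <- as_tibble(gt)
  stopifnot(all(c("truth_id", "truth_track_id") %in% names(gt)))
  real <- gt |>
    filter(.data$truth_id != FALSE_POSITIVE, !is.na(.data$truth_track_id)) |>
    arrange(.data$truth_track_id, .data$frame)
  empty <- tibble(
    track_a = integer(), a_start_frame = integer(), a_end_frame = integer(),
    track_b = integer(), b_start_frame = integer(), b_end_frame = integer(),
    !!!setNames(rep(list(numeric()), 6), step2_feature_names()),
    label = logical()
  )
  if (nrow(real) == 0) {
    return(empty)
  }
  tracks <- split(real, real$truth_track_id)
  track_ids <- as.integer(names(tracks))
  info <- tibble(
    track = track_ids,
    bee = vapply(tracks, function(d) d$truth_id[1], numeric(1)),
    start = vapply(tracks, function(d) min(d$frame), integer(1)),
    end = vapply(tracks, function(d) max(d$frame), integer(1)),
    n = vapply(tracks, nrow, integer(1))
  )

  # fragment requests: (track, s, e) by detection index within the track
  frags <- list()
  samples <- list()
  add <- function(lst, item) c(lst, list(item))

  # rule 1: full-track splits; rule 2: sub-tracks of length <= 3
  for (ti in seq_along(tracks)) {
    d <- tracks[[ti]]
    n <- nrow(d)
    tid <- track_ids[ti]
    if (n >= 2) {
      k <- seq_len(n - 1)
      ok <- (d$frame[k + 1] - d$frame[k] - 1L) <= max_gap
      if (any(ok)) {
        samples <- add(samples, tibble(
          track_a = tid, a_s = 1L, a_e = k[ok],
          track_b = tid, b_s = k[ok] + 1L, b_e = n, label = TRUE
        ))
      }
      # length-2 sub-tracks: split (i | i+1)
      i <- seq_len(n - 1)
      ok2 <- (d$frame[i + 1] - d$frame[i] - 1L) <= max_gap
      if (any(ok2)) {
        samples <- add(samples, tibble(
          track_a = tid, a_s = i[ok2], a_e = i[ok2],
          track_b = tid, b_s = i[ok2] + 1L, b_e = i[ok2] + 1L, label = TRUE
        ))
      }
    }
    if (n >= 3) {
      i <- seq_len(n - 2)
      g1 <- (d$frame[i + 1] - d$frame[i] - 1L) <= max_gap
      g2 <- (d$frame[i + 2] - d$frame[i + 1] - 1L) <= max_gap
      if (any(g1)) {
        samples <- add(samples, tibble(
          track_a = tid, a_s = i[g1], a_e = i[g1],
          track_b = tid, b_s = i[g1] + 1L, b_e = i[g1] + 2L, label = TRUE
        ))
      }
      if (any(g2)) {
        samples <- add(samples, tibble(
          track_a = tid, a_s = i[g2], a_e = i[g2] + 1L,
          track_b = tid, b_s = i[g2] + 2L, b_e = i[g2] + 2L, label = TRUE
        ))
      }
    }
  }

  # rule 3: same-time-step splits of different-ID track pairs
  cand <- dplyr::cross_join(
    rename_with_prefix(info, "a_"),
    rename_with_prefix(info, "b_")
  ) |>
    filter(
      .data$a_bee != .data$b_bee,
      .data$a_start <= .data$b_end - 1L,
      .data$b_start <= .data$a_end + max_gap + 1L
    )
  if (nrow(cand) > 0) {
    for (r in seq_len(nrow(cand))) {
      da <- tracks[[as.character(cand$a_track[r])]]
      db <- tracks[[as.character(cand$b_track[r])]]
      t_lo <- da$frame[1]
      t_hi <- db$frame[nrow(db)] - 1L
      if (t_lo > t_hi) next
      t <- t_lo:t_hi
      ka <- findInterval(t, da$frame) # last A index with frame <= t
      kb <- findInterval(t, db$frame) + 1L # first B index with frame > t
      ok <- ka >= 1L & kb <= nrow(db)
      if (!any(ok)) next
      ka <- ka[ok]
      kb <- kb[ok]
      gap <- db$frame[kb] - da$frame[ka] - 1L
      ok <- gap >= 0L & gap <= max_gap
      if (!any(ok)) next
      samples <- add(samples, distinct(tibble(
        track_a = cand$a_track[r], a_s = 1L, a_e = ka[ok],
        track_b = cand$b_track[r], b_s = kb[ok], b_e = nrow(db), label = FALSE
      )))
    }
  }

  if (length(samples) == 0) {
    return(empty)
  }
  samples <- distinct(bind_rows(samples))

  # fragment summaries: prefixes (s = 1), suffixes (e = n), short leftovers
  needed <- distinct(bind_rows(
    select(samples, track = "track_a", s = "a_s", e = "a_e"),
    select(samples, track = "track_b", s = "b_s", e = "b_e")
  ))
  nmap <- setNames(info$n, as.character(info$track))
  needed$track_n <- as.integer(nmap[as.character(needed$track)])
  needed$kind <- ifelse(
    needed$s == 1L, "prefix",
    ifelse(needed$e == needed$track_n, "suffix", "short")
  )

  sum_list <- list()
  for (tid in unique(needed$track)) {
    d <- tracks[[as.character(tid)]]
    sub <- needed[needed$track == tid, ]
    if (any(sub$kind == "prefix")) {
      ps <- track_prefix_summaries(d, reverse = FALSE)
      idx <- sub$e[sub$kind == "prefix"]
      sum_list <- add(sum_list, dplyr::bind_cols(
        tibble(track = tid, s = 1L, e = idx), ps[idx, ]
      ))
    }
    if (any(sub$kind == "suffix")) {
      ss <- track_prefix_summaries(d, reverse = TRUE)
      idx <- sub$s[sub$kind == "suffix"]
      sum_list <- add(sum_list, dplyr::bind_cols(
        tibble(track = tid, s = idx, e = nrow(d)),
        ss[nrow(d) - idx + 1L, ]
      ))
    }
    shorts <- sub[sub$kind == "short", ]
    if (nrow(shorts) > 0) {
      sum_list <- add(sum_list, dplyr::bind_cols(
        tibble(track = shorts$track, s = shorts$s, e = shorts$e),
        short_fragment_summaries(d, shorts$s, shorts$e)
      ))
    }
  }
  summaries <- bind_rows(sum_list) |>
    distinct(.data$track, .data$s, .data$e, .keep_all = TRUE) |>
    mutate(tid = row_number())

  key <- summaries |> select("track", "s", "e", "tid")
  samples <- samples |>
    inner_join(key, by = c("track_a" = "track", "a_s" = "s", "a_e" = "e")) |>
    rename(tid_a = "tid") |>
    inner_join(key, by = c("track_b" = "track", "b_s" = "s", "b_e" = "e")) |>
    rename(tid_b = "tid")

  feat <- step2_features_bulk(
    select(samples, "tid_a", "tid_b"),
    select(summaries, -"track", -"s", -"e")
  )
  ext <- summaries |> select("tid", "start_frame", "end_frame")
  out <- samples |>
    select("track_a", "track_b", "label", "tid_a", "tid_b") |>
    inner_join(rename_with_prefix(ext, "a_"), by = c("tid_a" = "a_tid")) |>
    inner_join(rename_with_prefix(ext, "b_"), by = c("tid_b" = "b_tid")) |>
    dplyr::bind_cols(feat[, step2_feature_names()]) |>
    select(
      "track_a", "a_start_frame", "a_end_frame",
      "track_b", "b_start_frame", "b_end_frame",
      all_of(step2_feature_names()), "label"
    )
  arrange(
    out, .data$track_a, .data$track_b,
    .data$a_end_frame, .data$b_start_frame, .data$a_start_frame, .data$b_end_frame
  )
}
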