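#' Read and write detection tables as CSV
#'
#' The on-disk format is a UTF-8 CSV with a header row, `.` decimal
#' separator, and the columns of [detection_columns()] (plus `truth_id` /
#' `truth_track_id` when present). Soft bits and positions round-trip at
#' full double precision. Reading validates the schema and aborts with a
#' diagnostic naming the offending rows.
#'
#' @param path File path.
#' @return `read_detections()` returns a validated detection tibble.
#' @export
read_detections <- function(path) {
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  int_cols <- intersect(
    c("det_id", "frame", "cam", "truth_id", "truth_track_id"),
    header
  )
  spec <- do.call(readr::cols, c(
    setNames(
      replicate(length(int_cols), readr::col_integer(), simplify = FALSE),
      int_cols
    ),
    list(.default = readr::col_double())
  ))
  det <- suppressWarnings(readr::read_csv(path, col_types = spec, progress = FALSE))
  probs <- readr::problems(det)
  if (nrow(probs) > 0) {
    abort(paste0(
      "Malformed rows in ", path, ": e.g. row ", probs$row[1],
      " (", probs$expected[1], " but got ", probs$actual[1], ")"
    ))
  }
  validate_detections(det)
}

#' @param det A detection table.
#' @rdname read_detections
#' @return `write_detections()` returns `path` invisibly.
#' @export
write_detections <- function(det, path) {
  keep <- intersect(
    c(detection_columns(), "truth_id", "truth_track_id"),
    names(det)
  )
  readr::write_csv(as_tibble(det)[, keep], path, progress = FALSE)
  invisible(path)
}

#' Read and write track collections as newline-delimited JSON
#'
#' One JSON object per line per track: `track_id`, `assigned_id`,
#' `confidence`, and the ordered member detections as parallel `det_id`
#' and `frame` arrays. Membership lists are variable-length, which is why
#' tracks are not kept in the rectangular CSV.
#'
#' @param det A detection table with a track membership column.
#' @param ids The matching [assign_track_ids()] table.
#' @param path File path.
#' @param track_col Membership column name.
#' @return `write_tracks_ndjson()` returns `path` invisibly;
#'   `read_tracks_ndjson()` returns a tibble with one row per track and a
#'   list-column `detections`.
#' @export
write_tracks_ndjson <- function(det, ids, path, track_col = "track_id") {
  det <- arrange(as_tibble(det), .data[[track_col]], .data$frame)
  members <- split(
    det[, c("det_id", "frame")],
    det[[track_col]]
  )
  ids <- arrange(ids, .data[[names(ids)[1]]])
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (r in seq_len(nrow(ids))) {
    tid <- ids[[1]][r]
    m <- members[[as.character(tid)]]
    line <- jsonlite::toJSON(
      list(
        track_id = tid,
        assigned_id = ids$assigned_id[r],
        confidence = ids$confidence[r],
        det_id = m$det_id,
        frame = m$frame
      ),
      auto_unbox = TRUE, digits = NA
    )
    writeLines(line, con)
  }
  invisible(path)
}

#' @rdname write_tracks_ndjson
#' @export
read_tracks_ndjson <- function(path) {
  lines <- readLines(path)
  rows <- purrr::map(lines, function(l) {
    x <- jsonlite::fromJSON(l)
    tibble(
      track_id = x$track_id,
      assigned_id = x$assigned_id,
      confidence = x$confidence,
      detections = list(tibble(det_id = x$det_id, frame = x$frame))
    )
  })
  bind_rows(rows)
}

#' Write a run manifest
#'
#' Records everything needed to regenerate an output: the command, the
#' configuration, the seed, package version, and the MD5 of each input
#' file.
#'
#' @param path Manifest file path (JSON).
#' @param command Character tag for the operation.
#' @param config A configuration list (`tracking_config`/`sim_config`).
#' @param seed Integer seed used.
#' @param inputs Character vector of input file paths.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, command, config = NULL, seed = NULL,
                               inputs = character()) {
  manifest <- list(
    command = command,
    package_version = as.character(utils::packageVersion("beetrackr")),
    seed = seed,
    config = unclass(config),
    inputs = lapply(inputs, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    })
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
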