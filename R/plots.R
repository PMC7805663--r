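#' Plot trajectories from a detection table
#'
#' Draws the comb-plane paths of a tracked (or ground-truth) detection
#' table, one line per track.
#'
#' @param det A detection table.
#' @param id_col Membership column to color by.
#' @param max_tracks Cap on the number of tracks drawn (largest first).
#' @return A ggplot object.
#' @export
plot_tracks <- function(det, id_col = "track_id", max_tracks = 50) {
  det <- filter(as_tibble(det), !is.na(.data[[id_col]]))
  keep <- det |>
    count(.data[[id_col]], sort = TRUE) |>
    slice(seq_len(min(n(), max_tracks))) |>
    pull(1)
  det <- filter(det, .data[[id_col]] %in% keep) |>
    arrange(.data[[id_col]], .data$frame)
  ggplot2::ggplot(
    det,
    ggplot2::aes(.data$x, .data$y, group = factor(.data[[id_col]]),
      color = factor(.data[[id_col]])
    )
  ) +
    ggplot2::geom_path(alpha = 0.7, show.legend = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
}

#' Plot a simulated colony
#'
#' @param object A `bee_sim` from [simulate_colony()].
#' @param ... Passed to [plot_tracks()].
#' @return A ggplot object showing the ground-truth trajectories.
#' @method autoplot bee_sim
#' @export
autoplot.bee_sim <- function(object, ...) {
  plot_tracks(object$detections, id_col = "truth_track_id", ...)
}

#' Plot a metrics report
#'
#' Bar chart of the percentage-scale metrics of one or several
#' [compute_metrics()] reports (e.g. baseline vs. step 1 vs. step 2 vs.
#' perfect tracking).
#'
#' @param object A `bee_metrics` row, or several row-bound together with a
#'   `method` column.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bee_metrics
#' @export
autoplot.bee_metrics <- function(object, ...) {
  df <- as_tibble(object)
  if (!"method" %in% names(df)) df$method <- "result"
  long <- df |>
    select("method", dplyr::starts_with("pct_")) |>
    tidyr::pivot_longer(-"method", names_to = "metric", values_to = "percent")
  ggplot2::ggplot(
    long,
    ggplot2::aes(.data$metric, .data$percent, fill = .data$method)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "%") +
    ggplot2::theme_minimal()
}
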