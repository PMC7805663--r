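#' Optimal bipartite assignment of correspondence scores
#'
#' Solves the rectangular assignment problem on a matrix of correspondence
#' probabilities with the Hungarian method (cost `1 - score`), keeping the
#' matching that maximizes the total score among all complete matchings of
#' size `min(nrow, ncol)`. Matches scoring below `threshold` are discarded
#' *after* solving, so the global optimum decides the pairing and the
#' threshold only decides which pairings are believed. Entries that should
#' never be assigned (ungated candidates) are encoded as score 0.
#'
#' @param scores Numeric matrix with entries in \[0, 1\]; rows are open
#'   items, columns are candidates.
#' @param threshold Minimum score for a match to be kept.
#' @return A tibble with columns `row`, `col`, `score`, one row per kept
#'   match; zero rows for an empty matrix.
#' @export
#' @examples
#' solve_assignment(matrix(c(0.9, 0.2, 0.1, 0.8), 2, 2))
solve_assignment <- function(scores, threshold = 0.5) {
  empty <- tibble(row = integer(), col = integer(), score = numeric())
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  nr <- nrow(scores)
  nc <- ncol(scores)
  if (nr == 0 || nc == 0) {
    return(empty)
  }
  if (any(scores < 0 | scores > 1)) {
    abort("Assignment scores must lie in [0, 1].")
  }
  if (nr <= nc) {
    sol <- clue::solve_LSAP(scores, maximum = TRUE)
    row <- seq_len(nr)
    col <- as.integer(sol)
  } else {
    sol <- clue::solve_LSAP(t(scores), maximum = TRUE)
    col <- seq_len(nc)
    row <- as.integer(sol)
  }
  keep <- scores[cbind(row, col)] >= threshold
  tibble(row = row[keep], col = col[keep], score = scores[cbind(row, col)][keep]) |>
    arrange(.data$row)
}
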