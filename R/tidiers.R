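# broom-style tidiers for result containers.

#' Tidy a contact map into long format
#' @param x A `contact_map`.
#' @param ... Unused.
#' @return Tibble with `bin1`, `bin2`, `start1_kb`, `start2_kb`,
#'   `distance_kb`, `prob`.
#' @export
tidy.contact_map <- function(x, ...) {
  n <- nrow(x$matrix)
  idx <- expand.grid(bin1 = seq_len(n) - 1L, bin2 = seq_len(n) - 1L)
  tibble(bin1 = idx$bin1, bin2 = idx$bin2,
         start1_kb = idx$bin1 * x$bin_size_kb,
         start2_kb = idx$bin2 * x$bin_size_kb,
         distance_kb = abs(idx$bin2 - idx$bin1) * x$bin_size_kb,
         prob = as.vector(x$matrix))
}

#' @export
glance.contact_map <- function(x, ...) {
  tibble(n_bins = nrow(x$matrix), bin_size_kb = x$bin_size_kb,
         n_snapshots = x$n_snapshots, chain_length_kb = x$chain_length_kb,
         mean_offdiag_prob = mean(x$matrix[upper.tri(x$matrix)]))
}

#' Tidy an occupancy track
#' @param x An `occupancy_track`.
#' @param ... Unused.
#' @return The per-bin tibble (`bin`, `start_kb`, `end_kb`, `value`).
#' @export
tidy.occupancy_track <- function(x, ...) x$track

#' Tidy a comparison result
#' @param x A `comparison_result`.
#' @param ... Unused.
#' @return One-row tibble with the score and its metadata.
#' @export
tidy.comparison_result <- function(x, ...) {
  tibble(chi2 = x$chi2, n_pairs_used = x$n_pairs_used,
         n_excluded = x$n_excluded, scale_factor = x$scale_factor,
         band_min_kb = x$distance_range_kb[1],
         band_max_kb = x$distance_range_kb[2],
         variance_mode = x$variance_mode)
}

#' @export
glance.comparison_result <- function(x, ...) tidy(x)

#' Tidy a grid summary into long format
#' @param x A `grid_summary`.
#' @param ... Unused.
#' @return Tibble with one row per populated grid cell plus `is_best`.
#' @export
tidy.grid_summary <- function(x, ...) {
  ax <- names(x$axes)
  grid <- expand.grid(i = seq_along(x$axes[[1]]), j = seq_along(x$axes[[2]]))
  out <- tibble(
    !!ax[1] := x$axes[[1]][grid$i],
    !!ax[2] := x$axes[[2]][grid$j],
    chi2 = x$scores[cbind(grid$i, grid$j)],
    is_best = grid$i == x$best_cell$row & grid$j == x$best_cell$col
  )
  out[!is.na(out$chi2), ]
}
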