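# Quantitative agreement between model and reference contact maps.

#' Contact probability versus genomic distance
#'
#' Mean contact probability over all bin pairs at each genomic separation —
#' the standard P(s) diagnostic of a Hi-C map.
#'
#' @param map A `contact_map`.
#' @return Tibble with `distance_kb` and `prob`.
#' @export
ps_curve <- function(map) {
  stopifnot(inherits(map, "contact_map"))
  n <- nrow(map$matrix)
  prob <- vapply(0:(n - 1), function(s) {
    idx <- seq_len(n - s)
    mean(map$matrix[cbind(idx, idx + s)])
  }, numeric(1))
  tibble(distance_kb = (0:(n - 1)) * map$bin_size_kb, prob = prob)
}

#' Rebin a contact map by block averaging
#'
#' @param map A `contact_map`.
#' @param bin_kb Target bin size, an integer multiple of the current size.
#' @return A `contact_map` at the coarser resolution.
#' @export
rebin_map <- function(map, bin_kb) {
  stopifnot(inherits(map, "contact_map"))
  if (bin_kb == map$bin_size_kb) return(map)
  if (bin_kb %% map$bin_size_kb != 0) {
    validation_error(sprintf(
      "target bin (%g kb) must be an integer multiple of the current bin (%g kb)",
      bin_kb, map$bin_size_kb))
  }
  fac <- as.integer(bin_kb / map$bin_size_kb)
  n <- nrow(map$matrix)
  grp <- ((seq_len(n) - 1L) %/% fac) + 1L
  n2 <- max(grp)
  agg <- matrix(0, n2, n2)
  cnt <- matrix(0, n2, n2)
  for (a in seq_len(n)) {
    ga <- grp[a]
    agg[ga, ] <- agg[ga, ] + rowsum(map$matrix[a, ], grp)[, 1]
    cnt[ga, ] <- cnt[ga, ] + rowsum(rep(1, n), grp)[, 1]
  }
  mat <- agg / cnt
  diag(mat) <- 1
  structure(list(matrix = (mat + t(mat)) / 2, counts = NULL, pair_mult = NULL,
                 bin_size_kb = bin_kb, n_snapshots = map$n_snapshots,
                 chrom_label = map$chrom_label,
                 chain_length_kb = map$chain_length_kb),
            class = "contact_map")
}

#' Chi-squared agreement score between two contact maps
#'
#' Distance-banded, variance-normalized, scale-aligned mean squared
#' deviation: the model map is first multiplied by a scale factor obtained by
#' least-squares alignment of the mean P(s) curves over the band (weighted by
#' the number of pairs per distance), then
#' `chi2 = mean((scale * model_ij - ref_ij)^2 / sigma2_ij)` over off-diagonal
#' bin pairs whose genomic separation lies in `band_kb`. Lower is better; the
#' argmin over a parameter grid defines the optimum.
#'
#' @param model,reference `contact_map` objects at the same binning (rebin
#'   the reference first otherwise).
#' @param band_kb Length-2 distance band (min, max), defaults to one bin up
#'   to half the chain.
#' @param variance_mode `"replicates"` (per-pair variance of the replicate
#'   model maps, divided by the replicate count), `"poisson"` (Poisson
#'   approximation `ref_ij / n_snapshots` of the reference), or `"fixed"`
#'   (`sigma2` supplied).
#' @param replicate_maps List of per-replicate model maps
#'   (for `variance_mode = "replicates"`; see [contact_map_replicates()]).
#' @param sigma2 Scalar or matrix variance for `variance_mode = "fixed"`.
#' @param pool_variance_by_distance Pool the replicate variance over all bin
#'   pairs at the same genomic separation before weighting. Per-pair variance
#'   estimates from a modest replicate count are heavy-tailed (a few
#'   underestimates dominate the score); pooling by distance stabilizes the
#'   weights and is recommended when ranking parameter-grid cells.
#' @return A `comparison_result`: `chi2`, `n_pairs_used`, `n_excluded`
#'   (zero-variance pairs dropped), `distance_range_kb`, `scale_factor`.
#' @export
chi2_score <- function(model, reference, band_kb = NULL,
                       variance_mode = c("replicates", "poisson", "fixed"),
                       replicate_maps = NULL, sigma2 = NULL,
                       pool_variance_by_distance = FALSE) {
  stopifnot(inherits(model, "contact_map"), inherits(reference, "contact_map"))
  variance_mode <- match.arg(variance_mode)
  if (model$bin_size_kb != reference$bin_size_kb ||
      nrow(model$matrix) != nrow(reference$matrix)) {
    validation_error(paste0(
      "model and reference maps have mismatched binning (",
      sprintf("%g kb x %d vs %g kb x %d", model$bin_size_kb, nrow(model$matrix),
              reference$bin_size_kb, nrow(reference$matrix)),
      "); rebin the reference with rebin_map() first"))
  }
  n <- nrow(model$matrix)
  span_kb <- n * model$bin_size_kb
  if (is.null(band_kb)) band_kb <- c(model$bin_size_kb, span_kb / 2)
  if (band_kb[1] > band_kb[2] || band_kb[2] > span_kb) {
    validation_error("band_kb must lie within the map span")
  }

  sep <- abs(outer(seq_len(n), seq_len(n), "-")) * model$bin_size_kb
  in_band <- sep >= band_kb[1] & sep <= band_kb[2] & upper.tri(sep)

  # scale: least-squares alignment of the mean P(s) curves over the band,
  # weighted by the number of pairs contributing at each distance
  pm <- ps_curve(model)
  pr <- ps_curve(reference)
  sel <- pm$distance_kb >= band_kb[1] & pm$distance_kb <= band_kb[2]
  w <- (n - pm$distance_kb / model$bin_size_kb)[sel]
  denom <- sum(w * pm$prob[sel]^2)
  scale_factor <- if (denom > 0) sum(w * pm$prob[sel] * pr$prob[sel]) / denom else 1

  m <- model$matrix[in_band]
  r <- reference$matrix[in_band]
  if (all(m == r)) scale_factor <- 1  # self-comparison is exactly zero
  s2 <- switch(variance_mode,
    replicates = {
      if (is.null(replicate_maps) || length(replicate_maps) < 2) {
        validation_error("variance_mode='replicates' needs >= 2 replicate_maps")
      }
      vals <- sapply(replicate_maps, function(mp) mp$matrix[in_band])
      v <- apply(vals, 1, stats::var) / length(replicate_maps)
      if (pool_variance_by_distance) v <- stats::ave(v, sep[in_band], FUN = mean)
      v
    },
    poisson = r / max(1, reference$n_snapshots),
    fixed = {
      if (is.null(sigma2)) validation_error("variance_mode='fixed' needs sigma2")
      if (is.matrix(sigma2)) sigma2[in_band] else rep(sigma2, sum(in_band))
    })

  dev2 <- (scale_factor * m - r)^2
  usable <- is.finite(s2) & s2 > 0
  n_excluded <- sum(!usable)
  if (sum(usable) == 0) {
    # degenerate but well-defined: identical maps have zero deviation everywhere
    chi2 <- if (all(dev2 == 0)) 0 else Inf
    n_used <- sum(in_band)
  } else {
    chi2 <- mean(dev2[usable] / s2[usable])
    n_used <- sum(usable)
    if (all(dev2 == 0)) chi2 <- 0
  }
  structure(list(chi2 = chi2, n_pairs_used = n_used, n_excluded = n_excluded,
                 distance_range_kb = band_kb, scale_factor = scale_factor,
                 variance_mode = variance_mode),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> chi2 = %.4g over %d pairs (%d excluded), band %g-%g kb, scale %.4g (%s variance)\n",
              x$chi2, x$n_pairs_used, x$n_excluded, x$distance_range_kb[1],
              x$distance_range_kb[2], x$scale_factor, x$variance_mode))
  invisible(x)
}

#' Summarize a parameter-grid sweep
#'
#' Collects per-cell chi-squared scores into a dense (possibly sparse-filled)
#' score matrix over a declared two-axis grid, and locates the best cell
#' (minimum score among present cells).
#'
#' @param results Tibble (or data frame) with one row per evaluated cell:
#'   two parameter-coordinate columns and a `chi2` column.
#' @param axes Named list of the two axis value vectors; defaults to the
#'   sorted unique values found in `results`.
#' @return A `grid_summary`: `axes`, `scores` matrix (NA where absent),
#'   `best_cell` (row/col indices and values), `n_cells`.
#' @export
grid_summarize <- function(results, axes = NULL) {
  results <- as_tibble(as.data.frame(results))
  if (!"chi2" %in% names(results)) {
    validation_error("results must contain a 'chi2' column")
  }
  coord_cols <- setdiff(names(results), "chi2")
  if (length(coord_cols) != 2) {
    validation_error("results must have exactly two parameter-coordinate columns")
  }
  if (is.null(axes)) {
    axes <- lapply(results[coord_cols], function(v) sort(unique(v)))
    names(axes) <- coord_cols
  }
  a1 <- axes[[1]]; a2 <- axes[[2]]
  i <- match(results[[coord_cols[1]]], a1)
  j <- match(results[[coord_cols[2]]], a2)
  if (anyNA(i) || anyNA(j)) {
    validation_error("result coordinates must lie on the declared grid axes")
  }
  if (anyDuplicated(cbind(i, j))) {
    validation_error("duplicate grid cell in results")
  }
  scores <- matrix(NA_real_, length(a1), length(a2),
                   dimnames = list(as.character(a1), as.character(a2)))
  scores[cbind(i, j)] <- results$chi2
  best <- which(scores == min(scores, na.rm = TRUE), arr.ind = TRUE)[1, ]
  structure(list(
    axes = axes,
    scores = scores,
    best_cell = list(row = unname(best[1]), col = unname(best[2]),
                     values = setNames(c(a1[best[1]], a2[best[2]]), names(axes)),
                     chi2 = scores[best[1], best[2]]),
    n_cells = sum(!is.na(scores))
  ), class = "grid_summary")
}

#' @export
print.grid_summary <- function(x, ...) {
  cat(sprintf("<grid_summary> %s x %s grid (%d/%d cells), best: %s = %s, %s = %s (chi2 = %.4g)\n",
              length(x$axes[[1]]), length(x$axes[[2]]), x$n_cells,
              length(x$scores), names(x$axes)[1], x$best_cell$values[1],
              names(x$axes)[2], x$best_cell$values[2], x$best_cell$chi2))
  invisible(x)
}

#' Write a grid summary as a tab-separated score table
#' @param summary A `grid_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_grid_scores <- function(summary, path) {
  stopifnot(inherits(summary, "grid_summary"))
  df <- tidy(summary)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
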