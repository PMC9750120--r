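# Virtual Hi-C maps, virtual ChIP-seq occupancy tracks, and three-way
# contact statistics from snapshot streams.

.bin_index <- function(n_monomers, monomer_size_kb, bin_kb) {
  if (bin_kb %% monomer_size_kb != 0) {
    validation_error(sprintf(
      "bin size (%g kb) must be a multiple of the monomer size (%g kb)",
      bin_kb, monomer_size_kb))
  }
  per_bin <- as.integer(bin_kb / monomer_size_kb)
  as.integer((seq_len(n_monomers) - 1L) %/% per_bin)
}

.stream_inputs <- function(snapshots) {
  if (inherits(snapshots, "snapshot_stream")) {
    list(positions = snapshot_positions(snapshots),
         legs = snapshot_legs(snapshots),
         n_monomers = snapshots$genome$n_monomers,
         monomer_size_kb = snapshots$genome$monomer_size_kb,
         chain_length_kb = snapshots$genome$chain_length_kb,
         chrom_label = snapshots$genome$chrom_label,
         params = snapshots$params)
  } else {
    abort("expected a snapshot_stream", class = "polyloopsim_error")
  }
}

#' Virtual Hi-C contact map
#'
#' Declares a contact between monomers `(i, j)` in a snapshot when their
#' Euclidean distance is at most `cutoff_nm`, pools monomer contacts into
#' genomic bins, and normalizes per snapshot and per bin-pair size into a
#' contact probability. The (uninformative) diagonal is set to 1 by
#' convention.
#'
#' @param snapshots A [run_coupled()] `snapshot_stream`.
#' @param cutoff_nm Contact capture radius; default `contact_cutoff_nm` from
#'   the run's parameters (2 x monomer diameter).
#' @param bin_kb Output bin size; default `hic_bin_kb`.
#' @return A `contact_map`: probability `matrix` (symmetric, entries in
#'   `[0, 1]`), raw `counts`, `pair_mult` (monomer pairs per bin pair),
#'   `bin_size_kb`, `n_snapshots`, `chrom_label`, `chain_length_kb`.
#' @export
contact_map <- function(snapshots, cutoff_nm = NULL, bin_kb = NULL) {
  inp <- .stream_inputs(snapshots)
  if (length(inp$positions) == 0) {
    abort("empty snapshot stream: no conformations to measure",
          class = "polyloopsim_error")
  }
  cutoff_nm <- cutoff_nm %||% inp$params$contact_cutoff_nm
  bin_kb <- bin_kb %||% inp$params$hic_bin_kb
  bins <- .bin_index(inp$n_monomers, inp$monomer_size_kb, bin_kb)
  n_bins <- max(bins) + 1L
  counts <- cpp_contact_counts(inp$positions, cutoff_nm, bins, n_bins)
  .new_contact_map(counts, bins, n_bins, length(inp$positions), bin_kb,
                   inp$chrom_label, inp$chain_length_kb)
}

.new_contact_map <- function(counts, bins, n_bins, n_snapshots, bin_kb,
                             chrom_label, chain_length_kb) {
  mult <- cpp_pair_multiplicity(bins, n_bins)
  prob <- counts / (n_snapshots * mult)
  prob[!is.finite(prob)] <- 0
  diag(prob) <- 1
  structure(list(matrix = prob, counts = counts, pair_mult = mult,
                 bin_size_kb = bin_kb, n_snapshots = n_snapshots,
                 chrom_label = chrom_label, chain_length_kb = chain_length_kb),
            class = "contact_map")
}

#' Construct a contact map from a dense matrix
#'
#' Wraps an externally produced symmetric probability matrix (e.g. a
#' reference dataset) in the `contact_map` container.
#'
#' @param mat Symmetric numeric matrix.
#' @param bin_kb Bin size in kb.
#' @param n_snapshots Normalization denominator the probabilities came from
#'   (used by the Poisson variance approximation).
#' @param chrom_label Chromosome label.
#' @return A `contact_map`.
#' @export
contact_map_from_matrix <- function(mat, bin_kb, n_snapshots = 1,
                                    chrom_label = "chrSim") {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) validation_error("contact matrix must be square")
  if (max(abs(mat - t(mat))) > 1e-8) validation_error("contact matrix must be symmetric")
  structure(list(matrix = (mat + t(mat)) / 2, counts = NULL, pair_mult = NULL,
                 bin_size_kb = bin_kb, n_snapshots = n_snapshots,
                 chrom_label = chrom_label,
                 chain_length_kb = nrow(mat) * bin_kb),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> %d x %d bins of %g kb (%s), %d snapshot(s)\n",
              nrow(x$matrix), ncol(x$matrix), x$bin_size_kb, x$chrom_label,
              x$n_snapshots))
  invisible(x)
}

#' Per-replicate contact maps
#'
#' @param stream A `snapshot_stream` with >= 1 replicates.
#' @inheritParams contact_map
#' @return List of `contact_map`, one per replicate (used for the
#'   replicate-variance mode of [chi2_score()]).
#' @export
contact_map_replicates <- function(stream, cutoff_nm = NULL, bin_kb = NULL) {
  stopifnot(inherits(stream, "snapshot_stream"))
  lapply(seq_along(stream$replicates), function(r) {
    sub <- stream
    sub$replicates <- stream$replicates[r]
    contact_map(sub, cutoff_nm = cutoff_nm, bin_kb = bin_kb)
  })
}

#' Virtual ChIP-seq occupancy profile
#'
#' Mean number of LEF legs per genomic bin per snapshot — the simulation
#' analogue of an SMC ChIP-seq enrichment track. Summed over bins the track
#' equals twice the mean number of bound LEFs.
#'
#' @inheritParams contact_map
#' @param bin_kb Track bin size; default `hic_bin_kb`.
#' @return An `occupancy_track` with a `track` tibble
#'   (`bin`, `start_kb`, `end_kb`, `value`).
#' @export
chip_profile <- function(snapshots, bin_kb = NULL) {
  inp <- .stream_inputs(snapshots)
  if (length(inp$legs) == 0) {
    abort("empty snapshot stream: no samples to measure",
          class = "polyloopsim_error")
  }
  bin_kb <- bin_kb %||% inp$params$hic_bin_kb
  bins <- .bin_index(inp$n_monomers, inp$monomer_size_kb, bin_kb)
  n_bins <- max(bins) + 1L
  acc <- numeric(n_bins)
  for (legs in inp$legs) {
    if (nrow(legs) == 0) next
    idx <- bins[c(legs[, 1], legs[, 2]) + 1L] + 1L
    acc <- acc + tabulate(idx, nbins = n_bins)
  }
  values <- acc / length(inp$legs)
  structure(list(
    track = tibble(bin = seq_len(n_bins) - 1L,
                   start_kb = (seq_len(n_bins) - 1L) * bin_kb,
                   end_kb = pmin(seq_len(n_bins) * bin_kb, inp$chain_length_kb),
                   value = values),
    bin_size_kb = bin_kb, n_snapshots = length(inp$legs),
    chrom_label = inp$chrom_label, chain_length_kb = inp$chain_length_kb
  ), class = "occupancy_track")
}

#' @export
print.occupancy_track <- function(x, ...) {
  cat(sprintf("<occupancy_track> %d bins of %g kb (%s), total %.3g legs/snapshot\n",
              nrow(x$track), x$bin_size_kb, x$chrom_label, sum(x$track$value)))
  invisible(x)
}

#' Three-way contact statistics
#'
#' Counts monomer triplets `(i < j < k)` whose three pairwise distances are
#' all within the capture radius, pooled into canonical bin triplets. An
#' optional per-snapshot cap subsamples triplets i.i.d. and reweights counts
#' by `total/kept` (unbiased estimator).
#'
#' @inheritParams contact_map
#' @param max_triplets_per_snapshot Cap per snapshot; 0 disables subsampling.
#' @param subsample_seed Seed for the subsampling draws.
#' @return A `triplet_counts` tibble (`bin_i <= bin_j <= bin_k`, `count`,
#'   `frequency` per snapshot) with map metadata in attributes.
#' @export
threeway_counts <- function(snapshots, cutoff_nm = NULL, bin_kb = NULL,
                            max_triplets_per_snapshot = 0, subsample_seed = 1) {
  inp <- .stream_inputs(snapshots)
  cutoff_nm <- cutoff_nm %||% inp$params$contact_cutoff_nm
  bin_kb <- bin_kb %||% inp$params$hic_bin_kb
  bins <- .bin_index(inp$n_monomers, inp$monomer_size_kb, bin_kb)
  df <- cpp_triplet_counts(inp$positions, cutoff_nm, bins,
                           as.integer(max_triplets_per_snapshot),
                           as.integer(subsample_seed))
  out <- as_tibble(df)
  out$frequency <- out$count / max(1, length(inp$positions))
  structure(out, class = c("triplet_counts", class(out)),
            bin_size_kb = bin_kb, n_snapshots = length(inp$positions),
            chrom_label = inp$chrom_label)
}

#' Write an occupancy track as bedGraph
#'
#' Four-column bedGraph (chrom, start, end, value) with 0-based half-open
#' coordinates in bp, one line per bin; zero values are written explicitly.
#'
#' @param track An [chip_profile()] `occupancy_track`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "occupancy_track"))
  df <- data.frame(chrom = track$chrom_label,
                   start = format(track$track$start_kb * 1000, scientific = FALSE, trim = TRUE),
                   end = format(track$track$end_kb * 1000, scientific = FALSE, trim = TRUE),
                   value = track$track$value)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph file into an occupancy track
#'
#' @param path bedGraph file (chrom, start, end, value; bp coordinates).
#' @return An `occupancy_track`.
#' @export
read_bedgraph <- function(path) {
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          col.names = c("chrom", "start", "end", "value"),
                          stringsAsFactors = FALSE)
  bin_kb <- (df$end[1] - df$start[1]) / 1000
  structure(list(
    track = tibble(bin = seq_len(nrow(df)) - 1L,
                   start_kb = df$start / 1000,
                   end_kb = df$end / 1000,
                   value = df$value),
    bin_size_kb = bin_kb, n_snapshots = NA_integer_,
    chrom_label = df$chrom[1], chain_length_kb = max(df$end) / 1000
  ), class = "occupancy_track")
}
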