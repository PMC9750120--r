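# cooler-schema HDF5 I/O, delegated to a bundled Python helper (h5py).

find_python <- function() {
  for (cand in c("python", "python3")) {
    p <- Sys.which(cand)
    if (nzchar(p)) return(unname(p))
  }
  abort("no python interpreter found on PATH (needed for cooler HDF5 I/O)",
        class = "polyloopsim_error")
}

.cooler_helper <- function() {
  path <- system.file("python", "cooler_io.py", package = "polyloopsim")
  if (!nzchar(path)) abort("bundled cooler helper not found", class = "polyloopsim_error")
  path
}

.run_cooler_helper <- function(args) {
  py <- find_python()
  out <- suppressWarnings(system2(py, c(shQuote(.cooler_helper()), args),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status") %||% 0
  if (status != 0) {
    abort(paste0("cooler helper failed:\n", paste(out, collapse = "\n")),
          class = "polyloopsim_io_error")
  }
  invisible(out)
}

#' Write a contact map in cooler format
#'
#' Produces a single-resolution cooler-schema HDF5 file
#' (`chroms`/`bins`/`pixels`/`indexes`) with upper-triangular sparse pixel
#' storage (`bin1_id <= bin2_id`); contact probabilities are stored in the
#' `count` column as floats. The file round-trips through [read_cooler()] to
#' the same dense matrix.
#'
#' @param map A [contact_map()].
#' @param path Output `.cool` path.
#' @return `path`, invisibly.
#' @export
write_cooler <- function(map, path) {
  stopifnot(inherits(map, "contact_map"))
  n_bins <- nrow(map$matrix)
  bin_bp <- map$bin_size_kb * 1000
  chrom_len <- map$chain_length_kb * 1000
  starts <- (seq_len(n_bins) - 1) * bin_bp
  ends <- pmin(seq_len(n_bins) * bin_bp, chrom_len)

  ut <- which(upper.tri(map$matrix, diag = TRUE) & map$matrix != 0, arr.ind = TRUE)
  pixels <- data.frame(bin1 = ut[, 1] - 1L, bin2 = ut[, 2] - 1L,
                       count = map$matrix[ut])

  td <- tempfile("coolerio")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  bins_tsv <- file.path(td, "bins.tsv")
  pixels_tsv <- file.path(td, "pixels.tsv")
  utils::write.table(
    data.frame(start = format(starts, scientific = FALSE, trim = TRUE),
               end = format(ends, scientific = FALSE, trim = TRUE)),
    bins_tsv, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(format(pixels, digits = 17, scientific = TRUE, trim = TRUE),
                     pixels_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  .run_cooler_helper(c("write", shQuote(path), shQuote(bins_tsv),
                       shQuote(pixels_tsv), shQuote(map$chrom_label),
                       format(chrom_len, scientific = FALSE),
                       format(bin_bp, scientific = FALSE)))
  invisible(path)
}

#' Read a cooler file into a contact map
#'
#' @param path A single-resolution `.cool` file.
#' @param n_snapshots Normalization denominator to record on the returned
#'   map (cooler files do not carry it).
#' @return A [contact_map()] with the dense symmetric matrix.
#' @export
read_cooler <- function(path, n_snapshots = 1) {
  if (!file.exists(path)) {
    abort(sprintf("cooler file not found: %s", path), class = "polyloopsim_io_error")
  }
  td <- tempfile("coolerio")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  bins_tsv <- file.path(td, "bins.tsv")
  pixels_tsv <- file.path(td, "pixels.tsv")
  .run_cooler_helper(c("read", shQuote(path), shQuote(bins_tsv), shQuote(pixels_tsv)))

  hdr <- readLines(bins_tsv, n = 1)
  chrom <- sub(".*chrom=([^ ]+).*", "\\1", hdr)
  bins <- utils::read.table(bins_tsv, header = FALSE, comment.char = "#",
                            col.names = c("start", "end"))
  n_bins <- nrow(bins)
  bin_kb <- (bins$end[1] - bins$start[1]) / 1000
  mat <- matrix(0, n_bins, n_bins)
  if (file.info(pixels_tsv)$size > 0) {
    px <- utils::read.table(pixels_tsv, header = FALSE,
                            col.names = c("bin1", "bin2", "count"))
    idx1 <- cbind(px$bin1 + 1L, px$bin2 + 1L)
    mat[idx1] <- px$count
    mat[idx1[, c(2, 1), drop = FALSE]] <- px$count
  }
  structure(list(matrix = mat, counts = NULL, pair_mult = NULL,
                 bin_size_kb = bin_kb, n_snapshots = n_snapshots,
                 chrom_label = chrom, chain_length_kb = max(bins$end) / 1000),
            class = "contact_map")
}

#' Write a contact map as dense whitespace-separated text
#' @param map A `contact_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dense_matrix <- function(map, path) {
  stopifnot(inherits(map, "contact_map"))
  utils::write.table(format(map$matrix, digits = 17, scientific = TRUE, trim = TRUE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a contact map (cooler HDF5 or dense text)
#'
#' Dispatches on the file: `.cool`/`.mcool` files go through the cooler
#' reader, anything else is parsed as a dense whitespace matrix.
#'
#' @param path Input file.
#' @param bin_kb Bin size (required for dense text input).
#' @param n_snapshots Normalization denominator to record.
#' @return A `contact_map`.
#' @export
read_contact_map <- function(path, bin_kb = NULL, n_snapshots = 1) {
  if (grepl("\\.m?cool$", path)) {
    return(read_cooler(path, n_snapshots = n_snapshots))
  }
  mat <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(mat) <- NULL
  if (is.null(bin_kb)) {
    abort("bin_kb is required when reading a dense text matrix",
          class = "polyloopsim_error")
  }
  contact_map_from_matrix(mat, bin_kb = bin_kb, n_snapshots = n_snapshots)
}
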