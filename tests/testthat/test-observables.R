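test_that("contact maps follow the geometry of explicit conformations", {
  # straight chain at rest length with cutoff 1.5x bond: only |i-j| <= 1 touch
  pos <- straight_chain(30, 50)
  st <- fake_stream(list(pos))
  mp <- contact_map(st, cutoff_nm = 75, bin_kb = 2)
  expect_identical(mp$matrix, t(mp$matrix))
  offdiag <- abs(outer(1:30, 1:30, "-"))
  expect_true(all(mp$matrix[offdiag == 1] == 1))
  expect_true(all(mp$matrix[offdiag > 1] == 0))
  expect_true(all(diag(mp$matrix) == 1))
  expect_true(all(mp$matrix >= 0 & mp$matrix <= 1))
})

test_that("monomer-level contacts equal a brute-force distance threshold oracle", {
  # ring conformation
  n <- 50
  theta <- 2 * pi * (0:(n - 1)) / n
  R <- 50 / (2 * sin(pi / n))     # radius making neighbours 50 nm apart
  pos <- cbind(R * cos(theta), R * sin(theta), 0)
  st <- fake_stream(list(pos))
  cutoff <- 130
  mp <- contact_map(st, cutoff_nm = cutoff, bin_kb = 2)
  brute <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    if (i != j && sqrt(sum((pos[i, ] - pos[j, ])^2)) <= cutoff) brute[i, j] <- 1
  }
  diag(brute) <- 1
  expect_identical(mp$matrix, brute)
})

test_that("binning pools monomer pairs with the right normalization", {
  pos <- straight_chain(12, 50)
  st <- fake_stream(list(pos, pos))      # two identical snapshots
  mp <- contact_map(st, cutoff_nm = 75, bin_kb = 8)  # 4 monomers per bin
  # between adjacent bins: only the touching pair across the edge out of 16
  expect_equal(mp$matrix[1, 2], 1 / 16)
  expect_equal(mp$n_snapshots, 2L)
  expect_error(contact_map(fake_stream(list())), "empty")
})

test_that("occupancy tracks count LEF legs per bin per snapshot", {
  pos <- straight_chain(30, 50)
  legs0 <- matrix(integer(0), ncol = 2)
  legs1 <- cbind(5L, 20L)
  st <- fake_stream(list(pos, pos), list(legs1, legs1))
  tr <- chip_profile(st, bin_kb = 2)
  expect_equal(sum(tr$track$value), 2)          # one LEF = two legs
  expect_equal(tr$track$value[6], 1)            # monomer 5 -> bin 5 (0-based)
  st0 <- fake_stream(list(pos), list(legs0))
  expect_true(all(chip_profile(st0, bin_kb = 2)$track$value == 0))

  # live run: track total equals twice the mean bound LEF count
  p <- toy_params(chain_length_kb = 120, sim_time_min = 20,
                  equilibration_time_min = 0.5)
  stl <- run_coupled(p, build_genome(p), seed = 2)
  tr2 <- chip_profile(stl)
  mean_bound <- mean(vapply(stl$replicates[[1]], `[[`, numeric(1), "n_bound"))
  expect_equal(sum(tr2$track$value), 2 * mean_bound, tolerance = 1e-9)
})

test_that("three-way counts match a brute-force triple loop", {
  # equilateral triangle of beads within the cutoff: exactly one triplet
  pos <- rbind(c(0, 0, 0), c(60, 0, 0), c(30, 52, 0), c(500, 0, 0))
  st <- fake_stream(list(pos))
  tc <- threeway_counts(st, cutoff_nm = 70, bin_kb = 2)
  expect_identical(nrow(tc), 1L)
  expect_equal(tc$count, 1)
  expect_equal(c(tc$bin_i, tc$bin_j, tc$bin_k), c(0, 1, 2))

  # straight chain with small cutoff: no triplets at all
  st2 <- fake_stream(list(straight_chain(20, 50)))
  expect_identical(nrow(threeway_counts(st2, cutoff_nm = 60, bin_kb = 2)), 0L)

  # random cloud vs O(n^3) oracle
  set.seed(31)
  pos3 <- matrix(stats::runif(30 * 3, 0, 250), ncol = 3)
  st3 <- fake_stream(list(pos3))
  tc3 <- threeway_counts(st3, cutoff_nm = 120, bin_kb = 2)
  brute <- 0
  for (i in 1:28) for (j in (i + 1):29) for (k in (j + 1):30) {
    d <- c(sqrt(sum((pos3[i, ] - pos3[j, ])^2)),
           sqrt(sum((pos3[i, ] - pos3[k, ])^2)),
           sqrt(sum((pos3[j, ] - pos3[k, ])^2)))
    if (all(d <= 120)) brute <- brute + 1
  }
  expect_equal(sum(tc3$count), brute)

  # every counted triplet implies its three pairwise contacts
  mp3 <- contact_map(st3, cutoff_nm = 120, bin_kb = 2)$matrix
  for (r in seq_len(nrow(tc3))) {
    ii <- tc3$bin_i[r] + 1; jj <- tc3$bin_j[r] + 1; kk <- tc3$bin_k[r] + 1
    expect_true(mp3[ii, jj] > 0 && mp3[ii, kk] > 0 && mp3[jj, kk] > 0)
  }
})

test_that("subsampled triplet counts stay unbiased in expectation", {
  set.seed(8)
  pos <- matrix(stats::runif(40 * 3, 0, 200), ncol = 3)
  st <- fake_stream(rep(list(pos), 40))
  full <- sum(threeway_counts(st, cutoff_nm = 120, bin_kb = 2)$count)
  capped <- sum(threeway_counts(st, cutoff_nm = 120, bin_kb = 2,
                                max_triplets_per_snapshot = 25,
                                subsample_seed = 5)$count)
  expect_gt(capped, 0.7 * full)
  expect_lt(capped, 1.3 * full)
})

test_that("cooler files round-trip and store upper-triangular pixels", {
  n <- 3
  mat <- matrix(c(1, .2, 0, .2, 1, .05, 0, .05, 1), 3)
  mp <- contact_map_from_matrix(mat, bin_kb = 10, n_snapshots = 50)
  f <- tempfile(fileext = ".cool")
  write_cooler(mp, f)
  rt <- read_cooler(f, n_snapshots = 50)
  expect_identical(rt$matrix, mp$matrix)       # bitwise on stored values
  expect_equal(rt$bin_size_kb, 10)
  expect_equal(rt$chain_length_kb, 30)
  expect_identical(rt$chrom_label, "chrSim")

  # inspect the raw pixel table: bin1 <= bin2, at most n(n+1)/2 entries
  td <- tempfile(); dir.create(td)
  polyloopsim:::.run_cooler_helper(c("read", shQuote(f),
                                     shQuote(file.path(td, "b.tsv")),
                                     shQuote(file.path(td, "p.tsv"))))
  px <- utils::read.table(file.path(td, "p.tsv"),
                          col.names = c("bin1", "bin2", "count"))
  expect_true(all(px$bin1 <= px$bin2))
  expect_lte(nrow(px), n * (n + 1) / 2)
  # bins table spans the chain
  bins <- utils::read.table(file.path(td, "b.tsv"), comment.char = "#",
                            col.names = c("start", "end"))
  expect_equal(max(bins$end), 30000)
  expect_equal(min(bins$start), 0)
})

test_that("bedGraph output is 0-based half-open with explicit zeros", {
  pos <- straight_chain(3, 50)
  st <- fake_stream(list(pos), list(matrix(integer(0), ncol = 2)))
  tr <- chip_profile(st, bin_kb = 2)
  f <- tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, f)
  lines <- readLines(f)
  expect_length(lines, 3)
  fields <- do.call(rbind, strsplit(lines, "\t"))
  expect_equal(as.numeric(fields[, 3]), c(2000, 4000, 6000))
  expect_equal(as.numeric(fields[, 2]), c(0, 2000, 4000))
  expect_true(all(fields[, 4] == "0"))         # zeros written, not omitted

  tr$track$value <- c(0.25, 1.5, 0)
  write_bedgraph(tr, f)
  rt <- read_bedgraph(f)
  expect_equal(rt$track$value, tr$track$value)
  expect_equal(rt$bin_size_kb, tr$bin_size_kb)
})
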