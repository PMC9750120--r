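test_that("initial conformations satisfy every hard constraint, reproducibly", {
  p <- toy_params()
  m <- energy_model(p)
  c2 <- init_conformation(2, m, seed = 1)
  expect_equal(sqrt(sum((c2$positions[1, ] - c2$positions[2, ])^2)),
               m$bond_rest_nm, tolerance = 1e-9)

  cc <- init_conformation(400, m, seed = 7)
  expect_true(check_conformation(cc, m))
  cc2 <- init_conformation(400, m, seed = 7)
  expect_identical(cc$positions, cc2$positions)
  cc3 <- init_conformation(400, m, seed = 8)
  expect_false(identical(cc$positions, cc3$positions))
})

test_that("energies match closed forms and an independent term-by-term oracle", {
  p <- toy_params()
  m <- energy_model(p)
  conf <- list(positions = straight_chain(10, m$bond_rest_nm),
               loop_bonds = matrix(integer(0), ncol = 2), time_min = 0)
  class(conf) <- "conformation"
  e <- total_energy(conf, m)
  expect_equal(as.numeric(e), 0)

  # one 90-degree kink: bending energy = bend_k * (1 - cos 90) = bend_k
  kink <- straight_chain(3, m$bond_rest_nm)
  kink[3, ] <- c(kink[2, 1], m$bond_rest_nm, 0)
  confk <- conf; confk$positions <- kink
  ek <- total_energy(confk, m)
  expect_equal(as.numeric(ek), m$bend_k, tolerance = 1e-9)
  expect_equal(unname(attr(ek, "components")["bend"]), m$bend_k, tolerance = 1e-9)

  # random (valid) conformation against the R oracle, with loop bonds
  confr <- init_conformation(60, m, seed = 3)
  confr$loop_bonds <- cbind(left = c(5L, 20L), right = c(15L, 50L))
  er <- total_energy(confr, m)
  expect_equal(as.numeric(er),
               energy_oracle_r(confr$positions, confr$loop_bonds, m),
               tolerance = 1e-8)
})

test_that("Metropolis sweeps preserve invariants and respect the temperature limit", {
  p <- toy_params()
  m <- energy_model(p)
  conf <- init_conformation(80, m, seed = 2)
  r <- mc_sweep(conf, m, n_sweeps = 200, seed = 5)
  expect_true(check_conformation(r$conformation, m))
  expect_gt(r$acceptance, 0.02)
  e <- total_energy(r$conformation, m)
  expect_true(is.finite(as.numeric(e)))

  # near-zero temperature: energy cannot go up (within float noise)
  e0 <- as.numeric(total_energy(r$conformation, m))
  rc <- mc_sweep(r$conformation, m, n_sweeps = 50, seed = 6, temperature = 1e-9)
  expect_lte(as.numeric(total_energy(rc$conformation, m)), e0 + 1e-6)
})

test_that("the ideal-chain submodel recovers R^2(s) proportional to s", {
  p <- toy_params()
  m <- energy_model(p, bend_k = 0, hardcore_factor = 0)
  m$hardcore_nm <- 0
  conf <- init_conformation(24, m, seed = 4)
  # long equilibration, then decorrelated samples
  r <- mc_sweep(conf, m, n_sweeps = 5000, seed = 9)
  rs <- r$rng_state
  conf <- r$conformation
  seps <- c(4, 8, 12)
  acc <- matrix(0, 0, length(seps))
  msb <- c()
  for (k in 1:400) {
    r <- mc_sweep(conf, m, n_sweeps = 25, rng_state = rs)
    conf <- r$conformation; rs <- r$rng_state
    pos <- conf$positions
    msb <- c(msb, mean(rowSums((pos[-1, ] - pos[-nrow(pos), ])^2)))
    acc <- rbind(acc, vapply(seps, function(s) {
      idx <- seq_len(nrow(pos) - s)
      mean(rowSums((pos[idx + s, ] - pos[idx, ])^2))
    }, numeric(1)))
  }
  b2 <- mean(msb)                 # effective squared bond length
  r2 <- colMeans(acc)
  expect_equal(r2 / (seps * b2), rep(1, length(seps)), tolerance = 0.12)
})

test_that("loop bonds track the bound LEFs and contract to bonded distances", {
  p <- toy_params(chain_length_kb = 600)
  m <- energy_model(p)
  g <- build_genome(p)
  sys <- lef_system(p, g, seed = 1)
  conf <- init_conformation(300, m, seed = 1)
  expect_identical(nrow(sync_loops(conf, sys)$loop_bonds), 0L)

  sys$bound[1] <- 1L
  sys$left[1] <- 100L; sys$right[1] <- 200L
  conf <- sync_loops(conf, sys)
  expect_equal(unname(conf$loop_bonds[1, ]), c(100L, 200L))

  r <- mc_sweep(conf, m, n_sweeps = 600, seed = 3)
  pos <- r$conformation$positions
  d_loop <- sqrt(sum((pos[101, ] - pos[201, ])^2))
  d_bonds <- sqrt(rowSums((pos[-1, ] - pos[-300, ])^2))
  # the persistent loop bond behaves like a chain bond
  expect_lt(d_loop, m$bond_max_nm)
  expect_gt(d_loop, m$bond_min_nm * 0.9)
  expect_lt(abs(d_loop - mean(d_bonds)), 4 * stats::sd(d_bonds) + 5)
})

test_that("coupled runs emit the scheduled snapshots and stay valid", {
  p <- toy_params(chain_length_kb = 120, sim_time_min = 2,
                  snapshot_interval_min = 1, equilibration_time_min = 0.2)
  g <- build_genome(p)
  st <- run_coupled(p, g, seed = 6)
  expect_length(st$replicates, 1)
  expect_length(st$replicates[[1]], 2)   # sim_time 2, interval 1
  m <- energy_model(p)
  for (s in st$replicates[[1]]) {
    conf <- structure(list(positions = s$positions, loop_bonds = s$legs,
                           time_min = s$time_min), class = "conformation")
    expect_true(check_conformation(conf, m))
  }
  # reproducibility of the full stream
  st2 <- run_coupled(p, g, seed = 6)
  expect_identical(st$replicates, st2$replicates)

  # no extruders: every snapshot has an empty loop set
  p0 <- toy_params(chain_length_kb = 120, n_lef_target = 0, sim_time_min = 2,
                   equilibration_time_min = 0.2)
  st0 <- run_coupled(p0, build_genome(p0), seed = 6)
  expect_true(all(vapply(st0$replicates[[1]],
                         function(s) nrow(s$legs) == 0, logical(1))))
})

test_that("the bare homopolymer shows monotonically decaying contact probability", {
  p <- toy_params(chain_length_kb = 100, n_lef_target = 0, sim_time_min = 80,
                  snapshot_interval_min = 1, equilibration_time_min = 40,
                  n_replicates = 3)
  st <- run_coupled(p, build_genome(p), seed = 10)
  ps <- ps_curve(contact_map(st))
  # decreasing beyond a few monomers, up to sampling noise in the rare
  # long-range contacts: rank correlation and block means
  sel <- ps$distance_kb >= 6 & ps$distance_kb <= 50
  v <- ps$prob[sel]
  expect_lt(stats::cor(ps$distance_kb[sel], v, method = "spearman"), -0.6)
  blocks <- split(v, cut(seq_along(v), 5))
  mb <- vapply(blocks, mean, numeric(1))
  expect_true(all(diff(mb[1:3]) < 0))
  expect_gt(mb[1], 10 * mb[5])
})

test_that("fixed-loop energy samples reweight between temperatures (detailed balance)", {
  p <- toy_params()
  m <- energy_model(p, hardcore_factor = 0)
  m$hardcore_nm <- 0
  conf <- init_conformation(12, m, seed = 13)
  sample_E <- function(temp, seed) {
    cf <- conf; rs <- NULL; E <- numeric(0)
    r <- mc_sweep(cf, m, n_sweeps = 500, seed = seed, temperature = temp)
    cf <- r$conformation; rs <- r$rng_state
    for (k in 1:800) {
      r <- mc_sweep(cf, m, n_sweeps = 5, rng_state = rs, temperature = temp)
      cf <- r$conformation; rs <- r$rng_state
      E <- c(E, as.numeric(total_energy(cf, m)))
    }
    E
  }
  E1 <- sample_E(1.0, 17)
  E2 <- sample_E(1.25, 19)
  # mean energy must increase with temperature, and the Boltzmann estimate
  # <E exp(-dB E)>/<exp(-dB E)> at T2 reweighted from T1 must agree with <E>_T2
  expect_gt(mean(E2), mean(E1))
  dB <- 1 / 1.25 - 1 / 1.0
  w <- exp(-dB * (E1 - mean(E1)))
  rew <- sum(E1 * w) / sum(w)
  expect_equal(rew, mean(E2), tolerance = 0.12)
})
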