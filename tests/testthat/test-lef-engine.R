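test_that("population targets and arithmetic follow the density parameterization", {
  p <- sim_params(chain_length_kb = 6000, monomer_size_kb = 2, lef_density_kb = 60)
  expect_identical(p$n_lef_target, 100L)  # one bound LEF per 60 kb of a 6 Mb chain
  g <- build_genome(toy_params())
  sys <- lef_system(toy_params(), g)
  # velocity 20 kb/min over 2 kb monomers -> 10 steps/min/leg
  expect_equal(sys$step_rate, 10)
  # balance k_bind = k_off * n / (pool - n) with pool = 2n
  expect_equal(sys$k_bind, sys$k_unbind)
  expect_error(lef_system(sim_params(chain_length_kb = 20, monomer_size_kb = 2,
                                     n_lef_target = 8, sim_time_min = 1),
                          build_genome(sim_params(chain_length_kb = 20,
                                                  monomer_size_kb = 2,
                                                  n_lef_target = 8,
                                                  sim_time_min = 1))),
               "n_lef_target", class = "polyloopsim_validation_error")
})

test_that("an empty population never produces extrusion events", {
  p <- toy_params(n_lef_target = 0)
  sys <- lef_system(p, build_genome(p))
  adv <- advance_1d(sys, 100, record_events = TRUE)
  expect_identical(nrow(adv$events), 0L)
  expect_equal(sum(adv$stats$event_counts), 0)
})

test_that("identical seeds give identical event logs, different seeds differ", {
  p <- toy_params()
  g <- build_genome(p)
  a <- advance_1d(lef_system(p, g, seed = 5), 50, record_events = TRUE)
  b <- advance_1d(lef_system(p, g, seed = 5), 50, record_events = TRUE)
  c <- advance_1d(lef_system(p, g, seed = 6), 50, record_events = TRUE)
  expect_identical(a$events, b$events)
  expect_false(identical(a$events, c$events))
})

test_that("binding draws are uniform over admissible adjacent pairs", {
  sys <- single_lef_system(n_sites = 12, k_bind = 1, seed = 3)
  draws <- integer(2e4)
  s <- sys
  for (i in seq_along(draws)) {
    r <- bind_lef(s, 1)
    draws[i] <- r$system$left[1]
    s$rng_state <- r$system$rng_state  # keep the stream, discard the binding
  }
  tab <- table(factor(draws, levels = 0:10))
  pval <- stats::chisq.test(tab)$p.value
  expect_gt(pval, 1e-3)
})

test_that("loading-site binding anchors at the site and rejects blocked sites", {
  sys <- single_lef_system(n_sites = 12, loading_kb = 10)  # monomer 5
  for (i in 1:5) {
    r <- bind_lef(sys, 1)
    expect_identical(r$outcome, "bind")
    expect_identical(r$system$left[1], 5L)
    expect_identical(r$system$right[1], 6L)
    sys$rng_state <- r$system$rng_state
  }
  # impenetrable mode: site already hosting legs rejects the attempt
  p <- sim_params(chain_length_kb = 24, monomer_size_kb = 2, n_lef_target = 2,
                  velocity_kb_per_min = 10, unbind_rate_per_min = 1,
                  rebind_mode = "loading_sites", sim_time_min = 1)
  g <- build_genome(p, loading_spec = 10)
  s2 <- lef_system(p, g, seed = 1)
  r1 <- bind_lef(s2, 1)
  expect_identical(r1$outcome, "bind")
  r2 <- bind_lef(r1$system, 2)
  expect_identical(r2$outcome, "bind_reject")
  expect_identical(r2$system$bound, r1$system$bound)  # system unchanged
})

test_that("leg steps stall, pass and cross according to boundaries and collisions", {
  # impermeable boundary blocking leftward motion at monomer 5
  b <- data.frame(position_kb = 10, orientation = "blocks_leftward", permeability = 0)
  sys <- single_lef_system(n_sites = 12, boundary = b, loading_kb = 12)
  sys <- bind_lef(sys, 1)$system            # legs at (6, 7)
  r <- attempt_leg_step(sys, 1, "left")
  expect_identical(r$outcome, "stall_boundary")
  expect_identical(r$system$left[1], 6L)

  # permeability 1: always passes
  b1 <- data.frame(position_kb = 10, orientation = "blocks_leftward", permeability = 1)
  sysp <- single_lef_system(n_sites = 12, boundary = b1, loading_kb = 12)
  sysp <- bind_lef(sysp, 1)$system
  r <- attempt_leg_step(sysp, 1, "left")
  expect_identical(r$outcome, "pass_boundary")
  expect_identical(r$system$left[1], 5L)

  # chain end stalls
  syse <- single_lef_system(n_sites = 4, loading_kb = 0)
  syse <- bind_lef(syse, 1)$system          # legs (0, 1)
  expect_identical(attempt_leg_step(syse, 1, "left")$outcome, "stall_boundary")

  # collisions: impenetrable stalls, phantom crosses and moves
  mk2 <- function(collision) {
    p <- sim_params(chain_length_kb = 24, monomer_size_kb = 2, n_lef_target = 2,
                    velocity_kb_per_min = 10, unbind_rate_per_min = 1,
                    collision_mode = collision, rebind_mode = "loading_sites",
                    sim_time_min = 1)
    g <- build_genome(p, loading_spec = c(8, 12))
    s <- lef_system(p, g, seed = 2)
    # place LEF 1 at (4,5) and LEF 2 at (6,7) by direct construction
    s$bound <- c(1L, 1L)
    s$left <- c(4L, 6L); s$right <- c(5L, 7L)
    s$left_mobile <- c(1L, 1L); s$right_mobile <- c(1L, 1L)
    s
  }
  ri <- attempt_leg_step(mk2("impenetrable"), 1, "right")
  expect_identical(ri$outcome, "stall_collision")
  expect_identical(ri$system$right[1], 5L)
  rp <- attempt_leg_step(mk2("phantom"), 1, "right")
  expect_identical(rp$outcome, "cross_phantom")
  expect_identical(rp$system$right[1], 6L)

  # contract violations
  expect_error(attempt_leg_step(single_lef_system(), 1, "left"), "not bound")
  pasym <- single_lef_system(extrusion = "asymmetric", loading_kb = 10, seed = 4)
  pasym <- bind_lef(pasym, 1)$system
  anchored <- if (pasym$left_mobile[1] == 1) "right" else "left"
  expect_error(attempt_leg_step(pasym, 1, anchored), "anchored")
})

test_that("time-averaged loop length approaches the closed form 2v/k and v/k", {
  for (ext in c("symmetric", "asymmetric")) {
    p <- sim_params(chain_length_kb = 3000, monomer_size_kb = 2, n_lef_target = 1,
                    velocity_kb_per_min = 40, unbind_rate_per_min = 1,
                    extrusion_mode = ext, sim_time_min = 10)
    g <- build_genome(p)
    sys <- lef_system(p, g, seed = 5, pool_size = 1, k_bind_per_min = 1)
    adv <- advance_1d(sys, 5000)
    expect_gt(adv$stats$n_unbind, 2000)
    mean_loop_kb <- adv$stats$loop_integral_monomer_min /
      adv$stats$bound_integral_lef_min * p$monomer_size_kb
    expected <- if (ext == "symmetric") 2 * 40 else 40
    expect_lt(abs(mean_loop_kb - expected) / expected, 0.1)
  }
})

test_that("stationary bound fraction matches the two-state closed form", {
  sys <- single_lef_system(n_sites = 100, step_rate_kb = 10,
                           k_unbind = 2, k_bind = 3, seed = 2)
  adv <- advance_1d(sys, 8000)
  expect_lt(abs(adv$stats$bound_integral_lef_min / 8000 - 3 / 5), 0.02)
})

test_that("engine invariants hold along sampled trajectories", {
  p <- toy_params(n_lef_target = 8, chain_length_kb = 240, sim_time_min = 5,
                  velocity_kb_per_min = 40, unbind_rate_per_min = 0.2)
  g <- build_genome(p, alternating_boundaries(240, c(60, 40)))
  adv <- advance_1d(lef_system(p, g, seed = 9), 300, sample_dt = 0.5,
                    record_samples = TRUE)
  smp <- adv$samples
  expect_gt(nrow(smp), 100)
  expect_true(all(smp$left_leg <= smp$right_leg))
  expect_true(all(smp$left_leg >= 0 & smp$right_leg < g$n_monomers))
  # impenetrable: no monomer hosts two legs at any sample
  per_sample <- split(c(smp$left_leg, smp$right_leg), c(smp$sample, smp$sample))
  expect_true(all(vapply(per_sample, function(v) !anyDuplicated(v), logical(1))))
})

test_that("phantom mode produces crossings where impenetrable mode stalls", {
  run_mode <- function(mode) {
    p <- toy_params(n_lef_target = 10, chain_length_kb = 200,
                    velocity_kb_per_min = 60, unbind_rate_per_min = 0.2,
                    collision_mode = mode, sim_time_min = 5)
    advance_1d(lef_system(p, build_genome(p), seed = 3), 200)$stats$event_counts
  }
  imp <- run_mode("impenetrable")
  pha <- run_mode("phantom")
  expect_gt(imp[["stall_collision"]], 0)
  expect_identical(unname(imp[["cross_phantom"]]), 0)
  expect_gt(pha[["cross_phantom"]], 0)
  expect_identical(unname(pha[["stall_collision"]]), 0)
})

test_that("occupancy accumulates two legs per bound LEF and peaks at boundaries", {
  sys <- single_lef_system(n_sites = 12)
  acc <- numeric(12)
  expect_identical(occupancy_accumulate(sys, acc), acc)  # nothing bound
  sysb <- bind_lef(sys, 1)$system
  expect_equal(sum(occupancy_accumulate(sysb, acc)), 2)
  expect_error(occupancy_accumulate(sysb, numeric(5)), "length",
               class = "polyloopsim_validation_error")

  # a strong impermeable boundary accumulates excess occupancy next to it
  p <- sim_params(chain_length_kb = 200, monomer_size_kb = 2, n_lef_target = 4,
                  velocity_kb_per_min = 50, unbind_rate_per_min = 0.1,
                  sim_time_min = 10)
  g <- build_genome(p, data.frame(position_kb = 100))  # monomer 50
  adv <- advance_1d(lef_system(p, g, seed = 12), 4000, sample_dt = 1)
  occ <- adv$occupancy
  near <- mean(occ[c(50, 52)])   # monomers 49 and 51 flank the boundary
  interior <- mean(occ[c(20:40, 60:80)])
  expect_gt(near, 2 * interior)
})

test_that("single-LEF empirical occupancy matches the exact Markov oracle", {
  b <- data.frame(position_kb = 8, orientation = "blocks_both", permeability = 0.5)
  sys <- single_lef_system(n_sites = 8, boundary = b, seed = 21)
  emp <- empirical_state_frequencies(sys, 8000, n_batches = 20)
  ora <- exact_stationary_oracle(sys)
  m <- dplyr::inner_join(emp$freq, ora, by = "state_id")
  z <- abs(m$freq - m$prob) / pmax(m$se, 1e-4)
  expect_lt(max(z), 3)
  # unreachable states (boundary fully blocks nothing here) have prob mass ~ freq
  expect_equal(sum(m$prob), 1, tolerance = 1e-8)
})

test_that("oracle limits behave: fast unbinding empties the lattice, hard walls are unreachable", {
  sys <- single_lef_system(n_sites = 6, k_unbind = 1e6, k_bind = 1)
  ora <- exact_stationary_oracle(sys)
  expect_gt(ora$prob[ora$state_id == 0], 0.999)

  # loading at the chain start, impermeable boundary at monomer 3: the right
  # leg can never enter site 3, so every state with right_leg >= 3 is
  # unreachable and must carry zero stationary probability
  b <- data.frame(position_kb = 6, orientation = "blocks_both", permeability = 0)
  sysb <- single_lef_system(n_sites = 6, boundary = b, loading_kb = 0)
  orab <- exact_stationary_oracle(sysb)
  blocked <- !is.na(orab$right_leg) & orab$right_leg >= 3
  expect_true(all(orab$prob[blocked] == 0))
  reachable <- !is.na(orab$right_leg) & orab$right_leg < 3
  expect_gt(sum(orab$prob[reachable]), 0)
})
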