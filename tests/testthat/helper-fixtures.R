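# Shared fixture builders: everything is generated in code, no stored data.

toy_params <- function(...) {
  defaults <- list(chain_length_kb = 120, monomer_size_kb = 2, n_lef_target = 3,
                   velocity_kb_per_min = 20, unbind_rate_per_min = 1,
                   sim_time_min = 5, snapshot_interval_min = 1,
                   equilibration_time_min = 0.5, seed = 1)
  do.call(sim_params, utils::modifyList(defaults, list(...)))
}

single_lef_system <- function(n_sites = 8, step_rate_kb = 10, k_unbind = 1,
                              k_bind = 2, extrusion = "symmetric",
                              collision = "impenetrable", boundary = NULL,
                              loading_kb = numeric(0), seed = 11) {
  p <- sim_params(chain_length_kb = n_sites * 2, monomer_size_kb = 2,
                  n_lef_target = 1, velocity_kb_per_min = step_rate_kb,
                  unbind_rate_per_min = k_unbind, extrusion_mode = extrusion,
                  collision_mode = collision, sim_time_min = 10,
                  rebind_mode = if (length(loading_kb)) "loading_sites" else "uniform")
  g <- build_genome(p, boundary, loading_kb)
  lef_system(p, g, seed = seed, pool_size = 1, k_bind_per_min = k_bind)
}

# wrap explicit conformations in the snapshot_stream container
fake_stream <- function(positions_list, legs_list = NULL, params = NULL,
                        n_monomers = if (length(positions_list) > 0)
                          nrow(positions_list[[1]]) else 10) {
  if (is.null(params)) {
    params <- sim_params(chain_length_kb = n_monomers * 2, monomer_size_kb = 2,
                         n_lef_target = 0, sim_time_min = 1)
  }
  g <- build_genome(params)
  if (is.null(legs_list)) {
    legs_list <- replicate(length(positions_list),
                           matrix(integer(0), ncol = 2), simplify = FALSE)
  }
  snaps <- lapply(seq_along(positions_list), function(i) {
    list(time_min = i, positions = positions_list[[i]], legs = legs_list[[i]],
         n_bound = nrow(legs_list[[i]]))
  })
  structure(list(replicates = list(snaps), event_counts = NULL,
                 replicate_ids = 1L, params = params, genome = g,
                 model = energy_model(params), seed = 1L),
            class = "snapshot_stream")
}

# straight chain along x at given spacing (nm)
straight_chain <- function(n, spacing = 50) {
  cbind(x = (seq_len(n) - 1) * spacing, y = 0, z = 0)
}

# independent R-side energy computation, term by term
energy_oracle_r <- function(pos, loops, model) {
  n <- nrow(pos)
  e <- 0
  for (i in seq_len(n - 1)) {
    d <- sqrt(sum((pos[i, ] - pos[i + 1, ])^2))
    e <- e + model$bond_k * (d - model$bond_rest_nm)^2
  }
  if (n >= 3) {
    for (j in 2:(n - 1)) {
      b1 <- pos[j, ] - pos[j - 1, ]
      b2 <- pos[j + 1, ] - pos[j, ]
      ct <- sum(b1 * b2) / sqrt(sum(b1^2) * sum(b2^2))
      e <- e + model$bend_k * (1 - ct)
    }
  }
  if (!is.null(loops) && nrow(loops) > 0) {
    for (k in seq_len(nrow(loops))) {
      d <- sqrt(sum((pos[loops[k, 1] + 1, ] - pos[loops[k, 2] + 1, ])^2))
      e <- e + model$loop_k * (d - model$bond_rest_nm)^2
    }
  }
  e
}
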