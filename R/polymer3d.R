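# 3D dynamics of the coarse-grained chain: bead-spring connectivity, excluded
# volume, bending rigidity, and LEF loops as transient harmonic bonds.
#
# Energies are expressed in units of kT (temperature 1 by default). Chain
# bonds live in a hard window [bond_min, bond_max] around the rest length;
# excluded volume is a hard-core rejection below 0.8 x monomer diameter. Both
# act as infinite-energy terms inside the Metropolis rule, preserving
# detailed balance with respect to the total energy.

#' Energy model of the bead-spring chain
#'
#' @param params A [sim_params()] object (sets the rest length to the monomer
#'   diameter).
#' @param bond_k Harmonic bond stiffness (kT/nm^2).
#' @param bend_k Bending stiffness (kT) of the `bend_k * (1 - cos theta)`
#'   term; the persistence length is roughly `bend_k * bond_rest` nm.
#' @param loop_k Loop-bond stiffness (kT/nm^2); defaults to `bond_k`.
#' @param hardcore_factor Hard-core diameter as a fraction of the monomer
#'   diameter.
#' @param bond_max_factor Upper edge of the allowed bond window as a multiple
#'   of the rest length.
#' @param temperature Temperature in kT units.
#' @param max_disp_nm Maximum single-bead trial displacement per axis.
#' @return An `energy_model` list.
#' @export
energy_model <- function(params, bond_k = 0.1, bend_k = 2, loop_k = bond_k,
                         hardcore_factor = 0.8, bond_max_factor = 1.5,
                         temperature = 1, max_disp_nm = 10) {
  stopifnot(inherits(params, "sim_params"))
  rest <- params$monomer_diameter_nm
  m <- list(bond_k = bond_k, bond_rest_nm = rest, bend_k = bend_k,
            loop_k = loop_k, hardcore_nm = hardcore_factor * rest,
            bond_min_nm = hardcore_factor * rest,
            bond_max_nm = bond_max_factor * rest,
            temperature = temperature, max_disp_nm = max_disp_nm)
  if (any(unlist(m[c("bond_k", "bend_k", "loop_k")]) < 0)) {
    validation_error("stiffness parameters must be non-negative")
  }
  if (m$hardcore_nm > m$bond_rest_nm) {
    validation_error("hard-core diameter must not exceed the bond rest length")
  }
  structure(m, class = "energy_model")
}

.empty_loops <- function() matrix(integer(0), ncol = 2,
                                  dimnames = list(NULL, c("left", "right")))

#' Initial self-avoiding conformation
#'
#' Grows a random walk with fixed bond length and hard-core rejection
#' (backtracking on dead ends), reproducible by seed.
#'
#' @param n_monomers Number of beads (>= 2).
#' @param model An [energy_model()].
#' @param seed Integer seed.
#' @return A `conformation`: `positions` (n x 3 matrix, nm), `loop_bonds`
#'   (0-based index pairs, initially empty), `time_min`.
#' @export
init_conformation <- function(n_monomers, model, seed = 1) {
  stopifnot(n_monomers >= 2, inherits(model, "energy_model"))
  pos <- cpp_grow_chain(as.integer(n_monomers), model$bond_rest_nm,
                        model$hardcore_nm, as.integer(seed),
                        max_backtrack = 50L * n_monomers)
  structure(list(positions = pos, loop_bonds = .empty_loops(), time_min = 0),
            class = "conformation")
}

#' @export
print.conformation <- function(x, ...) {
  cat(sprintf("<conformation> %d beads, %d loop bond(s), t = %.3g min\n",
              nrow(x$positions), nrow(x$loop_bonds), x$time_min))
  invisible(x)
}

#' Total energy of a conformation
#'
#' Sum of harmonic bond terms `bond_k (d - d0)^2`, bending terms
#' `bend_k (1 - cos theta)` over consecutive triplets, harmonic loop-bond
#' terms, and an infinite hard-core / bond-window penalty.
#'
#' @param conformation A `conformation`.
#' @param model An [energy_model()].
#' @return Total energy (kT); `Inf` when a hard constraint is violated. The
#'   `"components"` attribute carries the bond/bend/loop breakdown.
#' @export
total_energy <- function(conformation, model) {
  res <- cpp_polymer_energy(conformation$positions,
                            .loops_matrix(conformation), unclass(model))
  structure(res$total, components = c(bond = res$bond, bend = res$bend,
                                      loop = res$loop))
}

.loops_matrix <- function(conformation) {
  lb <- conformation$loop_bonds
  if (is.null(lb) || nrow(lb) == 0) return(matrix(integer(0), ncol = 2))
  matrix(as.integer(lb), ncol = 2)
}

#' Metropolis Monte-Carlo sweeps
#'
#' Performs `n_sweeps` sweeps of `n_monomers` single-bead trial displacements
#' each, Metropolis-accepted against [total_energy()]; moves that violate the
#' excluded-volume or bond-window constraints are rejected.
#'
#' @param conformation A `conformation`.
#' @param model An [energy_model()].
#' @param n_sweeps Number of sweeps.
#' @param seed Integer seed (used when `rng_state` is `NULL`).
#' @param rng_state Raw RNG state from a previous call, to continue a stream.
#' @param temperature Override of the model temperature.
#' @return List: updated `conformation`, `acceptance` fraction, `rng_state`.
#' @export
mc_sweep <- function(conformation, model, n_sweeps = 1, seed = 1,
                     rng_state = NULL, temperature = model$temperature) {
  stopifnot(inherits(model, "energy_model"))
  if (is.null(rng_state)) rng_state <- cpp_rng_state(as.integer(seed))
  res <- cpp_mc_run(conformation$positions, .loops_matrix(conformation),
                    unclass(model), temperature, model$max_disp_nm,
                    as.integer(n_sweeps), rng_state)
  conformation$positions <- res$positions
  list(conformation = conformation,
       acceptance = res$accepted / max(1, res$attempted),
       rng_state = res$rng_state)
}

#' Impose the current LEF loops on a conformation
#'
#' Replaces `loop_bonds` by the `(left_leg, right_leg)` pairs of currently
#' bound LEFs. A bond whose beads are farther apart than the bond window is
#' added as a stretched harmonic spring that subsequent sweeps contract —
#' beads are never teleported.
#'
#' @param conformation A `conformation`.
#' @param lef_system A [lef_system()].
#' @return The conformation with updated `loop_bonds`.
#' @export
sync_loops <- function(conformation, lef_system) {
  b <- lef_system$bound == 1
  if (!any(b)) {
    conformation$loop_bonds <- .empty_loops()
  } else {
    conformation$loop_bonds <- cbind(left = lef_system$left[b],
                                     right = lef_system$right[b])
  }
  conformation$time_min <- lef_system$time_min
  conformation
}

#' Check conformation invariants
#'
#' @param conformation A `conformation`.
#' @param model An [energy_model()].
#' @param strict_loops Also require loop bonds inside the bond window
#'   (freshly advanced legs may transiently exceed it).
#' @return Logical scalar; details in the `"checks"` attribute.
#' @export
check_conformation <- function(conformation, model, strict_loops = FALSE) {
  res <- cpp_check_conformation(conformation$positions,
                                .loops_matrix(conformation),
                                model$bond_min_nm, model$bond_max_nm,
                                model$hardcore_nm)
  ok <- res$bond_ok && res$excluded_volume_ok && (!strict_loops || res$loop_ok)
  structure(ok, checks = res)
}

#' Run the coupled 1D/3D simulation
#'
#' Alternates the continuous-time extrusion kinetics over a coupling interval
#' with a proportional number of Metropolis sweeps (`sweeps_per_min` sweeps
#' per simulated minute). The chain is first relaxed without extrusion for
#' `equilibration_time_min`; snapshots of the conformation and the bound LEF
#' legs are then emitted every `snapshot_interval_min` over `sim_time_min`,
#' independently for each replicate (decorrelated derived seeds).
#'
#' @param params A [sim_params()] object.
#' @param genome A [build_genome()] annotation.
#' @param seed Master seed (defaults to `params$seed`).
#' @param model An [energy_model()]; defaults to `energy_model(params)`.
#' @param n_replicates Override of `params$n_replicates`.
#' @param replicate_ids Which replicate indices to run (for distributed
#'   execution); defaults to `1:n_replicates`.
#' @return A `snapshot_stream`: per replicate a list of snapshots
#'   (`time_min`, `positions`, `legs` 0-based k x 2 matrix, `n_bound`), plus
#'   the parameters, genome, model, and aggregate 1D event counts.
#' @export
run_coupled <- function(params, genome, seed = params$seed,
                        model = energy_model(params),
                        n_replicates = params$n_replicates,
                        replicate_ids = seq_len(n_replicates)) {
  stopifnot(inherits(params, "sim_params"), inherits(genome, "genome_annotation"))
  reps <- lapply(replicate_ids, function(r) {
    .run_one_replicate(params, genome, model,
                       seed_1d = derive_seed(seed, r, 1L),
                       seed_3d = derive_seed(seed, r, 2L))
  })
  structure(list(
    replicates = lapply(reps, `[[`, "snapshots"),
    event_counts = Reduce(`+`, lapply(reps, `[[`, "event_counts")),
    replicate_ids = replicate_ids,
    params = params, genome = genome, model = model, seed = seed
  ), class = "snapshot_stream")
}

.run_one_replicate <- function(params, genome, model, seed_1d, seed_3d) {
  n <- genome$n_monomers
  sys <- lef_system(params, genome, seed = seed_1d)
  conf <- init_conformation(n, model, seed = seed_3d)
  rng3d <- cpp_rng_state(as.integer(derive_seed(seed_3d, 3L, 0L)))

  # pre-extrusion burn-in: relax the bare homopolymer
  burn_sweeps <- as.integer(round(params$equilibration_time_min * params$sweeps_per_min))
  if (burn_sweeps > 0) {
    r <- mc_sweep(conf, model, n_sweeps = burn_sweeps, rng_state = rng3d)
    conf <- r$conformation
    rng3d <- r$rng_state
  }

  dt <- params$coupling_interval_min
  t_total <- params$sim_time_min
  snap_int <- params$snapshot_interval_min
  snapshots <- list()
  counts <- setNames(numeric(length(.lef_event_levels)), .lef_event_levels)

  t <- 0
  next_snap <- snap_int
  sweep_carry <- 0
  eps <- 1e-9
  while (t < t_total - eps) {
    step <- min(dt, t_total - t, next_snap - t)
    adv <- advance_1d(sys, step)
    sys <- adv$system
    counts <- counts + adv$stats$event_counts
    conf <- sync_loops(conf, sys)
    sweep_carry <- sweep_carry + step * params$sweeps_per_min
    n_sw <- floor(sweep_carry)
    if (n_sw >= 1) {
      r <- mc_sweep(conf, model, n_sweeps = n_sw, rng_state = rng3d)
      conf <- r$conformation
      rng3d <- r$rng_state
      sweep_carry <- sweep_carry - n_sw
    }
    t <- t + step
    if (t >= next_snap - eps) {
      snapshots[[length(snapshots) + 1]] <- list(
        time_min = t,
        positions = conf$positions,
        legs = .loops_matrix(conf),
        n_bound = sum(sys$bound))
      next_snap <- next_snap + snap_int
    }
  }
  list(snapshots = snapshots, event_counts = counts)
}

#' @export
print.snapshot_stream <- function(x, ...) {
  cat(sprintf("<snapshot_stream> %d replicate(s) x %d snapshot(s), %d beads\n",
              length(x$replicates),
              if (length(x$replicates) > 0) length(x$replicates[[1]]) else 0,
              x$genome$n_monomers))
  invisible(x)
}

#' Flatten a snapshot stream into position matrices
#' @param stream A `snapshot_stream`.
#' @return List of n x 3 position matrices over all replicates and times.
#' @export
snapshot_positions <- function(stream) {
  unlist(lapply(stream$replicates,
                function(rep) lapply(rep, `[[`, "positions")),
         recursive = FALSE)
}

#' @rdname snapshot_positions
#' @return For `snapshot_legs()`: list of 0-based k x 2 leg-index matrices.
#' @export
snapshot_legs <- function(stream) {
  unlist(lapply(stream$replicates, function(rep) lapply(rep, `[[`, "legs")),
         recursive = FALSE)
}
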