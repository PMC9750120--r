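# Stochastic 1D dynamics of loop-extruding factors on the monomer lattice.
#
# Kinetics are realized as exact continuous-time (Gillespie) sampling over the
# current event set {bind, unbind, leg step}: waiting times are exponential in
# the total rate and one event is executed per draw. Boundary permeability is
# applied per arrival attempt: a stalled leg retries at its stepping rate, so
# a permeability p boundary passes legs at an effective rate p * step_rate.

.lef_event_levels <- c("bind", "unbind", "step", "stall_boundary",
                       "stall_collision", "pass_boundary", "cross_phantom",
                       "bind_reject")

#' Initialize a loop-extruder population
#'
#' Creates the 1D engine state: a pool of `2 * n_lef_target` LEFs, all
#' initially unbound, on the annotated lattice. The per-LEF binding rate is
#' set to `k_unbind * n_lef_target / (pool - n_lef_target)` so the stationary
#' mean bound count equals `n_lef_target` (two-state occupancy balance).
#' Extrusion steps occur per translocating leg at
#' `velocity_kb_per_min / monomer_size_kb` steps/min. Chain ends act as
#' permanent impermeable boundaries.
#'
#' @param params A [sim_params()] object.
#' @param genome A [build_genome()] annotation (must match `params`).
#' @param seed Integer seed for the engine's own reproducible RNG stream.
#' @param pool_size,k_bind_per_min Optional low-level overrides of the pool
#'   size and per-LEF binding rate (used e.g. for single-LEF studies).
#' @return A `lef_system` object.
#' @examples
#' p <- sim_params(chain_length_kb = 600, monomer_size_kb = 2)
#' g <- build_genome(p)
#' sys <- lef_system(p, g, seed = 1)
#' @export
lef_system <- function(params, genome, seed = params$seed,
                       pool_size = NULL, k_bind_per_min = NULL) {
  stopifnot(inherits(params, "sim_params"), inherits(genome, "genome_annotation"))
  n <- genome$n_monomers
  n_target <- params$n_lef_target
  if (is.null(pool_size)) pool_size <- 2L * n_target
  pool_size <- as.integer(pool_size)
  if (n_target > n %/% 2) {
    validation_error(sprintf(
      "n_lef_target (%d) exceeds n_monomers/2 (%d): cannot place that many leg pairs",
      n_target, n %/% 2))
  }
  if (is.null(k_bind_per_min)) {
    k_bind_per_min <- if (pool_size > n_target && n_target > 0) {
      params$unbind_rate_per_min * n_target / (pool_size - n_target)
    } else if (n_target == 0) 0 else params$unbind_rate_per_min
  }

  pass_left <- rep(1, n); pass_right <- rep(1, n)
  block_left <- integer(n); block_right <- integer(n)
  if (nrow(genome$boundaries) > 0) {
    for (i in seq_len(nrow(genome$boundaries))) {
      m <- genome$boundaries$monomer_index[i] + 1L
      ori <- genome$boundaries$orientation[i]
      perm <- genome$boundaries$permeability[i]
      if (ori %in% c("blocks_rightward", "blocks_both")) {
        block_right[m] <- 1L; pass_right[m] <- perm
      }
      if (ori %in% c("blocks_leftward", "blocks_both")) {
        block_left[m] <- 1L; pass_left[m] <- perm
      }
    }
  }

  structure(list(
    n_monomers = n,
    pass_left = pass_left, pass_right = pass_right,
    block_left = block_left, block_right = block_right,
    loading_sites = as.integer(genome$loading_sites),
    symmetric = params$extrusion_mode == "symmetric",
    phantom = params$collision_mode == "phantom",
    k_bind = k_bind_per_min,
    k_unbind = params$unbind_rate_per_min,
    step_rate = params$velocity_kb_per_min / params$monomer_size_kb,
    left = integer(pool_size), right = integer(pool_size),
    bound = integer(pool_size),
    left_mobile = integer(pool_size), right_mobile = integer(pool_size),
    time_min = 0,
    rng_state = cpp_rng_state(as.integer(seed)),
    n_lef_target = n_target,
    genome = genome
  ), class = "lef_system")
}

#' @export
print.lef_system <- function(x, ...) {
  cat(sprintf("<lef_system> %d monomers, pool %d LEFs (%d bound), t = %.3g min\n",
              x$n_monomers, length(x$bound), sum(x$bound), x$time_min))
  cat(sprintf("  k_bind %.4g, k_off %.4g /min, %.4g steps/min/leg, %s, %s\n",
              x$k_bind, x$k_unbind, x$step_rate,
              if (x$symmetric) "symmetric" else "asymmetric",
              if (x$phantom) "phantom" else "impenetrable"))
  invisible(x)
}

#' Current per-LEF state as a tibble
#' @param system A `lef_system`.
#' @return Tibble with one row per pool slot: `lef` (1-based id), `bound`,
#'   `left_leg`, `right_leg` (0-based monomer indices), mobility flags.
#' @export
lef_state <- function(system) {
  tibble(lef = seq_along(system$bound),
         bound = system$bound == 1,
         left_leg = ifelse(system$bound == 1, system$left, NA_integer_),
         right_leg = ifelse(system$bound == 1, system$right, NA_integer_),
         left_mobile = system$left_mobile == 1,
         right_mobile = system$right_mobile == 1)
}

.events_tibble <- function(ev) {
  leg <- c("left", "right")[pmax(ev$leg, 0) + 1L]
  leg[ev$leg < 0] <- NA_character_
  tibble(time_min = ev$time_min,
         event = factor(.lef_event_levels[ev$kind + 1L], levels = .lef_event_levels),
         lef = ev$lef + 1L,
         leg = leg,
         monomer = ifelse(ev$pos < 0, NA_integer_, ev$pos))
}

#' Advance the 1D loop-extrusion kinetics
#'
#' Propagates the continuous-time dynamics for `duration_min` simulated
#' minutes: LEFs bind (uniformly or at loading sites), unbind (dissolving
#' their loop instantly), and translocate their mobile legs outward, stalling
#' at directional boundary elements (passing with the element's permeability
#' per attempt) and, in impenetrable mode, at other legs.
#'
#' @param system A [lef_system()] state.
#' @param duration_min Positive duration to simulate.
#' @param record_events Record the full event log (tibble) — off by default.
#' @param sample_dt If positive, occupancy and (optionally) bound-leg
#'   positions are sampled every `sample_dt` minutes.
#' @param record_samples Keep per-sample bound-leg tables.
#' @param track_batches Internal: single-LEF state-occupancy tracking split
#'   into this many batches (for comparisons against the exact oracle).
#' @return List with `system` (advanced state), `events` (tibble, empty
#'   unless recorded), `occupancy` (per-monomer leg counts summed over
#'   samples), `samples`, `stats` (time-integrals and event counts), and
#'   `state_time` when tracking is on.
#' @export
advance_1d <- function(system, duration_min, record_events = FALSE,
                       sample_dt = 0, record_samples = FALSE,
                       track_batches = 0) {
  stopifnot(inherits(system, "lef_system"), duration_min > 0)
  res <- cpp_lef_advance(unclass(system), duration_min, record_events,
                         sample_dt, record_samples, as.integer(track_batches))
  out_state <- res$state
  class(out_state) <- "lef_system"
  samples <- tibble(sample = res$samples$sample,
                    time_min = res$samples$time_min,
                    lef = res$samples$lef + 1L,
                    left_leg = res$samples$left,
                    right_leg = res$samples$right)
  stats <- res$stats
  stats$event_counts <- setNames(stats$event_counts, .lef_event_levels)
  out <- list(system = out_state,
              events = .events_tibble(res$events),
              occupancy = res$occupancy,
              n_samples = res$samples$n_samples,
              samples = samples,
              stats = stats)
  if (track_batches > 0) out$state_time <- res$state_time
  out
}

#' Bind one LEF
#'
#' Executes a single binding attempt for an unbound LEF: in uniform mode a
#' monomer pair `(i, i+1)` is drawn uniformly among pairs admissible under the
#' collision mode; in loading-site mode the pair is anchored at a uniformly
#' drawn loading site. An inadmissible draw rejects the attempt and leaves the
#' system unchanged.
#'
#' @param system A `lef_system`.
#' @param lef_id 1-based LEF id (must be unbound).
#' @return List with the updated `system` and the `outcome`
#'   (`"bind"` or `"bind_reject"`).
#' @export
bind_lef <- function(system, lef_id) {
  stopifnot(inherits(system, "lef_system"))
  res <- cpp_lef_bind(unclass(system), as.integer(lef_id) - 1L)
  st <- res$state
  class(st) <- "lef_system"
  list(system = st, outcome = .lef_event_levels[res$code + 1L])
}

#' Attempt one outward leg step
#'
#' Moves the given leg of a bound LEF one monomer outward (left leg toward
#' smaller indices, right leg toward larger). The move stalls at the chain
#' end, stalls or passes a direction-blocking boundary element according to
#' its permeability, and stalls at (impenetrable) or crosses (phantom)
#' another LEF's leg.
#'
#' @param system A `lef_system`.
#' @param lef_id 1-based id of a bound LEF.
#' @param leg `"left"` or `"right"` (must be a mobile leg).
#' @return List with the updated `system` and the `outcome`, one of
#'   `"step"`, `"stall_boundary"`, `"stall_collision"`, `"pass_boundary"`,
#'   `"cross_phantom"`.
#' @export
attempt_leg_step <- function(system, lef_id, leg = c("left", "right")) {
  stopifnot(inherits(system, "lef_system"))
  leg <- match.arg(leg)
  res <- cpp_lef_step(unclass(system), as.integer(lef_id) - 1L,
                      if (leg == "left") 0L else 1L)
  st <- res$state
  class(st) <- "lef_system"
  list(system = st, outcome = .lef_event_levels[res$code + 1L])
}

#' Accumulate instantaneous LEF-leg occupancy
#'
#' Increments the accumulator at every monomer currently occupied by a bound
#' LEF leg (a sampling estimator of the virtual ChIP-seq signal, not
#' event-weighted).
#'
#' @param system A `lef_system`.
#' @param accumulator Numeric vector of length `n_monomers`.
#' @return The updated accumulator.
#' @export
occupancy_accumulate <- function(system, accumulator) {
  stopifnot(inherits(system, "lef_system"))
  if (length(accumulator) != system$n_monomers) {
    validation_error(sprintf("accumulator length %d != n_monomers %d",
                             length(accumulator), system$n_monomers))
  }
  idx <- c(system$left[system$bound == 1], system$right[system$bound == 1]) + 1L
  if (length(idx) > 0) {
    tab <- tabulate(idx, nbins = system$n_monomers)
    accumulator <- accumulator + tab
  }
  accumulator
}
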