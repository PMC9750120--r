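# Exact stationary distribution of the single-LEF kinetics on a small lattice.
#
# Independent of the event engine: enumerates every state (unbound plus all
# bound leg pairs, with the anchored-leg identity in asymmetric mode), builds
# the continuous-time Markov generator of the same kinetics, and solves
# pi Q = 0. A permeability-p boundary contributes a thinned transition rate
# p * step_rate, exactly equivalent to per-attempt Bernoulli passage.

#' Exact single-LEF stationary distribution
#'
#' @param system A [lef_system()] with pool size 1 and `n_monomers <= 12`
#'   (enumeration-sized lattice).
#' @return Tibble with one row per state: `state_id` (aligned with the
#'   engine's state-tracking index: `0` unbound, `1 + 2*(l*n + r) + bit` with
#'   bit 1 when only the right leg is mobile), `left_leg`, `right_leg`,
#'   `mobility`, and the stationary probability `prob`. Unreachable states
#'   carry probability 0.
#' @export
exact_stationary_oracle <- function(system) {
  stopifnot(inherits(system, "lef_system"))
  n <- system$n_monomers
  if (length(system$bound) != 1) {
    abort("exact_stationary_oracle supports exactly one LEF",
          class = "polyloopsim_error")
  }
  if (n > 12) {
    abort("exact_stationary_oracle supports n_monomers <= 12",
          class = "polyloopsim_error")
  }

  sym <- system$symmetric
  # state table: id 0 = unbound; bound states (l < r, mobility bit)
  bits <- if (sym) 0L else c(0L, 1L)
  states <- list(list(id = 0L, l = NA_integer_, r = NA_integer_, bit = NA_integer_))
  for (l in 0:(n - 2)) {
    for (r in (l + 1):(n - 1)) {
      for (b in bits) {
        states[[length(states) + 1]] <-
          list(id = 1L + 2L * (l * n + r) + b, l = l, r = r, bit = b)
      }
    }
  }
  ns <- length(states)
  id_of <- function(l, r, b) 1L + 2L * (l * n + r) + b
  row_of <- setNames(seq_len(ns), vapply(states, function(s) s$id, integer(1)))

  Q <- matrix(0, ns, ns)
  add <- function(from_id, to_id, rate) {
    i <- row_of[[as.character(from_id)]]
    j <- row_of[[as.character(to_id)]]
    Q[i, j] <<- Q[i, j] + rate
  }

  # binding out of the unbound state
  if (length(system$loading_sites) == 0) {
    pairs <- 0:(n - 2)
    per_pair <- system$k_bind / length(pairs)
    for (i in pairs) {
      for (b in bits) add(0L, id_of(i, i + 1L, b), per_pair / length(bits))
    }
  } else {
    sites <- system$loading_sites
    per_site <- system$k_bind / length(sites)
    for (s in sites) {
      if (s + 1 >= n) next  # rejected attempt: no transition
      for (b in bits) add(0L, id_of(s, s + 1L, b), per_site / length(bits))
    }
  }

  for (st in states[-1]) {
    from <- st$id
    add(from, 0L, system$k_unbind)
    left_mobile <- sym || st$bit == 0L
    right_mobile <- sym || st$bit == 1L
    if (left_mobile && st$l - 1 >= 0) {
      tgt <- st$l - 1L
      p <- system$pass_left[tgt + 1L]
      if (p > 0) add(from, id_of(tgt, st$r, st$bit), system$step_rate * p)
    }
    if (right_mobile && st$r + 1 <= n - 1) {
      tgt <- st$r + 1L
      p <- system$pass_right[tgt + 1L]
      if (p > 0) add(from, id_of(st$l, tgt, st$bit), system$step_rate * p)
    }
  }

  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)

  # stationary distribution: pi Q = 0, sum(pi) = 1
  A <- t(Q)
  A[ns, ] <- 1
  b <- c(rep(0, ns - 1), 1)
  prob <- solve(A, b)
  prob[abs(prob) < 1e-14] <- 0

  tibble(
    state_id = vapply(states, function(s) s$id, integer(1)),
    left_leg = vapply(states, function(s) s$l, integer(1)),
    right_leg = vapply(states, function(s) s$r, integer(1)),
    mobility = vapply(states, function(s) {
      if (is.na(s$bit)) NA_character_
      else if (sym) "both" else if (s$bit == 0) "left" else "right"
    }, character(1)),
    prob = as.numeric(prob)
  )
}

#' Empirical single-LEF state frequencies from the event engine
#'
#' Runs [advance_1d()] with state tracking and returns time-averaged state
#' frequencies with batch-means standard errors, aligned to the oracle's
#' `state_id` index.
#'
#' @param system Single-LEF [lef_system()] on a small lattice.
#' @param duration_min Total simulated time.
#' @param n_batches Number of batches for the standard-error estimate.
#' @return List with the advanced `system` and a tibble `freq`
#'   (`state_id`, `freq`, `se`).
#' @export
empirical_state_frequencies <- function(system, duration_min, n_batches = 20) {
  adv <- advance_1d(system, duration_min, track_batches = n_batches)
  st <- adv$state_time
  batch_len <- duration_min / n_batches
  frac <- st / batch_len                 # per-batch time fractions
  freq <- rowMeans(frac)
  se <- apply(frac, 1, stats::sd) / sqrt(n_batches)
  list(system = adv$system,
       freq = tibble(state_id = seq_len(nrow(st)) - 1L, freq = freq, se = se))
}
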