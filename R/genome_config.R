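# Configuration, parameter validation, and the annotated 1D lattice.

.param_defaults <- function() {
  list(
    chain_length_kb = 6000,
    monomer_size_kb = 2,
    monomer_diameter_nm = 50,
    n_lef_target = NULL,          # resolved from lef_density_kb when absent
    lef_density_kb = 60,          # genomic content per bound LEF (kb)
    velocity_kb_per_min = 100,
    unbind_rate_per_min = 1 / 20, # 20 min mean residence time
    rebind_mode = "uniform",
    extrusion_mode = "symmetric",
    collision_mode = "impenetrable",
    sim_time_min = 120,
    snapshot_interval_min = 1,
    n_replicates = 1,
    equilibration_time_min = 10,
    contact_cutoff_nm = NULL,     # resolved to 2 * monomer_diameter_nm
    hic_bin_kb = NULL,            # resolved to monomer_size_kb
    sweeps_per_min = 100,         # MC sweeps per simulated minute (time mapping)
    coupling_interval_min = NULL, # resolved to min(0.1, snapshot_interval/10)
    seed = 1
  )
}

.orientation_levels <- c("blocks_rightward", "blocks_leftward", "blocks_both")
.enum_values <- list(
  rebind_mode = c("uniform", "loading_sites"),
  extrusion_mode = c("symmetric", "asymmetric"),
  collision_mode = c("impenetrable", "phantom")
)

schema_error <- function(msg) {
  abort(msg, class = c("polyloopsim_schema_error", "polyloopsim_error"))
}

validation_error <- function(msg) {
  abort(msg, class = c("polyloopsim_validation_error", "polyloopsim_error"))
}

#' Simulation parameters
#'
#' Builds and validates the full parameter set of one coupled loop-extrusion /
#' polymer run. The chain is a string of monomers each holding
#' `monomer_size_kb` kb of chromatin in a bead of `monomer_diameter_nm` nm.
#' Loop extruder (LEF) kinetics are given as an extrusion velocity per
#' translocating leg, a detachment rate, and a target mean number of
#' simultaneously bound LEFs — supplied directly as `n_lef_target` or as a
#' density (`lef_density_kb`, kb of chain per bound LEF), mirroring how LEF
#' abundance is usually reported.
#'
#' @param ... Named parameter overrides; see Details for the schema.
#'
#' @details Recognized keys and defaults:
#' `chain_length_kb` (6000), `monomer_size_kb` (2), `monomer_diameter_nm` (50),
#' `n_lef_target` (derived), `lef_density_kb` (60), `velocity_kb_per_min`
#' (100), `unbind_rate_per_min` (0.05), `rebind_mode`
#' ("uniform"/"loading_sites"), `extrusion_mode` ("symmetric"/"asymmetric"),
#' `collision_mode` ("impenetrable"/"phantom"), `sim_time_min` (120),
#' `snapshot_interval_min` (1), `n_replicates` (1), `equilibration_time_min`
#' (10), `contact_cutoff_nm` (2 x monomer diameter), `hic_bin_kb`
#' (monomer size), `sweeps_per_min` (100), `coupling_interval_min`
#' (min(0.1, snapshot_interval/10)), `seed` (1).
#'
#' @return An object of class `sim_params` (a validated named list).
#' @examples
#' p <- sim_params(chain_length_kb = 6000, monomer_size_kb = 2)
#' n_monomers(p)
#' @export
sim_params <- function(...) {
  user <- list(...)
  if (length(user) == 1 && is.null(names(user)) && is.list(user[[1]])) {
    user <- user[[1]]
  }
  defaults <- .param_defaults()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    schema_error(sprintf("unknown configuration key(s): %s",
                         paste(unknown, collapse = ", ")))
  }
  p <- utils::modifyList(defaults, user, keep.null = TRUE)

  # resolve derived defaults
  if (is.null(p$contact_cutoff_nm)) p$contact_cutoff_nm <- 2 * p$monomer_diameter_nm
  if (is.null(p$hic_bin_kb)) p$hic_bin_kb <- p$monomer_size_kb
  if (is.null(p$coupling_interval_min)) {
    p$coupling_interval_min <- min(0.1, p$snapshot_interval_min / 10)
  }
  if (is.null(p$n_lef_target)) {
    p$n_lef_target <- round(p$chain_length_kb / p$lef_density_kb)
  }

  validate_sim_params(p)
}

validate_sim_params <- function(p) {
  pos_fields <- c("chain_length_kb", "monomer_size_kb", "monomer_diameter_nm",
                  "velocity_kb_per_min", "unbind_rate_per_min", "sim_time_min",
                  "snapshot_interval_min", "n_replicates", "contact_cutoff_nm",
                  "hic_bin_kb", "sweeps_per_min", "coupling_interval_min",
                  "lef_density_kb")
  for (f in pos_fields) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      validation_error(sprintf("field '%s' must be a single strictly positive number", f))
    }
  }
  for (f in c("n_lef_target", "equilibration_time_min")) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0) {
      validation_error(sprintf("field '%s' must be a single non-negative number", f))
    }
  }
  for (f in names(.enum_values)) {
    if (!is.character(p[[f]]) || length(p[[f]]) != 1 ||
        !(p[[f]] %in% .enum_values[[f]])) {
      validation_error(sprintf("field '%s' must be one of: %s", f,
                               paste(.enum_values[[f]], collapse = ", ")))
    }
  }
  if (p$chain_length_kb %% p$monomer_size_kb != 0) {
    validation_error(sprintf(
      "field 'chain_length_kb' (%s) must be divisible by monomer_size_kb (%s)",
      p$chain_length_kb, p$monomer_size_kb))
  }
  if (p$hic_bin_kb %% p$monomer_size_kb != 0) {
    validation_error(sprintf(
      "field 'hic_bin_kb' (%s) must be an integer multiple of monomer_size_kb (%s)",
      p$hic_bin_kb, p$monomer_size_kb))
  }
  if (p$snapshot_interval_min > p$sim_time_min) {
    validation_error("field 'snapshot_interval_min' must not exceed sim_time_min")
  }
  if (!is.numeric(p$seed) || length(p$seed) != 1 || p$seed != round(p$seed)) {
    validation_error("field 'seed' must be a single integer")
  }
  p$n_lef_target <- as.integer(round(p$n_lef_target))
  p$seed <- as.integer(p$seed)
  p$n_replicates <- as.integer(round(p$n_replicates))
  structure(p, class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>\n")
  cat(sprintf("  chain: %g kb, %g kb/monomer (%d monomers), %g nm beads\n",
              x$chain_length_kb, x$monomer_size_kb, n_monomers(x),
              x$monomer_diameter_nm))
  cat(sprintf("  LEFs: target %d bound, v = %g kb/min, k_off = %g /min, %s/%s/%s\n",
              x$n_lef_target, x$velocity_kb_per_min, x$unbind_rate_per_min,
              x$extrusion_mode, x$collision_mode, x$rebind_mode))
  cat(sprintf("  schedule: %g min (+%g burn-in), snapshots every %g min, %d replicate(s), seed %d\n",
              x$sim_time_min, x$equilibration_time_min, x$snapshot_interval_min,
              x$n_replicates, x$seed))
  invisible(x)
}

#' Number of monomers of the simulated chain
#' @param params A `sim_params` object.
#' @return Integer monomer count (`chain_length_kb / monomer_size_kb`).
#' @export
n_monomers <- function(params) {
  as.integer(params$chain_length_kb / params$monomer_size_kb)
}

.genome_keys <- c("boundaries", "boundaries_file", "loading_sites_kb",
                  "alternating_gaps_kb", "reference_map", "grid", "grid_mask")

#' Load a simulation configuration
#'
#' Parses the YAML key-value configuration describing one run (or a grid of
#' runs). Top-level keys are either simulation parameters (see [sim_params()])
#' or genome/pipeline sections: `boundaries` (inline list of
#' `{position_kb, orientation, permeability}` maps), `boundaries_file`
#' (3-column BED-like text: start_kb, orientation, permeability),
#' `alternating_gaps_kb` (cyclic gap list for [alternating_boundaries()]),
#' `loading_sites_kb`, `reference_map` (path to a cooler or dense-text map),
#' `grid` (per-parameter value arrays) and `grid_mask`.
#'
#' @param config Path to a YAML file, or YAML text.
#' @return A `sim_config` list with elements `params` (a `sim_params`),
#'   `boundary_spec` (tibble), `loading_sites_kb`, `grid`, `grid_mask`,
#'   `reference_map`.
#' @export
load_config <- function(config) {
  dir <- "."
  if (length(config) == 1 && !grepl("\n", config) && file.exists(config)) {
    dir <- dirname(config)
    raw <- yaml::read_yaml(config)
  } else {
    raw <- yaml::yaml.load(paste(config, collapse = "\n"))
  }
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) schema_error("configuration must be a YAML mapping")

  known <- c(names(.param_defaults()), .genome_keys)
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    schema_error(sprintf("unknown configuration key(s): %s",
                         paste(unknown, collapse = ", ")))
  }

  params <- sim_params(raw[intersect(names(raw), names(.param_defaults()))])

  boundary_spec <- NULL
  if (!is.null(raw$boundaries_file)) {
    path <- raw$boundaries_file
    if (!file.exists(path)) path <- file.path(dir, raw$boundaries_file)
    boundary_spec <- read_boundary_file(path)
  } else if (!is.null(raw$boundaries)) {
    boundary_spec <- dplyr::bind_rows(lapply(raw$boundaries, function(b) {
      tibble(position_kb = as.numeric(b$position_kb),
             orientation = b$orientation %||% "blocks_both",
             permeability = as.numeric(b$permeability %||% 0))
    }))
  } else if (!is.null(raw$alternating_gaps_kb)) {
    boundary_spec <- alternating_boundaries(params$chain_length_kb,
                                            as.numeric(raw$alternating_gaps_kb))
  }

  structure(list(
    params = params,
    boundary_spec = boundary_spec,
    loading_sites_kb = if (is.null(raw$loading_sites_kb)) numeric(0)
                       else as.numeric(raw$loading_sites_kb),
    grid = raw$grid,
    grid_mask = raw$grid_mask,
    reference_map = raw$reference_map
  ), class = "sim_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a BED-like boundary-element file
#'
#' Three whitespace-separated columns: start position (kb), orientation
#' (`blocks_rightward`/`blocks_leftward`/`blocks_both`), permeability in
#' `[0, 1]`. Lines starting with `#` are skipped.
#'
#' @param path File path.
#' @return Tibble with `position_kb`, `orientation`, `permeability`.
#' @export
read_boundary_file <- function(path) {
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          col.names = c("position_kb", "orientation", "permeability"),
                          stringsAsFactors = FALSE)
  as_tibble(df)
}

#' Serialize simulation parameters to configuration text
#'
#' @param params A `sim_params` object.
#' @param path Optional file to write; when `NULL` the YAML text is returned.
#' @return The YAML text, invisibly when written to a file.
#' @export
write_config <- function(params, path = NULL) {
  stopifnot(inherits(params, "sim_params"))
  txt <- yaml::as.yaml(unclass(params))
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Boundary positions with alternating spacing
#'
#' Places boundary elements at the cumulative sums of a cyclic gap sequence,
#' strictly inside the chain — e.g. gaps of 300 and 600 kb produce TADs
#' alternating between those two sizes. Defaults produce impermeable,
#' bidirectional boundaries.
#'
#' @param chain_length_kb Chain length in kb.
#' @param gaps_kb Positive gap lengths in kb, recycled cyclically.
#' @param orientation Orientation given to every element.
#' @param permeability Pass probability given to every element.
#' @return A boundary-spec tibble (`position_kb`, `orientation`, `permeability`).
#' @examples
#' alternating_boundaries(1800, c(300, 600))
#' @export
alternating_boundaries <- function(chain_length_kb, gaps_kb,
                                   orientation = "blocks_both",
                                   permeability = 0) {
  if (any(gaps_kb <= 0)) validation_error("gaps_kb must be strictly positive")
  pos <- numeric(0)
  cur <- 0
  i <- 0
  repeat {
    cur <- cur + gaps_kb[(i %% length(gaps_kb)) + 1]
    if (cur >= chain_length_kb) break
    pos <- c(pos, cur)
    i <- i + 1
  }
  tibble(position_kb = pos, orientation = orientation, permeability = permeability)
}

#' Build the annotated 1D lattice
#'
#' Converts boundary-element and loading-site positions (kb, 0-based
#' half-open in `[0, chain_length_kb)`) into monomer indices by integer
#' division by the monomer size: a position anywhere inside a monomer
#' assigns that whole monomer as the element's site.
#'
#' @param params A `sim_params` object.
#' @param boundary_spec `NULL`, or a data frame with columns `position_kb`,
#'   and optionally `orientation` (default `blocks_both`) and `permeability`
#'   (default 0, i.e. impermeable).
#' @param loading_spec Numeric vector of loading-site positions in kb; empty
#'   means uniform (non-specific) loading.
#' @return A `genome_annotation` object: `n_monomers`, `boundaries` (tibble
#'   sorted by monomer index), `loading_sites` (0-based monomer indices),
#'   plus the chain geometry.
#' @examples
#' p <- sim_params(chain_length_kb = 6000, monomer_size_kb = 2)
#' g <- build_genome(p, alternating_boundaries(6000, c(300, 600)))
#' g$n_monomers
#' @export
build_genome <- function(params, boundary_spec = NULL, loading_spec = numeric(0)) {
  stopifnot(inherits(params, "sim_params"))
  n <- n_monomers(params)

  if (is.null(boundary_spec) || nrow(as.data.frame(boundary_spec)) == 0) {
    boundaries <- tibble(monomer_index = integer(0), orientation = character(0),
                         permeability = numeric(0), position_kb = numeric(0))
  } else {
    b <- as_tibble(as.data.frame(boundary_spec))
    if (!"position_kb" %in% names(b)) {
      schema_error("boundary_spec must contain a 'position_kb' column")
    }
    if (!"orientation" %in% names(b)) b$orientation <- "blocks_both"
    if (!"permeability" %in% names(b)) b$permeability <- 0
    bad <- which(b$position_kb < 0 | b$position_kb >= params$chain_length_kb)
    if (length(bad) > 0) {
      validation_error(sprintf("boundary position out of range [0, %g): %g",
                               params$chain_length_kb, b$position_kb[bad[1]]))
    }
    if (!all(b$orientation %in% .orientation_levels)) {
      validation_error(sprintf("orientation must be one of: %s",
                               paste(.orientation_levels, collapse = ", ")))
    }
    if (any(b$permeability < 0 | b$permeability > 1)) {
      validation_error("permeability must lie in [0, 1]")
    }
    b$monomer_index <- as.integer(b$position_kb %/% params$monomer_size_kb)
    if (anyDuplicated(b$monomer_index)) {
      d <- b$monomer_index[duplicated(b$monomer_index)][1]
      validation_error(sprintf(
        "duplicate boundary elements map to monomer %d (one element per monomer)", d))
    }
    boundaries <- b[order(b$monomer_index),
                    c("monomer_index", "orientation", "permeability", "position_kb")]
  }

  loading_spec <- as.numeric(loading_spec)
  if (length(loading_spec) > 0) {
    bad <- which(loading_spec < 0 | loading_spec >= params$chain_length_kb)
    if (length(bad) > 0) {
      validation_error(sprintf("loading site out of range [0, %g): %g",
                               params$chain_length_kb, loading_spec[bad[1]]))
    }
  }
  loading <- sort(unique(as.integer(loading_spec %/% params$monomer_size_kb)))

  structure(list(
    n_monomers = n,
    boundaries = boundaries,
    loading_sites = loading,
    monomer_size_kb = params$monomer_size_kb,
    chain_length_kb = params$chain_length_kb,
    chrom_label = "chrSim"
  ), class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %d monomers (%g kb), %d boundary element(s), %s loading\n",
              x$n_monomers, x$chain_length_kb, nrow(x$boundaries),
              if (length(x$loading_sites) == 0) "uniform"
              else sprintf("%d site", length(x$loading_sites))))
  invisible(x)
}
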