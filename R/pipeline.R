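# Single-command pipeline: Simulations -> Analysis -> Comparison, grid
# expansion, local replicate parallelism, seeding and manifests.

#' Derive a reproducible child seed
#'
#' Stable cross-platform hash of (master seed, replicate index, grid cell
#' index); distinct inputs give decorrelated streams.
#'
#' @param master Master integer seed.
#' @param replicate Replicate index.
#' @param cell Grid cell index (0 outside grids).
#' @return An integer seed in `[1, 2^31 - 1]`.
#' @export
derive_seed <- function(master, replicate, cell = 0L) {
  cpp_derive_seed(as.integer(master), as.integer(replicate), as.integer(cell))
}

#' Expand a grid configuration into per-cell parameter sets
#'
#' Takes a configuration with a `grid:` section (named per-parameter value
#' arrays) and returns the Cartesian product minus masked cells, each child
#' inheriting the non-grid keys, with deterministic ordering and distinct
#' derived seeds.
#'
#' @param config A `sim_config` from [load_config()] (or a path / YAML text).
#' @return Tibble with one row per grid cell: `cell` (1-based, in
#'   deterministic column-major order over the declared axes), one column
#'   per grid parameter, `seed`, and a `params` list-column of `sim_params`.
#' @export
expand_param_grid <- function(config) {
  if (!inherits(config, "sim_config")) config <- load_config(config)
  grid <- config$grid
  if (is.null(grid) || length(grid) == 0) {
    schema_error("configuration has no 'grid' section to expand")
  }
  unknown <- setdiff(names(grid), names(.param_defaults()))
  if (length(unknown) > 0) {
    schema_error(sprintf("grid key(s) not a known parameter: %s",
                         paste(unknown, collapse = ", ")))
  }
  if (any(lengths(grid) == 0)) schema_error("grid value lists must be non-empty")

  cells <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells <- as_tibble(cells)
  cells$cell <- seq_len(nrow(cells))

  if (!is.null(config$grid_mask)) {
    drop <- vapply(config$grid_mask, function(m) {
      hit <- rep(TRUE, nrow(cells))
      for (k in names(m)) hit <- hit & cells[[k]] == m[[k]]
      which(hit)[1]
    }, numeric(1))
    drop <- drop[!is.na(drop)]
    if (length(drop) > 0) cells <- cells[-drop, ]
  }

  base <- unclass(config$params)
  cells$seed <- vapply(cells$cell, function(cl) {
    derive_seed(base$seed, 0L, cl)
  }, integer(1))
  cells$params <- lapply(seq_len(nrow(cells)), function(r) {
    ov <- as.list(cells[r, names(grid), drop = FALSE])
    p <- utils::modifyList(base, ov)
    p$seed <- cells$seed[r]
    # a grid over density overrides any explicit target count
    if ("lef_density_kb" %in% names(ov)) p$n_lef_target <- NULL
    sim_params(p)
  })
  cells[, c("cell", names(grid), "seed", "params")]
}

#' Run replicates across local workers
#'
#' Distributes the replicates of one simulation over forked local workers.
#' Each replicate uses its own derived seed, so results are identical to
#' serial execution regardless of scheduling.
#'
#' @param params A [sim_params()] object.
#' @param genome A [build_genome()] annotation.
#' @param n_workers Number of local workers (1 = serial).
#' @param seed Master seed.
#' @param model Energy model override.
#' @return A `snapshot_stream` over all replicates.
#' @export
parallel_replicates <- function(params, genome, n_workers = 1,
                                seed = params$seed,
                                model = energy_model(params)) {
  reps <- seq_len(params$n_replicates)
  run_one <- function(r) {
    tryCatch(run_coupled(params, genome, seed = seed, model = model,
                         replicate_ids = r),
             error = function(e) e)
  }
  parts <- if (n_workers > 1 && .Platform$OS.type == "unix") {
    parallel::mclapply(reps, run_one, mc.cores = n_workers)
  } else {
    lapply(reps, run_one)
  }
  failed <- vapply(parts, inherits, logical(1), what = "error")
  ok <- parts[!failed]
  if (length(ok) == 0) {
    abort("all replicates failed", class = "polyloopsim_error")
  }
  structure(list(
    replicates = unlist(lapply(ok, `[[`, "replicates"), recursive = FALSE),
    event_counts = Reduce(`+`, lapply(ok, `[[`, "event_counts")),
    replicate_ids = reps[!failed],
    failed_replicates = reps[failed],
    params = params, genome = genome, model = model, seed = seed
  ), class = "snapshot_stream")
}

# ---- snapshot persistence (plain text) --------------------------------------

write_snapshots_tsv <- function(stream, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_along(stream$replicates)) {
    r <- stream$replicate_ids[k]
    snaps <- stream$replicates[[k]]
    pos <- dplyr::bind_rows(lapply(seq_along(snaps), function(s) {
      p <- snaps[[s]]$positions
      tibble(snapshot = s, time_min = snaps[[s]]$time_min,
             monomer = seq_len(nrow(p)) - 1L,
             x = p[, 1], y = p[, 2], z = p[, 3])
    }))
    legs <- dplyr::bind_rows(lapply(seq_along(snaps), function(s) {
      lg <- snaps[[s]]$legs
      if (nrow(lg) == 0) return(NULL)
      tibble(snapshot = s, time_min = snaps[[s]]$time_min,
             left = lg[, 1], right = lg[, 2])
    }))
    readr::write_tsv(pos, file.path(dir, sprintf("positions_rep%03d.tsv", r)))
    if (is.null(legs) || nrow(legs) == 0) {
      legs <- tibble(snapshot = integer(0), time_min = numeric(0),
                     left = integer(0), right = integer(0))
    }
    readr::write_tsv(legs, file.path(dir, sprintf("legs_rep%03d.tsv", r)))
  }
  invisible(dir)
}

read_snapshots_tsv <- function(dir, params, genome, model = energy_model(params)) {
  pos_files <- sort(list.files(dir, "^positions_rep[0-9]+\\.tsv$", full.names = TRUE))
  if (length(pos_files) == 0) {
    abort(sprintf("no snapshot files found under %s (run the simulations stage first)", dir),
          class = "polyloopsim_io_error")
  }
  reps <- lapply(pos_files, function(pf) {
    lf <- sub("positions_rep", "legs_rep", pf)
    pos <- readr::read_tsv(pf, show_col_types = FALSE, progress = FALSE)
    legs <- readr::read_tsv(lf, show_col_types = FALSE, progress = FALSE)
    lapply(split(pos, pos$snapshot), function(ps) {
      s <- ps$snapshot[1]
      lg <- legs[legs$snapshot == s, , drop = FALSE]
      list(time_min = ps$time_min[1],
           positions = cbind(ps$x, ps$y, ps$z)[order(ps$monomer), , drop = FALSE],
           legs = if (nrow(lg) == 0) matrix(integer(0), ncol = 2)
                  else cbind(lg$left, lg$right),
           n_bound = nrow(lg))
    })
  })
  structure(list(replicates = reps, event_counts = NULL,
                 replicate_ids = seq_along(reps),
                 params = params, genome = genome, model = model,
                 seed = params$seed),
            class = "snapshot_stream")
}

# ---- pipeline ---------------------------------------------------------------

#' Run the Simulations -> Analysis -> Comparison pipeline
#'
#' Executes the requested stages in order for one configuration:
#' `simulations` runs the coupled 1D/3D model and stores snapshots
#' (plain-text tables under `output_dir/snapshots/`); `analysis` converts
#' them into a virtual Hi-C map (`map.tsv` dense text and `map.cool` cooler
#' HDF5), a virtual ChIP-seq track (`occupancy.bedgraph`) and three-way
#' contact counts (`triplets.tsv`); `comparison` scores the map against the
#' configured `reference_map` (`comparison.json`). Completed stages are
#' skipped on re-run unless `force = TRUE`. A run manifest (`manifest.json`)
#' is written before the first stage starts and finalized at the end.
#'
#' @param config Path to a YAML configuration, YAML text, or a `sim_config`.
#' @param output_dir Output directory (created if needed).
#' @param stages Subset of `c("simulations", "analysis", "comparison")`.
#' @param force Re-run stages whose artifacts already exist.
#' @param workers Local workers for replicate parallelism.
#' @return The run manifest (list), invisibly.
#' @export
run_pipeline <- function(config, output_dir,
                         stages = c("simulations", "analysis", "comparison"),
                         force = FALSE, workers = 1) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (!inherits(config, "sim_config")) config <- load_config(config)
  params <- config$params
  genome <- build_genome(params, config$boundary_spec, config$loading_sites_kb)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)

  manifest <- list(
    params = unclass(params),
    n_boundaries = nrow(genome$boundaries),
    replicate_seeds = vapply(seq_len(params$n_replicates),
                             function(r) derive_seed(params$seed, r, 1L), integer(1)),
    stages_requested = stages,
    stages_completed = character(0),
    stages_skipped = character(0),
    artifacts = list(),
    wall_time_s = list(),
    started = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
    finalized = FALSE
  )
  manifest_path <- file.path(output_dir, "manifest.json")
  .write_manifest <- function() {
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }
  .write_manifest()

  snap_dir <- file.path(output_dir, "snapshots")

  if ("simulations" %in% stages) {
    done <- length(list.files(snap_dir, "^positions_rep")) >= params$n_replicates
    if (done && !force) {
      manifest$stages_skipped <- c(manifest$stages_skipped, "simulations")
    } else {
      t0 <- Sys.time()
      stream <- parallel_replicates(params, genome, n_workers = workers)
      write_snapshots_tsv(stream, snap_dir)
      manifest$event_counts <- as.list(stream$event_counts)
      manifest$failed_replicates <- stream$failed_replicates %||% integer(0)
      manifest$wall_time_s$simulations <-
        as.numeric(difftime(Sys.time(), t0, units = "secs"))
      manifest$stages_completed <- c(manifest$stages_completed, "simulations")
    }
    manifest$artifacts$snapshots <- snap_dir
    .write_manifest()
  }

  map_tsv <- file.path(output_dir, "map.tsv")
  map_cool <- file.path(output_dir, "map.cool")
  bedgraph <- file.path(output_dir, "occupancy.bedgraph")
  triplets_tsv <- file.path(output_dir, "triplets.tsv")

  if ("analysis" %in% stages) {
    if (file.exists(map_tsv) && !force) {
      manifest$stages_skipped <- c(manifest$stages_skipped, "analysis")
    } else {
      t0 <- Sys.time()
      stream <- read_snapshots_tsv(snap_dir, params, genome)
      map <- contact_map(stream)
      write_dense_matrix(map, map_tsv)
      cool_ok <- tryCatch({ write_cooler(map, map_cool); TRUE },
                          error = function(e) { warning(conditionMessage(e)); FALSE })
      track <- chip_profile(stream)
      write_bedgraph(track, bedgraph)
      trip <- threeway_counts(stream)
      readr::write_tsv(as_tibble(trip), triplets_tsv)
      manifest$wall_time_s$analysis <-
        as.numeric(difftime(Sys.time(), t0, units = "secs"))
      manifest$stages_completed <- c(manifest$stages_completed, "analysis")
      manifest$cooler_written <- cool_ok
    }
    manifest$artifacts$map_tsv <- map_tsv
    if (file.exists(map_cool)) manifest$artifacts$map_cool <- map_cool
    manifest$artifacts$occupancy <- bedgraph
    manifest$artifacts$triplets <- triplets_tsv
    .write_manifest()
  }

  comparison_json <- file.path(output_dir, "comparison.json")
  if ("comparison" %in% stages && !is.null(config$reference_map)) {
    if (file.exists(comparison_json) && !force) {
      manifest$stages_skipped <- c(manifest$stages_skipped, "comparison")
    } else {
      t0 <- Sys.time()
      if (!file.exists(map_tsv)) {
        abort(sprintf("missing model map %s (run the analysis stage first)", map_tsv),
              class = "polyloopsim_io_error")
      }
      n_bins <- genome$chain_length_kb / params$hic_bin_kb
      model_map <- read_contact_map(map_tsv, bin_kb = params$hic_bin_kb,
                                    n_snapshots = 1)
      ref <- read_contact_map(config$reference_map, bin_kb = params$hic_bin_kb)
      if (ref$bin_size_kb != model_map$bin_size_kb) {
        ref <- rebin_map(ref, model_map$bin_size_kb)
      }
      res <- chi2_score(model_map, ref, variance_mode = "poisson")
      jsonlite::write_json(
        c(as.list(tidy(res)), list(n_bins = n_bins)),
        comparison_json, auto_unbox = TRUE, pretty = TRUE, digits = NA)
      manifest$wall_time_s$comparison <-
        as.numeric(difftime(Sys.time(), t0, units = "secs"))
      manifest$stages_completed <- c(manifest$stages_completed, "comparison")
    }
    manifest$artifacts$comparison <- comparison_json
    .write_manifest()
  }

  manifest$finalized <- TRUE
  manifest$finished <- format(Sys.time(), "%Y-%m-%d %H:%M:%S")
  .write_manifest()
  invisible(manifest)
}

#' Run a grid of simulations and summarize the scores
#'
#' Expands the configuration's `grid:` section, runs the full pipeline in a
#' sub-directory per cell, scores each cell against the configured reference
#' map, and writes `grid_scores.tsv` plus a heat-map figure.
#'
#' @param config Path / YAML text / `sim_config` with `grid` and
#'   `reference_map`.
#' @param output_dir Output directory.
#' @param workers Local workers (used within each cell's replicates).
#' @param force Re-run completed cells.
#' @return A [grid_summarize()] `grid_summary`, invisibly.
#' @export
run_grid <- function(config, output_dir, workers = 1, force = FALSE) {
  if (!inherits(config, "sim_config")) config <- load_config(config)
  if (is.null(config$reference_map)) {
    schema_error("grid runs need a 'reference_map' to score against")
  }
  cells <- expand_param_grid(config)
  grid_names <- setdiff(names(cells), c("cell", "seed", "params"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)

  scores <- vapply(seq_len(nrow(cells)), function(r) {
    cell_dir <- file.path(output_dir, sprintf("cell_%03d", cells$cell[r]))
    cfg <- config
    cfg$params <- cells$params[[r]]
    run_pipeline(cfg, cell_dir, force = force, workers = workers)
    res <- jsonlite::read_json(file.path(cell_dir, "comparison.json"))
    res$chi2
  }, numeric(1))

  results <- cells[, grid_names]
  results$chi2 <- scores
  gs <- grid_summarize(results, axes = config$grid[grid_names])
  write_grid_scores(gs, file.path(output_dir, "grid_scores.tsv"))
  tryCatch({
    p <- autoplot(gs)
    ggplot2::ggsave(file.path(output_dir, "grid_heatmap.pdf"), p,
                    width = 6, height = 5)
  }, error = function(e) warning("heat-map rendering failed: ", conditionMessage(e)))
  invisible(gs)
}
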