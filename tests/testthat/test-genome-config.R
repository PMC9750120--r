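test_that("configuration resolves chain geometry and defaults", {
  cfg <- load_config("chain_length_kb: 6000\nmonomer_size_kb: 2")
  expect_s3_class(cfg$params, "sim_params")
  expect_identical(n_monomers(cfg$params), 3000L)

  # empty config: every default, valid object
  cfg0 <- load_config("")
  expect_s3_class(cfg0$params, "sim_params")
  expect_identical(n_monomers(cfg0$params), 3000L)
  expect_equal(cfg0$params$monomer_diameter_nm, 50)
  expect_equal(cfg0$params$contact_cutoff_nm, 100)
  expect_equal(cfg0$params$n_lef_target, 100L)  # 6000 kb at 1 LEF / 60 kb
})

test_that("schema and invariant violations are rejected by name", {
  expect_error(load_config("not_a_parameter: 3"),
               "not_a_parameter", class = "polyloopsim_schema_error")
  expect_error(sim_params(chain_length_kb = 5, monomer_size_kb = 2),
               "divisible", class = "polyloopsim_validation_error")
  expect_error(sim_params(hic_bin_kb = 3, monomer_size_kb = 2),
               "hic_bin_kb", class = "polyloopsim_validation_error")
  expect_error(sim_params(velocity_kb_per_min = -1),
               "velocity_kb_per_min", class = "polyloopsim_validation_error")
  expect_error(sim_params(snapshot_interval_min = 50, sim_time_min = 10),
               "snapshot_interval_min", class = "polyloopsim_validation_error")
  expect_error(sim_params(extrusion_mode = "sideways"),
               "extrusion_mode", class = "polyloopsim_validation_error")
})

test_that("parameters round-trip through config text", {
  p <- sim_params(chain_length_kb = 1200, monomer_size_kb = 2,
                  n_lef_target = 7, velocity_kb_per_min = 42,
                  extrusion_mode = "asymmetric", collision_mode = "phantom",
                  sim_time_min = 33, seed = 99)
  txt <- write_config(p)
  p2 <- load_config(txt)$params
  expect_identical(unclass(p2), unclass(p))
})

test_that("positions convert to monomer indices by integer division", {
  p <- sim_params(chain_length_kb = 6000, monomer_size_kb = 2)
  g <- build_genome(p, data.frame(position_kb = 300))
  expect_identical(g$n_monomers, 3000L)
  expect_identical(g$boundaries$monomer_index, 150L)
  # a position inside a monomer maps to that monomer
  g2 <- build_genome(p, data.frame(position_kb = 301))
  expect_identical(g2$boundaries$monomer_index, 150L)
})

test_that("build_genome validates and sorts independently of input order", {
  p <- sim_params(chain_length_kb = 600, monomer_size_kb = 2)
  spec <- data.frame(position_kb = c(400, 100, 250),
                     orientation = c("blocks_both", "blocks_leftward", "blocks_rightward"),
                     permeability = c(0, 0.5, 1))
  g1 <- build_genome(p, spec)
  g2 <- build_genome(p, spec[c(3, 1, 2), ])
  expect_identical(g1$boundaries, g2$boundaries)
  expect_identical(g1$boundaries$monomer_index, c(50L, 125L, 200L))

  expect_error(build_genome(p, data.frame(position_kb = 600)),
               "600", class = "polyloopsim_validation_error")
  expect_error(build_genome(p, data.frame(position_kb = c(100, 101))),
               "duplicate", class = "polyloopsim_validation_error")
  expect_error(build_genome(p, loading_spec = 900),
               "900", class = "polyloopsim_validation_error")
})

test_that("alternating-spacing helper places boundaries at cyclic cumulative sums", {
  expect_equal(alternating_boundaries(1800, c(300, 600))$position_kb,
               c(300, 900, 1200))
  # independent brute-force enumeration of cumulative sums below the chain end
  brute <- function(L, gaps) {
    out <- numeric(0); cur <- 0; i <- 0
    repeat {
      cur <- cur + gaps[(i %% length(gaps)) + 1]; i <- i + 1
      if (cur >= L) return(out)
      out <- c(out, cur)
    }
  }
  b <- alternating_boundaries(6000, c(300, 600))
  expect_equal(b$position_kb, brute(6000, c(300, 600)))
  expect_identical(nrow(b), 13L)
  p <- sim_params(chain_length_kb = 6000, monomer_size_kb = 2)
  g <- build_genome(p, b)
  expect_identical(g$boundaries$monomer_index,
                   c(150L, 450L, 600L, 900L, 1050L, 1350L, 1500L, 1800L,
                     1950L, 2250L, 2400L, 2700L, 2850L))
  # defaults: impermeable, bidirectional
  expect_true(all(b$permeability == 0))
  expect_true(all(b$orientation == "blocks_both"))

  expect_identical(nrow(alternating_boundaries(6000, 6000)), 0L)
  expect_error(alternating_boundaries(600, c(100, -5)),
               class = "polyloopsim_validation_error")
})

test_that("boundary specs load from BED-like files and inline config", {
  f <- tempfile(fileext = ".bed")
  writeLines(c("# start_kb orientation permeability",
               "100\tblocks_rightward\t0.25",
               "400\tblocks_both\t0"), f)
  spec <- read_boundary_file(f)
  expect_equal(spec$position_kb, c(100, 400))
  expect_equal(spec$permeability, c(0.25, 0))

  cfg <- load_config(sprintf(
    "chain_length_kb: 600\nmonomer_size_kb: 2\nboundaries_file: %s", f))
  expect_equal(cfg$boundary_spec$position_kb, c(100, 400))

  cfg2 <- load_config(paste(
    "chain_length_kb: 600", "monomer_size_kb: 2",
    "boundaries:",
    "  - {position_kb: 100, orientation: blocks_leftward, permeability: 0.5}",
    "  - {position_kb: 300}", sep = "\n"))
  expect_equal(cfg2$boundary_spec$permeability, c(0.5, 0))
  expect_equal(cfg2$boundary_spec$orientation[2], "blocks_both")
})
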