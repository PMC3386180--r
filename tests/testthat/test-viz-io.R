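p0 <- default_params()

make_mini_traj <- function() {
  M <- synth_traveling_pulse(6, seq(0, 240), period = 120)
  synth_trajectory(M, seq(0, 240), species = "mesp2_mc")
}

test_that("rendering is a pure deterministic function of its inputs", {
  tr <- make_mini_traj()
  a <- render_snapshot(tr, 120, "mesp2_mc")
  b <- render_snapshot(tr, 120, "mesp2_mc")
  expect_identical(a, b)
  expect_true(all(a >= 0 & a <= 1))
  # mRNA species render on the blue channel
  expect_equal(max(a[, , 1]), 0)
  expect_gt(max(a[, , 3]), 0.99)
})

test_that("all-zero fields render as background, peaks as full blocks", {
  M <- matrix(0, 4, 5)
  tr <- synth_trajectory(M, seq(0, 4), species = "mesp2_mc")
  img <- render_snapshot(tr, 2, "mesp2_mc")
  expect_equal(max(img), 0)    # no division by zero, uniform background
  M2 <- matrix(0, 4, 5); M2[2, ] <- 3
  tr2 <- synth_trajectory(M2, seq(0, 4), species = "mesp2_mc")
  img2 <- render_snapshot(tr2, 2, render_spec("mesp2_mc", scale = 2))
  blue <- img2[, , 3]
  expect_equal(max(blue), 1)
  # exactly one cell block saturated (scale^2 pixels)
  expect_equal(sum(blue == 1), 4)
})

test_that("double staining blends to white where both channels saturate", {
  M <- matrix(2, 3, 5)
  tr <- synth_trajectory(M, seq(0, 4), species = "hes7_pn")
  tr$data <- array(rep(tr$data, 2), dim = c(3, 5, 2),
                   dimnames = list(NULL, NULL, c("hes7_pn", "nicd_n")))
  tr$species <- c("hes7_pn", "nicd_n")
  img <- render_double(tr, 2, "hes7_pn", "nicd_n", scale = 2)
  expect_equal(min(img), 1)    # green + magenta at equal strength = white
  # single channel renders pure green
  tr$data[, , 2] <- 0
  img2 <- render_double(tr, 2, "hes7_pn", "nicd_n", scale = 2)
  expect_equal(max(img2[, , 1]), 0)
  expect_equal(max(img2[, , 2]), 1)
})

test_that("fixed-window normalization clamps into [0, 1]", {
  M <- matrix(seq(0, 10, length.out = 4), 4, 3)
  tr <- synth_trajectory(M, 0:2, species = "mesp2_pc")
  img <- render_snapshot(tr, 1, render_spec("mesp2_pc", normalize = c(0, 5)))
  expect_true(all(img >= 0 & img <= 1))
  expect_error(render_snapshot(tr, 1, render_spec("mesp2_pc",
                                                  normalize = c(5, 5))))
})

test_that("configuration files load, default and round-trip", {
  f <- tempfile(fileext = ".txt")
  writeLines(character(0), f)          # empty file -> full defaults
  cfg <- load_config(f)
  expect_equal(unclass(cfg$params), unclass(default_params()))
  expect_null(cfg$experiment)
  # overrides and experiment stanza
  writeLines(c("param.k_dn = 0.5", "sim.t_end = 240", "sim.seed = 9",
               "experiment = ripply2_ko"), f)
  cfg2 <- load_config(f)
  expect_equal(cfg2$params$k_dn, 0.5)
  expect_equal(cfg2$config$t_end, 240)
  expect_equal(cfg2$experiment, knockout("ripply2"))
  # unknown keys are strict errors
  writeLines("param.bogus = 1", f)
  expect_error(load_config(f), "unknown parameter key")
  # save/load round trip
  p <- set_params(default_params(), k_dn = 0.77)
  c0 <- sim_config(t_end = 120, seed = 3)
  f2 <- tempfile()
  save_config(p, c0, f2)
  back <- load_config(f2)
  expect_equal(back$params$k_dn, 0.77)
  expect_equal(back$config$t_end, 120)
  expect_equal(back$config$seed, 3L)
})

test_that("trajectory CSV export is long-format and re-readable", {
  tr <- make_mini_traj()
  f <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, f)
  df <- read.csv(f)
  expect_identical(sort(names(df)), sort(c("time", "cell", "species", "value")))
  back <- read_trajectory_csv(f)
  expect_equal(back$data[, , 1], tr$data[, , 1], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("the CLI entry point reports a version and runs a tiny simulate", {
  expect_output(psm_cli("--version"), "psmclock")
  out <- tempfile()
  cfgf <- tempfile()
  writeLines(c("sim.t_end = 48", "sim.record_every = 2",
               "geometry.n_rows = 1", "geometry.n_cols = 1",
               "geometry.n_layers = 3", "geometry.gz_depth = 3"), cfgf)
  suppressMessages(psm_cli(c("simulate", "--config", cfgf, "--seed", "2",
                             "--out", out)))
  expect_true(file.exists(file.path(out, "trajectory.csv")))
  expect_true(file.exists(file.path(out, "events.jsonl")))
  expect_true(file.exists(file.path(out, "params_used.txt")))
})
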