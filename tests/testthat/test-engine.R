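p0 <- default_params()

test_that("one RK4 step on pure exponential decay matches the textbook update", {
  # a cell with only epha4_pc nonzero and all production off decays
  # linearly: one step must equal the RK4 stability polynomial
  p <- p0
  p$epha4_k_tr <- 0; p$epha4_k_tl <- 0; p$epha4_d_pc <- 1
  t <- new_tissue(1, 1, 1, gz_depth = 1)
  t$state[1, "epha4_pc"] <- 2
  topo <- neighbor_topology(t)
  h <- 0.5
  out <- psmclock:::.rk4_segment(t$state, p, topo$idx, topo$ptr, FALSE,
                                 h, 1L, 0, 0L, integer(0), FALSE, 0, 0, 0,
                                 p$epha4_threshold)
  poly <- 1 - h + h^2 / 2 - h^3 / 6 + h^4 / 24
  expect_equal(unname(out$state[1, "epha4_pc"]), 2 * poly, tolerance = 1e-14)
})

test_that("zero-dynamics state stays constant", {
  # all-zero state with growth-zone transcription disabled: every
  # production term has a zero factor
  p <- set_params(p0, wnt3a_k_tr = 0, fgf8_k_tr = 0)
  t <- new_tissue(2, 2, 3, gz_depth = 3)
  cfg <- sim_config(t_end = 10, record_every = 1, division_interval = NULL)
  tr <- integrate_tissue(t, p, cfg)
  expect_equal(max(abs(tr$data), na.rm = TRUE), 0)
})

test_that("initialize_tissue starts synchronous on gradient steady states", {
  tis <- initialize_tissue(p0, 2, 2, 4, 4)
  expect_equal(unname(tis$state[1, "wnt3a_m"]), p0$wnt3a_k_tr / p0$wnt3a_d_m,
               tolerance = 1e-6)
  # all cells identical
  expect_equal(max(abs(sweep(tis$state, 2, tis$state[1, ]))), 0)
  # after one clock period with no growth, symmetry-equivalent cells stay
  # identical (cells within a layer are equivalent under the 2 x 2
  # cross-section symmetry; layers 1/4 and 2/3 are mirror images; tissue
  # boundaries make layer 1 differ from layer 2 through the conservation
  # apportionment of the D/N reaction)
  cfg <- sim_config(t_end = 120, division_interval = NULL)
  tr <- integrate_tissue(tis, p0, cfg)
  S <- tr$tissue$state
  lay <- tr$tissue$layer
  for (l in 1:4) {
    Sl <- S[lay == l, , drop = FALSE]
    expect_lt(max(abs(sweep(Sl, 2, Sl[1, ]))), 1e-9)
  }
  expect_lt(max(abs(S[lay == 1, ][1, ] - S[lay == 4, ][1, ])), 1e-9)
  expect_lt(max(abs(S[lay == 2, ][1, ] - S[lay == 3, ][1, ])), 1e-9)
})

test_that("initialization fails loudly for non-oscillatory parameters", {
  p <- apply_experiment(p0, knockout("hes7"))
  expect_error(limit_cycle_state(p), "failed to oscillate")
})

test_that("trajectories are reproducible bit for bit", {
  p <- p0
  cfg <- sim_config(t_end = 96, seed = 42)
  a <- integrate_tissue(initialize_tissue(p, 2, 2), p, cfg)
  b <- integrate_tissue(initialize_tissue(p, 2, 2), p, cfg)
  expect_identical(a$data, b$data)
  expect_identical(a$cells, b$cells)
})

test_that("with k_dn = 0 and frozen gradients cells evolve independently", {
  p <- set_params(p0, k_dn = 0)
  tis <- initialize_tissue(p0, 1, 2, 2, 2)   # 4 cells, all growth zone
  tis2 <- tis
  tis2$state[4, "hes7_pn"] <- tis2$state[4, "hes7_pn"] + 1  # perturb one cell
  cfg <- sim_config(t_end = 60, division_interval = NULL)
  a <- integrate_tissue(tis, p, cfg)
  b <- integrate_tissue(tis2, p, cfg)
  # cells 1-3 are unaffected by the perturbation of cell 4
  expect_equal(a$data[1:3, , ], b$data[1:3, , ], tolerance = 1e-14)
  expect_false(isTRUE(all.equal(a$data[4, , ], b$data[4, , ])))
})

test_that("config validation rejects inconsistent stepping", {
  expect_error(sim_config(t_end = 10, dt = 0.3, record_every = 1),
               "integer multiple")
  expect_error(sim_config(t_end = 10, dt = 0.025, record_every = 1,
                          division_interval = 1.5), "record_every")
  expect_error(sim_config(t_end = 10, record_species = "not_a_species"),
               "unknown record species")
})

test_that("default full-tissue run integrates cleanly", {
  tr <- wt_run()
  expect_equal(tr$clamp_events, 0)         # no negativity clamps
  expect_true(all(diff(tr$times) > 0))
  expect_true(all(tr$data >= 0, na.rm = TRUE))
  # growth: one layer per division round
  expect_equal(tr$tissue$n_layers, 15 + floor((720 - 1) / 24))
})
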