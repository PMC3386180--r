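p0 <- default_params()

test_that("experiment transforms modify parameters as declared", {
  expect_equal(apply_experiment(p0, knockout("hes7"))$hes7_k_tr, 0)
  expect_equal(apply_experiment(p0, knockout("ripply2"))$ripply2_k_tr, 0)
  expect_error(knockout("sonic"), "unknown gene")
  # applying then reverting leaves the baseline untouched (params are
  # immutable values, so this is an identity by construction)
  spec <- knockout("hes7")
  p1 <- apply_experiment(p0, spec)
  expect_equal(unclass(revert_experiment(p0, spec)), unclass(p0))
  expect_false(identical(p1$hes7_k_tr, p0$hes7_k_tr))
})

test_that("remove_feedback makes the Dll1 promoter HES7-independent", {
  p <- apply_experiment(p0, remove_feedback())
  a1 <- promoter_activity("dll1", c(tbx6_p = 2, wnt_avg = 3, hes7_pn = 0), p)
  a2 <- promoter_activity("dll1", c(tbx6_p = 2, wnt_avg = 3, hes7_pn = 100), p)
  expect_equal(a1, a2)   # partial derivative w.r.t. HES7 is identically 0
})

test_that("identity transforms are identities", {
  expect_equal(unclass(apply_experiment(p0, constitutive_nicd(0))),
               unclass(p0))
  spec <- timed_fgf8_reduction(1, 600)
  sched <- experiment_schedule(spec)
  expect_equal(sched$value, 1)
  expect_equal(unclass(apply_experiment(p0, clock_rate_variation(1))),
               unclass(p0))
})

test_that("timed transforms become an engine schedule, lazy until triggered", {
  spec <- timed_fgf8_reduction(0.5, 600)
  # no t = 0 change
  expect_equal(unclass(apply_experiment(p0, spec)), unclass(p0))
  sched <- experiment_schedule(spec)
  expect_equal(sched$time, 600)
  expect_identical(sched$op, "mul")
})

test_that("all-rates clock scaling rescales the period as 1/s", {
  s <- 1.2
  p <- apply_experiment(p0, clock_rate_variation(s, mode = "all"))
  tr <- run_twocell(p, env = growth_zone_env(p0), t_end = 1200, init = "kick")
  T1 <- detect_period(tr$data[1, , "hes7_pn"], tr$times, 0.5)$period
  expect_equal(T1, 120 / s, tolerance = 0.02)
})

test_that("config experiment stanzas match the constructors", {
  expect_equal(make_experiment("hes7_ko"), knockout("hes7"))
  expect_equal(make_experiment("ripply2_ko"), knockout("ripply2"))
  expect_equal(make_experiment("dll1_feedback"), remove_feedback())
  expect_equal(make_experiment("fgf8_half", list(factor = 0.5, time = 600)),
               timed_fgf8_reduction(0.5, 600))
  expect_error(make_experiment("warp_drive"), "unknown experiment")
})

test_that("synchronization wiring uses HES1 as Dll1 repressor", {
  spec <- sync_experiment(0.25, nicd_hill = 2)
  p <- apply_experiment(p0, spec)
  expect_identical(p$dll1_repressor, "hes1")
  expect_equal(p$hes1_h_nicd, 2)
  expect_equal(spec$sync$max_phase_offset, 0.25)
})

test_that("zero phase offset preserves perfect synchrony", {
  p <- apply_experiment(p0, sync_experiment(0))
  tis <- initialize_tissue(p0, 2, 2, 1, 1)
  set.seed(1)
  tis <- randomize_phases(tis, p0, 0)
  cfg <- sim_config(t_end = 480, division_interval = NULL)
  tr <- integrate_tissue(tis, p, cfg)
  pd <- phase_dispersion(tr, time = 480, species = "hes1_pn")
  expect_equal(pd$dispersion, 0)
})

test_that("randomized phases disperse and D/N coupling pulls them back", {
  p <- apply_experiment(p0, sync_experiment(0.25, nicd_hill = 2))
  tis <- initialize_tissue(p0, 4, 4, 1, 1)
  set.seed(5)
  tis <- randomize_phases(tis, p0, 0.25)
  cfg <- sim_config(t_end = 1440, division_interval = NULL)
  tr <- integrate_tissue(tis, p, cfg)
  early <- phase_dispersion(tr, time = 240, species = "hes1_pn")$dispersion
  late <- mean(c(phase_dispersion(tr, time = 1080, species = "hes1_pn")$dispersion,
                 phase_dispersion(tr, time = 1320, species = "hes1_pn")$dispersion))
  expect_gt(early, 0.3)    # the offsets produced real dispersion
  expect_lt(late, early)   # dimer NICD coupling reduces it over cycles
})
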