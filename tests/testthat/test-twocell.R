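p0 <- default_params()

test_that("symmetric two-cell systems stay symmetric", {
  tr <- wt_twocell()
  expect_equal(tr$data[1, , ], tr$data[2, , ], tolerance = 1e-12)
  expect_equal(tr$clamp_events, 0)
})

test_that("without the D/N reaction there is no NICD and no oscillation", {
  p <- set_params(p0, k_dn = 0)
  tr <- run_twocell(p, t_end = 1200, init = "kick")
  # the initial NICD kick decays; nothing replenishes it
  expect_lt(max(tr$data[1, tr$times > 600, "nicd_n"]), 1e-3)
  s <- detect_period(tr$data[1, , "hes7_pn"], tr$times, 0.5)
  expect_true(s$damping != "sustained" || s$amp_max - s$amp_min < 1e-3)
})

test_that("scanning a single value reproduces run_twocell", {
  sc <- scan_parameter("k_dn", p0$k_dn, p0, t_end = 1200)
  tr <- run_twocell(p0, t_end = 1200, init = "kick")
  s <- detect_period(tr$data[1, , "hes7_pn"], tr$times)
  expect_equal(sc$period, s$period)
  expect_equal(sc$hes7_max, s$amp_max)
  expect_error(scan_parameter("nope", 1), "unknown")
})

test_that("oscillation period follows the Goodwin monotonicity laws", {
  # faster Hes7 mRNA decay -> shorter period
  vals <- p0$hes7_d_mc * c(0.7, 0.85, 1, 1.15, 1.3)
  sc <- scan_parameter("hes7_d_mc", vals, p0, t_end = 2400)
  expect_true(all(sc$damping == "sustained"))
  expect_true(all(diff(sc$period) < 0))
  # higher transcription rate -> longer period
  sc2 <- scan_parameter("hes7_k_tr", p0$hes7_k_tr * c(0.7, 1, 1.4), p0,
                        t_end = 2400)
  expect_true(all(diff(sc2$period) > 0))
})

test_that("period depends only weakly on Dll1/Notch1 protein decays", {
  for (nm in c("dll1_d_pm", "notch1_d_pm")) {
    sc <- scan_parameter(nm, p0[[nm]] * c(0.5, 1, 2), p0, t_end = 2400)
    rel <- (max(sc$period) - min(sc$period)) / min(sc$period)
    expect_lt(rel, 0.1)   # < 10% over a 4-fold range
  }
})

test_that("NICD amplitude difference saturates with the D/N reaction rate", {
  sc <- scan_parameter("k_dn", p0$k_dn * c(0.05, 0.2, 0.5, 1), p0,
                       t_end = 2400)
  d <- sc$nicd_max - sc$nicd_min
  # rises from the low end and is nearly constant across the upper range
  expect_gt(d[4], d[1])
  expect_lt(abs(d[4] - d[3]) / d[3], 0.15)
})

test_that("Dll1 mRNA decay decouples or couples NICD and the clock", {
  # slower Dll1 mRNA decay: NICD becomes nearly constant while HES7 keeps
  # oscillating on its own feedback
  p_slow <- set_params(p0, dll1_d_mc = p0$dll1_d_mc * 0.25)
  tr <- run_twocell(p_slow, t_end = 2400, init = "kick")
  sn <- detect_period(tr$data[1, , "nicd_n"], tr$times, 0.5)
  s7 <- detect_period(tr$data[1, , "hes7_pn"], tr$times, 0.5)
  expect_identical(s7$damping, "sustained")
  expect_lt((sn$amp_max - sn$amp_min) / sn$amp_max, 0.05)
  # faster decay: NICD minima collapse and amplitudes shrink
  p_fast <- set_params(p0, dll1_d_mc = p0$dll1_d_mc * 4)
  trf <- run_twocell(p_fast, t_end = 2400, init = "kick")
  snf <- detect_period(trf$data[1, , "nicd_n"], trf$times, 0.5)
  sn0 <- detect_period(wt_twocell()$data[1, , "nicd_n"], wt_twocell()$times, 0.5)
  expect_lt(snf$amp_max, sn0$amp_max)
  expect_lt(snf$amp_min, 0.5 * sn0$amp_min)
})

test_that("weakening the activating LFNG input reduces NICD amplitudes", {
  base <- set_params(p0, lfng_mode = "activating", lfng_K_mod = 2)
  with_lfng <- run_twocell(base, t_end = 2400, init = "kick")
  s1 <- detect_period(with_lfng$data[1, , "nicd_n"], with_lfng$times, 0.5)
  ko <- run_twocell(set_params(base, lfng_k_tr = 0), t_end = 2400,
                    init = "kick")
  s0 <- detect_period(ko$data[1, , "nicd_n"], ko$times, 0.5)
  expect_lt(s0$amp_max - s0$amp_min, s1$amp_max - s1$amp_min)
})

test_that("robustness_sample is reproducible and handles degenerate ranges", {
  rb0 <- robustness_sample(c(1, 1), n = 3, seed = 1, t_end = 3600)
  expect_equal(rb0$fraction_sustained, 1)   # all draws equal the defaults
  rb1 <- robustness_sample(c(0.9, 1.1), n = 2, seed = 9, t_end = 2400)
  rb2 <- robustness_sample(c(0.9, 1.1), n = 2, seed = 9, t_end = 2400)
  expect_identical(rb1$draws, rb2$draws)
  expect_error(robustness_sample(list(), n = 1), "empty")
})

test_that("calibration is idempotent on the shipped defaults", {
  cal <- calibrate_defaults()
  expect_equal(cal$report$period_gz, 120, tolerance = 0.005)
  expect_equal(tail(cal$report$scales, 1), 1, tolerance = 2e-3)
  expect_true(cal$report$anterior_ok)
  # re-measured growth-zone period of the calibrated output
  tr <- run_twocell(cal$params, t_end = 1200)
  s <- detect_period(tr$data[1, , "hes7_pn"], tr$times)
  expect_equal(s$period, 120, tolerance = 0.02 * 120)
})

test_that("rescaling all core rates rescales the period exactly", {
  s <- 1.25
  p <- p0
  for (nm in core_rate_names()) p[[nm]] <- p[[nm]] * s
  tr <- run_twocell(p, env = growth_zone_env(p0), t_end = 1200, init = "kick")
  tr0 <- run_twocell(p0, env = growth_zone_env(p0), t_end = 1500, init = "kick")
  T1 <- detect_period(tr$data[1, , "hes7_pn"], tr$times, 0.5)$period
  T0 <- detect_period(tr0$data[1, , "hes7_pn"], tr0$times, 0.5)$period
  expect_equal(T1, T0 / s, tolerance = 2e-3)
})
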