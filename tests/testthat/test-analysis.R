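test_that("detect_period recovers known signals", {
  t <- seq(0, 1200, by = 0.25)
  s <- detect_period(synth_oscillation(t, period = 120), t)
  expect_equal(s$period, 120, tolerance = 0.1 / 120)
  expect_identical(s$damping, "sustained")
  # constant series
  expect_identical(detect_period(rep(3, length(t)), t)$damping, "stationary")
  # exponentially damped oscillation
  sd <- detect_period(synth_oscillation(t, 120, damping_tau = 500,
                                        baseline = 0, amplitude = 1) + 2, t)
  expect_identical(sd$damping, "damped")
  expect_equal(sd$period, 120, tolerance = 0.02)
  # too few maxima -> non-oscillatory result, not an error
  short <- detect_period(sin(2 * pi * seq(0, 100) / 120), seq(0, 100))
  expect_true(is.na(short$period))
})

test_that("detect_period is invariant under positive affine transforms", {
  t <- seq(0, 1200, by = 0.5)
  x <- synth_oscillation(t, 97, amplitude = 1.3)
  s0 <- detect_period(x, t)
  for (ab in list(c(2, 0), c(0.3, 5), c(10, -1))) {
    s <- detect_period(ab[1] * x + ab[2], t)
    expect_equal(s$period, s0$period)
    expect_identical(s$damping, s0$damping)
  }
})

test_that("detect_period agrees with a discrete-autocorrelation estimate", {
  # independent oracle: lag of the first autocorrelation peak
  acf_period <- function(x, t) {
    dt <- t[2] - t[1]
    a <- stats::acf(x, lag.max = length(x) - 1, plot = FALSE)$acf[, 1, 1]
    pk <- which(diff(sign(diff(a))) == -2) + 1
    (pk[1] - 1) * dt
  }
  t <- seq(0, 2400, by = 0.25)
  for (T0 in c(85, 120, 151)) {
    x <- synth_oscillation(t, T0)
    expect_equal(detect_period(x, t)$period, acf_period(x, t),
                 tolerance = 0.01)
  }
  # and on a genuine model trajectory
  tr <- wt_twocell()
  x <- tr$data[1, , "hes7_pn"]
  keep <- tr$times >= 240
  expect_equal(detect_period(x, tr$times)$period,
               acf_period(x[keep] - mean(x[keep]), tr$times[keep]),
               tolerance = 0.01)
})

test_that("somite_lengths measures midpoint-to-midpoint distances", {
  pat <- rep(FALSE, 30); pat[10] <- TRUE; pat[20] <- TRUE
  expect_equal(somite_lengths(synth_epi_tissue(pat)), 10)
  pat2 <- rep(FALSE, 30); pat2[10:11] <- TRUE; pat2[20:21] <- TRUE
  expect_equal(somite_lengths(synth_epi_tissue(pat2)), 10)
  # period-7 stripe pattern: all lengths 7
  pat3 <- rep(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE), 5)
  expect_equal(somite_lengths(synth_epi_tissue(pat3)), rep(7, 4))
  # fewer than 2 stripes -> empty
  expect_length(somite_lengths(synth_epi_tissue(rep(FALSE, 10))), 0)
})

test_that("stripe_count counts contiguous half-max runs", {
  t <- 0:10
  one <- matrix(rep(exp(-((1:30) - 15)^2 / 8), 11), 30)
  expect_equal(stripe_count(synth_trajectory(one, t, "mesp2_mc"), 10), 1L)
  two <- matrix(rep(exp(-((1:30) - 8)^2 / 4) + exp(-((1:30) - 22)^2 / 4), 11), 30)
  expect_equal(stripe_count(synth_trajectory(two, t, "mesp2_mc"), 10), 2L)
  zero <- matrix(0, 30, 11)
  expect_equal(stripe_count(synth_trajectory(zero, t, "mesp2_mc"), 10), 0L)
})

test_that("wave_detect classifies travelling and synchronous fields", {
  t <- seq(0, 600)
  M <- synth_traveling_pulse(20, t, period = 120)
  expect_identical(wave_detect(synth_trajectory(M, t), "hes7_pn"), "wave")
  Ms <- matrix(rep(synth_oscillation(t, 120), each = 20), 20)
  expect_identical(wave_detect(synth_trajectory(Ms, t), "hes7_pn"), "static")
  flat <- matrix(1, 20, length(t))
  expect_identical(wave_detect(synth_trajectory(flat, t), "hes7_pn"), "none")
})

test_that("oscillations_per_cell counts maxima between birth and epithelialization", {
  t <- seq(0, 700)
  M <- matrix(rep(2 + sin(2 * pi * t / 120), each = 3), 3)
  tr <- synth_trajectory(M, t)
  tr$cells$epi_time[1] <- 590   # five maxima at 30, 150, 270, 390, 510
  expect_equal(oscillations_per_cell(tr, 1)$count, 5)
  expect_false(oscillations_per_cell(tr, 1)$censored)
  # never-epithelialized cell: counted to t_end (one more maximum at 630)
  r2 <- oscillations_per_cell(tr, 2)
  expect_true(r2$censored)
  expect_equal(r2$count, 6)
  # non-oscillating cell
  M[3, ] <- 1
  tr3 <- synth_trajectory(M, t)
  expect_equal(oscillations_per_cell(tr3, 3)$count, 0)
})

test_that("beat_envelope finds the textbook beat and ignores pure tones", {
  t <- seq(0, 6000, by = 0.5)
  x <- synth_beat(t, 110, 130)
  be <- beat_envelope(x, t)
  expect_equal(be$beat_period, 1 / (1 / 110 - 1 / 130), tolerance = 0.05)
  pure <- beat_envelope(2 + cos(2 * pi * t / 120), t)
  expect_true(is.na(pure$beat_period))
  expect_lt(pure$modulation, 0.02)
})

test_that("phase_dispersion measures the spread of recent maxima", {
  t <- seq(0, 600)
  M <- rbind(2 + sin(2 * pi * t / 120),
             2 + sin(2 * pi * (t - 30) / 120))
  tr <- synth_trajectory(M, t)
  pd <- phase_dispersion(tr, time = 600, species = "hes7_pn", period = 120)
  expect_equal(pd$dispersion, 0.25, tolerance = 0.02)
  # identical cells -> 0
  M2 <- rbind(M[1, ], M[1, ])
  pd2 <- phase_dispersion(synth_trajectory(M2, t), time = 600,
                          species = "hes7_pn", period = 120)
  expect_equal(pd2$dispersion, 0)
})

test_that("analysis operations do not mutate their inputs", {
  tr <- wt_twocell()
  before <- tr$data
  invisible(detect_period(tr$data[1, , "hes7_pn"], tr$times))
  invisible(max_expression_time(tr, "hes7_pn"))
  expect_identical(tr$data, before)
})
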