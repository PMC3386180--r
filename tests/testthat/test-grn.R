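p0 <- default_params()

test_that("promoter_activity composes the per-gene Hill factors", {
  # Mesp2 with all four inputs at their thresholds: 0.5^4
  p <- set_params(p0, mesp2_K_nicd = 1, mesp2_K_tbx6 = 1, mesp2_K_fgf8 = 1,
                  mesp2_K_ripply2 = 1)
  a <- promoter_activity("mesp2", c(nicd_n = 1, tbx6_p = 1, fgf_avg = 1,
                                    ripply2_pn = 1), p)
  expect_equal(a, 0.5^4)
  # an overwhelming repressor shuts the promoter
  a2 <- promoter_activity("mesp2", c(nicd_n = 1e6, tbx6_p = 1e6, fgf_avg = 0,
                                     ripply2_pn = 1e9), p)
  expect_lt(a2, 1e-6)
  # no transcription without the NICD activator
  expect_equal(promoter_activity("hes7", c(nicd_n = 0, hes7_pn = 0), p0), 0)
  expect_error(promoter_activity("nosuchgene", c(x = 1), p0), "unknown gene")
  expect_error(promoter_activity("hes7", c(nicd_n = 1), p0), "hes7_pn")
  expect_error(promoter_activity("hes7", c(nicd_n = -1, hes7_pn = 0), p0))
})

test_that("nicd_nuclear_decay_rate interpolates between base and max", {
  expect_equal(nicd_nuclear_decay_rate(1e12, p0), p0$nicd_g_base,
               tolerance = 1e-6)
  expect_equal(nicd_nuclear_decay_rate(0, p0), p0$nicd_g_max)
  expect_equal(nicd_nuclear_decay_rate(p0$nicd_K_wnt, p0),
               (p0$nicd_g_base + p0$nicd_g_max) / 2)
  expect_error(nicd_nuclear_decay_rate(-1, p0))
})

test_that("lfng_modulation implements the three coupling modes", {
  expect_equal(lfng_modulation(c(0, 5, 1e6), set_params(p0, lfng_mode = "off")),
               rep(1, 3))
  pa <- set_params(p0, lfng_mode = "activating", lfng_eps = 0.07)
  expect_equal(lfng_modulation(0, pa), 0.07)  # residual unmodified reaction
  pin <- set_params(p0, lfng_K_mod = 3)
  expect_equal(lfng_modulation(3, pin), 0.5)
  pbad <- p0; pbad$lfng_eps <- -1; pbad$lfng_mode <- "activating"
  expect_error(lfng_modulation(1, pbad), "lfng_eps")
})

test_that("dn_reaction returns the shared reaction flux", {
  p <- set_params(p0, k_dn = 1, lfng_mode = "off")
  cell <- c(notch1_pm = 2, lfng_pc = 0)
  r <- dn_reaction(cell, neighbor_dll1_mem = 3, p)
  expect_equal(r$nicd_production, 6)     # k_dn * N_mem * D_mem = 1*2*3
  expect_equal(r$notch_mem_loss, 6)
  expect_equal(r$dll1_mem_loss_per_donor, 6)
  r0 <- dn_reaction(cell, 0, p)
  expect_equal(r0$nicd_production, 0)
})

test_that("the D/N conservation ledger is exact for every evaluation", {
  set.seed(42)
  for (rep in 1:5) {
    tissue <- new_tissue(2, 2, sample(2:5, 1), gz_depth = 2)
    nc <- nrow(tissue$state)
    tissue$state[] <- matrix(runif(nc * 38, 0, 5), nc)
    topo <- neighbor_topology(tissue)
    dS <- psm_rhs(tissue$state, p0, topo$A, in_growth_zone(tissue))
    flux <- attr(dS, "dn_flux")
    loss <- attr(dS, "dn_donor_loss")
    # tissue-summed NICD gain = NOTCH1 membrane loss = DLL1 membrane loss
    expect_equal(sum(flux), sum(loss), tolerance = 1e-12)
    expect_gte(min(flux), 0)
  }
})

test_that("compiled RHS agrees with the R reference on random states", {
  set.seed(7)
  tissue <- new_tissue(2, 2, 5, gz_depth = 3)
  n <- nrow(tissue$state)
  for (mode in c("wnt_nicd", "fgf_hes7_protein", "fgf_hes7_mrna")) {
    p <- p0
    p$gradient_coupling <- mode
    p$hes7_d_pn_max <- 0.05
    tissue$state[] <- matrix(runif(n * 38, 0, 8), n)
    topo <- neighbor_topology(tissue)
    gz <- in_growth_zone(tissue)
    ref <- psm_rhs(tissue$state, p, topo$A, gz)
    cpp <- psmclock:::.rhs_eval(tissue$state, p, topo$idx, topo$ptr, gz,
                                FALSE, 0, 0, 0)$deriv
    expect_equal(unname(cpp), unname(as.matrix(ref)), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("cell_rhs handles boundary cases", {
  z <- setNames(rep(0, 38), psm_species())
  d <- cell_rhs(z, in_growth_zone = FALSE)
  expect_equal(unname(d), rep(0, 38))  # every production term has a zero factor
  # growth-zone Wnt3a mRNA steady state
  z2 <- z; z2["wnt3a_m"] <- p0$wnt3a_k_tr / p0$wnt3a_d_m
  d2 <- cell_rhs(z2, in_growth_zone = TRUE)
  expect_equal(unname(d2["wnt3a_m"]), 0, tolerance = 1e-12)
  expect_error(cell_rhs(z - 1), ">= 0")
})

test_that("Hes7 subsystem matches a finer-step independent integration", {
  # isolated Hes7 transport chain with frozen NICD input, integrated by a
  # hand-rolled RK4 at dt and dt/10
  p <- p0
  act <- 0.8
  f <- function(y) {
    prom <- act / (1 + (y[4] / p$hes7_K_self)^p$hes7_h_self)
    c(p$hes7_k_tr * prom - (p$hes7_r_m + p$hes7_d_mn) * y[1],
      p$hes7_r_m * y[1] - p$hes7_d_mc * y[2],
      p$hes7_k_tl * y[2] - (p$hes7_r_in + p$hes7_d_pc) * y[3] +
        p$hes7_r_out * y[4],
      p$hes7_r_in * y[3] - p$hes7_r_out * y[4] -
        p$hes7_v_sat * y[4] / (p$hes7_k_sat + y[4]))
  }
  y0 <- c(0.1, 0.5, 0.5, 0.5)
  a <- oracle_rk4(f, y0, 240, 0.025)
  b <- oracle_rk4(f, y0, 240, 0.0025)
  expect_equal(a, b, tolerance = 1e-6)
})

test_that("negative feedback is necessary for oscillation", {
  # with self-repression forced to the constant 1 and constant NICD input
  # the Hes7 chain is linear-with-saturation and converges to one fixed
  # point from different starts
  p <- p0
  # activation low enough that the nuclear influx stays below the
  # saturated-decay capacity (otherwise nuclear protein grows without bound)
  act <- 0.2
  f <- function(y) {
    c(p$hes7_k_tr * act - (p$hes7_r_m + p$hes7_d_mn) * y[1],
      p$hes7_r_m * y[1] - p$hes7_d_mc * y[2],
      p$hes7_k_tl * y[2] - (p$hes7_r_in + p$hes7_d_pc) * y[3] +
        p$hes7_r_out * y[4],
      p$hes7_r_in * y[3] - p$hes7_r_out * y[4] -
        p$hes7_v_sat * y[4] / (p$hes7_k_sat + y[4]))
  }
  a <- oracle_rk4(f, c(0, 0, 0, 0), 4000, 0.05)
  b <- oracle_rk4(f, c(5, 5, 5, 5), 4000, 0.05)
  expect_equal(a, b, tolerance = 1e-6)
  # and the end state is stationary
  expect_equal(f(a), rep(0, 4), tolerance = 1e-4)
})
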