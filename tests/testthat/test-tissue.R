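p0 <- default_params()

test_that("grow_step inserts one daughter per column and keeps geometry", {
  t1 <- new_tissue(1, 1, 5, gz_depth = 5)
  t1$state[, "hes7_pn"] <- 1:5
  t2 <- grow_step(t1, rng_layers = 3L)
  expect_equal(t2$n_layers, 6L)
  # anterior cells unchanged, daughter is an exact copy of the mother
  expect_equal(unname(t2$state[t2$layer == 1, "hes7_pn"]), 1)
  expect_equal(unname(t2$state[t2$layer == 2, "hes7_pn"]), 2)
  d <- which(t2$id == 6)           # the daughter
  m <- which(t2$id == t2$mother[d])
  expect_equal(t2$state[d, ], t2$state[m, ])
  expect_equal(t2$layer[d], 3L)    # daughter at the mother's location
  expect_equal(t2$layer[m], 4L)    # mother pushed posteriorly
})

test_that("lattice stays rectangular and growth zone tracks the posterior", {
  set.seed(11)
  t <- new_tissue(2, 3, 4, gz_depth = 4)
  for (i in 1:100) {
    t <- grow_step(t)
    counts <- table(t$layer)
    expect_true(all(counts == 6))           # every layer full
    expect_equal(length(counts), t$n_layers)
    gz <- in_growth_zone(t)
    expect_setequal(unique(t$layer[gz]), (t$n_layers - 3):t$n_layers)
  }
  # ids unique, lineage resolvable
  expect_identical(anyDuplicated(t$id), 0L)
})

test_that("halving the division interval doubles the final length", {
  p <- p0
  tr1 <- integrate_tissue(initialize_tissue(p, 1, 1, 5, 5), p,
           sim_config(t_end = 250, seed = 1, division_interval = 24))
  tr2 <- integrate_tissue(initialize_tissue(p, 1, 1, 5, 5), p,
           sim_config(t_end = 250, seed = 1, division_interval = 12))
  g1 <- tr1$tissue$n_layers - 5
  g2 <- tr2$tissue$n_layers - 5
  expect_equal(g2, 2 * g1)
})

test_that("neighbor_average is the mean over face neighbours", {
  t <- new_tissue(2, 2, 3, gz_depth = 3)
  # corner cell (layer 1, row 1, col 1) has 3 neighbours
  i <- which(t$layer == 1 & t$row == 1 & t$col == 1)
  nb <- c(which(t$layer == 2 & t$row == 1 & t$col == 1),
          which(t$layer == 1 & t$row == 2 & t$col == 1),
          which(t$layer == 1 & t$row == 1 & t$col == 2))
  t$state[nb, "dll1_pm"] <- c(1, 2, 3)
  expect_equal(neighbor_average(t, i, "dll1_pm"), 2)
  # uniform field averages to itself
  t$state[, "wnt3a_p"] <- 7
  expect_equal(neighbor_average(t, i, "wnt3a_p"), 7)
  # interior cell of a 3x3x3 lattice with one hot face neighbour
  t3 <- new_tissue(3, 3, 3, gz_depth = 3)
  mid <- which(t3$layer == 2 & t3$row == 2 & t3$col == 2)
  up <- which(t3$layer == 3 & t3$row == 2 & t3$col == 2)
  t3$state[up, "dll1_pm"] <- 6
  expect_equal(neighbor_average(t3, mid, "dll1_pm"), 1)
})

test_that("epithelialization flags are thresholded at >= and irreversible", {
  t <- new_tissue(1, 1, 3, gz_depth = 3)
  t$state[, "epha4_pc"] <- c(0.5, p0$epha4_threshold, 5)
  t <- apply_epithelialization(t, p0)
  expect_equal(!is.na(t$epi_time), c(FALSE, TRUE, TRUE))
  # flags never unset even if EPHA4 falls again
  t$state[, "epha4_pc"] <- 0
  t$time <- 10
  t <- apply_epithelialization(t, p0)
  expect_equal(!is.na(t$epi_time), c(FALSE, TRUE, TRUE))
})

test_that("tissue snapshots export all 38 variables", {
  t <- new_tissue(2, 2, 3, gz_depth = 2)
  df <- as.data.frame(t)
  expect_equal(nrow(df), 12)
  expect_true(all(psm_species() %in% names(df)))
  expect_true(all(c("layer", "in_growth_zone", "epithelialized") %in% names(df)))
})
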