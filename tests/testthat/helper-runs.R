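# Shared, lazily computed simulation fixtures. Heavy tissue runs are
# computed once per session and reused across test files.

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.run_cache[[key]])) .run_cache[[key]] <- force(expr)
  .run_cache[[key]]
}

# default wild-type tissue run (12 simulated hours, 4 x 4 cross-section)
wt_run <- function() cached("wt720", {
  p <- default_params()
  integrate_tissue(initialize_tissue(p), p, sim_config(t_end = 720, seed = 1))
})

# wild-type two-cell run on the limit cycle (20 simulated hours)
wt_twocell <- function() cached("tc1200", {
  run_twocell(default_params(), t_end = 1200)
})

# small 2 x 2 cross-section run used by the scaling tests
small_run <- function(params, t_end, division_interval = 24, seed = 1) {
  key <- paste0("small|", t_end, "|", division_interval, "|", seed, "|",
                psmclock:::params_key(params))
  cached(key, integrate_tissue(
    initialize_tissue(params, n_rows = 2, n_cols = 2), params,
    sim_config(t_end = t_end, seed = seed,
               division_interval = division_interval)))
}

# hand-rolled RK4 for small oracle systems, independent of the package
# integrator
oracle_rk4 <- function(f, y0, t_end, dt) {
  n <- ceiling(t_end / dt)
  y <- y0
  for (i in seq_len(n)) {
    k1 <- f(y); k2 <- f(y + dt / 2 * k1)
    k3 <- f(y + dt / 2 * k2); k4 <- f(y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  y
}
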