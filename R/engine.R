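#' Simulation configuration
#'
#' @param t_end simulated time (min).
#' @param dt RK4 step (min); default 0.025, the largest step at which
#'   the shipped default runs show zero negativity-clamp events (also
#'   validated by the dt/2 refinement test).
#' @param record_every recording interval (min); must be a multiple of
#'   \code{dt} and divide \code{division_interval}.
#' @param record_species state columns to record (default: a standard set
#'   covering the clock, the wave and the boundary module).
#' @param seed integer seed for all randomness (division sites, phase
#'   offsets).
#' @param division_interval minutes between growth rounds (one layer per
#'   round; default 24 min, i.e. ~5 layers per 120-min clock cycle, the
#'   elongation velocity at which a growth-zone-born cell experiences ~5
#'   clock oscillations before epithelialization); \code{NULL} disables
#'   growth.
#' @param schedule optional data.frame of timed parameter changes with
#'   columns \code{time}, \code{name}, \code{value}, \code{op}
#'   (\code{"set"} or \code{"mul"}); applied when the clock reaches
#'   \code{time}.
#' @return object of class \code{psm_config}.
#' @export
sim_config <- function(t_end, dt = 0.025, record_every = 1,
                       record_species = default_record_species(),
                       seed = 1L, division_interval = 24,
                       schedule = NULL) {
  stopifnot(dt > 0, t_end > 0, record_every >= dt)
  if (abs(record_every / dt - round(record_every / dt)) > 1e-9) {
    stop("record_every must be an integer multiple of dt")
  }
  if (!is.null(division_interval)) {
    if (abs(division_interval / dt - round(division_interval / dt)) > 1e-9) {
      stop("division_interval must be an integer multiple of dt")
    }
    if (abs(division_interval / record_every -
            round(division_interval / record_every)) > 1e-9) {
      stop("division_interval must be an integer multiple of record_every")
    }
  }
  bad <- setdiff(record_species, psm_species())
  if (length(bad)) stop("unknown record species: ", paste(bad, collapse = ", "))
  structure(list(t_end = t_end, dt = dt, record_every = record_every,
                 record_species = record_species, seed = as.integer(seed),
                 division_interval = division_interval,
                 schedule = schedule),
            class = "psm_config")
}

#' @rdname sim_config
#' @export
default_record_species <- function() {
  c("hes7_pn", "hes7_mc", "hes1_mc", "hes1_pn", "lfng_mc", "dll1_mc", "dll1_pm",
    "nicd_n", "mesp2_mc", "mesp2_pc", "ripply2_pc", "epha4_pc",
    "tbx6_p", "notch1_m", "wnt3a_p", "fgf8_p")
}

# ---- limit-cycle cache -----------------------------------------------------

.psm_cache <- new.env(parent = emptyenv())

params_key <- function(p) {
  paste(vapply(p, function(v) paste(format(v, digits = 17), collapse = ","),
               character(1)), collapse = "|")
}

#' Reference limit-cycle state of the two-cell core oscillator
#'
#' Runs the reduced two-cell system in the growth-zone environment for
#' \code{t_pre} minutes from a standard kick and returns the final
#' 38-variable state (a reference point on the limit cycle) together with
#' a one-period table of the cycle sampled at 1-min resolution. Results
#' are cached per parameter set.
#'
#' @param params a \code{psm_params}.
#' @param t_pre pre-run length (min).
#' @return list with \code{state} (named 38-vector), \code{cycle}
#'   (matrix time x 38), \code{period} (min).
#' @export
limit_cycle_state <- function(params, t_pre = 3600) {
  key <- paste0("lc|", t_pre, "|", params_key(params))
  if (!is.null(.psm_cache[[key]])) return(.psm_cache[[key]])
  env <- growth_zone_env(params)
  S0 <- new_state_matrix(2)
  S0[, "nicd_n"] <- 0.5; S0[, "notch1_pm"] <- 1
  S0[, "dll1_pm"] <- 1;  S0[, "tbx6_p"] <- 2
  out <- rk4_twocell(S0, params, env, t_end = t_pre, dt = 0.025,
                     record_every = 1, rec = "hes7_pn")
  x <- out$X[1, , 1]
  pk <- local_maxima(x)
  if (length(pk) < 3) {
    stop("initialization pre-run failed to oscillate for this parameter set")
  }
  period <- mean(diff(out$times[pk]))
  # sample one period of the cycle from the final state
  cyc <- rk4_twocell(out$S_end, params, env, t_end = ceiling(period) + 1,
                     dt = 0.025, record_every = 1, rec = psm_species())
  res <- list(state = out$S_end[1, ], cycle = cyc$X[1, , ], period = period)
  dimnames(res$cycle) <- list(NULL, psm_species())
  .psm_cache[[key]] <- res
  res
}

# low-level two-cell segment (both cells in the growth zone, fixed env)
rk4_twocell <- function(S0, params, env, t_end, dt, record_every, rec) {
  sp <- psm_species()
  stride <- as.integer(round(record_every / dt))
  nst <- as.integer(round(t_end / dt))
  out <- .rk4_segment(S0, params, c(1L, 0L), c(0L, 1L, 2L), c(TRUE, TRUE),
                      dt, nst, 0, stride, match(rec, sp) - 1L,
                      TRUE, env$wnt, env$fgf,
                      if (is.null(env$wnt_decay)) env$wnt else env$wnt_decay,
                      params$epha4_threshold)
  nt <- length(out$rec_times)
  X <- array(out$recorded, dim = c(2, nt, length(rec)),
             dimnames = list(NULL, NULL, rec))
  list(times = out$rec_times, X = X, S_end = out$state, clamps = out$clamp_events)
}

local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

#' Initialize a tissue at t = 0
#'
#' All cells start synchronously: gradient species at their growth-zone
#' steady states and every cell placed at the same reference point of the
#' two-cell limit cycle (obtained by a cached pre-run). The default
#' geometry is the growth zone alone (15 layers of a 4 x 4 cross-section).
#'
#' @param params a \code{psm_params}.
#' @param n_rows,n_cols,n_layers,gz_depth geometry (see
#'   \code{\link{new_tissue}}).
#' @return a synchronous \code{psm_tissue}.
#' @export
initialize_tissue <- function(params, n_rows = 4, n_cols = 4,
                              n_layers = 15, gz_depth = 15) {
  lc <- limit_cycle_state(params)
  n <- n_rows * n_cols * n_layers
  S <- matrix(rep(lc$state, each = n), nrow = n,
              dimnames = list(NULL, psm_species()))
  new_tissue(n_rows, n_cols, n_layers, gz_depth, state = S)
}

# ---- integration -----------------------------------------------------------

#' Integrate the coupled tissue system
#'
#' Classic fixed-step RK4 over the full coupled system. Growth events are
#' applied strictly between steps at multiples of the division interval;
#' timed parameter changes from the config schedule likewise.
#' Epithelialization is checked after every step; negative excursions are
#' clamped to zero and counted. Deterministic given (tissue, params,
#' config).
#'
#' @param tissue a \code{psm_tissue} (see \code{\link{initialize_tissue}}).
#' @param params a \code{psm_params}.
#' @param config a \code{psm_config}.
#' @param sync optional synchronization-experiment settings (see
#'   \code{\link{sync_experiment}}); newborn cells get a random phase
#'   offset instead of exact inheritance.
#' @return a \code{psm_trajectory}: recorded concentrations (cell x time x
#'   species), per-time AP positions, cell metadata, event log.
#' @export
integrate_tissue <- function(tissue, params, config, sync = NULL) {
  validate_params(params)
  set.seed(config$seed)
  dt <- config$dt
  rec_sp <- config$record_species
  sp <- psm_species()
  rec_idx <- match(rec_sp, sp) - 1L
  stride <- as.integer(round(config$record_every / dt))

  div <- config$division_interval
  breaks <- config$t_end
  if (!is.null(div)) breaks <- c(breaks, seq(div, config$t_end, by = div))
  if (!is.null(config$schedule)) breaks <- c(breaks, config$schedule$time)
  breaks <- sort(unique(breaks))
  breaks <- breaks[breaks > 0 & breaks <= config$t_end]
  if (any(abs(breaks / config$record_every -
              round(breaks / config$record_every)) > 1e-9)) {
    stop("event times must be multiples of record_every")
  }

  segs <- list()   # per-segment: ids, times, rec array, layers
  init <- list(ids = tissue$id, state = tissue$state[, rec_sp, drop = FALSE],
               layers = tissue$layer)
  events <- list()
  clamps <- 0
  worst_neg <- 0
  t0 <- 0
  p_now <- params
  for (t1 in breaks) {
    nst <- as.integer(round((t1 - t0) / dt))
    if (nst > 0) {
      topo <- neighbor_topology(tissue)
      gz <- in_growth_zone(tissue)
      out <- .rk4_segment(tissue$state, p_now, topo$idx, topo$ptr, gz,
                          dt, nst, t0, stride, rec_idx,
                          FALSE, 0, 0, 0, p_now$epha4_threshold)
      tissue$state <- out$state
      tissue$time <- t1
      n <- length(tissue$id)
      nt <- length(out$rec_times)
      segs[[length(segs) + 1]] <- list(
        ids = tissue$id, times = out$rec_times,
        rec = array(out$recorded, dim = c(n, nt, length(rec_sp))),
        layers = tissue$layer)
      # merge epithelialization times found inside the segment
      newly <- is.na(tissue$epi_time) & !is.na(out$epi_time)
      tissue$epi_time[newly] <- out$epi_time[newly]
      if (any(newly)) {
        events[[length(events) + 1]] <- data.frame(
          time = out$epi_time[newly], type = "epithelialization",
          id = tissue$id[newly])
      }
      clamps <- clamps + out$clamp_events
      worst_neg <- min(worst_neg, out$worst_neg)
    }
    # growth event
    if (!is.null(div) && abs(t1 / div - round(t1 / div)) < 1e-9 &&
        t1 < config$t_end) {
      n_before <- length(tissue$id)
      tissue <- grow_step(tissue)
      born <- (n_before + 1):length(tissue$id)
      if (!is.null(sync)) tissue <- sync_phase_shift(tissue, born, p_now, sync)
      events[[length(events) + 1]] <- data.frame(
        time = t1, type = "division", id = tissue$id[born])
    }
    # scheduled parameter changes
    if (!is.null(config$schedule)) {
      due <- config$schedule[abs(config$schedule$time - t1) < 1e-9, , drop = FALSE]
      for (k in seq_len(nrow(due))) {
        nm <- due$name[k]
        val <- if (identical(due$op[k], "mul")) p_now[[nm]] * due$value[k] else due$value[k]
        p_now <- set_params(p_now, structure(list(val), names = nm))
        events[[length(events) + 1]] <- data.frame(
          time = t1, type = paste0("param:", nm), id = NA_integer_)
      }
    }
    t0 <- t1
  }

  traj <- assemble_trajectory(tissue, segs, init, events, clamps, params, config)
  traj$worst_neg <- worst_neg
  traj
}

# phase-shift machinery: the oscillator variables of a cell are replaced
# by the limit-cycle state nearest its current one, advanced by a phase
# offset (fraction of the period)
#' Randomize oscillator phases across cells
#'
#' Replaces each cell's oscillator variables by the two-cell limit-cycle
#' state nearest its current one, advanced by a phase offset drawn
#' uniformly from \code{[0, max_offset]} of the period. Uses the current
#' RNG stream (set a seed for reproducibility).
#'
#' @param tissue a \code{psm_tissue}.
#' @param params a \code{psm_params} (for the cached limit cycle).
#' @param max_offset maximal offset as a fraction of the period.
#' @param cells indices to shift (default all).
#' @return tissue with shifted phases.
#' @export
randomize_phases <- function(tissue, params, max_offset, cells = NULL) {
  if (is.null(cells)) cells <- seq_len(nrow(tissue$state))
  lc <- limit_cycle_state(params)
  osc <- osc_species()
  cyc <- lc$cycle[, osc, drop = FALSE]
  scale <- pmax(apply(cyc, 2, max), 1e-12)
  cyc_n <- sweep(cyc, 2, scale, "/")
  nt <- nrow(cyc)
  for (i in cells) {
    off <- stats::runif(1, 0, max_offset)
    if (off == 0) next
    v <- tissue$state[i, osc] / scale
    d2 <- rowSums(sweep(cyc_n, 2, v, "-")^2)
    k0 <- which.min(d2)
    k1 <- 1L + ((k0 - 1L + as.integer(round(off * lc$period))) %% nt)
    tissue$state[i, osc] <- cyc[k1, ]
  }
  tissue
}

# newborn cells in the synchronization experiment start with a randomly
# shifted phase instead of exact inheritance
sync_phase_shift <- function(tissue, born, params, sync) {
  randomize_phases(tissue, params, sync$max_phase_offset, cells = born)
}

assemble_trajectory <- function(tissue, segs, init, events, clamps, params, config) {
  rec_sp <- config$record_species
  all_times <- c(0, unlist(lapply(segs, `[[`, "times")))
  ids <- tissue$id
  n <- length(ids)
  nt <- length(all_times)
  data <- array(NA_real_, dim = c(n, nt, length(rec_sp)),
                dimnames = list(NULL, NULL, rec_sp))
  layer <- matrix(NA_integer_, n, nt)
  pos0 <- match(init$ids, ids)
  data[pos0, 1, ] <- init$state
  layer[pos0, 1] <- init$layers
  ti <- 1L
  for (s in segs) {
    pos <- match(s$ids, ids)
    k <- length(s$times)
    data[pos, ti + seq_len(k), ] <- s$rec
    layer[pos, ti + seq_len(k)] <- s$layers
    ti <- ti + k
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(time = numeric(0), type = character(0), id = integer(0))
  structure(list(
    times = all_times, species = rec_sp, data = data, layer = layer,
    cells = data.frame(id = ids, row = tissue$row, col = tissue$col,
                       layer = tissue$layer,
                       birth_time = tissue$birth_time,
                       epi_time = tissue$epi_time,
                       mother = tissue$mother),
    events = ev, clamp_events = clamps,
    params = params, config = config, tissue = tissue
  ), class = "psm_trajectory")
}

#' @export
print.psm_trajectory <- function(x, ...) {
  cat("psm_trajectory:", nrow(x$cells), "cells x", length(x$times),
      "times x", length(x$species), "species | t in [0,",
      max(x$times), "] min |", x$clamp_events, "clamp events\n")
  invisible(x)
}

#' Extract a recorded time series
#'
#' @param traj a \code{psm_trajectory}.
#' @param species recorded species name.
#' @param cell cell id (default: first founder).
#' @return data.frame \code{time}, \code{value} (NA before the cell's
#'   birth).
#' @export
traj_series <- function(traj, species, cell = traj$cells$id[1]) {
  i <- match(cell, traj$cells$id)
  if (is.na(i)) stop("unknown cell id: ", cell)
  k <- match(species, traj$species)
  if (is.na(k)) stop("species not recorded: ", species)
  data.frame(time = traj$times, value = traj$data[i, , k])
}

#' Per-layer mean expression at a recorded time (AP profile)
#'
#' @param traj a \code{psm_trajectory}.
#' @param time recorded time (min).
#' @param species recorded species.
#' @return data.frame \code{layer}, \code{value} (mean over the cells of
#'   each AP layer alive at that time).
#' @export
ap_profile <- function(traj, time, species) {
  ti <- match_time(traj, time)
  k <- match(species, traj$species)
  if (is.na(k)) stop("species not recorded: ", species)
  lay <- traj$layer[, ti]
  val <- traj$data[, ti, k]
  ok <- !is.na(lay) & !is.na(val)
  agg <- tapply(val[ok], lay[ok], mean)
  data.frame(layer = as.integer(names(agg)), value = as.numeric(agg))
}

match_time <- function(traj, time) {
  ti <- which.min(abs(traj$times - time))
  if (abs(traj$times[ti] - time) > traj$config$record_every / 2 + 1e-9) {
    stop("time ", time, " not within the recorded range")
  }
  ti
}

#' Growth-zone steady-state environment of the two-cell system
#'
#' WNT3A and FGF8 protein levels a cell sees in the growth zone
#' (production/decay steady state of the gradient equations).
#'
#' @param params a \code{psm_params}.
#' @return list with \code{wnt}, \code{fgf}, \code{wnt_decay}.
#' @export
growth_zone_env <- function(params) {
  w <- params$wnt3a_k_tl * (params$wnt3a_k_tr / params$wnt3a_d_m) / params$wnt3a_d_p
  f <- params$fgf8_k_tl * (params$fgf8_k_tr / params$fgf8_d_m) / params$fgf8_d_p
  list(wnt = w, fgf = f, wnt_decay = w)
}

#' Mid-PSM environment for beat experiments
#'
#' Growth-zone promoter inputs with the NICD-decay coupling pinned at an
#' intermediate WNT3A level (default 1 a.u., nuclear NICD decay ~2.5/min):
#' NICD dips below the Hes1/Hes7 activation threshold each cycle, so a
#' detuned HES7 oscillator genuinely interferes with the Hes1 feedback
#' loop instead of either enslaving it (deep gating) or decoupling from it
#' (saturated activation). This is the gradient-free setting in which beat
#' envelopes are measured.
#'
#' @param params a \code{psm_params}.
#' @param wnt_decay WNT3A level seen by the decay coupling.
#' @return env list for \code{\link{run_twocell}}.
#' @export
beat_env <- function(params, wnt_decay = 1) {
  e <- growth_zone_env(params)
  e$wnt_decay <- wnt_decay
  e
}

#' Anterior-regime environment of the two-cell system
#'
#' Cells just anterior to the growth zone retain near-posterior promoter
#' inputs (long-lived Tbx6/Notch1 mRNAs, receding gradients) while the
#' inverted-Wnt coupling already drives nuclear NICD degradation at its
#' maximum; this environment fixes promoter inputs at growth-zone levels
#' and the decay-channel WNT3A at zero.
#'
#' @param params a \code{psm_params}.
#' @return list with \code{wnt}, \code{fgf}, \code{wnt_decay = 0}.
#' @export
anterior_env <- function(params) {
  e <- growth_zone_env(params)
  e$wnt_decay <- 0
  e
}
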