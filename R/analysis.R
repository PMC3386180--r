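# Quantitative extraction from trajectories: period/amplitude/damping,
# somite lengths, stripe counts, wave detection, beat envelopes, phase
# dispersion. All operations are pure (no mutation of their inputs).

#' Oscillation summary of a time series
#'
#' Discards the initial transient, finds local maxima by three-point
#' comparison (plateaus tie-break to the first index) and summarises the
#' oscillation: period = mean spacing of successive maxima, amplitudes =
#' cycle-mean maxima/minima, and a damping class: \code{"sustained"} if
#' successive maxima decline by less than 1\% per cycle,
#' \code{"stationary"} if the series range is below 1e-6 of its maximum,
#' otherwise \code{"damped"}. Fewer than 3 maxima yield a non-oscillatory
#' result (period NA, class from the range), not an error.
#'
#' @param series numeric vector.
#' @param times matching time vector (min).
#' @param transient_fraction initial fraction of the time span discarded
#'   (default 0.2).
#' @return list of class \code{osc_summary}: \code{period},
#'   \code{amp_max}, \code{amp_min}, \code{n_cycles}, \code{damping},
#'   \code{peak_times}, \code{peak_values}.
#' @export
detect_period <- function(series, times, transient_fraction = 0.2) {
  stopifnot(length(series) == length(times))
  keep <- times >= transient_fraction * max(times)
  x <- series[keep]; t <- times[keep]
  rng <- max(x) - min(x)
  non_osc <- function(damping) {
    structure(list(period = NA_real_, amp_max = max(x), amp_min = min(x),
                   n_cycles = 0L, damping = damping,
                   peak_times = numeric(0), peak_values = numeric(0)),
              class = "osc_summary")
  }
  if (rng < 1e-6 * max(abs(x), 1e-300)) return(non_osc("stationary"))
  pk <- local_maxima(x)
  # plateau tie-break: drop maxima whose predecessor point is equal (the
  # 3-point rule with >= on the right already keeps the first index)
  if (length(pk) < 3) return(non_osc("damped"))
  tr <- local_minima(x)
  decline <- diff(x[pk]) / x[pk][-length(pk)]
  damping <- if (mean(decline) > -0.01) "sustained" else "damped"
  structure(list(
    period = mean(diff(t[pk])),
    amp_max = mean(x[pk]),
    amp_min = if (length(tr)) mean(x[tr]) else min(x),
    n_cycles = length(pk) - 1L,
    damping = damping,
    peak_times = t[pk], peak_values = x[pk]
  ), class = "osc_summary")
}

local_minima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] < x[1:(n - 2)] & x[2:(n - 1)] <= x[3:n]) + 1L
}

#' @export
print.osc_summary <- function(x, ...) {
  cat("oscillation:", x$damping,
      if (!is.na(x$period)) sprintf("| period %.2f min | amp [%.3g, %.3g] | %d cycles",
                                    x$period, x$amp_min, x$amp_max, x$n_cycles),
      "\n")
  invisible(x)
}

#' Somite lengths from the epithelialization pattern
#'
#' Stripes are maximal runs of consecutive AP layers whose fraction of
#' epithelialized cells is at least 0.5; somite length is measured from
#' stripe midpoint to stripe midpoint (even-width stripes use the mean of
#' the two central layers), in cell-layer units.
#'
#' @param tissue a \code{psm_tissue} (or the \code{tissue} element of a
#'   trajectory).
#' @return numeric vector of midpoint-to-midpoint distances; empty if
#'   fewer than 2 stripes.
#' @export
somite_lengths <- function(tissue) {
  lay <- tissue$layer
  epi <- !is.na(tissue$epi_time)
  frac <- tapply(epi, lay, mean)
  layers <- as.integer(names(frac))
  full <- rep(FALSE, max(layers))
  full[layers] <- frac >= 0.5
  mids <- stripe_midpoints(full)
  if (length(mids) < 2) return(numeric(0))
  diff(mids)
}

stripe_midpoints <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  on <- which(r$values)
  vapply(on, function(k) (starts[k] + ends[k]) / 2, numeric(1))
}

#' Count expression stripes along the AP axis
#'
#' Counts maximal contiguous runs of AP layers whose layer-mean expression
#' is at least \code{level} times the snapshot maximum. Snapshots are
#' usually taken at the phase of maximal total expression within a cycle
#' (see \code{\link{max_expression_time}}).
#'
#' @param traj a \code{psm_trajectory}.
#' @param time recorded time of the snapshot.
#' @param species recorded species (default cytoplasmic Mesp2 mRNA).
#' @param level threshold as a fraction of the snapshot maximum (default
#'   0.5, half-max).
#' @return integer stripe count (0 for an all-zero field).
#' @export
stripe_count <- function(traj, time, species = "mesp2_mc", level = 0.5) {
  pr <- ap_profile(traj, time, species)
  m <- max(pr$value)
  if (m <= 0) return(0L)
  full <- rep(FALSE, max(pr$layer))
  full[pr$layer] <- pr$value >= level * m
  r <- rle(full)
  sum(r$values)
}

#' Time of maximal summed expression within a late window
#'
#' Finds the recorded time (within the last \code{window} minutes, default
#' one clock period) at which the tissue-summed expression of a species is
#' maximal -- the snapshot phase used for stripe counting.
#'
#' @param traj a \code{psm_trajectory}.
#' @param species recorded species.
#' @param window minutes from the end of the run to search (default 120).
#' @return recorded time (min).
#' @export
max_expression_time <- function(traj, species = "mesp2_mc", window = 120) {
  k <- match(species, traj$species)
  if (is.na(k)) stop("species not recorded: ", species)
  tot <- apply(traj$data[, , k, drop = FALSE], 2, sum, na.rm = TRUE)
  sel <- traj$times >= max(traj$times) - window
  traj$times[sel][which.max(tot[sel])]
}

#' Classify a species' spatiotemporal pattern as wave, static or none
#'
#' Computes, for each AP layer, the phase (time of peak layer-mean
#' expression) within the last recorded clock cycle. The pattern is a
#' \code{"wave"} when the peak time decreases monotonically towards the
#' anterior over at least \code{min_layers} consecutive layers with a
#' total span of at least 25\% of the period (posterior-to-anterior
#' propagation), \code{"static"} when the total span is below 5\% of the
#' period, and \code{"none"} otherwise (including non-oscillatory fields).
#'
#' @param traj a \code{psm_trajectory}.
#' @param species recorded species.
#' @param period clock period (min; default 120).
#' @param min_layers minimum run length for a wave (default 5).
#' @param layers optional subset of AP layers to analyse (default: layers
#'   alive through the final cycle).
#' @return \code{"wave"}, \code{"static"} or \code{"none"}.
#' @export
wave_detect <- function(traj, species, period = 120, min_layers = 5,
                        layers = NULL) {
  k <- match(species, traj$species)
  if (is.na(k)) stop("species not recorded: ", species)
  t1 <- max(traj$times)
  sel <- traj$times > t1 - 2 * period & traj$times <= t1
  tt <- traj$times[sel]
  lay_final <- traj$layer[, ncol(traj$layer)]
  if (is.null(layers)) {
    layers <- sort(unique(lay_final[!is.na(lay_final)]))
  }
  # per layer: linearly detrend the layer-mean series (the receding
  # gradients impose large secular trends), then take the Fourier phase at
  # the clock frequency; the phase is reported as an equivalent peak time
  # in cycle units
  w <- 2 * pi / period
  phase <- rep(NA_real_, length(layers))
  amp <- rep(NA_real_, length(layers))
  for (li in seq_along(layers)) {
    l <- layers[li]
    rows <- which(lay_final == l)
    if (!length(rows)) next
    series <- colMeans(traj$data[rows, sel, k, drop = FALSE], na.rm = TRUE)
    if (any(!is.finite(series))) next
    res <- stats::lm.fit(cbind(1, tt), series)$residuals
    z <- sum(res * exp(-1i * w * tt))
    phase[li] <- -Arg(z) / (2 * pi)  # peak-time equivalent, cycle units
    # modulation depth relative to the layer's own mean level, so weakly
    # expressing anterior layers are judged on their own scale
    amp[li] <- Mod(z) / length(tt) * 2 / max(mean(abs(series)), 1e-12)
  }
  ok <- is.finite(phase) & is.finite(amp)
  ok <- ok & amp > 0.1
  if (sum(ok) < min_layers) return("none")
  ph <- phase[ok]
  # unwrap along the AP axis (nearest-branch continuation)
  u <- ph
  for (i in seq_along(u)[-1]) u[i] <- ph[i] + round(u[i - 1] - ph[i])
  span <- max(u) - min(u)
  if (span < 0.05) return("static")
  # posterior (high layer index) leads: peak time decreases towards the
  # posterior, so a posterior-to-anterior wave shows a monotone decrease of
  # the unwrapped peak time along ascending layer index
  best <- longest_sign_run(diff(u), -1)
  if (best + 1 >= min_layers && span >= 0.25) return("wave")
  if (span < 0.05) return("static")
  "none"
}

longest_sign_run <- function(d, sgn) {
  good <- sign(d) == sgn
  if (!any(good)) return(0L)
  r <- rle(good)
  max(r$lengths[r$values])
}

#' Count HES7 oscillations a cell experiences
#'
#' Number of nuclear-HES7 maxima between a cell's birth and its
#' epithelialization (or the end of the run for never-epithelialized
#' cells, flagged in the result).
#'
#' @param traj a \code{psm_trajectory} recording \code{"hes7_pn"}.
#' @param cell cell id.
#' @return list with \code{count}, \code{censored} (TRUE if the cell never
#'   epithelialized), \code{birth_time}, \code{end_time}.
#' @export
oscillations_per_cell <- function(traj, cell) {
  i <- match(cell, traj$cells$id)
  if (is.na(i)) stop("unknown cell id: ", cell)
  k <- match("hes7_pn", traj$species)
  if (is.na(k)) stop("trajectory must record hes7_pn")
  birth <- traj$cells$birth_time[i]
  epi <- traj$cells$epi_time[i]
  censored <- is.na(epi)
  end <- if (censored) max(traj$times) else epi
  sel <- traj$times >= birth & traj$times <= end
  x <- traj$data[i, sel, k]
  x <- x[!is.na(x)]
  list(count = length(local_maxima(x)), censored = censored,
       birth_time = birth, end_time = end)
}

#' Beat envelope of an oscillatory series
#'
#' Interpolates through the carrier maxima to form the amplitude envelope
#' and measures its period with \code{\link{detect_period}}. A flat
#' envelope (peak-to-peak modulation below 2\% of its mean) yields no beat.
#'
#' @param series numeric vector (at least ~10 carrier cycles).
#' @param times time vector (min).
#' @param transient_fraction discarded initial fraction.
#' @return list with \code{envelope} (data.frame time/value at carrier
#'   maxima), \code{beat_period} (min or NA), \code{modulation}.
#' @export
beat_envelope <- function(series, times, transient_fraction = 0.2) {
  keep <- times >= transient_fraction * max(times)
  x <- series[keep]; t <- times[keep]
  pk <- local_maxima(x)
  if (length(pk) < 4) {
    return(list(envelope = data.frame(time = numeric(0), value = numeric(0)),
                beat_period = NA_real_, modulation = 0))
  }
  env <- data.frame(time = t[pk], value = x[pk])
  modulation <- (max(env$value) - min(env$value)) / mean(env$value)
  if (modulation < 0.02) {
    return(list(envelope = env, beat_period = NA_real_,
                modulation = modulation))
  }
  s <- detect_period(env$value, env$time, transient_fraction = 0)
  list(envelope = env, beat_period = s$period, modulation = modulation)
}

#' Phase dispersion across cells
#'
#' Spread of the most recent nuclear-HES oscillation maxima across the
#' given cells at a reference time, as a fraction of the clock period:
#' (latest - earliest most-recent-maximum time) / period. Identical,
#' synchronous cells give 0; two cells offset by a quarter period give
#' 0.25.
#'
#' @param traj a \code{psm_trajectory}.
#' @param cells cell ids (default: all alive at \code{time}).
#' @param time reference time (default: end of run).
#' @param species oscillator readout (default \code{"hes7_pn"}).
#' @param period clock period (min).
#' @return list with \code{dispersion} (fraction of period; NA if any cell
#'   is non-oscillatory, flagged via \code{n_valid}) and the per-cell last
#'   maximum times.
#' @export
phase_dispersion <- function(traj, cells = NULL, time = max(traj$times),
                             species = "hes7_pn", period = 120) {
  k <- match(species, traj$species)
  if (is.na(k)) stop("species not recorded: ", species)
  ti <- traj$times <= time
  if (is.null(cells)) {
    alive <- !is.na(traj$layer[, match_time(traj, time)])
    cells <- traj$cells$id[alive]
  }
  last_max <- vapply(cells, function(id) {
    i <- match(id, traj$cells$id)
    x <- traj$data[i, ti, k]
    tt <- traj$times[ti]
    ok <- !is.na(x)
    pk <- local_maxima(x[ok])
    if (!length(pk)) return(NA_real_)
    max(tt[ok][pk])
  }, numeric(1))
  # cells whose most recent maximum is older than ~1.5 periods (or absent)
  # have not completed a cycle yet (newborns) or stopped oscillating; they
  # are excluded from the spread and flagged through n_valid
  valid <- is.finite(last_max) & (time - last_max) <= 1.5 * period
  disp <- if (sum(valid) >= 2) {
    (max(last_max[valid]) - min(last_max[valid])) / period
  } else NA_real_
  list(dispersion = disp, last_max_times = last_max, n_valid = sum(valid))
}
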