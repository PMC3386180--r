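# Synthetic oscillatory fixtures for testing the analysis module. These
# are first-class generators: deterministic given their arguments, with
# closed-form ground truth.

#' Synthetic oscillatory time series
#'
#' \code{baseline + amplitude * exp(-t/damping_tau) * sin(2*pi*(t/period) +
#' phase)}, the canonical fixture with known period, amplitude and damping.
#'
#' @param times time vector (min).
#' @param period oscillation period (min).
#' @param amplitude amplitude (a.u.).
#' @param phase phase offset (radians).
#' @param damping_tau exponential damping time (min; Inf = sustained).
#' @param baseline additive offset.
#' @return numeric vector.
#' @export
synth_oscillation <- function(times, period = 120, amplitude = 1, phase = 0,
                              damping_tau = Inf, baseline = 2) {
  baseline + amplitude * exp(-times / damping_tau) *
    sin(2 * pi * times / period + phase)
}

#' Two-tone beat fixture
#'
#' \code{cos(2*pi*t/T1) + cos(2*pi*t/T2)} plus a baseline; the textbook
#' beat with envelope period \code{1/|1/T1 - 1/T2|} (one amplitude
#' maximum per envelope cycle).
#'
#' @param times time vector (min).
#' @param period1,period2 the two carrier periods (min).
#' @return numeric vector.
#' @export
synth_beat <- function(times, period1 = 110, period2 = 130) {
  2 + cos(2 * pi * times / period1) + cos(2 * pi * times / period2)
}

#' Wrap per-layer series into a minimal trajectory
#'
#' Builds a \code{psm_trajectory} with one cell per AP layer from a
#' layers x times matrix, so the spatial analysis operations
#' (\code{\link{wave_detect}}, \code{\link{stripe_count}},
#' \code{\link{ap_profile}}) can be tested on constructed fields.
#'
#' @param M numeric matrix, AP layers x time points.
#' @param times time vector matching \code{ncol(M)}.
#' @param species species label for the single channel.
#' @return a \code{psm_trajectory}.
#' @export
synth_trajectory <- function(M, times, species = "hes7_pn") {
  n <- nrow(M)
  data <- array(M, dim = c(n, length(times), 1),
                dimnames = list(NULL, NULL, species))
  cfg <- sim_config(t_end = max(times),
                    dt = min(diff(times)),
                    record_every = min(diff(times)),
                    record_species = species,
                    division_interval = NULL)
  structure(list(
    times = times, species = species, data = data,
    layer = matrix(rep(seq_len(n), length(times)), n, length(times)),
    cells = data.frame(id = seq_len(n), row = 1L, col = 1L,
                       layer = seq_len(n), birth_time = 0,
                       epi_time = NA_real_, mother = NA_integer_),
    events = data.frame(time = numeric(0), type = character(0),
                        id = integer(0)),
    clamp_events = 0, params = default_params(), config = cfg,
    tissue = NULL), class = "psm_trajectory")
}

#' Travelling-pulse fixture
#'
#' A Gaussian pulse of activity sweeping from the posterior (highest
#' layer) towards the anterior once per period: layer l peaks at time
#' \code{t0 + period * (n_layers - l) / n_layers (mod period)}.
#'
#' @param n_layers number of AP layers.
#' @param times time vector.
#' @param period sweep period (min).
#' @param width temporal pulse width (min).
#' @return layers x times matrix.
#' @export
synth_traveling_pulse <- function(n_layers = 20, times = seq(0, 600),
                                  period = 120, width = 15) {
  M <- matrix(0, n_layers, length(times))
  for (l in seq_len(n_layers)) {
    lag <- period * (n_layers - l) / n_layers
    ph <- (times - lag) %% period
    d <- pmin(ph, period - ph)
    M[l, ] <- exp(-(d / width)^2)
  }
  M
}

#' Tissue with a synthetic epithelialization pattern
#'
#' Builds a one-column tissue whose epithelialized flags follow a logical
#' AP pattern; used to test somite-length measurement.
#'
#' @param pattern logical vector over AP layers (TRUE = epithelialized).
#' @param n_rows,n_cols cross-section (default 1 x 1).
#' @return a \code{psm_tissue}.
#' @export
synth_epi_tissue <- function(pattern, n_rows = 1, n_cols = 1) {
  t <- new_tissue(n_rows, n_cols, length(pattern), gz_depth = 1)
  flagged <- pattern[t$layer]
  t$epi_time[flagged] <- 0
  t
}
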