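# Declarative virtual experiments: each experiment is a list of parameter
# transforms (set / multiply, optionally time-triggered). Knockouts zero a
# gene's transcription rather than deleting equations, so the 38-variable
# state layout is invariant across experiments.

#' Construct an experiment specification
#'
#' @param name experiment name.
#' @param transforms list of lists with \code{name}, \code{value},
#'   \code{op} ("set"/"mul"), and optional \code{time} (min; 0 = applied
#'   before integration).
#' @param sync optional synchronization settings (see
#'   \code{\link{sync_experiment}}).
#' @return object of class \code{psm_experiment}.
#' @export
experiment_spec <- function(name, transforms = list(), sync = NULL) {
  for (tr in transforms) {
    stopifnot(!is.null(tr$name), !is.null(tr$value))
    if (!is.null(tr$time)) stopifnot(tr$time >= 0)
  }
  structure(list(name = name, transforms = transforms, sync = sync),
            class = "psm_experiment")
}

#' Apply an experiment's t = 0 transforms to a parameter set
#'
#' Timed transforms (time > 0) are not applied here; they become the
#' engine schedule via \code{\link{experiment_schedule}}.
#'
#' @param params a \code{psm_params}.
#' @param spec a \code{psm_experiment}.
#' @return modified \code{psm_params}.
#' @export
apply_experiment <- function(params, spec) {
  stopifnot(inherits(spec, "psm_experiment"))
  for (tr in spec$transforms) {
    if (!is.null(tr$time) && tr$time > 0) next
    if (!tr$name %in% names(params)) stop("unknown parameter: ", tr$name)
    val <- if (identical(tr$op, "mul")) params[[tr$name]] * tr$value else tr$value
    params <- set_params(params, structure(list(val), names = tr$name))
  }
  params
}

#' @rdname apply_experiment
#' @return data.frame schedule (time, name, value, op) for the engine, or
#'   NULL if the experiment has no timed transforms.
#' @export
experiment_schedule <- function(spec) {
  timed <- Filter(function(tr) !is.null(tr$time) && tr$time > 0,
                  spec$transforms)
  if (!length(timed)) return(NULL)
  do.call(rbind, lapply(timed, function(tr) {
    data.frame(time = tr$time, name = tr$name, value = tr$value,
               op = if (is.null(tr$op)) "set" else tr$op)
  }))
}

#' Virtual knockout of a gene
#'
#' Sets the gene's maximal transcription rate to zero; every downstream
#' effect emerges from the network (e.g. a Hes7 null produces static NICD
#' and a constant receding Mesp2 stripe; a Ripply2 null produces a double
#' Mesp2 stripe).
#'
#' @param gene one of hes7, hes1, lfng, mesp2, ripply2, dll1, notch1,
#'   tbx6, fgf8, wnt3a, epha4.
#' @return a \code{psm_experiment}.
#' @export
knockout <- function(gene) {
  genes <- c("hes7", "hes1", "lfng", "mesp2", "ripply2", "dll1", "notch1",
             "tbx6", "fgf8", "wnt3a", "epha4")
  if (!gene %in% genes) stop("unknown gene: ", gene)
  experiment_spec(paste0(gene, "_ko"),
                  list(list(name = paste0(gene, "_k_tr"), value = 0,
                            op = "set")))
}

#' Remove the HES7 feedback on the Dll1 promoter
#'
#' Replaces the inhibiting HES7 factor in the Dll1 promoter product by the
#' constant 1 (implemented as an infinite repression threshold). Hes7
#' keeps oscillating cell-autonomously, but DLL1 -- and hence NICD --
#' becomes static and no expression wave forms.
#'
#' @return a \code{psm_experiment}.
#' @export
remove_feedback <- function() {
  experiment_spec("dll1_feedback_removed",
                  list(list(name = "dll1_K_hes7", value = Inf, op = "set")))
}

#' Constitutive cytoplasmic NICD production
#'
#' Adds a constant flux to cytoplasmic NICD in every cell, emulating
#' ubiquitous NICD expression; Mesp2 then moves within the window set by
#' TBX6 and FGF8 alone.
#'
#' @param rate production flux (a.u./min); 0 is the identity.
#' @return a \code{psm_experiment}.
#' @export
constitutive_nicd <- function(rate) {
  stopifnot(rate >= 0)
  experiment_spec("nicd_const",
                  list(list(name = "nicd_const_prod", value = rate,
                            op = "set")))
}

#' Timed reduction of FGF8 protein production
#'
#' Multiplies the Fgf8 translation rate by \code{factor} from time
#' \code{t} onward (default: halved at 600 min), the in-silico surrogate
#' of pharmacological Fgf-signaling inhibition; the anterior Mesp2 domain
#' broadens in the following cycle.
#'
#' @param factor multiplicative factor (default 0.5).
#' @param t trigger time in minutes (default 600).
#' @return a \code{psm_experiment}.
#' @export
timed_fgf8_reduction <- function(factor = 0.5, t = 600) {
  stopifnot(factor >= 0, t >= 0)
  experiment_spec("fgf8_reduction",
                  list(list(name = "fgf8_k_tl", value = factor, op = "mul",
                            time = t)))
}

#' Clock-rate variation
#'
#' Rescales rates by \code{scale}. In \code{"all"} mode every
#' core-oscillator rate is rescaled -- a pure time rescaling of the clock,
#' so the period transforms exactly as 1/scale; in \code{"hes7_mrna"} mode
#' only the cytoplasmic Hes7 mRNA decay changes (the paper's primary knob
#' for somite-length variation).
#'
#' @param scale positive factor (1 = identity).
#' @param mode \code{"all"} or \code{"hes7_mrna"}.
#' @return a \code{psm_experiment}.
#' @export
clock_rate_variation <- function(scale, mode = c("all", "hes7_mrna")) {
  mode <- match.arg(mode)
  stopifnot(scale > 0)
  if (mode == "hes7_mrna") {
    tr <- list(list(name = "hes7_d_mc", value = scale, op = "mul"))
  } else {
    tr <- lapply(core_rate_names(), function(nm)
      list(name = nm, value = scale, op = "mul"))
  }
  experiment_spec(paste0("clock_scale_", mode), tr)
}

#' Detune the HES7 nuclear decay to elicit beats in Hes1
#'
#' Sets the HES7 saturated nuclear decay Vmax while leaving the Hes1
#' oscillator untouched. With the two eigenfrequencies detuned, the Hes1
#' amplitude maxima oscillate slowly -- the genetic analogue of beat.
#' Intended for the gradient-free (two-cell) setting where envelopes are
#' clean.
#'
#' @param hes7_v_sat new Vmax (a.u./min); the default parameter value
#'   reproduces the identity.
#' @return a \code{psm_experiment}.
#' @export
beat_experiment <- function(hes7_v_sat) {
  stopifnot(hes7_v_sat > 0)
  experiment_spec("beat",
                  list(list(name = "hes7_v_sat", value = hes7_v_sat,
                            op = "set")))
}

#' Single-layer synchronization experiment
#'
#' The growth zone is reduced to a single layer, HES1 is wired as the
#' Dll1 repressor, and every newborn cell starts with a phase shifted
#' uniformly in [0, max_phase_offset] of the clock period relative to its
#' mother. Synchronization is then read out with
#' \code{\link{phase_dispersion}}. With NICD binding as a dimer (Hill
#' coefficient 2) and offsets up to 25\% of the period, Delta/Notch
#' coupling pulls the phases back together.
#'
#' @param max_phase_offset maximal phase offset as a fraction of the
#'   period (default 0.25).
#' @param nicd_hill Hill coefficient for NICD activation of Hes1/Hes7
#'   (default 2, dimer binding; 1 for the monomer comparison).
#' @return a \code{psm_experiment} with \code{sync} settings consumed by
#'   \code{\link{integrate_tissue}}.
#' @export
sync_experiment <- function(max_phase_offset = 0.25, nicd_hill = 2) {
  stopifnot(max_phase_offset >= 0, max_phase_offset <= 1, nicd_hill >= 1)
  experiment_spec(
    "sync",
    list(list(name = "dll1_repressor", value = "hes1", op = "set"),
         list(name = "hes1_h_nicd", value = nicd_hill, op = "set"),
         list(name = "hes7_h_nicd", value = nicd_hill, op = "set")),
    sync = list(max_phase_offset = max_phase_offset))
}

#' Revert an experiment
#'
#' Returns the baseline parameters unchanged -- experiments never mutate
#' their input set, so applying a spec and reverting is the identity by
#' construction. Provided for symmetry and used by the round-trip
#' property test.
#'
#' @param params baseline \code{psm_params}.
#' @param spec a \code{psm_experiment} (unused; documents intent).
#' @return \code{params}.
#' @export
revert_experiment <- function(params, spec) params

#' Run a named experiment on the standard tissue
#'
#' Convenience wrapper: builds the default tissue, applies the experiment
#' transforms and schedule, integrates, and returns the trajectory.
#'
#' @param spec a \code{psm_experiment}.
#' @param params baseline parameters.
#' @param t_end simulated minutes.
#' @param n_rows,n_cols cross-section.
#' @param seed RNG seed.
#' @param record_every recording interval (min).
#' @param gz_depth growth-zone depth; the sync experiment uses a
#'   single-layer growth zone regardless.
#' @return a \code{psm_trajectory}.
#' @export
run_experiment <- function(spec, params = default_params(), t_end = 720,
                           n_rows = 4, n_cols = 4, seed = 1,
                           record_every = 1, gz_depth = 15) {
  p <- apply_experiment(params, spec)
  if (!is.null(spec$sync)) gz_depth <- 1L
  # cells start from the baseline (wild-type) reference state: a knockout
  # set has no limit cycle of its own, and the downstream decay of the
  # eliminated product is part of the observed phenotype
  tissue <- initialize_tissue(params, n_rows = n_rows, n_cols = n_cols,
                              n_layers = gz_depth, gz_depth = gz_depth)
  cfg <- sim_config(t_end = t_end, seed = seed, record_every = record_every,
                    schedule = experiment_schedule(spec))
  integrate_tissue(tissue, p, cfg, sync = spec$sync)
}
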