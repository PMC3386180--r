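# Flat key = value run configuration: parameter overrides (param.*),
# simulation settings (sim.*) and an experiment stanza (experiment,
# experiment.*). Strict parsing: unknown keys are errors.

#' Build an experiment from a name and arguments
#'
#' Maps configuration/CLI experiment names to constructors:
#' \code{hes7_ko}, \code{hes1_ko}, \code{lfng_ko}, \code{ripply2_ko} (any
#' \code{<gene>_ko}), \code{dll1_feedback}, \code{nicd_const} (rate),
#' \code{fgf8_half} (factor, time), \code{clock_scale} (scale, mode),
#' \code{beat} (hes7_v_sat), \code{sync} (max_phase_offset, nicd_hill).
#'
#' @param name experiment name.
#' @param args named list of arguments.
#' @return a \code{psm_experiment}.
#' @export
make_experiment <- function(name, args = list()) {
  if (grepl("_ko$", name)) return(knockout(sub("_ko$", "", name)))
  switch(name,
    dll1_feedback = remove_feedback(),
    nicd_const = constitutive_nicd(args$rate %||% 0.1),
    fgf8_half = timed_fgf8_reduction(args$factor %||% 0.5,
                                     args$time %||% 600),
    clock_scale = clock_rate_variation(args$scale %||% 1,
                                       args$mode %||% "all"),
    beat = beat_experiment(args$hes7_v_sat %||%
                             (default_params()$hes7_v_sat * 1.6)),
    sync = sync_experiment(args$max_phase_offset %||% 0.25,
                           args$nicd_hill %||% 2),
    stop("unknown experiment: ", name)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_kv_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("malformed config line: ", ln)
    kv[[trimws(parts[1])]] <- trimws(parts[2])
  }
  kv
}

num_or_str <- function(x) {
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v)) x else v
}

#' Load a run configuration
#'
#' An empty file yields the full defaults (parameters from
#' \code{\link{default_params}}, a 720-min default simulation, no
#' experiment). Unknown keys are errors.
#'
#' @param path config file (flat \code{key = value}; \code{param.<name>},
#'   \code{sim.<field>}, \code{experiment}, \code{experiment.<arg>}).
#' @return list with \code{params} (\code{psm_params}), \code{config}
#'   (\code{psm_config}), \code{experiment} (\code{psm_experiment} or
#'   NULL), and \code{geometry} (rows/cols/layers/gz_depth).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  kv <- parse_kv_file(path)
  params <- default_params()
  sim <- list(t_end = 720, dt = 0.025, record_every = 1, seed = 1,
              division_interval = 24)
  geom <- list(n_rows = 4, n_cols = 4, n_layers = 15, gz_depth = 15)
  exp_name <- NULL; exp_args <- list()
  for (key in names(kv)) {
    val <- kv[[key]]
    if (startsWith(key, "param.")) {
      nm <- sub("^param\\.", "", key)
      if (!nm %in% names(params)) stop("unknown parameter key: ", key)
      params[[nm]] <- if (is.character(params[[nm]])) val else as.numeric(val)
    } else if (startsWith(key, "sim.")) {
      nm <- sub("^sim\\.", "", key)
      if (!nm %in% names(sim)) stop("unknown sim key: ", key)
      sim[[nm]] <- as.numeric(val)
    } else if (startsWith(key, "geometry.")) {
      nm <- sub("^geometry\\.", "", key)
      if (!nm %in% names(geom)) stop("unknown geometry key: ", key)
      geom[[nm]] <- as.integer(val)
    } else if (key == "experiment") {
      exp_name <- val
    } else if (startsWith(key, "experiment.")) {
      exp_args[[sub("^experiment\\.", "", key)]] <- num_or_str(val)
    } else {
      stop("unknown config key: ", key)
    }
  }
  validate_params(params)
  experiment <- if (!is.null(exp_name)) make_experiment(exp_name, exp_args)
  cfg <- sim_config(t_end = sim$t_end, dt = sim$dt,
                    record_every = sim$record_every, seed = sim$seed,
                    division_interval = sim$division_interval,
                    schedule = if (!is.null(experiment))
                      experiment_schedule(experiment))
  list(params = params, config = cfg, experiment = experiment,
       geometry = geom)
}

#' Save a run configuration
#'
#' Writes the non-default parameter values and the simulation settings as
#' a flat key = value file; \code{load_config} of the result reproduces
#' the inputs (round trip).
#'
#' @param params a \code{psm_params}.
#' @param config a \code{psm_config}.
#' @param path output file.
#' @param geometry optional geometry list.
#' @return the path, invisibly.
#' @export
save_config <- function(params, config, path, geometry = NULL) {
  def <- default_params()
  lines <- c("# psmclock run configuration")
  for (nm in names(params)) {
    if (!identical(params[[nm]], def[[nm]])) {
      lines <- c(lines, paste0("param.", nm, " = ",
                               format(params[[nm]], digits = 17)))
    }
  }
  for (nm in c("t_end", "dt", "record_every", "seed")) {
    lines <- c(lines, paste0("sim.", nm, " = ", format(config[[nm]], digits = 17)))
  }
  if (!is.null(config$division_interval)) {
    lines <- c(lines, paste0("sim.division_interval = ",
                             format(config$division_interval, digits = 17)))
  }
  if (!is.null(geometry)) {
    for (nm in names(geometry)) {
      lines <- c(lines, paste0("geometry.", nm, " = ", geometry[[nm]]))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Export a trajectory as long-format CSV
#'
#' Columns: time, cell, species, value (NA rows before a cell's birth are
#' dropped).
#'
#' @param traj a \code{psm_trajectory}.
#' @param path output file.
#' @param species subset of recorded species (default all).
#' @return the path, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, species = traj$species) {
  rows <- list()
  for (sp in species) {
    k <- match(sp, traj$species)
    m <- traj$data[, , k, drop = FALSE]
    df <- data.frame(
      time = rep(traj$times, each = nrow(traj$cells)),
      cell = rep(traj$cells$id, length(traj$times)),
      species = sp,
      value = as.vector(m[, , 1]))
    rows[[sp]] <- df[!is.na(df$value), ]
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$time, out$cell, out$species), ]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Export the event log as JSON lines
#'
#' @param traj a \code{psm_trajectory}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_events_jsonl <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  ev <- traj$events
  for (i in seq_len(nrow(ev))) {
    writeLines(jsonlite::toJSON(as.list(ev[i, ]), auto_unbox = TRUE), con)
  }
  invisible(path)
}
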