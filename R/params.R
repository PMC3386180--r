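#' Default parameter set for the PSM clock network
#'
#' All rates are per minute, concentrations and Hill thresholds in
#' arbitrary units (a.u.). The printed literature values that anchor the
#' set are the Wnt3a/Fgf8 mRNA half-life of 2 h and protein half-life of
#' 20 min; HES7/HES1 net decays sit near the measured ~22 min half-life;
#' membrane traffic of DLL1/NOTCH1/NICD uses fast rates (>= 5x the Hes7
#' transport rates). The remaining free rates are fixed by the documented
#' deterministic calibration (see \code{\link{calibrate_defaults}}) so that
#' the two-cell core oscillator runs at the murine clock period of 120 min
#' in the growth-zone environment and slows to the anterior plateau when
#' nuclear NICD degradation is maximal.
#'
#' @return an object of class \code{psm_params}: a named list of numeric
#'   rates/thresholds plus a few mode strings.
#' @export
default_params <- function() {
  # Global time-rescaling factor fixed by the deterministic calibration:
  # all rate-dimension constants of the core oscillator (Hes7/Hes1/Lfng
  # transport genes, Dll1, Notch1, NICD, k_dn) are multiplied by this
  # factor so that the two-cell growth-zone period is exactly 120 min.
  # Hill thresholds and saturation constants (concentration units) are
  # not rescaled. Re-running calibrate_defaults() reproduces it.
  cal <- 1.01302221967
  p <- list(
    ## --- Hes7 core oscillator (transport scheme) ------------------------
    hes7_k_tr  = 0.2 * cal,        # max transcription (a.u./min)
    hes7_k_tl  = 0.1 * cal,      # translation (1/min)
    hes7_r_m   = 0.2 * cal,      # mRNA export nucleus -> cytoplasm
    hes7_r_in  = 0.1 * cal,      # protein import cytoplasm -> nucleus
    hes7_r_out = 0.02 * cal,     # protein export nucleus -> cytoplasm
    hes7_d_mn  = 0.002 * cal,    # nuclear mRNA decay (very small, all genes)
    hes7_d_mc  = 0.031 * cal,    # cytoplasmic mRNA decay (t1/2 ~ 22 min)
    hes7_d_pc  = 0.031 * cal,    # cytoplasmic protein decay
    hes7_v_sat = 0.15 * cal,        # saturated nuclear decay Vmax (a.u./min)
    hes7_k_sat = 0.02,      # saturation constant (a.u.)
    hes7_K_nicd = 5, hes7_h_nicd = 2,   # activation by nuclear NICD (dimer)
    hes7_K_self = 1, hes7_h_self = 2,   # self-repression (one N-box dimer)

    ## --- Hes1 (same scheme; h = 3 self-repression; FGF8-coupled mRNA decay)
    hes1_k_tr  = 0.2 * cal,
    hes1_k_tl  = 0.1 * cal,
    hes1_r_m   = 0.2 * cal,
    hes1_r_in  = 0.1 * cal,
    hes1_r_out = 0.02 * cal,
    hes1_d_mn  = 0.002 * cal,
    hes1_d_mc_min = 0.008 * cal, # anterior floor of FGF8-coupled mRNA decay
    hes1_d_mc_max = 0.031 * cal, # posterior ceiling (= Hes7 value)
    hes1_K_fgf8 = 1, hes1_h_fgf8 = 1,   # activating Hill raising d_mc
    hes1_d_pc  = 0.031 * cal,
    hes1_v_sat = 0.15 * cal,
    hes1_k_sat = 0.02,
    hes1_K_nicd = 5, hes1_h_nicd = 2,
    hes1_K_self = 1, hes1_h_self = 3,   # three cooperating N-boxes

    ## --- Lfng (clock output; weak D/N modulation by default) -----------
    lfng_k_tr  = 0.2 * cal,
    lfng_k_tl  = 0.1 * cal,
    lfng_r_m   = 0.2 * cal,
    lfng_r_in  = 0.1 * cal,
    lfng_r_out = 0.02 * cal,
    lfng_d_mn  = 0.002 * cal,
    lfng_d_mc  = 0.031 * cal,
    lfng_d_pc  = 0.031 * cal,
    lfng_v_sat = 0.15 * cal,
    lfng_k_sat = 0.02,
    lfng_K_nicd = 5, lfng_h_nicd = 2,
    lfng_K_hes7 = 1, lfng_h_hes7 = 2,

    ## --- Mesp2 (boundary determinant) -----------------------------------
    mesp2_k_tr  = 0.2,
    mesp2_k_tl  = 0.3,
    mesp2_r_m   = 0.2,
    mesp2_r_in  = 0.1,
    mesp2_r_out = 0.02,
    mesp2_d_mn  = 0.002,
    mesp2_d_mc  = 0.062,   # short mRNA half-life: expression decays quickly
    mesp2_d_pc  = 0.062,
    mesp2_v_sat = 0.15,
    mesp2_k_sat = 0.05,
    mesp2_K_nicd = 4,  mesp2_h_nicd = 2,  # gates firing to the NICD wave crest
    mesp2_K_tbx6 = 1,  mesp2_h_tbx6 = 2,
    mesp2_K_fgf8 = 1,  mesp2_h_fgf8 = 4,  # steep posterior repression
    mesp2_K_ripply2 = 1, mesp2_h_ripply2 = 2,

    ## --- Ripply2 (Mesp2 repressor; induced by MESP2 dimer) --------------
    ripply2_k_tr  = 0.2,
    ripply2_k_tl  = 0.3,
    ripply2_r_m   = 0.2,
    ripply2_r_in  = 0.1,
    ripply2_r_out = 0.02,
    ripply2_d_mn  = 0.002,
    ripply2_d_mc  = 0.062,
    ripply2_d_pc  = 0.062,
    ripply2_v_sat = 0.15,
    ripply2_k_sat = 0.05,
    ripply2_K_mesp2 = 1, ripply2_h_mesp2 = 2,

    ## --- Dll1 (oscillatory ligand; fast membrane traffic) ---------------
    dll1_k_tr  = 2 * cal,
    dll1_k_tl  = 6 * cal,
    dll1_r_m   = 0.07 * cal,  # slow mRNA maturation/export: the relay delay
    dll1_r_mem = 1 * cal,        # cytoplasm -> membrane export (fast)
    dll1_d_mn  = 0.002 * cal,
    dll1_d_mc  = 0.057 * cal,    # fast (>= 5x Hes7 rates)
    dll1_d_pc  = 0.155 * cal,
    dll1_d_pm  = 0.155 * cal,    # membrane protein decay
    dll1_K_tbx6 = 1, dll1_h_tbx6 = 3,
    dll1_K_wnt  = 1, dll1_h_wnt  = 1,
    dll1_K_hes7 = 0.45, dll1_h_hes7 = 2,   # postulated negative feedback

    ## --- Notch1 (static receptor; single mRNA pool) ----------------------
    notch1_k_tr  = 0.1 * cal,
    notch1_k_tl  = 9 * cal,
    notch1_r_mem = 1 * cal,
    notch1_d_m   = 0.023 * cal,  # t1/2 ~ 30 min
    notch1_d_pc  = 0.155 * cal,
    notch1_d_pm  = 0.155 * cal,
    notch1_K_wnt = 1, notch1_h_wnt = 3, # sharp anterior boundary

    ## --- NICD ------------------------------------------------------------
    nicd_r_in  = 1 * cal,        # import > export: NICD acts in the nucleus
    nicd_r_out = 0.1 * cal,
    nicd_d_c   = 0.155 * cal,    # cytoplasmic decay (fast)
    nicd_g_base = 0.05 * cal,    # residual nuclear decay in the growth zone
    nicd_g_max  = 24 * cal,       # maximal nuclear decay when WNT3A is gone
    nicd_K_wnt  = 0.35, nicd_h_wnt = 2,    # inverted Wnt3a gradient coupling
    nicd_const_prod = 0,   # constitutive cytoplasmic production (experiments)

    ## --- D/N reaction and LFNG modulation --------------------------------
    k_dn = (4 / 9) * cal,  # bimolecular rate; membrane levels absorb the scale              # DLL1-NOTCH1 reaction rate (1/(a.u. min))
    lfng_mode = "inhibiting",   # "inhibiting" | "activating" | "off"
    lfng_K_mod = 20, lfng_h_mod = 2,    # high threshold: weak default action
    lfng_eps = 0.05,       # residual D/N rate in activating mode

    ## --- Tbx6 (coarse; long mRNA, short protein half-life) --------------
    tbx6_k_tr = 0.01,
    tbx6_k_tl = 0.1,
    tbx6_d_m  = 0.005,     # long mRNA half-life (~ 2.3 h)
    tbx6_d_p  = 0.069,     # short protein half-life (~ 10 min)
    tbx6_K_wnt = 1, tbx6_h_wnt = 3,

    ## --- Fgf8 / Wnt3a gradients (printed half-lives) ---------------------
    fgf8_k_tr = log(2) / 120,   # growth-zone transcription; 0 outside
    fgf8_k_tl = 4 * log(2) / 20,
    fgf8_d_m  = log(2) / 120,  # mRNA t1/2 = 2 h
    fgf8_d_p  = log(2) / 20,   # protein t1/2 = 20 min
    wnt3a_k_tr = log(2) / 120,
    wnt3a_k_tl = 4 * log(2) / 20,
    wnt3a_d_m  = log(2) / 120,
    wnt3a_d_p  = log(2) / 20,

    ## --- Epha4 (epithelialization marker; long protein half-life) -------
    epha4_k_tr = 0.2,
    epha4_k_tl = 0.05,
    epha4_r_m  = 0.2,
    epha4_d_mn = 0.002,
    epha4_d_mc = 0.062,
    epha4_d_pc = 0.004,    # t1/2 ~ 3 h: levels plateau; the irreversible flag keeps the record
    epha4_K_mesp2 = 1, epha4_h_mesp2 = 2,
    epha4_threshold = 2,   # epithelialization trigger (a.u.)

    ## --- wiring modes -----------------------------------------------------
    gradient_coupling = "wnt_nicd",  # | "fgf_hes7_protein" | "fgf_hes7_mrna"
    dll1_repressor = "hes7",         # "hes1" in the synchronization setting
    hes7_d_pn_min = 0, hes7_d_pn_max = 0,  # linear nuclear decay used by the
    hes7_K_fgf8 = 1, hes7_h_fgf8 = 1,      # FGF8-coupled gradient variants
    hes7_d_mc_max = 0.062                  # ceiling for the mRNA-decay variant
  )
  structure(p, class = "psm_params")
}

#' Validate a parameter set
#'
#' Checks the structural invariants of the network parameterization:
#' non-negative rates, base < max NICD nuclear decay, NICD import faster
#' than export, nuclear mRNA decay much smaller than cytoplasmic.
#'
#' @param p a \code{psm_params} object.
#' @return invisibly \code{p}; stops on violation.
#' @export
validate_params <- function(p) {
  stopifnot(inherits(p, "psm_params"))
  num <- p[vapply(p, is.numeric, logical(1))]
  if (any(unlist(num) < 0)) {
    bad <- names(num)[vapply(num, function(x) any(x < 0), logical(1))]
    stop("negative parameter value(s): ", paste(bad, collapse = ", "))
  }
  if (p$nicd_g_base >= p$nicd_g_max) stop("nicd_g_base must be < nicd_g_max")
  if (p$nicd_r_in <= p$nicd_r_out) stop("NICD nuclear import must exceed export")
  for (g in c("hes7", "hes1", "lfng", "mesp2", "ripply2", "dll1", "epha4")) {
    dmn <- p[[paste0(g, "_d_mn")]]
    dmc <- p[[paste0(g, "_d_mc")]]
    if (g == "hes1") dmc <- p$hes1_d_mc_max
    if (dmn > 0.5 * dmc) stop("nuclear mRNA decay must be << cytoplasmic for ", g)
  }
  if (!p$lfng_mode %in% c("inhibiting", "activating", "off")) {
    stop("unknown lfng_mode: ", p$lfng_mode)
  }
  if (!p$gradient_coupling %in% c("wnt_nicd", "fgf_hes7_protein", "fgf_hes7_mrna")) {
    stop("unknown gradient_coupling: ", p$gradient_coupling)
  }
  if (!p$dll1_repressor %in% c("hes7", "hes1")) {
    stop("unknown dll1_repressor: ", p$dll1_repressor)
  }
  invisible(p)
}

#' Modify a parameter set
#'
#' @param p a \code{psm_params}.
#' @param ... name = value pairs; names must already exist in \code{p}.
#' @return modified, validated \code{psm_params}.
#' @export
set_params <- function(p, ...) {
  upd <- list(...)
  if (length(upd) == 1L && is.list(upd[[1]]) && is.null(names(upd)[1])) {
    upd <- upd[[1]]
  }
  bad <- setdiff(names(upd), names(p))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  p[names(upd)] <- upd
  validate_params(p)
  p
}

#' Write / read a parameter set as a flat key = value file
#'
#' The on-disk format is one \code{key = value} pair per line, with
#' \code{#} comments; strings are unquoted. Every run directory gets an
#' echo of the parameters used, for provenance.
#'
#' @param p a \code{psm_params}.
#' @param path file path.
#' @export
write_params <- function(p, path) {
  stopifnot(inherits(p, "psm_params"))
  fmt <- function(v) {
    if (is.character(v)) v else format(v, digits = 17, scientific = FALSE, trim = TRUE)
  }
  lines <- c("# psmclock parameter set (flat key = value)",
             vapply(names(p), function(k) paste(k, "=", fmt(p[[k]])), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_params
#' @param strict error on keys absent from the defaults (default TRUE).
#' @export
read_params <- function(path, strict = TRUE) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  p <- default_params()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed parameter line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(p)) {
      if (strict) stop("unknown parameter key: ", key) else next
    }
    p[[key]] <- if (is.character(p[[key]])) val else as.numeric(val)
  }
  validate_params(p)
  p
}
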