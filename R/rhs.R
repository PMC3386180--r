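# Per-cell ODE right-hand side for the 38-variable GRN, vectorised over a
# state matrix (cells x species). This R implementation is the reference;
# the compiled integrator in src/ must agree with it (cross-checked in the
# test suite).

## ---- promoter logic ------------------------------------------------------

prom_hes7 <- function(nicd_n, hes7_pn, p) {
  hill_act(nicd_n, p$hes7_K_nicd, p$hes7_h_nicd) *
    hill_inh(hes7_pn, p$hes7_K_self, p$hes7_h_self)
}

prom_hes1 <- function(nicd_n, hes1_pn, p) {
  hill_act(nicd_n, p$hes1_K_nicd, p$hes1_h_nicd) *
    hill_inh(hes1_pn, p$hes1_K_self, p$hes1_h_self)
}

prom_lfng <- function(nicd_n, hes7_pn, p) {
  hill_act(nicd_n, p$lfng_K_nicd, p$lfng_h_nicd) *
    hill_inh(hes7_pn, p$lfng_K_hes7, p$lfng_h_hes7)
}

# repressor_pn is HES7 nuclear protein by default, HES1 in the
# synchronization wiring; an infinite threshold disables the feedback.
prom_dll1 <- function(tbx6_p, wnt_avg, repressor_pn, p) {
  hill_act(tbx6_p, p$dll1_K_tbx6, p$dll1_h_tbx6) *
    hill_act(wnt_avg, p$dll1_K_wnt, p$dll1_h_wnt) *
    hill_inh(repressor_pn, p$dll1_K_hes7, p$dll1_h_hes7)
}

prom_notch1 <- function(wnt_avg, p) hill_act(wnt_avg, p$notch1_K_wnt, p$notch1_h_wnt)

prom_tbx6 <- function(wnt_avg, p) hill_act(wnt_avg, p$tbx6_K_wnt, p$tbx6_h_wnt)

prom_mesp2 <- function(nicd_n, tbx6_p, fgf_avg, ripply2_pn, p) {
  hill_act(nicd_n, p$mesp2_K_nicd, p$mesp2_h_nicd) *
    hill_act(tbx6_p, p$mesp2_K_tbx6, p$mesp2_h_tbx6) *
    hill_inh(fgf_avg, p$mesp2_K_fgf8, p$mesp2_h_fgf8) *
    hill_inh(ripply2_pn, p$mesp2_K_ripply2, p$mesp2_h_ripply2)
}

prom_ripply2 <- function(mesp2_pn, p) {
  hill_act(mesp2_pn, p$ripply2_K_mesp2, p$ripply2_h_mesp2)
}

prom_epha4 <- function(mesp2_pn, p) {
  hill_act(mesp2_pn, p$epha4_K_mesp2, p$epha4_h_mesp2)
}

#' Promoter activity of a gene given its regulatory inputs
#'
#' Computes the product of the gene's Hill factors, a fraction in
#' \code{[0, 1]} that multiplies the maximal transcription rate in the
#' transcription term.
#'
#' @param gene one of \code{"hes7"}, \code{"hes1"}, \code{"lfng"},
#'   \code{"dll1"}, \code{"notch1"}, \code{"tbx6"}, \code{"mesp2"},
#'   \code{"ripply2"}, \code{"epha4"}.
#' @param inputs named numeric vector/list of input concentrations. The
#'   required names per gene: hes7/hes1 need \code{nicd_n} and the gene's
#'   own nuclear protein (\code{hes7_pn}/\code{hes1_pn}); lfng needs
#'   \code{nicd_n}, \code{hes7_pn}; dll1 needs \code{tbx6_p},
#'   \code{wnt_avg}, \code{hes7_pn}; notch1/tbx6 need \code{wnt_avg};
#'   mesp2 needs \code{nicd_n}, \code{tbx6_p}, \code{fgf_avg},
#'   \code{ripply2_pn}; ripply2/epha4 need \code{mesp2_pn}.
#' @param params a \code{psm_params}.
#' @return activity in \code{[0, 1]}.
#' @export
promoter_activity <- function(gene, inputs, params) {
  inputs <- as.list(inputs)
  if (any(vapply(inputs, function(x) any(!is.finite(x)) || any(x < 0), logical(1)))) {
    stop("promoter inputs must be finite and >= 0")
  }
  need <- function(nm) {
    if (is.null(inputs[[nm]])) stop("promoter_activity('", gene, "') needs input '", nm, "'")
    inputs[[nm]]
  }
  switch(gene,
    hes7    = prom_hes7(need("nicd_n"), need("hes7_pn"), params),
    hes1    = prom_hes1(need("nicd_n"), need("hes1_pn"), params),
    lfng    = prom_lfng(need("nicd_n"), need("hes7_pn"), params),
    dll1    = prom_dll1(need("tbx6_p"), need("wnt_avg"), need("hes7_pn"), params),
    notch1  = prom_notch1(need("wnt_avg"), params),
    tbx6    = prom_tbx6(need("wnt_avg"), params),
    mesp2   = prom_mesp2(need("nicd_n"), need("tbx6_p"), need("fgf_avg"),
                         need("ripply2_pn"), params),
    ripply2 = prom_ripply2(need("mesp2_pn"), params),
    epha4   = prom_epha4(need("mesp2_pn"), params),
    stop("unknown gene: ", gene)
  )
}

## ---- gradient coupling and D/N modulation --------------------------------

#' Nuclear NICD degradation rate under the inverted Wnt3a gradient
#'
#' The Wnt3a gradient is mathematically inverted before coupling to NICD
#' decay: in the growth zone (WNT3A high) only a residual base rate
#' remains; as WNT3A vanishes anteriorly the rate rises to its maximum,
#' slowing the oscillators and producing the wave.
#'
#' @param wnt3a_avg WNT3A protein averaged over neighbouring cells (a.u.).
#' @param params a \code{psm_params}.
#' @return decay rate in 1/min, between \code{nicd_g_base} and
#'   \code{nicd_g_max}.
#' @export
nicd_nuclear_decay_rate <- function(wnt3a_avg, params) {
  if (any(!is.finite(wnt3a_avg)) || any(wnt3a_avg < 0)) {
    stop("wnt3a_avg must be finite and >= 0")
  }
  params$nicd_g_base + (params$nicd_g_max - params$nicd_g_base) *
    hill_inh(wnt3a_avg, params$nicd_K_wnt, params$nicd_h_wnt)
}

#' Multiplicative LFNG modulation of the DLL1-NOTCH1 reaction rate
#'
#' Default mode is weak inhibition (a high Hill threshold makes Lfng a
#' near-pure clock output); the activating variant replaces the inhibiting
#' factor by an activating Hill plus a small residual \code{lfng_eps}
#' standing for unmodified DLL1/NOTCH1 reaction in the ER.
#'
#' @param lfng_p_cyt cytoplasmic LFNG protein (a.u.).
#' @param params a \code{psm_params}.
#' @return multiplicative factor applied to \code{k_dn}.
#' @export
lfng_modulation <- function(lfng_p_cyt, params) {
  if (params$lfng_eps < 0) stop("lfng_eps must be >= 0")
  switch(params$lfng_mode,
    off        = rep(1, length(lfng_p_cyt)),
    inhibiting = hill_inh(lfng_p_cyt, params$lfng_K_mod, params$lfng_h_mod),
    activating = hill_act(lfng_p_cyt, params$lfng_K_mod, params$lfng_h_mod) +
                 params$lfng_eps,
    stop("unknown lfng_mode: ", params$lfng_mode)
  )
}

#' Delta/Notch reaction fluxes for one cell
#'
#' The DLL1 ligand on neighbouring cells reacts with membrane NOTCH1;
#' cleavage releases NICD into the cytoplasm, destroys the NOTCH1 molecule
#' and (after endocytosis) the bound DLL1. The identical flux therefore
#' appears as NICD gain, NOTCH1 membrane loss, and DLL1 membrane loss
#' apportioned back to the donor cells.
#'
#' @param cell named numeric vector with at least \code{notch1_pm} and
#'   \code{lfng_pc}.
#' @param neighbor_dll1_mem mean membrane DLL1 over the neighbours (a.u.);
#'   use 0 for an isolated cell.
#' @param params a \code{psm_params}.
#' @return list with \code{nicd_production}, \code{notch_mem_loss} and
#'   \code{dll1_mem_loss_per_donor} (all equal in magnitude; the donor loss
#'   is the total to be split across donors in proportion to their DLL1).
#' @export
dn_reaction <- function(cell, neighbor_dll1_mem, params) {
  mod <- lfng_modulation(cell[["lfng_pc"]], params)
  flux <- params$k_dn * mod * cell[["notch1_pm"]] * neighbor_dll1_mem
  list(nicd_production = flux, notch_mem_loss = flux,
       dll1_mem_loss_per_donor = flux)
}

## ---- transport-scheme derivative (vectorised) ----------------------------

transport_rhs <- function(mn, mc, pc, pn, prom,
                          k_tr, k_tl, r_m, r_in, r_out,
                          d_mn, d_mc, d_pc, v_sat, k_sat,
                          extra_pn_decay = 0) {
  list(
    dmn = k_tr * prom - (r_m + d_mn) * mn,
    dmc = r_m * mn - d_mc * mc,
    dpc = k_tl * mc - (r_in + d_pc) * pc + r_out * pn,
    dpn = r_in * pc - r_out * pn - v_sat * pn / (k_sat + pn) - extra_pn_decay * pn
  )
}

## ---- full RHS ------------------------------------------------------------

#' Right-hand side of the coupled tissue ODE system (reference R version)
#'
#' @param S numeric matrix, cells x 38 (columns as \code{\link{psm_species}}).
#' @param p a \code{psm_params}.
#' @param A sparse neighbour-averaging matrix (rows: receivers; row i holds
#'   1/n_i at the columns of the n_i face neighbours of cell i). For two
#'   coupled cells this is the 2x2 anti-diagonal matrix.
#' @param in_gz logical vector: growth-zone membership (Wnt3a/Fgf8
#'   transcription only there).
#' @param env optional list overriding the neighbour-averaged gradient
#'   inputs with fixed levels (\code{wnt}, \code{fgf}); used by the
#'   reduced two-cell system.
#' @return derivative matrix like \code{S}, with attributes
#'   \code{dn_flux} (per-receiver NICD production) and \code{dn_donor_loss}
#'   (per-donor membrane DLL1 loss) for the conservation ledger.
#' @export
psm_rhs <- function(S, p, A, in_gz, env = NULL) {
  n <- nrow(S)
  avg <- function(x) as.numeric(A %*% x)

  W <- if (!is.null(env$wnt)) rep_len(env$wnt, n) else avg(S[, "wnt3a_p"])
  Fg <- if (!is.null(env$fgf)) rep_len(env$fgf, n) else avg(S[, "fgf8_p"])
  # the NICD-decay coupling may see a different WNT3A level than the
  # promoters (two-cell anterior regime); defaults to the promoter level
  Wd <- if (!is.null(env$wnt_decay)) rep_len(env$wnt_decay, n) else W
  Dn <- avg(S[, "dll1_pm"])

  mod <- lfng_modulation(S[, "lfng_pc"], p)
  kmodN <- p$k_dn * mod * S[, "notch1_pm"]
  flux <- kmodN * Dn                                   # NICD production per receiver
  donor_coef <- as.numeric(Matrix::crossprod(A, kmodN))
  dll1_loss <- S[, "dll1_pm"] * donor_coef             # DLL1 loss per donor

  dS <- matrix(0, n, ncol(S), dimnames = dimnames(S))

  # gradient-coupling variants redirect the gradient input
  mode <- p$gradient_coupling
  if (mode == "wnt_nicd") {
    g_nic <- nicd_nuclear_decay_rate(Wd, p)
    hes7_extra_pn <- 0
    hes7_d_mc_eff <- p$hes7_d_mc
  } else if (mode == "fgf_hes7_protein") {
    g_nic <- p$nicd_g_base
    hes7_extra_pn <- p$hes7_d_pn_min +
      (p$hes7_d_pn_max - p$hes7_d_pn_min) * hill_act(Fg, p$hes7_K_fgf8, p$hes7_h_fgf8)
    hes7_d_mc_eff <- p$hes7_d_mc
  } else { # fgf_hes7_mrna
    g_nic <- p$nicd_g_base
    hes7_extra_pn <- 0
    hes7_d_mc_eff <- p$hes7_d_mc +
      (p$hes7_d_mc_max - p$hes7_d_mc) * hill_act(Fg, p$hes7_K_fgf8, p$hes7_h_fgf8)
  }

  # Hes7 core oscillator
  d <- transport_rhs(S[, "hes7_mn"], S[, "hes7_mc"], S[, "hes7_pc"], S[, "hes7_pn"],
                     prom_hes7(S[, "nicd_n"], S[, "hes7_pn"], p),
                     p$hes7_k_tr, p$hes7_k_tl, p$hes7_r_m, p$hes7_r_in, p$hes7_r_out,
                     p$hes7_d_mn, hes7_d_mc_eff, p$hes7_d_pc,
                     p$hes7_v_sat, p$hes7_k_sat, hes7_extra_pn)
  dS[, c("hes7_mn", "hes7_mc", "hes7_pc", "hes7_pn")] <-
    cbind(d$dmn, d$dmc, d$dpc, d$dpn)

  # Hes1 (clock output; FGF8-coupled cytoplasmic mRNA decay)
  hes1_d_mc <- p$hes1_d_mc_min +
    (p$hes1_d_mc_max - p$hes1_d_mc_min) * hill_act(Fg, p$hes1_K_fgf8, p$hes1_h_fgf8)
  d <- transport_rhs(S[, "hes1_mn"], S[, "hes1_mc"], S[, "hes1_pc"], S[, "hes1_pn"],
                     prom_hes1(S[, "nicd_n"], S[, "hes1_pn"], p),
                     p$hes1_k_tr, p$hes1_k_tl, p$hes1_r_m, p$hes1_r_in, p$hes1_r_out,
                     p$hes1_d_mn, hes1_d_mc, p$hes1_d_pc, p$hes1_v_sat, p$hes1_k_sat)
  dS[, c("hes1_mn", "hes1_mc", "hes1_pc", "hes1_pn")] <-
    cbind(d$dmn, d$dmc, d$dpc, d$dpn)

  # Lfng
  d <- transport_rhs(S[, "lfng_mn"], S[, "lfng_mc"], S[, "lfng_pc"], S[, "lfng_pn"],
                     prom_lfng(S[, "nicd_n"], S[, "hes7_pn"], p),
                     p$lfng_k_tr, p$lfng_k_tl, p$lfng_r_m, p$lfng_r_in, p$lfng_r_out,
                     p$lfng_d_mn, p$lfng_d_mc, p$lfng_d_pc, p$lfng_v_sat, p$lfng_k_sat)
  dS[, c("lfng_mn", "lfng_mc", "lfng_pc", "lfng_pn")] <-
    cbind(d$dmn, d$dmc, d$dpc, d$dpn)

  # Mesp2
  d <- transport_rhs(S[, "mesp2_mn"], S[, "mesp2_mc"], S[, "mesp2_pc"], S[, "mesp2_pn"],
                     prom_mesp2(S[, "nicd_n"], S[, "tbx6_p"], Fg, S[, "ripply2_pn"], p),
                     p$mesp2_k_tr, p$mesp2_k_tl, p$mesp2_r_m, p$mesp2_r_in,
                     p$mesp2_r_out, p$mesp2_d_mn, p$mesp2_d_mc, p$mesp2_d_pc,
                     p$mesp2_v_sat, p$mesp2_k_sat)
  dS[, c("mesp2_mn", "mesp2_mc", "mesp2_pc", "mesp2_pn")] <-
    cbind(d$dmn, d$dmc, d$dpc, d$dpn)

  # Ripply2
  d <- transport_rhs(S[, "ripply2_mn"], S[, "ripply2_mc"], S[, "ripply2_pc"],
                     S[, "ripply2_pn"],
                     prom_ripply2(S[, "mesp2_pn"], p),
                     p$ripply2_k_tr, p$ripply2_k_tl, p$ripply2_r_m, p$ripply2_r_in,
                     p$ripply2_r_out, p$ripply2_d_mn, p$ripply2_d_mc, p$ripply2_d_pc,
                     p$ripply2_v_sat, p$ripply2_k_sat)
  dS[, c("ripply2_mn", "ripply2_mc", "ripply2_pc", "ripply2_pn")] <-
    cbind(d$dmn, d$dmc, d$dpc, d$dpn)

  # Dll1: protein exported to the membrane instead of the nucleus
  repressor <- if (p$dll1_repressor == "hes7") S[, "hes7_pn"] else S[, "hes1_pn"]
  prom_d <- prom_dll1(S[, "tbx6_p"], W, repressor, p)
  dS[, "dll1_mn"] <- p$dll1_k_tr * prom_d - (p$dll1_r_m + p$dll1_d_mn) * S[, "dll1_mn"]
  dS[, "dll1_mc"] <- p$dll1_r_m * S[, "dll1_mn"] - p$dll1_d_mc * S[, "dll1_mc"]
  dS[, "dll1_pc"] <- p$dll1_k_tl * S[, "dll1_mc"] -
    (p$dll1_r_mem + p$dll1_d_pc) * S[, "dll1_pc"]
  dS[, "dll1_pm"] <- p$dll1_r_mem * S[, "dll1_pc"] - p$dll1_d_pm * S[, "dll1_pm"] -
    dll1_loss

  # Notch1
  dS[, "notch1_m"] <- p$notch1_k_tr * prom_notch1(W, p) - p$notch1_d_m * S[, "notch1_m"]
  dS[, "notch1_pc"] <- p$notch1_k_tl * S[, "notch1_m"] -
    (p$notch1_r_mem + p$notch1_d_pc) * S[, "notch1_pc"]
  dS[, "notch1_pm"] <- p$notch1_r_mem * S[, "notch1_pc"] -
    p$notch1_d_pm * S[, "notch1_pm"] - flux

  # NICD
  dS[, "nicd_c"] <- flux + p$nicd_const_prod - (p$nicd_r_in + p$nicd_d_c) * S[, "nicd_c"] +
    p$nicd_r_out * S[, "nicd_n"]
  dS[, "nicd_n"] <- p$nicd_r_in * S[, "nicd_c"] - p$nicd_r_out * S[, "nicd_n"] -
    g_nic * S[, "nicd_n"]

  # Tbx6
  dS[, "tbx6_m"] <- p$tbx6_k_tr * prom_tbx6(W, p) - p$tbx6_d_m * S[, "tbx6_m"]
  dS[, "tbx6_p"] <- p$tbx6_k_tl * S[, "tbx6_m"] - p$tbx6_d_p * S[, "tbx6_p"]

  # Fgf8 / Wnt3a: transcription only in the growth zone
  gz <- as.numeric(in_gz)
  dS[, "fgf8_m"] <- p$fgf8_k_tr * gz - p$fgf8_d_m * S[, "fgf8_m"]
  dS[, "fgf8_p"] <- p$fgf8_k_tl * S[, "fgf8_m"] - p$fgf8_d_p * S[, "fgf8_p"]
  dS[, "wnt3a_m"] <- p$wnt3a_k_tr * gz - p$wnt3a_d_m * S[, "wnt3a_m"]
  dS[, "wnt3a_p"] <- p$wnt3a_k_tl * S[, "wnt3a_m"] - p$wnt3a_d_p * S[, "wnt3a_p"]

  # Epha4: accumulating epithelialization marker, long protein half-life
  dS[, "epha4_mn"] <- p$epha4_k_tr * prom_epha4(S[, "mesp2_pn"], p) -
    (p$epha4_r_m + p$epha4_d_mn) * S[, "epha4_mn"]
  dS[, "epha4_mc"] <- p$epha4_r_m * S[, "epha4_mn"] - p$epha4_d_mc * S[, "epha4_mc"]
  dS[, "epha4_pc"] <- p$epha4_k_tl * S[, "epha4_mc"] - p$epha4_d_pc * S[, "epha4_pc"]

  if (any(!is.finite(dS))) {
    bad <- which(!is.finite(dS), arr.ind = TRUE)[1, ]
    stop("non-finite derivative for cell ", bad[1], ", variable ",
         colnames(S)[bad[2]])
  }
  attr(dS, "dn_flux") <- flux
  attr(dS, "dn_donor_loss") <- dll1_loss
  dS
}

#' Single-cell right-hand side
#'
#' Convenience wrapper around \code{\link{psm_rhs}} for one cell with
#' explicitly supplied environment (neighbour averages).
#'
#' @param state named numeric vector of length 38.
#' @param env list with \code{dll1_nbr}, \code{wnt_avg}, \code{fgf_avg}
#'   (numbers; defaults 0).
#' @param in_growth_zone logical flag.
#' @param params a \code{psm_params}.
#' @return named derivative vector of length 38.
#' @export
cell_rhs <- function(state, env = list(), in_growth_zone = FALSE, params = default_params()) {
  if (any(!is.finite(state)) || any(state < 0)) {
    stop("cell state must be finite and >= 0")
  }
  S <- matrix(state, nrow = 1, dimnames = list(NULL, psm_species()))
  dll1_nbr <- if (is.null(env$dll1_nbr)) 0 else env$dll1_nbr
  # a 1x1 averaging matrix cannot express an external neighbour; emulate it
  # by placing the neighbour's DLL1 in a virtual second cell with zero
  # coupling back.
  S2 <- rbind(S, S)
  S2[2, "dll1_pm"] <- dll1_nbr
  A <- Matrix::sparseMatrix(i = c(1, 2), j = c(2, 1), x = c(1, 1), dims = c(2, 2))
  envv <- list(wnt = if (is.null(env$wnt_avg)) 0 else env$wnt_avg,
               fgf = if (is.null(env$fgf_avg)) 0 else env$fgf_avg)
  dS <- psm_rhs(S2, params, A, in_gz = rep(in_growth_zone, 2), env = envv)
  out <- dS[1, ]
  names(out) <- psm_species()
  out
}
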