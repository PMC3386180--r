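#' The 38-variable per-cell state
#'
#' Every virtual cell carries 38 concentration variables (arbitrary units).
#' The five fast oscillatory genes (Hes7, Hes1, Lfng, Mesp2, Ripply2) use a
#' four-compartment transport scheme (nuclear mRNA, cytoplasmic mRNA,
#' cytoplasmic protein, nuclear protein) so that gene-expression delay is
#' represented by a chain of first-order transport steps. Dll1 and Notch1
#' use membrane compartments for the ligand/receptor, NICD has cytoplasmic
#' and nuclear pools, Tbx6/Fgf8/Wnt3a are coarse two-variable genes, and
#' Epha4 is a three-variable accumulating epithelialization marker.
#'
#' @return character vector of the 38 canonical state-variable names, in
#'   the fixed column order used by state matrices.
#' @export
psm_species <- function() {
  c(
    # transport-scheme genes: m_nuc, m_cyt, p_cyt, p_nuc
    "hes7_mn", "hes7_mc", "hes7_pc", "hes7_pn",
    "hes1_mn", "hes1_mc", "hes1_pc", "hes1_pn",
    "lfng_mn", "lfng_mc", "lfng_pc", "lfng_pn",
    "mesp2_mn", "mesp2_mc", "mesp2_pc", "mesp2_pn",
    "ripply2_mn", "ripply2_mc", "ripply2_pc", "ripply2_pn",
    # Dll1: nuclear/cytoplasmic mRNA, cytoplasmic protein, membrane protein
    "dll1_mn", "dll1_mc", "dll1_pc", "dll1_pm",
    # Notch1: single mRNA pool, cytoplasmic and membrane protein
    "notch1_m", "notch1_pc", "notch1_pm",
    # NICD: cytoplasmic and nuclear
    "nicd_c", "nicd_n",
    # coarse genes: mRNA, protein
    "tbx6_m", "tbx6_p",
    "fgf8_m", "fgf8_p",
    "wnt3a_m", "wnt3a_p",
    # Epha4: nuclear/cytoplasmic mRNA, cytoplasmic protein (long half-life)
    "epha4_mn", "epha4_mc", "epha4_pc"
  )
}

#' Number of per-cell state variables (38)
#' @export
n_psm_species <- function() length(psm_species())

#' Create a state matrix for n cells
#'
#' @param n number of cells.
#' @param init optional named numeric vector of initial values; unnamed
#'   species start at 0.
#' @return numeric matrix, n rows x 38 named columns, all values >= 0.
#' @export
new_state_matrix <- function(n, init = NULL) {
  sp <- psm_species()
  S <- matrix(0, nrow = n, ncol = length(sp), dimnames = list(NULL, sp))
  if (!is.null(init)) {
    bad <- setdiff(names(init), sp)
    if (length(bad)) stop("unknown species in init: ", paste(bad, collapse = ", "))
    if (any(init < 0)) stop("initial concentrations must be >= 0")
    S[, names(init)] <- rep(init, each = n)
  }
  S
}

# names of the oscillator (clock-phase carrying) variables; used when a
# newborn cell is given a shifted phase in the synchronization experiment
osc_species <- function() {
  c("hes7_mn", "hes7_mc", "hes7_pc", "hes7_pn",
    "hes1_mn", "hes1_mc", "hes1_pc", "hes1_pn",
    "lfng_mn", "lfng_mc", "lfng_pc", "lfng_pn",
    "dll1_mn", "dll1_mc", "dll1_pc", "dll1_pm",
    "notch1_m", "notch1_pc", "notch1_pm",
    "nicd_c", "nicd_n")
}
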