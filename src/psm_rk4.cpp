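// Fixed-step RK4 integrator for the coupled PSM tissue system.
//
// The per-cell GRN right-hand side implemented here mirrors the reference
// R implementation in R/rhs.R one-to-one; the test suite cross-checks the
// two on random states. Neighbour topology is passed in CSR form and is
// fixed within one integration segment; growth events are applied from R
// between segments.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// species column indices, matching psm_species() order
enum {
  HES7_MN, HES7_MC, HES7_PC, HES7_PN,
  HES1_MN, HES1_MC, HES1_PC, HES1_PN,
  LFNG_MN, LFNG_MC, LFNG_PC, LFNG_PN,
  MESP2_MN, MESP2_MC, MESP2_PC, MESP2_PN,
  RIPPLY2_MN, RIPPLY2_MC, RIPPLY2_PC, RIPPLY2_PN,
  DLL1_MN, DLL1_MC, DLL1_PC, DLL1_PM,
  NOTCH1_M, NOTCH1_PC, NOTCH1_PM,
  NICD_C, NICD_N,
  TBX6_M, TBX6_P,
  FGF8_M, FGF8_P,
  WNT3A_M, WNT3A_P,
  EPHA4_MN, EPHA4_MC, EPHA4_PC,
  NSPEC
};

struct Pars {
  // transport genes
  double hes7_k_tr, hes7_k_tl, hes7_r_m, hes7_r_in, hes7_r_out,
         hes7_d_mn, hes7_d_mc, hes7_d_pc, hes7_v_sat, hes7_k_sat,
         hes7_K_nicd, hes7_h_nicd, hes7_K_self, hes7_h_self;
  double hes1_k_tr, hes1_k_tl, hes1_r_m, hes1_r_in, hes1_r_out,
         hes1_d_mn, hes1_d_mc_min, hes1_d_mc_max, hes1_K_fgf8, hes1_h_fgf8,
         hes1_d_pc, hes1_v_sat, hes1_k_sat,
         hes1_K_nicd, hes1_h_nicd, hes1_K_self, hes1_h_self;
  double lfng_k_tr, lfng_k_tl, lfng_r_m, lfng_r_in, lfng_r_out,
         lfng_d_mn, lfng_d_mc, lfng_d_pc, lfng_v_sat, lfng_k_sat,
         lfng_K_nicd, lfng_h_nicd, lfng_K_hes7, lfng_h_hes7;
  double mesp2_k_tr, mesp2_k_tl, mesp2_r_m, mesp2_r_in, mesp2_r_out,
         mesp2_d_mn, mesp2_d_mc, mesp2_d_pc, mesp2_v_sat, mesp2_k_sat,
         mesp2_K_nicd, mesp2_h_nicd, mesp2_K_tbx6, mesp2_h_tbx6,
         mesp2_K_fgf8, mesp2_h_fgf8, mesp2_K_ripply2, mesp2_h_ripply2;
  double ripply2_k_tr, ripply2_k_tl, ripply2_r_m, ripply2_r_in, ripply2_r_out,
         ripply2_d_mn, ripply2_d_mc, ripply2_d_pc, ripply2_v_sat, ripply2_k_sat,
         ripply2_K_mesp2, ripply2_h_mesp2;
  double dll1_k_tr, dll1_k_tl, dll1_r_m, dll1_r_mem,
         dll1_d_mn, dll1_d_mc, dll1_d_pc, dll1_d_pm,
         dll1_K_tbx6, dll1_h_tbx6, dll1_K_wnt, dll1_h_wnt,
         dll1_K_hes7, dll1_h_hes7;
  double notch1_k_tr, notch1_k_tl, notch1_r_mem,
         notch1_d_m, notch1_d_pc, notch1_d_pm, notch1_K_wnt, notch1_h_wnt;
  double nicd_r_in, nicd_r_out, nicd_d_c, nicd_g_base, nicd_g_max,
         nicd_K_wnt, nicd_h_wnt, nicd_const_prod;
  double k_dn, lfng_K_mod, lfng_h_mod, lfng_eps;
  double tbx6_k_tr, tbx6_k_tl, tbx6_d_m, tbx6_d_p, tbx6_K_wnt, tbx6_h_wnt;
  double fgf8_k_tr, fgf8_k_tl, fgf8_d_m, fgf8_d_p;
  double wnt3a_k_tr, wnt3a_k_tl, wnt3a_d_m, wnt3a_d_p;
  double epha4_k_tr, epha4_k_tl, epha4_r_m, epha4_d_mn, epha4_d_mc, epha4_d_pc,
         epha4_K_mesp2, epha4_h_mesp2, epha4_threshold;
  double hes7_d_pn_min, hes7_d_pn_max, hes7_K_fgf8, hes7_h_fgf8, hes7_d_mc_max;
  int lfng_mode;          // 0 off, 1 inhibiting, 2 activating
  int gradient_coupling;  // 0 wnt_nicd, 1 fgf_hes7_protein, 2 fgf_hes7_mrna
  int dll1_repressor;     // 0 hes7, 1 hes1
};

static double num(const List& p, const char* nm) {
  return as<double>(p[nm]);
}

static Pars unpack(const List& p) {
  Pars q;
#define GET(f) q.f = num(p, #f)
  GET(hes7_k_tr); GET(hes7_k_tl); GET(hes7_r_m); GET(hes7_r_in); GET(hes7_r_out);
  GET(hes7_d_mn); GET(hes7_d_mc); GET(hes7_d_pc); GET(hes7_v_sat); GET(hes7_k_sat);
  GET(hes7_K_nicd); GET(hes7_h_nicd); GET(hes7_K_self); GET(hes7_h_self);
  GET(hes1_k_tr); GET(hes1_k_tl); GET(hes1_r_m); GET(hes1_r_in); GET(hes1_r_out);
  GET(hes1_d_mn); GET(hes1_d_mc_min); GET(hes1_d_mc_max); GET(hes1_K_fgf8);
  GET(hes1_h_fgf8); GET(hes1_d_pc); GET(hes1_v_sat); GET(hes1_k_sat);
  GET(hes1_K_nicd); GET(hes1_h_nicd); GET(hes1_K_self); GET(hes1_h_self);
  GET(lfng_k_tr); GET(lfng_k_tl); GET(lfng_r_m); GET(lfng_r_in); GET(lfng_r_out);
  GET(lfng_d_mn); GET(lfng_d_mc); GET(lfng_d_pc); GET(lfng_v_sat); GET(lfng_k_sat);
  GET(lfng_K_nicd); GET(lfng_h_nicd); GET(lfng_K_hes7); GET(lfng_h_hes7);
  GET(mesp2_k_tr); GET(mesp2_k_tl); GET(mesp2_r_m); GET(mesp2_r_in); GET(mesp2_r_out);
  GET(mesp2_d_mn); GET(mesp2_d_mc); GET(mesp2_d_pc); GET(mesp2_v_sat); GET(mesp2_k_sat);
  GET(mesp2_K_nicd); GET(mesp2_h_nicd); GET(mesp2_K_tbx6); GET(mesp2_h_tbx6);
  GET(mesp2_K_fgf8); GET(mesp2_h_fgf8); GET(mesp2_K_ripply2); GET(mesp2_h_ripply2);
  GET(ripply2_k_tr); GET(ripply2_k_tl); GET(ripply2_r_m); GET(ripply2_r_in);
  GET(ripply2_r_out); GET(ripply2_d_mn); GET(ripply2_d_mc); GET(ripply2_d_pc);
  GET(ripply2_v_sat); GET(ripply2_k_sat); GET(ripply2_K_mesp2); GET(ripply2_h_mesp2);
  GET(dll1_k_tr); GET(dll1_k_tl); GET(dll1_r_m); GET(dll1_r_mem);
  GET(dll1_d_mn); GET(dll1_d_mc); GET(dll1_d_pc); GET(dll1_d_pm);
  GET(dll1_K_tbx6); GET(dll1_h_tbx6); GET(dll1_K_wnt); GET(dll1_h_wnt);
  GET(dll1_K_hes7); GET(dll1_h_hes7);
  GET(notch1_k_tr); GET(notch1_k_tl); GET(notch1_r_mem);
  GET(notch1_d_m); GET(notch1_d_pc); GET(notch1_d_pm);
  GET(notch1_K_wnt); GET(notch1_h_wnt);
  GET(nicd_r_in); GET(nicd_r_out); GET(nicd_d_c); GET(nicd_g_base); GET(nicd_g_max);
  GET(nicd_K_wnt); GET(nicd_h_wnt); GET(nicd_const_prod);
  GET(k_dn); GET(lfng_K_mod); GET(lfng_h_mod); GET(lfng_eps);
  GET(tbx6_k_tr); GET(tbx6_k_tl); GET(tbx6_d_m); GET(tbx6_d_p);
  GET(tbx6_K_wnt); GET(tbx6_h_wnt);
  GET(fgf8_k_tr); GET(fgf8_k_tl); GET(fgf8_d_m); GET(fgf8_d_p);
  GET(wnt3a_k_tr); GET(wnt3a_k_tl); GET(wnt3a_d_m); GET(wnt3a_d_p);
  GET(epha4_k_tr); GET(epha4_k_tl); GET(epha4_r_m); GET(epha4_d_mn);
  GET(epha4_d_mc); GET(epha4_d_pc); GET(epha4_K_mesp2); GET(epha4_h_mesp2);
  GET(epha4_threshold);
  GET(hes7_d_pn_min); GET(hes7_d_pn_max); GET(hes7_K_fgf8); GET(hes7_h_fgf8);
  GET(hes7_d_mc_max);
#undef GET
  std::string lm = as<std::string>(p["lfng_mode"]);
  q.lfng_mode = (lm == "off") ? 0 : (lm == "inhibiting") ? 1 : 2;
  std::string gc = as<std::string>(p["gradient_coupling"]);
  q.gradient_coupling = (gc == "wnt_nicd") ? 0 : (gc == "fgf_hes7_protein") ? 1 : 2;
  std::string dr = as<std::string>(p["dll1_repressor"]);
  q.dll1_repressor = (dr == "hes7") ? 0 : 1;
  return q;
}

static inline double hact(double x, double K, double h) {
  double r = std::pow(x / K, h);
  return r / (1.0 + r);
}
static inline double hinh(double x, double K, double h) {
  return 1.0 / (1.0 + std::pow(x / K, h));
}

struct Topo {
  std::vector<int> idx;  // concatenated 0-based neighbour indices
  std::vector<int> ptr;  // size n+1
};

// S, dS are column-major n x NSPEC
static void rhs(const std::vector<double>& S, std::vector<double>& dS,
                int n, const Pars& q, const Topo& topo,
                const std::vector<int>& in_gz,
                bool use_env, double wnt_env, double fgf_env, double wnt_decay_env,
                std::vector<double>& scratch) {
  const double* s = S.data();
  double* d = dS.data();
#define COL(k) (s + (size_t)(k) * n)
#define DCOL(k) (d + (size_t)(k) * n)

  // neighbour averages: W, F, Dll1_mem; donor return coefficient
  double* W  = scratch.data();
  double* Fg = scratch.data() + n;
  double* Dn = scratch.data() + 2 * n;
  double* kmodN = scratch.data() + 3 * n;
  double* donor = scratch.data() + 4 * n;

  const double* wnt_p = COL(WNT3A_P);
  const double* fgf_p = COL(FGF8_P);
  const double* dll_pm = COL(DLL1_PM);
  const double* lfng_pc = COL(LFNG_PC);
  const double* notch_pm = COL(NOTCH1_PM);

  for (int i = 0; i < n; ++i) {
    int a = topo.ptr[i], b = topo.ptr[i + 1];
    double sw = 0, sf = 0, sd = 0;
    for (int k = a; k < b; ++k) {
      int j = topo.idx[k];
      sw += wnt_p[j]; sf += fgf_p[j]; sd += dll_pm[j];
    }
    double m = (b > a) ? 1.0 / (b - a) : 0.0;
    W[i] = use_env ? wnt_env : sw * m;
    Fg[i] = use_env ? fgf_env : sf * m;
    Dn[i] = sd * m;
    double mod;
    if (q.lfng_mode == 0) mod = 1.0;
    else if (q.lfng_mode == 1) mod = hinh(lfng_pc[i], q.lfng_K_mod, q.lfng_h_mod);
    else mod = hact(lfng_pc[i], q.lfng_K_mod, q.lfng_h_mod) + q.lfng_eps;
    kmodN[i] = q.k_dn * mod * notch_pm[i];
    donor[i] = 0.0;
  }
  for (int i = 0; i < n; ++i) {
    int a = topo.ptr[i], b = topo.ptr[i + 1];
    if (b == a) continue;
    double v = kmodN[i] / (b - a);
    for (int k = a; k < b; ++k) donor[topo.idx[k]] += v;
  }

  for (int i = 0; i < n; ++i) {
    double flux = kmodN[i] * Dn[i];
    double Wd = use_env ? wnt_decay_env : W[i];
    double g_nic, hes7_extra_pn = 0.0, hes7_d_mc_eff = q.hes7_d_mc;
    if (q.gradient_coupling == 0) {
      g_nic = q.nicd_g_base + (q.nicd_g_max - q.nicd_g_base) *
              hinh(Wd, q.nicd_K_wnt, q.nicd_h_wnt);
    } else if (q.gradient_coupling == 1) {
      g_nic = q.nicd_g_base;
      hes7_extra_pn = q.hes7_d_pn_min + (q.hes7_d_pn_max - q.hes7_d_pn_min) *
                      hact(Fg[i], q.hes7_K_fgf8, q.hes7_h_fgf8);
    } else {
      g_nic = q.nicd_g_base;
      hes7_d_mc_eff = q.hes7_d_mc + (q.hes7_d_mc_max - q.hes7_d_mc) *
                      hact(Fg[i], q.hes7_K_fgf8, q.hes7_h_fgf8);
    }

    // Hes7
    {
      double prom = hact(s[NICD_N * n + i], q.hes7_K_nicd, q.hes7_h_nicd) *
                    hinh(s[HES7_PN * n + i], q.hes7_K_self, q.hes7_h_self);
      double mn = s[HES7_MN * n + i], mc = s[HES7_MC * n + i],
             pc = s[HES7_PC * n + i], pn = s[HES7_PN * n + i];
      d[HES7_MN * n + i] = q.hes7_k_tr * prom - (q.hes7_r_m + q.hes7_d_mn) * mn;
      d[HES7_MC * n + i] = q.hes7_r_m * mn - hes7_d_mc_eff * mc;
      d[HES7_PC * n + i] = q.hes7_k_tl * mc - (q.hes7_r_in + q.hes7_d_pc) * pc +
                           q.hes7_r_out * pn;
      d[HES7_PN * n + i] = q.hes7_r_in * pc - q.hes7_r_out * pn -
                           q.hes7_v_sat * pn / (q.hes7_k_sat + pn) -
                           hes7_extra_pn * pn;
    }
    // Hes1
    {
      double dmc = q.hes1_d_mc_min + (q.hes1_d_mc_max - q.hes1_d_mc_min) *
                   hact(Fg[i], q.hes1_K_fgf8, q.hes1_h_fgf8);
      double prom = hact(s[NICD_N * n + i], q.hes1_K_nicd, q.hes1_h_nicd) *
                    hinh(s[HES1_PN * n + i], q.hes1_K_self, q.hes1_h_self);
      double mn = s[HES1_MN * n + i], mc = s[HES1_MC * n + i],
             pc = s[HES1_PC * n + i], pn = s[HES1_PN * n + i];
      d[HES1_MN * n + i] = q.hes1_k_tr * prom - (q.hes1_r_m + q.hes1_d_mn) * mn;
      d[HES1_MC * n + i] = q.hes1_r_m * mn - dmc * mc;
      d[HES1_PC * n + i] = q.hes1_k_tl * mc - (q.hes1_r_in + q.hes1_d_pc) * pc +
                           q.hes1_r_out * pn;
      d[HES1_PN * n + i] = q.hes1_r_in * pc - q.hes1_r_out * pn -
                           q.hes1_v_sat * pn / (q.hes1_k_sat + pn);
    }
    // Lfng
    {
      double prom = hact(s[NICD_N * n + i], q.lfng_K_nicd, q.lfng_h_nicd) *
                    hinh(s[HES7_PN * n + i], q.lfng_K_hes7, q.lfng_h_hes7);
      double mn = s[LFNG_MN * n + i], mc = s[LFNG_MC * n + i],
             pc = s[LFNG_PC * n + i], pn = s[LFNG_PN * n + i];
      d[LFNG_MN * n + i] = q.lfng_k_tr * prom - (q.lfng_r_m + q.lfng_d_mn) * mn;
      d[LFNG_MC * n + i] = q.lfng_r_m * mn - q.lfng_d_mc * mc;
      d[LFNG_PC * n + i] = q.lfng_k_tl * mc - (q.lfng_r_in + q.lfng_d_pc) * pc +
                           q.lfng_r_out * pn;
      d[LFNG_PN * n + i] = q.lfng_r_in * pc - q.lfng_r_out * pn -
                           q.lfng_v_sat * pn / (q.lfng_k_sat + pn);
    }
    // Mesp2
    {
      double prom = hact(s[NICD_N * n + i], q.mesp2_K_nicd, q.mesp2_h_nicd) *
                    hact(s[TBX6_P * n + i], q.mesp2_K_tbx6, q.mesp2_h_tbx6) *
                    hinh(Fg[i], q.mesp2_K_fgf8, q.mesp2_h_fgf8) *
                    hinh(s[RIPPLY2_PN * n + i], q.mesp2_K_ripply2, q.mesp2_h_ripply2);
      double mn = s[MESP2_MN * n + i], mc = s[MESP2_MC * n + i],
             pc = s[MESP2_PC * n + i], pn = s[MESP2_PN * n + i];
      d[MESP2_MN * n + i] = q.mesp2_k_tr * prom - (q.mesp2_r_m + q.mesp2_d_mn) * mn;
      d[MESP2_MC * n + i] = q.mesp2_r_m * mn - q.mesp2_d_mc * mc;
      d[MESP2_PC * n + i] = q.mesp2_k_tl * mc - (q.mesp2_r_in + q.mesp2_d_pc) * pc +
                            q.mesp2_r_out * pn;
      d[MESP2_PN * n + i] = q.mesp2_r_in * pc - q.mesp2_r_out * pn -
                            q.mesp2_v_sat * pn / (q.mesp2_k_sat + pn);
    }
    // Ripply2
    {
      double prom = hact(s[MESP2_PN * n + i], q.ripply2_K_mesp2, q.ripply2_h_mesp2);
      double mn = s[RIPPLY2_MN * n + i], mc = s[RIPPLY2_MC * n + i],
             pc = s[RIPPLY2_PC * n + i], pn = s[RIPPLY2_PN * n + i];
      d[RIPPLY2_MN * n + i] = q.ripply2_k_tr * prom - (q.ripply2_r_m + q.ripply2_d_mn) * mn;
      d[RIPPLY2_MC * n + i] = q.ripply2_r_m * mn - q.ripply2_d_mc * mc;
      d[RIPPLY2_PC * n + i] = q.ripply2_k_tl * mc - (q.ripply2_r_in + q.ripply2_d_pc) * pc +
                              q.ripply2_r_out * pn;
      d[RIPPLY2_PN * n + i] = q.ripply2_r_in * pc - q.ripply2_r_out * pn -
                              q.ripply2_v_sat * pn / (q.ripply2_k_sat + pn);
    }
    // Dll1
    {
      double repr = (q.dll1_repressor == 0) ? s[HES7_PN * n + i] : s[HES1_PN * n + i];
      double prom = hact(s[TBX6_P * n + i], q.dll1_K_tbx6, q.dll1_h_tbx6) *
                    hact(W[i], q.dll1_K_wnt, q.dll1_h_wnt) *
                    hinh(repr, q.dll1_K_hes7, q.dll1_h_hes7);
      double mn = s[DLL1_MN * n + i], mc = s[DLL1_MC * n + i],
             pc = s[DLL1_PC * n + i], pm = s[DLL1_PM * n + i];
      d[DLL1_MN * n + i] = q.dll1_k_tr * prom - (q.dll1_r_m + q.dll1_d_mn) * mn;
      d[DLL1_MC * n + i] = q.dll1_r_m * mn - q.dll1_d_mc * mc;
      d[DLL1_PC * n + i] = q.dll1_k_tl * mc - (q.dll1_r_mem + q.dll1_d_pc) * pc;
      d[DLL1_PM * n + i] = q.dll1_r_mem * pc - q.dll1_d_pm * pm - pm * donor[i];
    }
    // Notch1
    {
      double m = s[NOTCH1_M * n + i], pc = s[NOTCH1_PC * n + i],
             pm = s[NOTCH1_PM * n + i];
      d[NOTCH1_M * n + i] = q.notch1_k_tr * hact(W[i], q.notch1_K_wnt, q.notch1_h_wnt) -
                            q.notch1_d_m * m;
      d[NOTCH1_PC * n + i] = q.notch1_k_tl * m - (q.notch1_r_mem + q.notch1_d_pc) * pc;
      d[NOTCH1_PM * n + i] = q.notch1_r_mem * pc - q.notch1_d_pm * pm - flux;
    }
    // NICD
    {
      double cc = s[NICD_C * n + i], cn = s[NICD_N * n + i];
      d[NICD_C * n + i] = flux + q.nicd_const_prod -
                          (q.nicd_r_in + q.nicd_d_c) * cc + q.nicd_r_out * cn;
      d[NICD_N * n + i] = q.nicd_r_in * cc - q.nicd_r_out * cn - g_nic * cn;
    }
    // Tbx6
    {
      double m = s[TBX6_M * n + i], pp = s[TBX6_P * n + i];
      d[TBX6_M * n + i] = q.tbx6_k_tr * hact(W[i], q.tbx6_K_wnt, q.tbx6_h_wnt) -
                          q.tbx6_d_m * m;
      d[TBX6_P * n + i] = q.tbx6_k_tl * m - q.tbx6_d_p * pp;
    }
    // gradients
    {
      double gz = in_gz[i] ? 1.0 : 0.0;
      d[FGF8_M * n + i] = q.fgf8_k_tr * gz - q.fgf8_d_m * s[FGF8_M * n + i];
      d[FGF8_P * n + i] = q.fgf8_k_tl * s[FGF8_M * n + i] -
                          q.fgf8_d_p * s[FGF8_P * n + i];
      d[WNT3A_M * n + i] = q.wnt3a_k_tr * gz - q.wnt3a_d_m * s[WNT3A_M * n + i];
      d[WNT3A_P * n + i] = q.wnt3a_k_tl * s[WNT3A_M * n + i] -
                           q.wnt3a_d_p * s[WNT3A_P * n + i];
    }
    // Epha4
    {
      double prom = hact(s[MESP2_PN * n + i], q.epha4_K_mesp2, q.epha4_h_mesp2);
      double mn = s[EPHA4_MN * n + i], mc = s[EPHA4_MC * n + i],
             pc = s[EPHA4_PC * n + i];
      d[EPHA4_MN * n + i] = q.epha4_k_tr * prom - (q.epha4_r_m + q.epha4_d_mn) * mn;
      d[EPHA4_MC * n + i] = q.epha4_r_m * mn - q.epha4_d_mc * mc;
      d[EPHA4_PC * n + i] = q.epha4_k_tl * mc - q.epha4_d_pc * pc;
    }
  }
#undef COL
#undef DCOL
}

// [[Rcpp::export(name = ".rk4_segment")]]
List rk4_segment(NumericMatrix state, List params,
                 IntegerVector nbr_idx, IntegerVector nbr_ptr,
                 LogicalVector in_gz,
                 double dt, int n_steps,
                 double t0, int rec_stride,
                 IntegerVector rec_species,
                 bool use_env, double wnt_env, double fgf_env,
                 double wnt_decay_env, double epha4_threshold) {
  int n = state.nrow();
  if (state.ncol() != NSPEC) stop("state must have 38 columns");
  Pars q = unpack(params);
  Topo topo;
  topo.idx.assign(nbr_idx.begin(), nbr_idx.end());
  topo.ptr.assign(nbr_ptr.begin(), nbr_ptr.end());
  std::vector<int> gz(n);
  for (int i = 0; i < n; ++i) gz[i] = in_gz[i] ? 1 : 0;

  size_t m = (size_t)n * NSPEC;
  std::vector<double> S(m), k1(m), k2(m), k3(m), k4(m), tmp(m), scratch(5 * n);
  for (int j = 0; j < NSPEC; ++j)
    for (int i = 0; i < n; ++i) S[(size_t)j * n + i] = state(i, j);

  int nrec_sp = rec_species.size();
  int nrec_t = (rec_stride > 0) ? n_steps / rec_stride : 0;
  NumericVector rec((size_t)nrec_t * n * nrec_sp);
  NumericVector rec_times(nrec_t);
  NumericVector epi_time(n, NA_REAL);
  // cells already above threshold at entry count as epithelialized at t0
  for (int i = 0; i < n; ++i)
    if (S[(size_t)EPHA4_PC * n + i] >= epha4_threshold) epi_time[i] = t0;

  long clamp_events = 0;
  double worst_neg = 0.0;
  int ri = 0;
  for (int step = 0; step < n_steps; ++step) {
    rhs(S, k1, n, q, topo, gz, use_env, wnt_env, fgf_env, wnt_decay_env, scratch);
    for (size_t u = 0; u < m; ++u) {
      double v = S[u] + 0.5 * dt * k1[u];
      tmp[u] = v > 0 ? v : 0;
    }
    rhs(tmp, k2, n, q, topo, gz, use_env, wnt_env, fgf_env, wnt_decay_env, scratch);
    for (size_t u = 0; u < m; ++u) {
      double v = S[u] + 0.5 * dt * k2[u];
      tmp[u] = v > 0 ? v : 0;
    }
    rhs(tmp, k3, n, q, topo, gz, use_env, wnt_env, fgf_env, wnt_decay_env, scratch);
    for (size_t u = 0; u < m; ++u) {
      double v = S[u] + dt * k3[u];
      tmp[u] = v > 0 ? v : 0;
    }
    rhs(tmp, k4, n, q, topo, gz, use_env, wnt_env, fgf_env, wnt_decay_env, scratch);
    for (size_t u = 0; u < m; ++u) {
      double v = S[u] + dt / 6.0 * (k1[u] + 2.0 * k2[u] + 2.0 * k3[u] + k4[u]);
      if (v < 0) {
        if (v < worst_neg) worst_neg = v;
        if (v < -1e-9) ++clamp_events;
        v = 0;
      }
      if (!std::isfinite(v)) {
        stop("non-finite state at t=%f, cell %d, variable %d",
             t0 + (step + 1) * dt, (int)(u % n) + 1, (int)(u / n) + 1);
      }
      S[u] = v;
    }
    double t_now = t0 + (step + 1) * dt;
    for (int i = 0; i < n; ++i) {
      if (NumericVector::is_na(epi_time[i]) &&
          S[(size_t)EPHA4_PC * n + i] >= epha4_threshold) {
        epi_time[i] = t_now;
      }
    }
    if (rec_stride > 0 && (step + 1) % rec_stride == 0) {
      for (int sp = 0; sp < nrec_sp; ++sp) {
        int col = rec_species[sp];
        for (int i = 0; i < n; ++i) {
          rec[((size_t)sp * nrec_t + ri) * n + i] = S[(size_t)col * n + i];
        }
      }
      rec_times[ri] = t_now;
      ++ri;
    }
  }

  NumericMatrix out(n, NSPEC);
  for (int j = 0; j < NSPEC; ++j)
    for (int i = 0; i < n; ++i) out(i, j) = S[(size_t)j * n + i];
  out.attr("dimnames") = state.attr("dimnames");

  return List::create(
    _["state"] = out,
    _["recorded"] = rec,           // layout: [cell, time, species] flattened
    _["rec_times"] = rec_times,
    _["epi_time"] = epi_time,
    _["clamp_events"] = (double)clamp_events,
    _["worst_neg"] = worst_neg
  );
}

// Single RHS evaluation, exposed for the R/C++ cross-check and the
// conservation-ledger test.
// [[Rcpp::export(name = ".rhs_eval")]]
List rhs_eval(NumericMatrix state, List params,
              IntegerVector nbr_idx, IntegerVector nbr_ptr,
              LogicalVector in_gz,
              bool use_env, double wnt_env, double fgf_env,
              double wnt_decay_env) {
  int n = state.nrow();
  Pars q = unpack(params);
  Topo topo;
  topo.idx.assign(nbr_idx.begin(), nbr_idx.end());
  topo.ptr.assign(nbr_ptr.begin(), nbr_ptr.end());
  std::vector<int> gz(n);
  for (int i = 0; i < n; ++i) gz[i] = in_gz[i] ? 1 : 0;
  size_t m = (size_t)n * NSPEC;
  std::vector<double> S(m), D(m), scratch(5 * n);
  for (int j = 0; j < NSPEC; ++j)
    for (int i = 0; i < n; ++i) S[(size_t)j * n + i] = state(i, j);
  rhs(S, D, n, q, topo, gz, use_env, wnt_env, fgf_env, wnt_decay_env, scratch);
  NumericMatrix out(n, NSPEC);
  for (int j = 0; j < NSPEC; ++j)
    for (int i = 0; i < n; ++i) out(i, j) = D[(size_t)j * n + i];
  out.attr("dimnames") = state.attr("dimnames");
  return List::create(_["deriv"] = out);
}
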