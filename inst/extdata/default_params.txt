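# psmclock parameter set (flat key = value)
hes7_k_tr = 0.20260444393400001
hes7_k_tl = 0.10130222196700001
hes7_r_m = 0.20260444393400001
hes7_r_in = 0.10130222196700001
hes7_r_out = 0.020260444393400003
hes7_d_mn = 0.00202604443934
hes7_d_mc = 0.03140368880977
hes7_d_pc = 0.03140368880977
hes7_v_sat = 0.15195333295050001
hes7_k_sat = 0.02
hes7_K_nicd = 5
hes7_h_nicd = 2
hes7_K_self = 1
hes7_h_self = 2
hes1_k_tr = 0.20260444393400001
hes1_k_tl = 0.10130222196700001
hes1_r_m = 0.20260444393400001
hes1_r_in = 0.10130222196700001
hes1_r_out = 0.020260444393400003
hes1_d_mn = 0.00202604443934
hes1_d_mc_min = 0.00810417775736
hes1_d_mc_max = 0.03140368880977
hes1_K_fgf8 = 1
hes1_h_fgf8 = 1
hes1_d_pc = 0.03140368880977
hes1_v_sat = 0.15195333295050001
hes1_k_sat = 0.02
hes1_K_nicd = 5
hes1_h_nicd = 2
hes1_K_self = 1
hes1_h_self = 3
lfng_k_tr = 0.20260444393400001
lfng_k_tl = 0.10130222196700001
lfng_r_m = 0.20260444393400001
lfng_r_in = 0.10130222196700001
lfng_r_out = 0.020260444393400003
lfng_d_mn = 0.00202604443934
lfng_d_mc = 0.03140368880977
lfng_d_pc = 0.03140368880977
lfng_v_sat = 0.15195333295050001
lfng_k_sat = 0.02
lfng_K_nicd = 5
lfng_h_nicd = 2
lfng_K_hes7 = 1
lfng_h_hes7 = 2
mesp2_k_tr = 0.20000000000000001
mesp2_k_tl = 0.29999999999999999
mesp2_r_m = 0.20000000000000001
mesp2_r_in = 0.10000000000000001
mesp2_r_out = 0.02
mesp2_d_mn = 0.002
mesp2_d_mc = 0.062
mesp2_d_pc = 0.062
mesp2_v_sat = 0.14999999999999999
mesp2_k_sat = 0.050000000000000003
mesp2_K_nicd = 4
mesp2_h_nicd = 2
mesp2_K_tbx6 = 1
mesp2_h_tbx6 = 2
mesp2_K_fgf8 = 1
mesp2_h_fgf8 = 4
mesp2_K_ripply2 = 1
mesp2_h_ripply2 = 2
ripply2_k_tr = 0.20000000000000001
ripply2_k_tl = 0.29999999999999999
ripply2_r_m = 0.20000000000000001
ripply2_r_in = 0.10000000000000001
ripply2_r_out = 0.02
ripply2_d_mn = 0.002
ripply2_d_mc = 0.062
ripply2_d_pc = 0.062
ripply2_v_sat = 0.14999999999999999
ripply2_k_sat = 0.050000000000000003
ripply2_K_mesp2 = 1
ripply2_h_mesp2 = 2
dll1_k_tr = 2.0260444393400001
dll1_k_tl = 6.0781333180200008
dll1_r_m = 0.070911555376900012
dll1_r_mem = 1.0130222196700001
dll1_d_mn = 0.00202604443934
dll1_d_mc = 0.057742266521190008
dll1_d_pc = 0.15701844404885001
dll1_d_pm = 0.15701844404885001
dll1_K_tbx6 = 1
dll1_h_tbx6 = 3
dll1_K_wnt = 1
dll1_h_wnt = 1
dll1_K_hes7 = 0.45000000000000001
dll1_h_hes7 = 2
notch1_k_tr = 0.10130222196700001
notch1_k_tl = 9.1171999770300012
notch1_r_mem = 1.0130222196700001
notch1_d_m = 0.023299511052410002
notch1_d_pc = 0.15701844404885001
notch1_d_pm = 0.15701844404885001
notch1_K_wnt = 1
notch1_h_wnt = 3
nicd_r_in = 1.0130222196700001
nicd_r_out = 0.10130222196700001
nicd_d_c = 0.15701844404885001
nicd_g_base = 0.050651110983500003
nicd_g_max = 24.312533272080003
nicd_K_wnt = 0.34999999999999998
nicd_h_wnt = 2
nicd_const_prod = 0
k_dn = 0.45023209763111111
lfng_mode = inhibiting
lfng_K_mod = 20
lfng_h_mod = 2
lfng_eps = 0.050000000000000003
tbx6_k_tr = 0.01
tbx6_k_tl = 0.10000000000000001
tbx6_d_m = 0.0050000000000000001
tbx6_d_p = 0.069000000000000006
tbx6_K_wnt = 1
tbx6_h_wnt = 3
fgf8_k_tr = 0.0057762265046662105
fgf8_k_tl = 0.13862943611198905
fgf8_d_m = 0.0057762265046662105
fgf8_d_p = 0.034657359027997263
wnt3a_k_tr = 0.0057762265046662105
wnt3a_k_tl = 0.13862943611198905
wnt3a_d_m = 0.0057762265046662105
wnt3a_d_p = 0.034657359027997263
epha4_k_tr = 0.20000000000000001
epha4_k_tl = 0.050000000000000003
epha4_r_m = 0.20000000000000001
epha4_d_mn = 0.002
epha4_d_mc = 0.062
epha4_d_pc = 0.0040000000000000001
epha4_K_mesp2 = 1
epha4_h_mesp2 = 2
epha4_threshold = 2
gradient_coupling = wnt_nicd
dll1_repressor = hes7
hes7_d_pn_min = 0
hes7_d_pn_max = 0
hes7_K_fgf8 = 1
hes7_h_fgf8 = 1
hes7_d_mc_max = 0.062
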