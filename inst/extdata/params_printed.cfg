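# Printed rate constants and culture geometry (flat key = value format).
# k_s is the rounded printed value; the package default (336) makes the
# resting fixed point exactly 800 receptors/cell.
k_f = 9.0e8
k_r = 3.6
k_fe = 2.9e-2
k_re = 2.9e1
k_s = 3.6e2
k_syn = 1.2
k_endo = 0.42
k_int = 2.4
k_rec = 7.4
k_deg = 2.1
k_f_p = 1.3e9
k_r_p = 5.0e-2
k_fe_p = 4.0e-4
k_re_p = 4.0e-1
k_syn_p = 1.5
N_tot = 25000
V_m = 2e-4
V_e = 1e-14
xi_surf = 1.1e-9
xi_endo = 1.5e-8
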