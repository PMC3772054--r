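# State layout of the intermediate-affinity system. Counts are per cell
# (mean-field, real-valued); L and L_e are molar. deg_R/deg_C/deg_L and
# syn_total are cumulative sink/source accumulators used by the conservation
# tests, not dynamical species.
INTERMEDIATE_SPECIES <- c("R_s", "C_s", "R_e", "C_e", "L", "L_e")
INTERMEDIATE_ACCUM <- c("deg_R", "deg_C", "syn_total")
HIGH_SPECIES <- c(INTERMEDIATE_SPECIES, "C_s_p", "C_e_p", "Lam_s", "Lam_e")
HIGH_ACCUM <- c(INTERMEDIATE_ACCUM, "deg_C_p", "syn_alpha")
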