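#!/usr/bin/env Rscript
# High-affinity dose response: activated NK cells upregulate IL-15Ra, which
# (pre-loaded with IL-15) acts as a membrane ligand for IL-15Rbg. Quantify
# the amplification of surface complex numbers over the intermediate model.

suppressPackageStartupMessages(library(il15nk))

p <- high_affinity_params()
g <- geometry_constants()
doses <- c(3.9 * 2^(0:7), 2000)

dir.create("results", showWarnings = FALSE)

rows <- lapply(doses, function(d) {
  ss <- steady_state_high_affinity(d, p, g)
  data.frame(dose_ng_ml = d, R_s = ss$R_s, C_s = ss$C_s, C_s_p = ss$C_s_p,
             total_complexes = ss$total_surface_complexes,
             trimeric_ratio = ss$C_s_p / ss$C_s,
             C_e = ss$C_e, C_e_p = ss$C_e_p,
             converged = ss$converged)
})
tab <- do.call(rbind, rows)
write.csv(tab, "results/high_affinity_steady_states.csv", row.names = FALSE)

message("High-affinity steady states:")
print(tab, digits = 4)
message(sprintf("\nTrimeric complexes outnumber intermediate ones %.1f-%.1f fold",
                min(tab$trimeric_ratio), max(tab$trimeric_ratio)))

fc <- fold_change_profile(doses, p, g)
write.csv(fc, "results/fold_change.csv", row.names = FALSE)
message("\nAmplification over the intermediate model (fold change):")
print(fc, digits = 3)
message(sprintf("Amplification is largest at the lowest dose (%.2f-fold at %.1f ng/ml) and fades toward saturation (%.2f-fold at 2000 ng/ml).",
                fc$fold_change[1], fc$dose_ng_ml[1],
                fc$fold_change[nrow(fc)]))
message("\nWrote results/high_affinity_steady_states.csv, results/fold_change.csv")
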