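# Shared fixtures: default parameter sets and the four experimental doses.
p_int <- intermediate_params()
p_high <- high_affinity_params()
geom <- geometry_constants()
th_printed <- threshold_model()
exp_doses <- c(9, 25, 50, 75)

# Random non-negative states for property-style derivative checks.
random_intermediate_state <- function() {
  c(R_s = runif(1, 0, 1000), C_s = runif(1, 0, 300),
    R_e = runif(1, 0, 500), C_e = runif(1, 0, 100),
    L = runif(1, 0, 2e-7), L_e = runif(1, 0, 1e-8),
    deg_R = 0, deg_C = 0, syn_total = 0)
}

random_high_state <- function() {
  c(R_s = runif(1, 0, 1000), C_s = runif(1, 0, 300),
    R_e = runif(1, 0, 500), C_e = runif(1, 0, 100),
    L = runif(1, 0, 2e-7), L_e = runif(1, 0, 1e-8),
    C_s_p = runif(1, 0, 300), C_e_p = runif(1, 0, 300),
    Lam_s = runif(1, 0, 200), Lam_e = runif(1, 0, 200),
    deg_R = 0, deg_C = 0, syn_total = 0, deg_C_p = 0, syn_alpha = 0)
}

# Recruitment datasets across the four doses in the layout recover_threshold
# expects (6 observation times between 40 and 90 h per dose).
make_recruitment_dataset <- function(seed, sd = 0.05, th = th_printed,
                                     Cs_ss = c(57.3, 116.7, 164.7, 190.9)) {
  do.call(rbind, lapply(seq_along(exp_doses), function(i) {
    d <- gen_recruitment_obs(exp_doses[i], seq(40, 90, by = 10), sd = sd,
                             seed = seed + i, th = th, Cs_ss = Cs_ss[i])
    d$Cs_ss <- Cs_ss[i]
    d
  }))
}
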