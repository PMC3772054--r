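test_that("with no ligand and no receptors, only constitutive synthesis acts", {
  s0 <- intermediate_initial_state(0, R_s0 = 0)
  drv <- intermediate_rhs(s0, p_int, geom)
  expect_equal(unname(drv["R_s"]), p_int$k_s)
  expect_equal(unname(drv["syn_total"]), p_int$k_s)
  others <- setdiff(names(drv), c("R_s", "syn_total"))
  expect_true(all(drv[others] == 0))
})

test_that("the unstimulated fixed point has zero derivatives", {
  s <- intermediate_initial_state(0, R_s0 = p_int$k_s / p_int$k_endo)
  s["R_e"] <- p_int$k_endo * s[["R_s"]] / p_int$k_deg  # endosomal balance
  drv <- intermediate_rhs(s, p_int, geom)
  dyn <- c("R_s", "C_s", "R_e", "C_e", "L", "L_e")
  expect_true(all(abs(drv[dyn]) < 1e-9))
})

test_that("receptor production balance holds for arbitrary states", {
  set.seed(101)
  for (i in 1:25) {
    s <- random_intermediate_state()
    drv <- intermediate_rhs(s, p_int, geom)
    # d/dt(receptor units) + degradation flux = synthesis flux
    lhs <- sum(drv[c("R_s", "C_s", "R_e", "C_e")]) +
      p_int$k_deg * (s[["R_e"]] + s[["C_e"]])
    expect_equal(lhs, p_int$k_s + p_int$k_syn * s[["C_s"]],
                 tolerance = 1e-10)
    # ligand units: media + endosomal + complexation + degradation close
    lig <- drv[["L"]] * geom$V_m +
      drv[["L_e"]] * geom$V_e * geom$N_tot +
      (drv[["C_s"]] + drv[["C_e"]] + drv[["deg_C"]]) * geom$N_tot / geom$N_A
    expect_equal(lig, 0, tolerance = 1e-20)
  }
})

test_that("the derivative rejects invalid states", {
  s <- intermediate_initial_state(1e-9)
  s["C_s"] <- -1
  expect_error(intermediate_rhs(s, p_int, geom), "negative")
  s <- intermediate_initial_state(NaN)
  expect_error(intermediate_rhs(s, p_int, geom), "non-finite")
})

test_that("simulation equilibrates onto the algebraic steady state within hours", {
  tc <- simulate_intermediate(25, p_int, geom, t_end = 48)
  ss <- steady_state_intermediate(25, p_int, geom)
  late <- tc$states[tc$states$time_h >= 6, ]
  expect_true(all(abs(late$C_s - ss$C_s) / ss$C_s < 0.02))
  expect_true(all(tc$states[, tc$species] >= 0))
})

test_that("zero-dose simulation holds the quiescent surface phenotype", {
  tc <- simulate_intermediate(0, p_int, geom, t_end = 48)
  expect_true(all(abs(tc$states$R_s - 800) < 1e-6))
  expect_true(all(abs(tc$states$C_s) < 1e-9))
})

test_that("steady-state complexes saturate at k_s / (k_int - k_syn)", {
  lim <- saturating_complexes(p_int)
  expect_equal(lim, p_int$k_s / (p_int$k_int - p_int$k_syn))
  huge <- steady_state_intermediate(dose(1e-4, "M"), p_int, geom)
  expect_equal(huge$C_s, lim, tolerance = 1e-3)
  p_bad <- p_int
  p_bad$k_int <- p_int$k_syn / 2
  expect_error(steady_state_intermediate(2000, p_bad, geom), "steady state")
  expect_error(saturating_complexes(p_bad), "k_int > k_syn")
})

test_that("complexes rise and free receptors fall monotonically with dose", {
  doses <- c(3.9, 9, 25, 75, 250, 2000)
  ss <- lapply(doses, steady_state_intermediate, p = p_int, g = geom)
  cs <- vapply(ss, `[[`, numeric(1), "C_s")
  rs <- vapply(ss, `[[`, numeric(1), "R_s")
  expect_true(all(diff(cs) > 0))
  expect_true(all(diff(rs) < 0))
  # ligand exposure downregulates total surface receptors below resting level
  expect_true(all(rs + cs < 800))
  # surface complexes outnumber endosomal ones at every dose
  ce <- vapply(ss, `[[`, numeric(1), "C_e")
  expect_true(all(cs > ce))
})

test_that("surface steady state is insensitive to the endosomal on-rate choice", {
  ss_printed <- steady_state_intermediate(25, p_int, geom)
  p_rule <- intermediate_params_kfe_rule()
  expect_equal(p_rule$k_fe, p_rule$k_f)
  tc_rule <- simulate_intermediate(25, p_rule, geom, t_end = 48)
  cs_rule <- tc_rule$states$C_s[nrow(tc_rule$states)]
  expect_equal(cs_rule, ss_printed$C_s, tolerance = 0.01)
})

test_that("timecourses serialize to tidy long CSV", {
  tc <- simulate_intermediate(9, p_int, geom, t_end = 24)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_timecourse(tc, csv)
  long <- utils::read.csv(csv)
  expect_setequal(names(long),
                  c("time_h", "species", "value", "unit", "dose_ng_ml"))
  expect_setequal(unique(long$species), c(tc$species, tc$accumulators))
  expect_equal(unique(long$dose_ng_ml), 9, tolerance = 1e-9)
  expect_equal(long$value[long$species == "L" & long$time_h == 0],
               dose_to_molar(dose(9, "ng/ml"), geom))
})
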