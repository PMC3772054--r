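test_that("the unit factor reproduces the unperturbed steady state exactly", {
  sc <- scan_parameter("intermediate", "k_f", factors = 1, d = 25)
  base <- simulate_intermediate(25, p_int, geom, t_end = 48)
  last <- base$states[nrow(base$states), ]
  expect_equal(scan_profile(sc, "C_s")$value, last$C_s)
  expect_equal(scan_profile(sc, "R_s")$value, last$R_s)
})

test_that("binding-rate perturbations move receptors and complexes oppositely", {
  f3 <- c(1/10, 1, 10)
  kf <- scan_parameter("intermediate", "k_f", factors = f3, d = 25)
  expect_true(all(diff(scan_profile(kf, "C_s")$value) > 0))
  expect_true(all(diff(scan_profile(kf, "R_s")$value) < 0))
  kr <- scan_parameter("intermediate", "k_r", factors = f3, d = 25)
  expect_true(all(diff(scan_profile(kr, "C_s")$value) < 0))
  expect_true(all(diff(scan_profile(kr, "R_s")$value) > 0))
})

test_that("trafficking and synthesis perturbations follow the expected signs", {
  f2 <- c(1, 10)
  ke <- scan_parameter("intermediate", "k_endo", factors = f2, d = 25)
  expect_lt(diff(scan_profile(ke, "R_s")$value), 0)
  expect_lt(diff(scan_profile(ke, "C_s")$value), 0)
  ki <- scan_parameter("intermediate", "k_int", factors = f2, d = 25)
  expect_lt(diff(scan_profile(ki, "C_s")$value), 0)
  rs_ki <- scan_profile(ki, "R_s")$value
  expect_lt(rs_ki[2], rs_ki[1])   # reduced ...
  expect_gt(rs_ki[2], 1)          # ... but not depleted
  ks <- scan_parameter("intermediate", "k_s", factors = f2, d = 25)
  expect_equal(scan_profile(ks, "C_s")$value[2],
               10 * scan_profile(ks, "C_s")$value[1], tolerance = 0.01)
  expect_equal(scan_profile(ks, "R_s")$value[2],
               10 * scan_profile(ks, "R_s")$value[1], tolerance = 0.01)
})

test_that("co-scaling k_f and k_r at fixed K_d blunts the complex gain", {
  f3 <- c(1, 10)
  only_kf <- scan_parameter("intermediate", "k_f", factors = f3, d = 25)
  fixed_kd <- scan_kf_kr_fixed_kd(factors = f3, d = 25)
  gain_kf <- diff(scan_profile(only_kf, "C_s")$value)
  gain_kd <- diff(scan_profile(fixed_kd, "C_s")$value)
  expect_gt(gain_kd, 0)
  expect_lt(gain_kd, gain_kf)
  expect_equal(unique(fixed_kd$K_d), p_int$k_r / p_int$k_f)
})

test_that("slow complex internalization is flagged as never reaching steady state", {
  sc <- scan_parameter("intermediate", "k_int", factors = c(1/100, 1), d = 25)
  flags <- unique(sc[, c("factor", "flag")])
  expect_false(flags$flag[flags$factor == 1/100] == "converged")
  expect_equal(flags$flag[flags$factor == 1], "converged")
  # dedicated classifier calls
  pk <- p_int
  pk$k_int <- p_int$k_int / 100
  expect_false(classify_steady_state(simulate_intermediate(25, pk, geom)) ==
                 "converged")
  expect_equal(classify_steady_state(simulate_intermediate(0, p_int, geom)),
               "converged")
  expect_error(classify_steady_state(simulate_intermediate(25, p_int, geom,
                                                           t_end = 12)),
               "24 h")
})

test_that("reduced complex internalization depletes receptors only with IL-15Ra", {
  f <- c(1/10, 1)
  hi <- scan_parameter("high", "k_int", factors = f, d = 25)
  lo <- scan_parameter("intermediate", "k_int", factors = f, d = 25)
  rs_hi <- scan_profile(hi, "R_s")$value
  rs_lo <- scan_profile(lo, "R_s")$value
  expect_lt(rs_hi[1], rs_hi[2])  # high model: fewer free receptors
  expect_gt(rs_lo[1], rs_lo[2])  # intermediate model: receptor build-up
})

test_that("unknown rate constants are rejected", {
  expect_error(scan_parameter("intermediate", "k_bogus"), "unknown rate")
  expect_error(scan_parameter("intermediate", "k_f", factors = c(-1, 1)))
})
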