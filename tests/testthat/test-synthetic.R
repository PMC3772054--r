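test_that("recruitment observations are seeded noise around an invariant truth", {
  th <- th_printed
  ts <- seq(40, 90, by = 10)
  noiseless <- gen_recruitment_obs(25, ts, sd = 0, seed = 5, th = th,
                                   Cs_ss = 116.7)
  expect_equal(noiseless$observed, noiseless$truth)
  a <- gen_recruitment_obs(25, ts, sd = 0.05, seed = 5, th = th, Cs_ss = 116.7)
  b <- gen_recruitment_obs(25, ts, sd = 0.05, seed = 5, th = th, Cs_ss = 116.7)
  c <- gen_recruitment_obs(25, ts, sd = 0.05, seed = 6, th = th, Cs_ss = 116.7)
  expect_identical(a, b)
  expect_false(all(a$observed == c$observed))
  expect_equal(a$truth, c$truth)  # truth independent of the noise draw
  expect_true(all(a$observed >= 0 & a$observed <= 1))
  expect_equal(a$truth, fractional_recruitment(116.7, ts, th))
  expect_error(gen_recruitment_obs(25, numeric(0), 0.05, 1, th, 116.7),
               "empty")
})

test_that("noisy recruitment data lands in the single-digit-to-teens NRMSD regime", {
  th <- th_printed
  vals <- sapply(1:20, function(s) {
    d <- gen_recruitment_obs(50, seq(40, 90, by = 10), sd = 0.05,
                             seed = s, th = th, Cs_ss = 164.7)
    nrmsd(d$truth, d$observed)
  })
  expect_true(all(vals > 0))
  expect_true(all(vals < 25))
})

test_that("division-count observations floor the truth and respect the CFSE cap", {
  th <- th_printed
  obs <- gen_max_division_obs(75, c(32, 60, 90), th = th, t_div = 8.2)
  expect_identical(obs$observed, c(0L, 3L, 7L))
  expect_true(all(diff(obs$observed) >= 0))
  late <- gen_max_division_obs(75, c(150, 300), th = th, t_div = 8.2)
  expect_true(all(late$observed == 8L))
  jit <- gen_max_division_obs(75, seq(40, 90, 5), th = th, t_div = 8.2,
                              seed = 9, jitter = 0.5)
  expect_true(all(jit$observed >= 0 & jit$observed <= 8))
  expect_error(gen_max_division_obs(75, 10, th = th, t_div = 8.2))
})

test_that("CFSE profiles are normalized mixtures with 2-fold cohort spacing", {
  pr <- gen_cfse_profile(4, cv = 0.05, seed = 21)
  expect_true(all(pr$density >= 0))
  expect_equal(sum(pr$density) * mean(diff(pr$grid)), 1, tolerance = 1e-6)
  expect_equal(diff(pr$means), rep(-1, 3))  # halving per division in log2
  expect_identical(gen_cfse_profile(4, cv = 0.05, seed = 21)$density,
                   pr$density)
  expect_error(gen_cfse_profile(3, weights = c(0.7, 0.6, -0.3)), "negative")
  expect_error(gen_cfse_profile(3, weights = c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("cohort decomposition recovers the generating weights and peak count", {
  w <- c(0.1, 0.25, 0.3, 0.2, 0.15)
  pr <- gen_cfse_profile(5, w, cv = 0.05, seed = 42)
  est <- estimate_cohort_fractions(pr)
  expect_equal(est$n_divisions, 5)
  expect_equal(sum(est$weights), 1)
  expect_true(all(abs(est$weights - w) <= 0.02))
  # equal weights over 4 cohorts: 4 modes
  eq <- estimate_cohort_fractions(gen_cfse_profile(4, cv = 0.04, seed = 7))
  expect_equal(eq$n_divisions, 4)
  # single cohort: unimodal with full weight
  one <- estimate_cohort_fractions(gen_cfse_profile(1, seed = 3))
  expect_equal(one$n_divisions, 1)
  expect_equal(one$weights, 1)
})

test_that("cohort recovery is stable to the histogram resolution", {
  w <- c(0.4, 0.35, 0.25)
  lo <- estimate_cohort_fractions(gen_cfse_profile(3, w, cv = 0.05, seed = 8,
                                                   grid_n = 256))
  hi <- estimate_cohort_fractions(gen_cfse_profile(3, w, cv = 0.05, seed = 8,
                                                   grid_n = 1024))
  expect_equal(lo$n_divisions, hi$n_divisions)
  expect_equal(lo$weights, hi$weights, tolerance = 0.02)
})

test_that("a flat profile has no detectable peak", {
  flat <- list(grid = seq(0, 10, length.out = 200), density = rep(0.1, 200))
  expect_error(estimate_cohort_fractions(flat), "flat profile")
})

test_that("seeded generation does not disturb the caller's RNG stream", {
  set.seed(99)
  x1 <- runif(1)
  set.seed(99)
  invisible(gen_cfse_profile(3, cv = 0.05, seed = 1))
  x2 <- runif(1)
  expect_identical(x1, x2)
})
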