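test_that("threshold and maximum stimulus are products of their factors", {
  expect_equal(cell_cycle_threshold(58.2, 37.8), 2198, tolerance = 1e-3)
  expect_equal(cell_cycle_threshold(1, 1), 1)
  expect_equal(cell_cycle_threshold(116, 37.8), 4384.8)
  expect_error(cell_cycle_threshold(0, 37.8), "positive")
  expect_equal(max_trigger_stimulus(257, 64), 16448)
  expect_equal(max_trigger_stimulus(0, 64), 0)
  expect_equal(max_trigger_stimulus(128.5, 64), 8224)
})

test_that("fractional recruitment clips at the threshold and at saturation", {
  th <- th_printed
  # boundary: cumulative stimulus exactly at threshold
  expect_equal(fractional_recruitment(58, th$Cs_threshold / 58, th), 0)
  expect_equal(fractional_recruitment(116, 64, th),
               (116 * 64 - 2198) / 16448)
  t_sat <- (th$Cs_threshold + th$max_stimulus) / 257  # ~72.6 h
  expect_equal(fractional_recruitment(257, t_sat, th), 1)
  expect_equal(fractional_recruitment(257, t_sat + 10, th), 1)
})

test_that("recruitment is monotone in stimulus and bounded in [0, 1]", {
  th <- th_printed
  ts <- seq(0, 120, by = 4)
  for (cs in c(30, 58, 116, 257)) {
    f <- fractional_recruitment(cs, ts, th)
    expect_true(all(f >= 0 & f <= 1))
    expect_true(all(diff(f) >= 0))
    # threshold-free variant dominates the thresholded one everywhere
    f0 <- fractional_recruitment_no_threshold(cs, ts, th)
    expect_true(all(f0 >= f))
  }
  cs_grid <- seq(10, 300, by = 10)
  f_cs <- fractional_recruitment(cs_grid, 64, th)
  expect_true(all(diff(f_cs) >= 0))
  expect_equal(fractional_recruitment_no_threshold(58, 0, th), 0)
  expect_equal(fractional_recruitment_no_threshold(116, 64, th), 0.451,
               tolerance = 1e-3)
})

test_that("interdivision times and rates reproduce the published table", {
  counts <- c(154, 224, 256, 270)
  tdiv <- interdivision_time(counts, th_printed)
  expect_equal(tdiv, c(14.2, 9.8, 8.6, 8.2), tolerance = 0.1 / 8.2)
  rates <- mean_division_rate(tdiv)
  expect_equal(rates, c(3.5, 5.1, 5.8, 6.1) * 1e-2, tolerance = 0.015)
  # definitional identities
  expect_equal(interdivision_time(2198, th_printed), 1)
  expect_equal(mean_division_rate(0.5), 1)
  expect_true(all(mean_division_rate(tdiv) * tdiv == 0.5))
  expect_warning(out <- interdivision_time(0, th_printed), "infinite")
  expect_identical(out, Inf)
  expect_error(mean_division_rate(0), "positive")
})

test_that("maximum divisions count interdivision times after the delay", {
  expect_equal(max_divisions(32, 32, 8.2), 0)
  expect_equal(max_divisions(20, 32, 8.2), 0)  # before the delay
  expect_equal(max_divisions(90, 32, 8.2), 58 / 8.2)
  expect_equal(max_divisions(90, 32, 8.2, floor = TRUE), 7)
  ts <- seq(32, 120, by = 2)
  expect_true(all(diff(max_divisions(ts, 32, 9.8)) >= 0))
  expect_true(all(max_divisions(80, 32, c(8, 10, 14)) ==
                    sort(max_divisions(80, 32, c(8, 10, 14)), decreasing = TRUE)))
})

test_that("threshold constants derive consistently from model steady states", {
  th <- derive_threshold_model(p_int, geom)
  cs9 <- steady_state_intermediate(9, p_int, geom)$C_s
  cs2000 <- steady_state_intermediate(2000, p_int, geom)$C_s
  expect_equal(th$Cs_threshold, cs9 * 37.8)
  expect_equal(th$max_stimulus, cs2000 * 64)
  expect_lt(th$Cs_threshold, th$max_stimulus)
  expect_error(threshold_model(Cs_threshold = 2e4, max_stimulus = 1e4))
})

test_that("the division table chains steady states into per-dose predictions", {
  tab <- division_table(c(9, 75), p_high, geom, th_printed, t_ref = 90)
  expect_equal(tab$t_div_h, th_printed$Cs_threshold / tab$total_Cs)
  expect_equal(tab$mean_rate_per_h, 1 / (2 * tab$t_div_h))
  expect_equal(tab$max_divisions, (90 - 32) / tab$t_div_h)
  expect_true(all(diff(tab$total_Cs) > 0))
})
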