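test_that("flat and declining segments use the right trapezoid rule", {
  # constant profile: both rules agree
  s <- concentration_series(c(0, 2), c(100, 100))
  expect_equal(auc_linlog(s), 200)
  # exponential decline over one segment: closed-form log trapezoid
  s <- concentration_series(c(0, 1), c(100, 50))
  expect_equal(auc_linlog(s), 50 / log(2), tolerance = 1e-12)
  # segment ending at zero falls back to the linear rule
  s <- concentration_series(c(0, 1), c(100, 0))
  expect_equal(auc_linlog(s), 50)
  # rising segment is linear
  s <- concentration_series(c(0, 1), c(50, 100))
  expect_equal(auc_linlog(s), 75)
})

test_that("linear-log AUC reproduces the mono-exponential closed form", {
  k <- log(2) / 1.5
  times <- seq(0, 10, length.out = 50)
  s <- concentration_series(times, 120 * exp(-k * times))
  expect_equal(auc_linlog(s), (120 / k) * (1 - exp(-k * 10)),
               tolerance = 1e-6)
})

test_that("AUC is additive and invariant to points on the interpolant", {
  set.seed(7)
  times <- sort(runif(12, 0, 10))
  conc <- 100 * exp(-0.4 * times) + 20 * exp(-0.05 * times)
  s <- concentration_series(times, conc)
  total <- auc_linlog(s)
  mid <- (times[5] + times[6]) / 2
  expect_equal(auc_linlog(s, times[1], mid) + auc_linlog(s, mid, times[12]),
               total, tolerance = 1e-9)
  # inserting the interpolated midpoint leaves the AUC unchanged
  cmid <- vblpbpk:::interp_linlog(times, conc, mid)
  s2 <- concentration_series(sort(c(times, mid)),
                             append(conc, cmid, after = 5))
  expect_equal(auc_linlog(s2), total, tolerance = 1e-9)
})

test_that("AUC input validation catches malformed series", {
  expect_error(concentration_series(c(0, 0), c(1, 1)), "increasing")
  expect_error(concentration_series(c(0, 1), c(1, -1)), "non-negative")
  expect_error(auc_linlog(concentration_series(0:2, c(1, 2, 3)), 0, 5),
               "within")
})

test_that("terminal half-life is exact for mono-exponential decay", {
  k <- log(2) / 2
  times <- seq(0, 8, by = 0.5)
  s <- concentration_series(times, 100 * exp(-k * times))
  hl <- terminal_half_life(s)
  expect_equal(hl$t_half, 2, tolerance = 1e-10)
  expect_equal(hl$r2, 1, tolerance = 1e-10)
  # scale invariance
  s10 <- concentration_series(times, 10 * 100 * exp(-k * times))
  expect_equal(terminal_half_life(s10)$t_half, hl$t_half, tolerance = 1e-12)
})

test_that("a rising profile reports no terminal phase instead of erroring", {
  s <- concentration_series(0:5, c(1, 2, 4, 6, 8, 10))
  hl <- terminal_half_life(s)
  expect_true(is.na(hl$t_half))
  expect_match(hl$reason, "terminal phase not achieved")
  # too few points after the maximum
  s2 <- concentration_series(0:2, c(1, 10, 5))
  expect_true(is.na(terminal_half_life(s2)$t_half))
})

test_that("last-k regression recovers the slow phase of a biexponential", {
  k_fast <- 5; k_slow <- 0.5
  times <- seq(0, 8, by = 0.5)
  s <- concentration_series(times, 100 * exp(-k_fast * times) +
                              10 * exp(-k_slow * times))
  hl <- terminal_half_life(s, min_points = 3)
  expect_equal(hl$t_half, log(2) / k_slow, tolerance = 0.05)
  hl_adaptive <- terminal_half_life(s, window = "best_r2")
  expect_equal(hl_adaptive$t_half, log(2) / k_slow, tolerance = 0.05)
})

test_that("extrapolated AUC adds the terminal tail", {
  k <- 0.25
  times <- seq(0, 12, by = 0.5)
  s <- concentration_series(times, 50 * exp(-k * times))
  expect_equal(auc_inf(s), 50 / k, tolerance = 1e-4)
})

test_that("the nca wrapper reports a simulated serum profile coherently", {
  row <- nca(mouse_sim("wild_type"))
  expect_equal(row$tissue, "blood")
  expect_gt(row$auc_nM_h, 0)
  expect_gt(row$t_half_h, 0)
  expect_equal(row$n_terminal_points, 3)
})
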