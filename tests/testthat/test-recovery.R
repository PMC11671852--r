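test_that("Gorgeous Year equals the brute-force per-month maximum", {
  set.seed(4)
  vals <- array(runif(264 * 2 * 2, 0.2, 0.9), c(264, 2, 2))
  cube <- make_monthly_cube(vals)
  gy <- compute_gorgeous_year(cube)
  for (r in 1:2) for (c in 1:2) {
    expect_equal(gy$gy[, r, c], brute_force_gy(vals[, r, c]))
    expect_equal(gy$gy_mean[r, c], mean(brute_force_gy(vals[, r, c])))
  }
  const <- compute_gorgeous_year(make_monthly_cube(array(0.5, c(264, 1, 1))))
  expect_equal(const$gy[, 1, 1], rep(0.5, 12))
  expect_equal(const$gy_mean[1, 1], 0.5)
  two <- array(0.5, c(24, 1, 1)); two[1, 1, 1] <- 0.3; two[13, 1, 1] <- 0.45
  expect_equal(compute_gorgeous_year(make_monthly_cube(two))$gy[1, 1, 1], 0.45)
})

test_that("loss series is the departure from GY, bounded in [-1, 0]", {
  set.seed(5)
  vals <- array(runif(264, 0.2, 0.9), c(264, 1, 1))
  cube <- make_monthly_cube(vals)
  gy <- compute_gorgeous_year(cube)
  y <- loss_series(cube, gy)
  expect_true(all(y <= 0 & y >= -1))
  expect_equal(max(y), 0)  # attained at each month's best year
  # identity: a cube equal to its GY has y identically zero
  gy_cube <- make_monthly_cube(array(rep(gy$gy[, 1, 1], 22), c(264, 1, 1)))
  expect_true(all(loss_series(gy_cube, compute_gorgeous_year(gy_cube)) == 0))
  # arithmetic: EVI 0.2 under GY 0.6 gives y = -0.4
  v2 <- array(0.6, c(24, 1, 1)); v2[13, 1, 1] <- 0.2
  cube2 <- make_monthly_cube(v2)
  expect_equal(loss_series(cube2, compute_gorgeous_year(cube2))[13, 1, 1], -0.4)
  # GY from a different (greener) cube is rejected
  gy_low <- compute_gorgeous_year(make_monthly_cube(vals - 0.1))
  expect_error(loss_series(cube, gy_low), "Gorgeous Year")
})

test_that("severity location finds the post-fire minimum with earliest-tie rule", {
  y <- rep(-0.05, 264)
  y[101] <- -0.5; y[100] <- -0.2
  s <- locate_severity(y, 100)
  expect_equal(s$a, -0.5); expect_equal(s$t0, 101L)
  # monotone recovery from the fire month itself
  y2 <- rep(0, 264); y2[100:110] <- -0.4 * exp(-0.2 * (0:10))
  s2 <- locate_severity(y2, 100)
  expect_equal(s2$t0, 100L)
  # ties break toward the earliest month
  y3 <- rep(0, 264); y3[100:103] <- -0.3
  expect_equal(locate_severity(y3, 100)$t0, 100L)
  expect_false(locate_severity(rep(NA_real_, 10), 2)$valid)
})

test_that("noiseless exponential deficits are fitted exactly for any window", {
  for (b in c(0.02, 0.05, 0.1, 0.3)) {
    y <- -0.4 * exp(-b * (0:263))
    fit <- fit_recovery(y, t0 = 1, a = -0.4, gy_mean = 0.6)
    expect_equal(fit$b, b, tolerance = 1e-10)
    expect_equal(fit$adj_r2, 1)
    expect_equal(fit$window_months, 24)   # perfect ties resolve to the shortest
    expect_true(fit$valid)
    expect_equal(fit$t_char * fit$b, 1)
    expect_equal(fit$a_rel, 0.4 / 0.6)
    # through-origin variant agrees in the noiseless case
    fit0 <- fit_recovery(y, 1, -0.4, intercept = FALSE)
    expect_equal(fit0$b, b, tolerance = 1e-10)
  }
})

test_that("the first event's fit window stops before the second fire", {
  y <- rep(0, 264)
  y[100:114] <- -0.4 * exp(-0.05 * (0:14))
  y[115:264] <- -0.9                       # second disturbance soon after
  fit <- fit_recovery(y, 100, -0.4, stop_before = 115)
  expect_equal(fit$b, 0.05, tolerance = 1e-10)
  expect_equal(fit$n_points, 15L)
  contaminated <- fit_recovery(y, 100, -0.4)  # every window hits the next fire
  expect_gt(abs(contaminated$b - 0.05), 1e-4)
})

test_that("scaling the deficit scales severity but not the rate", {
  set.seed(6)
  y <- pmin(0, -0.4 * exp(-0.07 * pmax(0:263 - 50, 0)) - (0:263 < 50) * 0.001)
  for (k in c(0.25, 0.5, 1)) {
    s <- locate_severity(k * y, 51)
    f <- fit_recovery(k * y, s$t0, s$a, gy_mean = 0.5)
    expect_equal(s$a, k * y[51], tolerance = 1e-12)
    expect_equal(f$b, 0.07, tolerance = 1e-9)
    expect_equal(f$a_rel, abs(k * y[51]) / 0.5, tolerance = 1e-12)
  }
})

test_that("lowering the r2 screen never invalidates a previously valid fit", {
  set.seed(7)
  for (i in 1:20) {
    y <- firerecov:::simulate_loss_series(264, 80, -0.3, 0.06, 0.04)
    s <- locate_severity(y, 80)
    f_strict <- fit_recovery(y, s$t0, s$a, r2_min = 0.25)
    f_loose <- fit_recovery(y, s$t0, s$a, r2_min = 0.10)
    if (isTRUE(f_strict$valid)) expect_true(f_loose$valid)
    expect_equal(f_strict$b, f_loose$b)  # screening only affects validity
  }
})

test_that("fits degrade gracefully on degenerate input", {
  expect_match(fit_recovery(rep(0, 264), 10, 0)$reason, "no loss")
  short <- c(rep(0, 9), -0.4 * exp(-0.05 * (0:5)), rep(0, 249))
  f <- fit_recovery(short, 10, -0.4)
  expect_false(f$valid)
  expect_match(f$reason, "too few usable points|no loss")
})

test_that("relative severity follows |a| / GY_MEAN with bare-pixel guard", {
  expect_equal(relative_severity(0, 0.6), 0)
  expect_equal(relative_severity(-0.3, 0.6), 0.5)
  expect_equal(relative_severity(-0.6, 0.3), 2)   # may exceed 1
  expect_true(is.na(relative_severity(-0.3, 0)))
})

test_that("pre-fire state is the median of the three preceding months", {
  y <- rep(0, 50)
  y[7:9] <- c(-0.1, -0.2, -0.3)
  expect_equal(prefire_state(y, 10), -0.2)
  expect_equal(prefire_state(rep(0, 50), 10), 0)
  expect_true(is.na(prefire_state(y, 3)))
  set.seed(8)
  for (i in 1:10) {
    y2 <- rnorm(20, -0.2, 0.1)
    expect_equal(prefire_state(y2, 15), sort(y2[12:14])[2])  # sort-and-middle
  }
})

test_that("confidence intervals bracket the estimate and widen with noise", {
  set.seed(9)
  y <- firerecov:::simulate_loss_series(264, 60, -0.4, 0.06, 0.02)
  s <- locate_severity(y, 60)
  f <- fit_recovery(y, s$t0, s$a)
  expect_lt(f$ci_low, f$b)
  expect_gt(f$ci_high, f$b)
  y2 <- firerecov:::simulate_loss_series(264, 60, -0.4, 0.06, 0)
  f2 <- fit_recovery(y2, 60, -0.4)
  expect_equal(f2$ci_low, f2$b)  # exact fit has zero-width interval
})
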