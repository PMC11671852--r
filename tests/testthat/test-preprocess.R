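test_that("an all-good cube passes through gap filling unchanged", {
  v <- 0.5 + 0.1 * sin(2 * pi * seq_len(23 * 4) / 23)
  cube <- make_raw_cube(v)
  out <- fill_low_quality(cube)
  expect_equal(out$values, cube$values)
  expect_equal(out$state, "gapfilled")
})

test_that("temporal interpolation restores constant and cubic series exactly", {
  # constant neighbourhood: a lone low-quality point takes the common value
  v <- rep(0.4, 23 * 3)
  q <- rep(FALSE, length(v)); q[30] <- TRUE
  v[30] <- 0.05  # contaminated
  out <- fill_low_quality(make_raw_cube(v, q))
  expect_equal(out$values[30, 1, 1], 0.4, tolerance = 1e-12)

  # cubic polynomial: the piecewise-cubic fill is exact at the gap date
  cube0 <- make_raw_cube(rep(0.5, 23 * 3))
  tt <- as.numeric(cube0$dates); ts <- (tt - mean(tt)) / 365
  poly <- 0.5 + 0.05 * ts + 0.02 * ts^2 - 0.01 * ts^3
  q <- rep(FALSE, length(poly)); q[40] <- TRUE
  vv <- poly; vv[40] <- 0
  out <- fill_low_quality(make_raw_cube(vv, q))
  expect_equal(out$values[40, 1, 1], poly[40], tolerance = 1e-8)
  expect_equal(out$values[-40, 1, 1], poly[-40])  # good values untouched
})

test_that("spatial fill uses the 8-neighbour mean of good observations", {
  n_t <- 23
  vals <- array(0.5, c(n_t, 3, 3))
  qual <- array(FALSE, c(n_t, 3, 3))
  vals[5, , ] <- matrix(c(0.3, 0.4, 0.5, 0.6, 0.1, 0.7, 0.8, 0.35, 0.45), 3, 3)
  qual[5, 2, 2] <- TRUE  # the centre is contaminated at one composite
  cube <- evi_cube(vals, composite_dates(2001, 2001), quality = qual,
                   state = "raw", start_year = 2001)
  out <- fill_low_quality(cube)
  nb <- c(0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.35, 0.45)
  expect_equal(out$values[5, 2, 2], mean(nb), tolerance = 1e-12)
})

test_that("pixels with almost no good observations are masked, not fatal", {
  v <- rep(0.5, 23 * 2)
  q <- rep(TRUE, length(v)); q[1:3] <- FALSE
  expect_message(out <- fill_low_quality(make_raw_cube(v, q)), "masked")
  expect_true(all(is.na(out$values)))
  expect_true(attr(out, "masked")[1, 1])
})

test_that("FFT low-pass keeps the annual harmonic and removes Nyquist noise", {
  n <- 23 * 22
  k <- seq_len(n)
  annual <- 0.5 + 0.1 * sin(2 * pi * k / 23)
  cube <- fill_low_quality(make_raw_cube(annual))
  sm <- fft_smooth(cube)
  expect_equal(sm$values[, 1, 1], annual, tolerance = 1e-9)

  noisy <- annual + 0.05 * (-1)^k  # alternating +/- at the Nyquist frequency
  sm2 <- fft_smooth(fill_low_quality(make_raw_cube(noisy)))
  expect_lt(max(abs(sm2$values[, 1, 1] - annual)), 1e-9)
})

test_that("FFT smoothing preserves the mean and never inflates variance", {
  set.seed(8)
  v <- pmin(1, pmax(0, 0.5 + 0.1 * sin(2 * pi * seq_len(23 * 10) / 23) +
                      rnorm(23 * 10, 0, 0.05)))
  cube <- fill_low_quality(make_raw_cube(v))
  sm <- fft_smooth(cube)
  expect_equal(mean(sm$values), mean(v), tolerance = 1e-9)
  expect_lte(stats::var(as.vector(sm$values)), stats::var(v))
  expect_error(fft_smooth(cube, keep_period_months = 0.5), "keep_period_months")
})

test_that("LOESS detrending removes a linear trend but not the mean", {
  n <- 23 * 22
  yearfrac <- (seq_len(n) - 1) / 23
  seasonal <- 0.5 + 0.08 * sin(2 * pi * seq_len(n) / 23)
  v <- seasonal + 0.01 * yearfrac
  cube <- fft_smooth(fill_low_quality(make_raw_cube(v)))
  out <- loess_detrend(cube)
  slope_after <- coef(lm(out$values[, 1, 1] ~ yearfrac))[2]
  expect_lt(abs(slope_after), 0.001)          # EVI/yr, from 0.01 EVI/yr
  expect_equal(mean(out$values), mean(cube$values), tolerance = 1e-9)

  const <- fft_smooth(fill_low_quality(make_raw_cube(rep(0.42, n))))
  out2 <- loess_detrend(const)
  expect_equal(out2$values[, 1, 1], rep(0.42, n), tolerance = 1e-6)
  expect_error(loess_detrend(cube, span_fraction = 0.05), "span_fraction")
})

test_that("monthly aggregation averages in-month composites", {
  n <- 23 * 22
  cube <- fill_low_quality(make_raw_cube(rep(0.37, n)))
  mo <- monthly_aggregate(cube)
  expect_equal(mo$state, "monthly")
  expect_length(mo$dates, 12 * 22)             # 264 monthly steps for 22 years
  expect_true(all(abs(mo$values - 0.37) < 1e-12))

  v <- rep(0.37, n); v[1] <- 0.2; v[2] <- 0.4  # January 2001 has composites 1 and 2
  mo2 <- monthly_aggregate(fill_low_quality(make_raw_cube(v)))
  expect_equal(mo2$values[1, 1, 1], 0.3)
})

test_that("land-cover aggregation follows the class mapping and rejects unknown codes", {
  codes <- c(70, 100, 20, 50, 90, 130, 40, 110, 150, 220, 80, 60, 10, 120, 30)
  expect_equal(as.character(aggregate_landcover(codes)),
               c("NL", "TW", "Cp", "BL", "MF", "Gs", "Shb", "Shb", "Oth",
                 "Oth", "NL", "BL", "Cp", "Shb", "Cp"))
  expect_error(aggregate_landcover(c(70, 135)), "135")
  m <- matrix(c(70, 100, 20, 50), 2, 2)
  expect_equal(dim(aggregate_landcover(m)), c(2L, 2L))
})

test_that("processing states enforce the fixed pipeline order", {
  v <- rep(0.5, 23 * 2)
  raw <- make_raw_cube(v)
  expect_error(fft_smooth(raw), "state")
  expect_error(monthly_aggregate(raw), "state")
  gap <- fill_low_quality(raw)
  expect_error(fill_low_quality(gap), "state")     # no silent re-application
  expect_error(loess_detrend(gap), "state")        # detrend only after smoothing
  sm <- fft_smooth(gap)
  expect_error(fft_smooth(sm), "state")
  expect_silent(monthly_aggregate(sm))
})
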