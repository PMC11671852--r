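make_climate <- function(precip, temp, years = 2001:2022, hemisphere = "north") {
  ny <- length(years)
  data.frame(cell = 1L, cell_row = 1L, cell_col = 1L,
             year = rep(years, each = 12), month = rep(1:12, ny),
             precip = precip, temp = temp, hemisphere = hemisphere)
}

test_that("constant series yield degenerate (zero-sd) seasonal climatologies", {
  clim <- make_climate(precip = 50, temp = 15)
  cl <- seasonal_climatology(clim)
  expect_true(all(cl$temp_mean == 15))
  expect_true(all(cl$temp_sd == 0))
  expect_true(all(cl$degenerate_temp))
  z <- standardized_anomaly(clim, cl)
  expect_true(all(is.na(z$z_temp)))
})

test_that("alternating warm/cold years give the direct sample sd per season", {
  years <- 2001:2022
  temp_offsets <- rep(c(1, -1), 11)[match(rep(years, each = 12), years)]
  clim <- make_climate(precip = 50, temp = 15 + temp_offsets)
  cl <- seasonal_climatology(clim)
  # DJF instances straddle two years and mix the +/-1 offsets (2 months of
  # one year, 1 of the other); the non-straddling seasons alternate cleanly
  for (s in c("MAM", "JJA", "SON")) {
    inst_vals <- rep(c(1, -1), 11)
    expect_equal(cl$temp_sd[cl$season == s], sd(inst_vals))  # sample-sd convention
  }
})

test_that("standardized anomalies are exact z-scores of the seasonal aggregate", {
  set.seed(16)
  clim <- make_climate(precip = pmax(0, rnorm(264, 60, 10)),
                       temp = rnorm(264, 15, 1))
  cl <- seasonal_climatology(clim)
  z <- standardized_anomaly(clim, cl)
  # aggregate equal to the mean -> z 0; one sd above -> z 1 (direct check)
  i <- which(z$season == "JJA")[1]
  row <- cl[cl$season == "JJA", ]
  agg <- sum(clim$precip[clim$year == z$instance_year[i] & clim$month %in% 6:8])
  expect_equal(z$z_precip[i], (agg - row$precip_mean) / row$precip_sd)
  # idempotence in expectation: z-scores have mean ~0, sd ~1 per season
  for (s in c("MAM", "JJA", "SON")) {
    zi <- z$z_precip[z$season == s]
    expect_lt(abs(mean(zi)), 1e-9)
    expect_equal(sd(zi), 1, tolerance = 1e-9)
  }
})

test_that("temperature anomalies are invariant to a constant location shift", {
  set.seed(17)
  temp <- rnorm(264, 15, 1.5)
  clim1 <- make_climate(precip = 50, temp = temp)
  clim2 <- make_climate(precip = 50, temp = temp + 7)
  z1 <- standardized_anomaly(clim1, seasonal_climatology(clim1))
  z2 <- standardized_anomaly(clim2, seasonal_climatology(clim2))
  expect_equal(z1$z_temp, z2$z_temp, tolerance = 1e-10)
})

test_that("post-fire quarters average the right season-instance z-scores", {
  zm <- data.frame(cell = 1L, month_index = 1:264,
                   z_precip = 1, z_temp = 1)
  prof <- postfire_profile(zm, fire_month = 100)
  expect_equal(unlist(prof), setNames(rep(1, 8), names(unlist(prof))))

  # an anomaly confined to one season lands in exactly one quarter:
  # fire in July 2010 (index 115); spring (MAM 2011) = indices 123-125,
  # i.e. months 8-10 post-fire, spanning Q3 (7-9) and Q4 (10-12)
  set.seed(18)
  clim <- make_climate(precip = pmax(0, rnorm(264, 60, 10)), temp = rnorm(264, 15, 1))
  cl <- seasonal_climatology(clim)
  z <- standardized_anomaly(clim, cl)
  zm2 <- firerecov:::monthly_z(clim, z, 2001)
  fire <- (2010 - 2001) * 12 + 7
  prof2 <- postfire_profile(zm2, fire)
  mam_z <- z$z_precip[z$season == "MAM" & z$instance_year == 2011]
  jja_z <- z$z_precip[z$season == "JJA" & z$instance_year == 2010]
  son_z <- z$z_precip[z$season == "SON" & z$instance_year == 2010]
  djf_z <- z$z_precip[z$season == "DJF" & z$instance_year == 2011]
  expect_equal(prof2$precip_q1, jja_z * (1 / 3) + son_z * (2 / 3))  # Aug-Oct
  expect_equal(prof2$precip_q3, djf_z * (1 / 3) + mam_z * (2 / 3))  # Feb-Apr
  # truncated record: missing quarters are masked
  prof3 <- postfire_profile(zm, fire_month = 260)
  expect_true(is.na(prof3$precip_q3))
})

test_that("hemisphere changes season labels but not z-values", {
  set.seed(19)
  temp <- rnorm(264, 15, 1.5)
  cn <- make_climate(precip = 50, temp = temp, hemisphere = "north")
  cs <- make_climate(precip = 50, temp = temp, hemisphere = "south")
  zn <- standardized_anomaly(cn, seasonal_climatology(cn))
  zs <- standardized_anomaly(cs, seasonal_climatology(cs))
  expect_equal(zn$z_temp, zs$z_temp)
  expect_equal(local_season_name("DJF", "north"), "winter")
  expect_equal(local_season_name("DJF", "south"), "summer")
})

test_that("group anomaly summaries aggregate profiles with conserved counts", {
  profiles <- data.frame(pixel = 1:6, event = 1L, cell = 1L, fire_month = 100,
                         precip_q1 = c(2, 2, 2, -2, -2, -2),
                         precip_q2 = 1, precip_q3 = 1, precip_q4 = 1,
                         temp_q1 = 0, temp_q2 = 0, temp_q3 = 0, temp_q4 = 0)
  pairs <- data.frame(pixel = 1:6, landcover = "NL",
                      group = rep(c("b1_lt_b2", "b1_gt_b2"), each = 3))
  g <- group_anomalies(profiles, pairs)
  q1 <- g[g$variable == "precip" & g$quarter == 1, ]
  expect_equal(q1$mean_z[q1$group == "b1_lt_b2"], 2)
  expect_equal(q1$mean_z[q1$group == "b1_gt_b2"], -2)  # opposite-sign groups
  expect_equal(sum(q1$n), 6)
  # single-pixel group reproduces that pixel's profile
  g1 <- group_anomalies(profiles[1, ], pairs[1, ])
  expect_equal(g1$mean_z[g1$variable == "precip" & g1$quarter == 1], 2)
})
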