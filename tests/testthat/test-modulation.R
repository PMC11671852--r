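make_fits <- function(b1, b2, valid1 = TRUE, valid2 = TRUE,
                      landcover = "NL", a_rel = 0.5, y_pre = -0.1) {
  n <- length(b1)
  rbind(
    data.frame(pixel = seq_len(n), event = 1L, b = b1, adj_r2 = 0.6,
               a_rel = a_rel, y_pre = y_pre, landcover = landcover,
               valid = valid1),
    data.frame(pixel = seq_len(n), event = 2L, b = b2, adj_r2 = 0.6,
               a_rel = a_rel, y_pre = y_pre, landcover = landcover,
               valid = valid2)
  )
}

test_that("event pairing computes rate differences and honours validity rules", {
  p <- pair_events(make_fits(b1 = c(0.05, 0.06), b2 = c(0.06, 0.06)))
  expect_equal(p$b_diff, c(0.01, 0))
  dup <- make_fits(0.05, 0.06)
  expect_error(pair_events(rbind(dup, dup[1, ])), "duplicate")
  # both_valid drops a pixel with one failed fit; literal keeps it
  f <- make_fits(b1 = c(0.05, 0.05), b2 = c(0.06, 0.06),
                 valid1 = c(TRUE, FALSE), valid2 = TRUE)
  expect_equal(nrow(pair_events(f, "both_valid")), 1L)
  expect_equal(nrow(pair_events(f, "literal")), 2L)
})

test_that("a cohort with an injected rate difference recovers it in the mean", {
  ie <- injected_difference_experiment(n_pairs = 150, delta = 0.005, seed = 2)
  mc_se <- sd(ie$pairs$b_diff) / sqrt(nrow(ie$pairs))
  expect_lt(abs(mean(ie$pairs$b_diff) - 0.005), 4 * mc_se)
})

test_that("signed-rank p-values match exact enumeration and stats::wilcox.test", {
  # frozen example: six positive differences, no ties -> p = 2/64
  w <- wilcoxon_signed_rank(1:6)
  expect_equal(w$p_value, 2 / 64)
  expect_equal(w$statistic, 0)
  # random small samples, with and without ties, against the 2^n oracle
  set.seed(10)
  for (i in 1:8) {
    d <- round(rnorm(sample(6:12, 1)), sample(c(1, 2), 1))
    d <- d[d != 0]
    if (length(d) < 5) next
    expect_equal(wilcoxon_signed_rank(d)$p_value, enumerate_signed_rank_p(d),
                 tolerance = 1e-12)
  }
  # continuous samples: agree with the independent exact implementation in stats
  for (i in 1:5) {
    d <- rnorm(15)
    expect_equal(wilcoxon_signed_rank(d)$p_value,
                 stats::wilcox.test(d, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("normal approximation tracks the exact signed-rank p at n = 12", {
  set.seed(11)
  d <- rnorm(12)
  exact <- wilcoxon_signed_rank(d)$p_value
  r <- rank(abs(d)); W <- min(sum(r[d > 0]), sum(r[d < 0])); n <- 12
  z <- (W - n * (n + 1) / 4 + 0.5) / sqrt(n * (n + 1) * (2 * n + 1) / 24)
  expect_lt(abs(exact - min(1, 2 * pnorm(z))), 0.02)
})

test_that("degenerate and antisymmetric differences give null results", {
  z <- wilcoxon_signed_rank(rep(0, 10))
  expect_true(z$degenerate)
  expect_equal(z$p_value, 1)
  sym <- c(-3, -2, -1, 1, 2, 3)
  expect_equal(wilcoxon_signed_rank(sym)$p_value, 1)
})

test_that("IQR-based group selection matches a sort-and-slice oracle", {
  p <- data.frame(pixel = 1:100, landcover = "NL",
                  b_diff = (1:100) / 1000, group = "middle")
  p$b_diff <- p$b_diff - 0.0505  # symmetric around 0, values 10^-3 apart
  g <- select_extreme_diffs(p)
  expect_equal(sum(g$group == "b1_gt_b2"), 25)
  expect_equal(sum(g$group == "b1_lt_b2"), 25)
  expect_equal(sort(which(g$group == "b1_gt_b2")), 1:25)   # bottom slice
  expect_equal(sort(which(g$group == "b1_lt_b2")), 76:100) # top slice
  expect_equal(nrow(g), sum(table(g$group)))               # groups partition

  same <- data.frame(pixel = 1:20, landcover = "NL", b_diff = 0.01,
                     group = "middle")
  expect_warning(g2 <- select_extreme_diffs(same), "degenerate")
  expect_true(all(g2$group == "middle"))

  set.seed(12)
  r <- data.frame(pixel = 1:60, landcover = rep(c("NL", "Shb"), 30),
                  b_diff = rnorm(60, 0, 0.01), group = "middle")
  gr <- select_extreme_diffs(r)
  for (lc in c("NL", "Shb")) {
    x <- r$b_diff[r$landcover == lc]
    q <- quantile(x, c(0.25, 0.75), type = 7)
    oracle <- rep("middle", length(x))
    oracle[x < q[1] & x < 0] <- "b1_gt_b2"
    oracle[x > q[2] & x > 0] <- "b1_lt_b2"
    expect_equal(gr$group[gr$landcover == lc], oracle)
  }
})

test_that("bivariate KDE integrates to one and centres on the sample mean", {
  set.seed(13)
  x <- rnorm(200, 0.5, 0.1); y <- rnorm(200, 0.06, 0.01)
  k <- kde_bivariate(x, y)
  expect_gt(k$mass, 0.99); expect_lt(k$mass, 1.01)
  expect_equal(k$centroid, c(mean(x), mean(y)))
  # two clusters: centroid is the weighted mean of the cluster means
  x2 <- c(rnorm(150, 0.2, 0.02), rnorm(50, 0.8, 0.02))
  y2 <- c(rnorm(150, 0.03, 0.005), rnorm(50, 0.1, 0.005))
  k2 <- kde_bivariate(x2, y2)
  expect_equal(k2$centroid[1],
               (150 * mean(x2[1:150]) + 50 * mean(x2[151:200])) / 200)
  expect_warning(kde_bivariate(rep(0.5, 20), rnorm(20)), "bandwidth floor")
})

test_that("quantile regression attains the two-point optimality certificate", {
  set.seed(14)
  # exact collinearity: zero loss, common slope at any tau
  x <- runif(30); y <- 0.02 + 0.1 * x
  for (tau in c(0.01, 0.5, 0.99)) {
    f <- quantile_regression(x, y, tau)
    expect_equal(f$slope, 0.1, tolerance = 1e-12)
    expect_equal(f$pinball_loss, 0, tolerance = 1e-12)
  }
  # median regression consistency under symmetric noise
  x2 <- runif(200); y2 <- 1 + 2 * x2 + rnorm(200, 0, 0.1)
  f2 <- quantile_regression(x2, y2, 0.5)
  expect_equal(f2$slope, 2, tolerance = 0.15)
  # optimality: no line through two sample points does better (n = 40)
  x3 <- runif(40); y3 <- 0.02 + 0.08 * x3 + rnorm(40, 0, 0.02)
  for (tau in c(0.1, 0.9)) {
    f3 <- quantile_regression(x3, y3, tau)
    for (i in 1:39) for (j in (i + 1):40) {
      if (x3[i] == x3[j]) next
      sl <- (y3[j] - y3[i]) / (x3[j] - x3[i])
      ic <- y3[i] - sl * x3[i]
      expect_gte(pinball_loss(x3, y3, ic, sl, tau) + 1e-12, f3$pinball_loss)
    }
    # a general-purpose optimizer cannot improve on the vertex solution
    opt <- optim(c(f3$intercept, f3$slope),
                 function(p) pinball_loss(x3, y3, p[1], p[2], tau))
    expect_gte(opt$value + 1e-9, f3$pinball_loss)
  }
})

test_that("pre-fire binning conserves counts and matches a group-by oracle", {
  set.seed(15)
  long <- data.frame(pixel = rep(1:60, 2), event = rep(1:2, each = 60),
                     landcover = "NL",
                     group = sample(c("b1_lt_b2", "b1_gt_b2"), 120, TRUE),
                     a_rel = runif(120, 0.1, 1), b = runif(120, 0.02, 0.12),
                     y_pre = runif(120, -0.4, 0))
  tb <- bin_prefire(long, n_bins = 3)
  expect_equal(sum(tb$n), nrow(long))
  for (g in unique(tb$group)) {
    expect_equal(sum(tb$n[tb$group == g]), sum(long$group == g))
    expect_equal(sum(tb$is_max_bin[tb$group == g] &
                       tb$n[tb$group == g] == max(tb$n[tb$group == g])) > 0, TRUE)
  }
  # all points in one bin: that bin carries everything and the global median
  one <- long; one$a_rel <- 0.5; one$b <- 0.06
  tb1 <- bin_prefire(one, n_bins = 3)
  expect_equal(nrow(tb1), length(unique(one$group)))
  for (g in unique(one$group)) {
    expect_equal(tb1$median_y_pre[tb1$group == g],
                 median(one$y_pre[one$group == g]))
  }
})
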