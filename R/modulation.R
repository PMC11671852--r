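#' Pair the two events of each twice-burned pixel
#'
#' Builds the per-pixel event-pair table with `b_diff = b2 - b1` (positive:
#' faster recovery after the second fire) and the carried covariates. Under
#' the default `"both_valid"` rule a pixel enters only when both events' fits
#' pass the adjusted r-squared screen; `"literal"` drops a pixel only when both
#' fits fail it (finite rates are still required for the difference).
#'
#' @param fits the table from [fit_scene_recovery()] (or any data.frame with
#'   columns pixel, event, b, adj_r2, a_rel, y_pre, landcover, valid).
#' @param rule validity rule, `"both_valid"` or `"literal"`.
#' @return data.frame, one row per eligible pixel: `pixel, landcover, b1, b2,
#'   b_diff, a_rel1, a_rel2, y_pre1, y_pre2, group` (group initialized
#'   `"middle"`; see [select_extreme_diffs()]).
#' @export
pair_events <- function(fits, rule = c("both_valid", "literal")) {
  rule <- match.arg(rule)
  if (anyDuplicated(fits[, c("pixel", "event")])) {
    stop("duplicate pixel-event rows in fits")
  }
  e1 <- fits[fits$event == 1L, ]
  e2 <- fits[fits$event == 2L, ]
  common <- intersect(e1$pixel, e2$pixel)
  e1 <- e1[match(common, e1$pixel), ]
  e2 <- e2[match(common, e2$pixel), ]
  keep <- if (rule == "both_valid") e1$valid & e2$valid else e1$valid | e2$valid
  keep <- keep & is.finite(e1$b) & is.finite(e2$b)
  out <- data.frame(
    pixel = common, landcover = e1$landcover,
    b1 = e1$b, b2 = e2$b, b_diff = e2$b - e1$b,
    a_rel1 = e1$a_rel, a_rel2 = e2$a_rel,
    y_pre1 = e1$y_pre, y_pre2 = e2$y_pre,
    group = "middle", stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Event-pair table in long (per-event) form
#'
#' One row per pixel x event with the event's severity, rate and pre-fire
#' state alongside the pair's group label; input to [bin_prefire()] and the
#' severity-recovery analyses.
#'
#' @param pairs a [pair_events()] table (after grouping if desired).
#' @return long data.frame with columns pixel, event, landcover, group,
#'   a_rel, b, y_pre.
#' @export
pairs_long <- function(pairs) {
  rbind(
    data.frame(pixel = pairs$pixel, event = 1L, landcover = pairs$landcover,
               group = pairs$group, a_rel = pairs$a_rel1, b = pairs$b1,
               y_pre = pairs$y_pre1),
    data.frame(pixel = pairs$pixel, event = 2L, landcover = pairs$landcover,
               group = pairs$group, a_rel = pairs$a_rel2, b = pairs$b2,
               y_pre = pairs$y_pre2)
  )
}

#' Wilcoxon signed-rank test for paired differences
#'
#' Tests whether paired differences are symmetric about zero. Zeros are
#' dropped; absolute differences are ranked with midranks for ties;
#' `W = min(W+, W-)`. For `n <= 25` the two-sided p-value is exact, computed
#' from the full null distribution of the signed-rank sum under all `2^n` sign
#' assignments (evaluated by convolution, so ties are handled exactly); for
#' larger samples a normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param d numeric vector of paired differences.
#' @return list: `statistic` (W), `w_plus`, `w_minus`, `n_used`, `p_value`,
#'   `method`, `degenerate` (all differences zero).
#' @export
wilcoxon_signed_rank <- function(d) {
  d <- d[!is.na(d)]
  dz <- d[d != 0]
  n <- length(dz)
  if (n == 0L) {
    return(list(statistic = 0, w_plus = 0, w_minus = 0, n_used = 0L,
                p_value = 1, method = "degenerate", degenerate = TRUE))
  }
  r <- rank(abs(dz))
  w_plus <- sum(r[dz > 0])
  w_minus <- sum(r[dz < 0])
  W <- min(w_plus, w_minus)
  if (n <= 25L) {
    # exact null distribution of 2*W+ (doubled midranks are integers)
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    f <- numeric(total + 1L); f[1L] <- 1
    for (ri in r2) {
      g <- f
      g[(ri + 1L):(total + 1L)] <- g[(ri + 1L):(total + 1L)] + f[1:(total + 1L - ri)]
      f <- g
    }
    probs <- f / 2^n
    w2 <- as.integer(round(2 * w_plus))
    p_lo <- sum(probs[1:(w2 + 1L)])
    p_hi <- sum(probs[(w2 + 1L):(total + 1L)])
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu + 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(z))
    method <- "normal approximation (tie- and continuity-corrected)"
  }
  list(statistic = W, w_plus = w_plus, w_minus = w_minus, n_used = n,
       p_value = p, method = method, degenerate = FALSE)
}

#' Select pixels with the most contrasted recovery-rate differences
#'
#' Within each land-cover category, pixels whose `b_diff` falls outside the
#' 25th-75th interquartile range are assigned to the contrast groups:
#' below Q25 and negative -> `b1_gt_b2` (faster first recovery); above Q75 and
#' positive -> `b1_lt_b2` (faster second recovery); everything else stays
#' `middle`. Quantiles use linear interpolation between order statistics.
#'
#' @param pairs a [pair_events()] table.
#' @param lo,hi quantile bounds (default 0.25 / 0.75).
#' @param min_stratum minimum pairs per land-cover stratum to attempt grouping.
#' @return the pairs table with `group` filled in.
#' @export
select_extreme_diffs <- function(pairs, lo = 0.25, hi = 0.75, min_stratum = 8L) {
  pairs$group <- "middle"
  for (lc in unique(pairs$landcover)) {
    sel <- pairs$landcover == lc
    x <- pairs$b_diff[sel]
    if (sum(sel) < min_stratum) {
      warning(sprintf("land-cover stratum %s has fewer than %d pairs; all middle",
                      lc, min_stratum))
      next
    }
    q <- stats::quantile(x, c(lo, hi), type = 7, names = FALSE)
    if (q[1] == q[2]) {
      warning(sprintf("degenerate b_diff distribution in stratum %s; all middle", lc))
      next
    }
    g <- rep("middle", length(x))
    g[x < q[1] & x < 0] <- "b1_gt_b2"
    g[x > q[2] & x > 0] <- "b1_lt_b2"
    pairs$group[sel] <- g
  }
  pairs
}

#' Bivariate kernel density of (relative severity, recovery rate)
#'
#' Gaussian product-kernel density on a rectangular grid with Scott's-rule
#' bandwidths (`sd * n^(-1/6)` per axis, floored for degenerate axes). The
#' distribution centroid is the sample mean.
#'
#' @param x,y coordinates (e.g. `a_rel` and `b`).
#' @param n_grid grid points per axis.
#' @param pad grid margin in bandwidths beyond the data range.
#' @return list: `x`, `y` (grid axes), `z` (density matrix), `h` (bandwidths),
#'   `centroid` (c(mean(x), mean(y))), `mass` (Riemann-sum integral).
#' @export
kde_bivariate <- function(x, y, n_grid = 64L, pad = 4) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 10L) stop("kde_bivariate requires at least 10 points")
  bw <- function(v) {
    h <- stats::sd(v) * n^(-1 / 6)
    if (!is.finite(h) || h <= 0) {
      warning("zero variance on an axis; bandwidth floor applied")
      h <- 1e-3 * (abs(mean(v)) + 1)
    }
    h
  }
  hx <- bw(x); hy <- bw(y)
  gx <- seq(min(x) - pad * hx, max(x) + pad * hx, length.out = n_grid)
  gy <- seq(min(y) - pad * hy, max(y) + pad * hy, length.out = n_grid)
  Dx <- stats::dnorm(outer(gx, x, "-") / hx) / hx
  Dy <- stats::dnorm(outer(gy, y, "-") / hy) / hy
  z <- (Dx %*% t(Dy)) / n
  mass <- sum(z) * diff(gx[1:2]) * diff(gy[1:2])
  list(x = gx, y = gy, z = z, h = c(hx, hy),
       centroid = c(mean(x), mean(y)), mass = mass)
}

#' Pinball (check) loss of a line at quantile level tau
#'
#' @param x,y data.
#' @param intercept,slope candidate line.
#' @param tau quantile level in (0, 1).
#' @return the summed check loss `sum(rho_tau(y - intercept - slope x))`.
#' @export
pinball_loss <- function(x, y, intercept, slope, tau) {
  u <- y - intercept - slope * x
  sum(u * (tau - (u < 0)))
}

#' Linear quantile regression by exact vertex search
#'
#' Minimizes the pinball loss over all lines through two sample points; for
#' the linear check-loss objective an optimal solution always passes through
#' at least two data points (a vertex of the LP), so the pairwise search is
#' exact. Intended for the moderate sample sizes of the severity-recovery
#' envelope analysis; cost grows as `O(n^3)`.
#'
#' @param x predictor (e.g. relative severity).
#' @param y response (e.g. recovery rate, month^-1).
#' @param tau quantile level in (0, 1), e.g. 0.01 or 0.99.
#' @return list: `tau`, `intercept`, `slope` (month^-1 per relative-severity
#'   unit when applied to `(a_rel, b)`), `pinball_loss`, `n`.
#' @export
quantile_regression <- function(x, y, tau) {
  stopifnot(length(x) == length(y), tau > 0, tau < 1)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2L) stop("quantile_regression requires at least 2 points")
  if (diff(range(x)) == 0) stop("degenerate predictor: all x equal")
  ij <- utils::combn(n, 2L)
  dx <- x[ij[2, ]] - x[ij[1, ]]
  keep <- dx != 0
  ij <- ij[, keep, drop = FALSE]
  slopes <- (y[ij[2, ]] - y[ij[1, ]]) / dx[keep]
  ints <- y[ij[1, ]] - slopes * x[ij[1, ]]
  m <- length(slopes)
  best_loss <- Inf; best <- 1L
  chunk <- 2000L
  for (s in seq(1L, m, by = chunk)) {
    e <- min(s + chunk - 1L, m)
    pred <- outer(slopes[s:e], x) + ints[s:e]       # candidates x points
    u <- matrix(y, nrow = e - s + 1L, ncol = n, byrow = TRUE) - pred
    loss <- rowSums(u * (tau - (u < 0)))
    i <- which.min(loss)
    if (loss[i] < best_loss - 1e-12) {
      best_loss <- loss[i]; best <- s + i - 1L
    }
  }
  list(tau = tau, intercept = ints[best], slope = slopes[best],
       pinball_loss = best_loss, n = n)
}

#' Bin event points by severity and rate, summarizing pre-fire state
#'
#' Partitions the long event table into `n_bins` equal-quantile bins per axis
#' (`a_rel` and `b`), and reports, for each bin x group x land-cover cell,
#' the median pre-fire loss `y_pre` and the point count; the most populated
#' bin of each group x land-cover stratum is flagged. Empty cells are omitted.
#'
#' @param long a [pairs_long()] table.
#' @param n_bins bins per axis (default 6).
#' @return data.frame: landcover, group, a_rel_bin, b_bin, n, median_y_pre,
#'   is_max_bin.
#' @export
bin_prefire <- function(long, n_bins = 6L) {
  ok <- is.finite(long$a_rel) & is.finite(long$b) & is.finite(long$y_pre)
  long <- long[ok, , drop = FALSE]
  if (!nrow(long)) return(data.frame())
  qbreaks <- function(v) {
    br <- unique(stats::quantile(v, probs = seq(0, 1, length.out = n_bins + 1),
                                 type = 7, names = FALSE))
    if (length(br) < 2L) br <- c(br, br + 1e-12)
    br
  }
  ab <- cut(long$a_rel, qbreaks(long$a_rel), include.lowest = TRUE)
  bb <- cut(long$b, qbreaks(long$b), include.lowest = TRUE)
  key <- factor(paste(long$landcover, long$group, ab, bb, sep = "\r"))
  n <- as.vector(table(key))
  med <- tapply(long$y_pre, key, stats::median)
  parts <- do.call(rbind, strsplit(names(med), "\r", fixed = TRUE))
  out <- data.frame(landcover = parts[, 1], group = parts[, 2],
                    a_rel_bin = parts[, 3], b_bin = parts[, 4],
                    n = n, median_y_pre = as.numeric(med))
  strat <- interaction(out$landcover, out$group, drop = TRUE)
  out$is_max_bin <- stats::ave(out$n, strat, FUN = function(v) v == max(v)) > 0
  rownames(out) <- NULL
  out
}
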