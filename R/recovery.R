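#' Ideal seasonal cycle ("Gorgeous Year") of a monthly cube
#'
#' For each pixel and calendar month, the Gorgeous Year value `GY(m)` is the
#' maximum monthly EVI observed for that month over the whole record; it
#' represents the pixel's ideal (undisturbed, best-year) seasonal cycle.
#' `GY_MEAN` is the mean of the 12 monthly values.
#'
#' @param cube a monthly [evi_cube()].
#' @return a `gorgeous_year` list: `gy` (array `12 x rows x cols`), `gy_mean`
#'   (rows x cols matrix) and `valid` (logical matrix; `FALSE` where any
#'   calendar month is entirely masked).
#' @export
compute_gorgeous_year <- function(cube) {
  assert_state(cube, "monthly", "compute_gorgeous_year")
  d <- dim(cube$values)
  n_mon <- d[1]
  stopifnot(n_mon %% 12L == 0L)
  ny <- n_mon %/% 12L
  M <- cube_matrix(cube)
  gy <- matrix(-Inf, 12L, ncol(M))
  for (y in seq_len(ny)) {
    block <- M[(y - 1L) * 12L + 1:12, , drop = FALSE]
    gy <- pmax(gy, block, na.rm = TRUE)
  }
  gy[!is.finite(gy)] <- NA_real_
  valid <- matrix(colSums(is.na(gy)) == 0L, d[2], d[3])
  structure(list(
    gy = array(gy, c(12L, d[2], d[3])),
    gy_mean = matrix(colMeans(gy), d[2], d[3]),
    valid = valid
  ), class = "gorgeous_year")
}

#' Loss-of-greenness series y(t) = EVI(t) - GY(month)
#'
#' Normalizes the monthly EVI record against the ideal seasonal cycle. By
#' construction of GY as a per-month maximum, `y(t)` lies in `[-1, 0]`: zero at
#' the month's best year, increasingly negative as greenness falls below the
#' ideal state.
#'
#' @param cube the monthly [evi_cube()] the Gorgeous Year was computed from.
#' @param gy the matching [compute_gorgeous_year()] result.
#' @return an array of the same dim as `cube$values` with the monthly loss
#'   series per pixel.
#' @export
loss_series <- function(cube, gy) {
  assert_state(cube, "monthly", "loss_series")
  stopifnot(inherits(gy, "gorgeous_year"))
  d <- dim(cube$values)
  mo <- month_of_index(seq_len(d[1]))
  y <- cube$values - gy$gy[mo, , , drop = FALSE]
  if (any(y > 1e-9, na.rm = TRUE)) {
    stop("positive loss values: Gorgeous Year does not match this cube")
  }
  y[which(y > 0)] <- 0  # clip float dust
  y
}

#' Locate the fire-driven greenness minimum (severity)
#'
#' Searches `y(t)` from the fire month through `search_months` months after it
#' and returns the minimum (the severity `a`, the maximum loss of greenness)
#' and its month; ties break toward the earliest month.
#'
#' @param y numeric vector, one pixel's monthly loss series.
#' @param fire_month month index of the fire.
#' @param search_months months after the fire month to search (default 3).
#' @return list `(a, t0)`; `valid = FALSE` with a reason if the window is
#'   entirely masked.
#' @export
locate_severity <- function(y, fire_month, search_months = 3) {
  stopifnot(fire_month >= 1, fire_month <= length(y))
  win <- fire_month:min(fire_month + search_months, length(y))
  yv <- y[win]
  if (all(is.na(yv))) {
    return(list(a = NA_real_, t0 = NA_integer_, valid = FALSE,
                reason = "window masked"))
  }
  i <- which.min(yv)  # which.min returns the first (earliest) minimum
  list(a = yv[i], t0 = win[i], valid = TRUE, reason = NA_character_)
}

# closed-form simple linear regression of z on t, optional through-origin.
#
# Standard-error choices for the slope:
#   "robust" (default): HC3 heteroscedasticity-robust SE inflated for lag-1
#     residual autocorrelation via the effective-sample-size correction
#     n_eff = n (1 - rho)/(1 + rho) (rho small-sample bias-corrected), the
#     standard treatment for trend uncertainty on serially correlated
#     geophysical series. The log of an additively noisy deficit is
#     heteroscedastic by construction, and composite-level noise aggregated
#     to months stays autocorrelated, so both corrections are needed.
#   "hc3": heteroscedasticity-robust only.
#   "ols": classical homoscedastic SE with n - 2 df.
fit_loglinear <- function(t, z, intercept = TRUE,
                          se_type = c("robust", "hc3", "ols")) {
  se_type <- match.arg(se_type)
  n <- length(t)
  if (intercept) {
    mt <- mean(t); mz <- mean(z)
    dt <- t - mt; dz <- z - mz
    sxx <- sum(dt^2); sxy <- sum(dt * dz); szz <- sum(dz^2)
    slope <- sxy / sxx
    b0 <- mz - slope * mt
    resid <- dz - slope * dt
    rss <- max(szz - slope * sxy, 0)
    df <- n - 2L
    r2 <- if (szz > 0) 1 - rss / szz else NA_real_
    adj <- if (is.na(r2)) NA_real_ else 1 - (1 - r2) * (n - 1) / (n - 2)
    hat <- pmin(1 / n + dt^2 / sxx, 1 - 1e-8)
  } else {
    stt <- sum(t^2)
    slope <- sum(t * z) / stt
    b0 <- 0
    resid <- z - slope * t
    rss <- max(sum(resid^2), 0)
    szz <- sum(z^2)
    df <- n - 1L
    r2 <- if (szz > 0) 1 - rss / szz else NA_real_
    adj <- if (is.na(r2)) NA_real_ else 1 - (1 - r2) * n / (n - 1)
    sxx <- stt
    dt <- t
    hat <- pmin(t^2 / stt, 1 - 1e-8)
  }
  if (se_type == "ols") {
    se <- sqrt(rss / df / sxx)
  } else {
    se <- sqrt(sum((dt * resid / (1 - hat))^2)) / sxx
    if (se_type == "robust" && n >= 6L && rss > 0) {
      rho <- suppressWarnings(stats::cor(resid[-n], resid[-1]))
      if (!is.finite(rho)) rho <- 0
      rho <- max(0, min(rho + (1 + 3 * rho) / n, 0.9))
      if (rho > 0) {
        se <- se * sqrt((1 + rho) / (1 - rho))
        df <- max(2, n * (1 - rho) / (1 + rho) - (n - df))
      }
    }
  }
  list(slope = slope, intercept = b0, r2 = r2, adj_r2 = adj,
       se_slope = se, df = df, n = n)
}

#' Fit the exponential recovery model to one event
#'
#' Assumes the greenness deficit decays as `y(t) = a * exp(-b * t)` after its
#' minimum, so `ln(-y)` is linear in time with slope `-b`. For each candidate
#' window length (24, 36, 48, 60 months by default), `ln(-y(t))` is regressed
#' on months since `t0` over `[t0, t0 + L]`, excluding months with `y >= 0`
#' (log undefined: full recovery attained) and months at or beyond a
#' subsequent fire. The window with the highest adjusted r-squared wins, ties
#' going to the shortest (most local) window. The 95% CI comes from the
#' slope's standard error and a Student-t quantile.
#'
#' @param y one pixel's monthly loss series.
#' @param t0 month index of the severity minimum.
#' @param a the severity (minimum of `y`), negative.
#' @param windows candidate window lengths in months.
#' @param r2_min adjusted r-squared screening threshold (default 0.25).
#' @param stop_before optional month index (e.g. the next fire's month); only
#'   months strictly before it enter the fit.
#' @param intercept `TRUE` fits a free intercept (default); `FALSE` forces the
#'   line through `ln(-a)` at `t = 0`.
#' @param se_type slope standard error: `"robust"` (default;
#'   heteroscedasticity-robust HC3 with an effective-sample-size correction
#'   for lag-1 residual autocorrelation -- the log of an additively noisy
#'   deficit has errors that grow as recovery completes, and monthly noise
#'   aggregated from composites is serially correlated), `"hc3"`, or `"ols"`
#'   (classical homoscedastic).
#' @param min_points minimum usable months required in a window.
#' @param gy_mean the pixel's mean Gorgeous Year, for relative severity.
#' @return one-row data.frame: `a, t0, b, adj_r2, window_months, ci_low,
#'   ci_high, n_points, a_rel, t_char, valid, reason`.
#' @export
fit_recovery <- function(y, t0, a, windows = c(24, 36, 48, 60), r2_min = 0.25,
                         stop_before = NULL, intercept = TRUE,
                         se_type = c("robust", "hc3", "ols"),
                         min_points = 12, gy_mean = NA_real_) {
  se_type <- match.arg(se_type)
  out <- data.frame(a = a, t0 = t0, b = NA_real_, adj_r2 = NA_real_,
                    window_months = NA_integer_, ci_low = NA_real_,
                    ci_high = NA_real_, n_points = NA_integer_,
                    a_rel = relative_severity(a, gy_mean),
                    t_char = NA_real_, valid = FALSE, reason = NA_character_)
  if (is.na(a) || a >= 0) {
    out$reason <- if (!is.na(a) && a == 0) "no loss to recover" else "no severity"
    return(out)
  }
  n <- length(y)
  last <- if (is.null(stop_before)) n else min(n, stop_before - 1L)
  best <- NULL
  any_points <- FALSE
  for (L in sort(windows)) {
    idx <- t0:min(t0 + L, last)
    yy <- y[idx]
    keep <- !is.na(yy) & yy < 0
    if (sum(keep)) any_points <- TRUE
    if (sum(keep) < min_points) next
    t_rel <- (idx - t0)[keep]
    z <- if (intercept) log(-yy[keep]) else log(-yy[keep]) - log(-a)
    f <- fit_loglinear(t_rel, z, intercept = intercept, se_type = se_type)
    if (is.na(f$adj_r2)) next
    if (is.null(best) || f$adj_r2 > best$adj_r2 + 1e-12) {
      best <- c(f, list(window = L))
    }
  }
  if (is.null(best)) {
    out$reason <- if (any_points) "too few usable points" else "no loss to recover"
    return(out)
  }
  b <- -best$slope
  tq <- stats::qt(0.975, best$df)
  out$b <- b
  out$adj_r2 <- best$adj_r2
  out$window_months <- best$window
  out$ci_low <- b - tq * best$se_slope
  out$ci_high <- b + tq * best$se_slope
  out$n_points <- best$n
  out$t_char <- if (b > 0) 1 / b else NA_real_
  out$valid <- is.finite(best$adj_r2) && best$adj_r2 >= r2_min && b > 0
  out$reason <- if (out$valid) NA_character_ else
    if (b <= 0) "non-positive rate" else "adjusted r2 below threshold"
  out
}

#' Relative fire severity
#'
#' `a_rel = |a| / GY_MEAN`: the greenness loss relative to the pixel's mean
#' ideal cycle. Ranges from 0 (no severity) upward without bound.
#'
#' @param a severity (minimum of `y`), non-positive.
#' @param gy_mean the pixel's mean Gorgeous Year; must be positive (a zero
#'   mean marks a bare pixel, returned as `NA`).
#' @return relative severity, `>= 0`.
#' @export
relative_severity <- function(a, gy_mean) {
  ifelse(is.na(gy_mean) | gy_mean <= 0, NA_real_, abs(a) / gy_mean)
}

#' Median pre-fire loss of greenness
#'
#' The median of `y(t)` over the three months preceding the fire month (the
#' fire month itself excluded); a proxy for pre-fire fuel/vegetation condition.
#'
#' @param y one pixel's monthly loss series.
#' @param fire_month month index of the fire.
#' @return the median, or `NA` when fewer than 3 pre-fire months exist.
#' @export
prefire_state <- function(y, fire_month) {
  if (fire_month < 4L) return(NA_real_)
  stats::median(y[(fire_month - 3L):(fire_month - 1L)])
}

#' Characteristic recovery time
#'
#' `1/b`, the time (months) at which about half of the relative recovery is
#' reached: b = 0.10 month^-1 corresponds to about 10 months, 0.04 to 25.
#'
#' @param b recovery rate, month^-1.
#' @return months.
#' @export
characteristic_time <- function(b) 1 / b

#' Fit both events of every twice-burned pixel in a scene
#'
#' @param cube monthly [evi_cube()].
#' @param gy matching [compute_gorgeous_year()].
#' @param pairs the `pairs` table from [select_twice_burned()].
#' @param landcover optional factor matrix of aggregated categories.
#' @param search_months,windows,r2_min,intercept,min_points fitting controls,
#'   see [locate_severity()] and [fit_recovery()].
#' @return data.frame, one row per pixel x event, with fit parameters,
#'   `y_pre` (pre-fire state) and land-cover category.
#' @export
fit_scene_recovery <- function(cube, gy, pairs, landcover = NULL,
                               search_months = 3, windows = c(24, 36, 48, 60),
                               r2_min = 0.25, intercept = TRUE, min_points = 12) {
  y_arr <- loss_series(cube, gy)
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    r <- pairs$row[i]; c <- pairs$col[i]
    yv <- y_arr[, r, c]
    gym <- gy$gy_mean[r, c]
    lc <- if (is.null(landcover)) NA_character_ else as.character(landcover[r, c])
    for (e in 1:2) {
      fm <- if (e == 1L) pairs$m1[i] else pairs$m2[i]
      stop_before <- if (e == 1L) pairs$m2[i] else NULL
      sev <- locate_severity(yv, fm, search_months)
      fit <- if (sev$valid) {
        fit_recovery(yv, sev$t0, sev$a, windows = windows, r2_min = r2_min,
                     stop_before = stop_before, intercept = intercept,
                     min_points = min_points, gy_mean = gym)
      } else {
        fit_recovery(yv, fm, NA_real_, gy_mean = gym)
      }
      fit$pixel <- pairs$pixel[i]; fit$row <- r; fit$col <- c
      fit$event <- e; fit$fire_month <- fm
      fit$y_pre <- prefire_state(yv, fm)
      fit$landcover <- lc
      rows[[length(rows) + 1L]] <- fit
    }
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  out[, c("pixel", "row", "col", "event", "fire_month", "a", "t0", "b",
          "adj_r2", "window_months", "ci_low", "ci_high", "n_points",
          "a_rel", "t_char", "y_pre", "landcover", "valid", "reason")]
}
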