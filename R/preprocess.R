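#' Replace low-quality observations by spatial, then temporal interpolation
#'
#' Low-quality observations (cloud, snow, aerosol flags) are first replaced by
#' the mean of good-quality values among their 8 spatial neighbours in the same
#' composite, where at least 3 good neighbours exist. Remaining gaps are filled
#' per pixel by piecewise-cubic interpolation over time (exact for series
#' sampled from a cubic polynomial); beyond the first/last anchor the nearest
#' valid value is extended. Good-quality observations are never modified.
#' Pixels with fewer than 4 good observations over the whole record are masked
#' (values set `NA`) and reported via the `masked` attribute rather than
#' aborting the run.
#'
#' @param cube a raw [evi_cube()] with quality flags.
#' @return the cube with `state = "gapfilled"`; attribute `masked` is a logical
#'   row x col matrix of pixels that could not be filled.
#' @export
fill_low_quality <- function(cube) {
  assert_state(cube, "raw", "fill_low_quality")
  if (is.null(cube$quality)) stop("fill_low_quality() requires quality flags")
  d <- dim(cube$values)
  n_t <- d[1]; n_r <- d[2]; n_c <- d[3]
  V <- cube$values
  Q <- array(as.logical(cube$quality), d)

  # spatial pass: 8-neighbour mean of good observations, >= 3 good neighbours
  filled_sp <- array(FALSE, d)
  shifts <- expand.grid(dr = -1:1, dc = -1:1)
  shifts <- shifts[!(shifts$dr == 0 & shifts$dc == 0), ]
  for (t in seq_len(n_t)) {
    qt <- matrix(Q[t, , ], n_r, n_c)
    if (!any(qt)) next
    vt <- matrix(V[t, , ], n_r, n_c)
    good <- !qt
    acc <- matrix(0, n_r, n_c); cnt <- matrix(0L, n_r, n_c)
    for (s in seq_len(nrow(shifts))) {
      dr <- shifts$dr[s]; dc <- shifts$dc[s]
      rs <- seq_len(n_r) + dr; cs <- seq_len(n_c) + dc
      okr <- rs >= 1 & rs <= n_r; okc <- cs >= 1 & cs <= n_c
      src_r <- rs[okr]; src_c <- cs[okc]
      gsub <- good[src_r, src_c, drop = FALSE]
      vsub <- vt[src_r, src_c, drop = FALSE]
      acc[okr, okc] <- acc[okr, okc] + ifelse(gsub, vsub, 0)
      cnt[okr, okc] <- cnt[okr, okc] + gsub
    }
    sel <- qt & cnt >= 3L
    if (any(sel)) {
      vt[sel] <- acc[sel] / cnt[sel]
      V[t, , ] <- vt
      filled_sp[t, , ][sel] <- TRUE
    }
  }

  # temporal pass: cubic interpolation through good + spatially-filled anchors
  masked <- matrix(FALSE, n_r, n_c)
  tt <- as.numeric(cube$dates)
  for (c in seq_len(n_c)) for (r in seq_len(n_r)) {
    known <- !Q[, r, c] | filled_sp[, r, c]
    if (sum(!Q[, r, c]) < 4L) {
      V[, r, c] <- NA_real_
      masked[r, c] <- TRUE
      next
    }
    if (all(known)) next
    f <- stats::splinefun(tt[known], V[known, r, c], method = "fmm")
    miss <- which(!known)
    vals <- f(tt[miss])
    # constant extension beyond the first/last anchor
    lo <- min(tt[known]); hi <- max(tt[known])
    vals[tt[miss] < lo] <- V[which(known)[1], r, c]
    vals[tt[miss] > hi] <- V[rev(which(known))[1], r, c]
    V[miss, r, c] <- vals
  }

  out <- evi_cube(V, cube$dates, quality = cube$quality, state = "gapfilled",
                  start_year = cube$start_year)
  attr(out, "masked") <- masked
  if (any(masked)) {
    message(sprintf("fill_low_quality: %d pixel(s) masked (< 4 good observations)",
                    sum(masked)))
  }
  out
}

#' FFT low-pass smoothing of each pixel's series
#'
#' Computes the discrete Fourier transform of each pixel's full record, zeroes
#' every coefficient whose period is shorter than `keep_period_months`, and
#' inverse-transforms. The zero-frequency term is always retained, so the
#' series mean is preserved exactly; by Parseval's identity the output variance
#' never exceeds the input variance. The default 3-month cutoff removes
#' composite-scale noise while keeping multi-month disturbance signatures.
#'
#' @param cube a gapfilled [evi_cube()].
#' @param keep_period_months shortest retained period, months; must be at
#'   least two composite intervals.
#' @return the cube with `state = "smoothed"`.
#' @export
fft_smooth <- function(cube, keep_period_months = 3) {
  assert_state(cube, "gapfilled", "fft_smooth")
  dt_days <- 365.25 / 23
  cutoff_days <- keep_period_months * 30.4375
  if (cutoff_days < 2 * dt_days) {
    stop("invalid `keep_period_months`: cutoff must be at least two composites")
  }
  M <- cube_matrix(cube)
  ok_px <- colSums(is.na(M)) == 0L
  n <- nrow(M)
  j <- seq_len(floor(n / 2))                # harmonic index (cycles per record)
  period_days <- n * dt_days / j
  drop <- j[period_days < cutoff_days]
  if (length(drop) && any(ok_px)) {
    FT <- stats::mvfft(M[, ok_px, drop = FALSE])
    FT[drop + 1L, ] <- 0                     # positive frequencies
    FT[n + 1L - drop, ] <- 0                 # conjugate mirror (covers Nyquist twice, harmless)
    M[, ok_px] <- Re(stats::mvfft(FT, inverse = TRUE)) / n
  }
  out <- evi_cube(matrix_to_cube_values(M, dim(cube$values)), cube$dates,
                  quality = cube$quality, state = "smoothed",
                  start_year = cube$start_year)
  attr(out, "masked") <- masked_pixels(cube)
  out
}

#' Remove each pixel's long-term trend by local regression
#'
#' Fits a locally weighted linear regression (LOESS, tricube weights,
#' `degree = 1`) with span `span_fraction` of the record to each pixel's series
#' and subtracts it, adding back the mean of the fitted trend so the series
#' mean is preserved exactly. The wide default span (half the record, about 11
#' years for a 22-year record) removes decadal greening trends without
#' absorbing 2-5-year post-fire recovery segments.
#'
#' @param cube a smoothed [evi_cube()].
#' @param span_fraction LOESS span as a fraction of the record, in `(0.1, 1]`.
#' @return the cube with `state = "detrended"`.
#' @export
loess_detrend <- function(cube, span_fraction = 0.5) {
  assert_state(cube, "smoothed", "loess_detrend")
  if (span_fraction <= 0.1 || span_fraction > 1) {
    stop("invalid `span_fraction`: must be in (0.1, 1]")
  }
  M <- cube_matrix(cube)
  tt <- seq_len(nrow(M))
  for (p in seq_len(ncol(M))) {
    v <- M[, p]
    if (anyNA(v)) next
    tr <- stats::fitted(stats::loess(v ~ tt, span = span_fraction, degree = 1,
                                     family = "gaussian"))
    M[, p] <- v - tr + mean(tr)
  }
  out <- evi_cube(matrix_to_cube_values(M, dim(cube$values)), cube$dates,
                  quality = cube$quality, state = "detrended",
                  start_year = cube$start_year)
  attr(out, "masked") <- masked_pixels(cube)
  out
}

#' Aggregate 16-day composites to calendar months
#'
#' The monthly value is the mean of the composites whose start date falls in
#' that calendar month (one or two composites under the 23-per-year calendar).
#' Smoothing and detrending may be skipped upstream, so any of the states
#' `gapfilled`, `smoothed` or `detrended` is accepted.
#'
#' @param cube an [evi_cube()] in state `gapfilled`, `smoothed` or `detrended`.
#' @return a monthly cube (`state = "monthly"`) of length `12 * n_years`,
#'   dated on the first of each month.
#' @export
monthly_aggregate <- function(cube) {
  assert_state(cube, c("gapfilled", "smoothed", "detrended"), "monthly_aggregate")
  M <- cube_matrix(cube)
  mi <- composite_month_index(cube$dates, cube$start_year)
  n_mon <- max(mi)
  counts <- tabulate(mi, nbins = n_mon)
  if (any(counts == 0L)) {
    stop("internal error: calendar month without composites")
  }
  agg <- rowsum(M, mi) / counts
  first_year <- cube$start_year
  mdates <- as.Date(sprintf("%d-%02d-01",
                            year_of_index(seq_len(n_mon), first_year),
                            month_of_index(seq_len(n_mon))))
  out <- evi_cube(matrix_to_cube_values(agg, c(n_mon, dim(cube$values)[2:3])),
                  mdates, quality = NULL, state = "monthly",
                  start_year = cube$start_year)
  attr(out, "masked") <- masked_pixels(cube)
  out
}

#' Run the full pre-processing chain
#'
#' Convenience wrapper applying [fill_low_quality()], optionally
#' [fft_smooth()] and [loess_detrend()], then [monthly_aggregate()], in the
#' fixed order the per-operation state checks enforce.
#'
#' @param cube a raw [evi_cube()].
#' @param smooth,detrend logical switches for the smoothing and detrending
#'   stages (noise-free experiments can skip both).
#' @param keep_period_months passed to [fft_smooth()].
#' @param span_fraction passed to [loess_detrend()].
#' @return a monthly [evi_cube()].
#' @export
preprocess_cube <- function(cube, smooth = TRUE, detrend = TRUE,
                            keep_period_months = 3, span_fraction = 0.5) {
  out <- fill_low_quality(cube)
  if (smooth) {
    out <- fft_smooth(out, keep_period_months)
    if (detrend) out <- loess_detrend(out, span_fraction)
  }
  monthly_aggregate(out)
}
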