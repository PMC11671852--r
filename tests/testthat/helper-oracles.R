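# Independent brute-force oracles used across the suite.

# Wilcoxon signed-rank two-sided p by full enumeration of all 2^n sign
# assignments (midranks for ties), feasible for n <= 12.
enumerate_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n >= 1, n <= 12)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p_lo <- mean(w_all <= w_obs + 1e-9)
  p_hi <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(p_lo, p_hi))
}

# per-calendar-month maximum by explicit reshape (Gorgeous Year oracle)
brute_force_gy <- function(v) {
  stopifnot(length(v) %% 12 == 0)
  apply(matrix(v, nrow = 12), 1, max)
}

# monthly cube with arbitrary values, bypassing the pre-processing chain
make_monthly_cube <- function(values, start_year = 2001) {
  d <- dim(values)
  n_mon <- d[1]
  dates <- as.Date(sprintf("%d-%02d-01",
                           start_year + (seq_len(n_mon) - 1) %/% 12,
                           (seq_len(n_mon) - 1) %% 12 + 1))
  evi_cube(values, dates, state = "monthly", start_year = start_year)
}

# raw single-pixel cube on the composite calendar
make_raw_cube <- function(v, quality = NULL, start_year = 2001,
                          end_year = start_year + length(v) / 23 - 1) {
  dates <- composite_dates(start_year, end_year)
  stopifnot(length(v) == length(dates))
  q <- if (is.null(quality)) array(FALSE, c(length(v), 1, 1)) else
    array(quality, c(length(v), 1, 1))
  evi_cube(array(v, c(length(v), 1, 1)), dates, quality = q,
           state = "raw", start_year = start_year)
}

noiseless_config <- function(..., seed = 1) {
  sim_config(noise_sd = 0, cloud_fraction = 0, trend_slope = 0,
             ar1_coeff = 0, seed = seed, ...)
}
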