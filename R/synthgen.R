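#' Configuration for the synthetic scene generator
#'
#' Builds and validates the parameter set of [simulate_scene()]. Defaults
#' describe a 22-year (2001-2022) MODIS-like record: 16-day composites, a
#' smooth annual greenness cycle, mild greening trend, AR(1) observational
#' noise, cloud-contaminated observations, and (for recurrence studies) two
#' fire events per pixel at least four years apart, each producing an
#' instantaneous greenness drop of depth `a` followed by exponential recovery
#' at rate `b` (month^-1).
#'
#' @param grid_rows,grid_cols scene dimensions in pixels.
#' @param start_year,end_year record span (inclusive); `end_year > start_year`.
#' @param cadence days per composite; only the 16-day/23-per-year calendar is supported.
#' @param seasonal_amplitude,seasonal_mean annual cycle of undisturbed EVI;
#'   `seasonal_mean +/- seasonal_amplitude` must stay in `[0, 1]`.
#' @param trend_slope long-term trend in EVI units per year.
#' @param noise_sd marginal standard deviation of the AR(1) observational noise (EVI units).
#' @param ar1_coeff lag-1 autocorrelation of the noise, in `[0, 1)`.
#' @param cloud_fraction share of observations flagged low quality (and contaminated).
#' @param events_per_pixel 0, 1 or 2 fire events per burned pixel.
#' @param event_pixel_fraction fraction of pixels that receive events.
#' @param a_true_range range (negative) of the injected greenness drop depth.
#' @param b_true_range range of the injected recovery rate, month^-1, within (0, 1].
#' @param b2_coupling `"independent"` draws the two events' rates independently;
#'   `"offset"` sets `b2 = b1 + b2_offset` (paired-difference experiments).
#' @param b2_offset offset added to the second event's rate under `"offset"` coupling.
#' @param event_gap_range range of the gap between the two events, months;
#'   minimum must be >= 48 when `events_per_pixel == 2`.
#' @param burn_uncertainty_range range (days) of the burn-date uncertainty.
#' @param landcover_categories categories sampled for the scene, a subset of
#'   `BL, NL, MF, Shb, TW, Gs, Cp, Oth`.
#' @param hemisphere `"north"` or `"south"`; sets the seasonal phase and fire season.
#' @param climate_cell_size pixels per climate cell along each axis (coarser grid).
#' @param climate_anomaly_spec optional data.frame with columns
#'   `variable` (`"precip"`/`"temp"`), `year`, `season` (`"DJF"`, `"MAM"`,
#'   `"JJA"`, `"SON"`) and `z`: standardized seasonal offsets injected into the
#'   climate fields.
#' @param seed integer seed; identical configs give bit-identical scenes.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(grid_rows = 10L, grid_cols = 10L,
                       start_year = 2001L, end_year = 2022L,
                       cadence = 16L,
                       seasonal_amplitude = 0.1, seasonal_mean = 0.6,
                       trend_slope = 0.001,
                       noise_sd = 0.02, ar1_coeff = 0.3,
                       cloud_fraction = 0.1,
                       events_per_pixel = 2L, event_pixel_fraction = 1,
                       a_true_range = c(-0.5, -0.2),
                       b_true_range = c(0.03, 0.12),
                       b2_coupling = c("independent", "offset"),
                       b2_offset = 0,
                       event_gap_range = c(48L, 96L),
                       burn_uncertainty_range = c(0L, 7L),
                       landcover_categories = c("BL", "NL", "Shb", "TW"),
                       hemisphere = c("north", "south"),
                       climate_cell_size = 4L,
                       climate_anomaly_spec = NULL,
                       seed = 1L) {
  bad <- function(field, why) stop(sprintf("invalid `%s`: %s", field, why), call. = FALSE)
  if (!(end_year > start_year)) bad("end_year", "must be greater than start_year")
  if (cadence != 16L) bad("cadence", "only the 16-day composite calendar is supported")
  if (grid_rows < 1 || grid_cols < 1) bad("grid_rows", "grid must be at least 1 x 1")
  if (seasonal_mean - seasonal_amplitude < 0 || seasonal_mean + seasonal_amplitude > 1) {
    bad("seasonal_mean", "seasonal_mean +/- seasonal_amplitude must lie in [0, 1]")
  }
  if (noise_sd < 0) bad("noise_sd", "must be non-negative")
  if (ar1_coeff < 0 || ar1_coeff >= 1) bad("ar1_coeff", "must be in [0, 1)")
  if (cloud_fraction < 0 || cloud_fraction > 1) bad("cloud_fraction", "must be in [0, 1]")
  if (!events_per_pixel %in% 0:2) bad("events_per_pixel", "must be 0, 1 or 2")
  if (event_pixel_fraction < 0 || event_pixel_fraction > 1) {
    bad("event_pixel_fraction", "must be in [0, 1]")
  }
  if (length(a_true_range) != 2 || any(a_true_range >= 0) ||
      a_true_range[1] > a_true_range[2]) {
    bad("a_true_range", "must be an increasing pair of negative values")
  }
  if (length(b_true_range) != 2 || any(b_true_range <= 0) || any(b_true_range > 1) ||
      b_true_range[1] > b_true_range[2]) {
    bad("b_true_range", "must be an increasing pair within (0, 1]")
  }
  if (events_per_pixel == 2L && event_gap_range[1] < 48) {
    bad("event_gap_range", "minimum gap must be >= 48 months for two-event scenes")
  }
  if (event_gap_range[1] > event_gap_range[2] || event_gap_range[1] < 0) {
    bad("event_gap_range", "must be an increasing non-negative pair (months)")
  }
  if (any(burn_uncertainty_range < 0) ||
      burn_uncertainty_range[1] > burn_uncertainty_range[2]) {
    bad("burn_uncertainty_range", "must be an increasing non-negative pair (days)")
  }
  if (!all(landcover_categories %in% landcover_category_levels())) {
    bad("landcover_categories", "must be a subset of the eight aggregated categories")
  }
  if (climate_cell_size < 1) bad("climate_cell_size", "must be >= 1")
  if (!is.null(climate_anomaly_spec)) {
    need <- c("variable", "year", "season", "z")
    if (!is.data.frame(climate_anomaly_spec) ||
        !all(need %in% names(climate_anomaly_spec))) {
      bad("climate_anomaly_spec",
          "must be a data.frame with columns variable, year, season, z")
    }
    if (!all(climate_anomaly_spec$variable %in% c("precip", "temp"))) {
      bad("climate_anomaly_spec", "variable must be \"precip\" or \"temp\"")
    }
    if (!all(climate_anomaly_spec$season %in% c("DJF", "MAM", "JJA", "SON"))) {
      bad("climate_anomaly_spec", "season must be DJF, MAM, JJA or SON")
    }
  }
  structure(list(
    grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
    start_year = as.integer(start_year), end_year = as.integer(end_year),
    cadence = 16L,
    seasonal_amplitude = seasonal_amplitude, seasonal_mean = seasonal_mean,
    trend_slope = trend_slope, noise_sd = noise_sd, ar1_coeff = ar1_coeff,
    cloud_fraction = cloud_fraction,
    events_per_pixel = as.integer(events_per_pixel),
    event_pixel_fraction = event_pixel_fraction,
    a_true_range = a_true_range, b_true_range = b_true_range,
    b2_coupling = match.arg(b2_coupling), b2_offset = b2_offset,
    event_gap_range = as.integer(event_gap_range),
    burn_uncertainty_range = as.integer(burn_uncertainty_range),
    landcover_categories = landcover_categories,
    hemisphere = match.arg(hemisphere),
    climate_cell_size = as.integer(climate_cell_size),
    climate_anomaly_spec = climate_anomaly_spec,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# hemisphere-dependent fire season (months) and seasonal phase
hemisphere_fire_season <- function(hemisphere) {
  if (hemisphere == "north") 6:10 else c(12L, 1L, 2L, 3L, 4L)
}

seasonal_evi <- function(doy, cfg) {
  peak <- if (cfg$hemisphere == "north") 196 else 15
  cfg$seasonal_mean + cfg$seasonal_amplitude * cos(2 * pi * (doy - peak) / 365.25)
}

# climatological monthly climate cycles (Mediterranean-type: wet mild winters,
# hot dry summers); winter month depends on hemisphere
precip_climatology <- function(month, hemisphere) {
  peak <- if (hemisphere == "north") 1 else 7
  60 + 50 * cos(2 * pi * (month - peak) / 12)
}

temp_climatology <- function(month, hemisphere) {
  peak <- if (hemisphere == "north") 7 else 1
  15 + 10 * cos(2 * pi * (month - peak) / 12)
}

precip_noise_frac <- function() 0.25  # sd as a fraction of the monthly climatology
temp_noise_sd <- function() 1.2       # deg C, monthly

season_month_sets <- function() {
  list(DJF = c(12L, 1L, 2L), MAM = 3:5, JJA = 6:8, SON = 9:11)
}

# sample event months for one pixel; returns integer month indices
sample_event_months <- function(cfg, n_mon, season) {
  ny <- cfg$end_year - cfg$start_year + 1L
  feas1 <- which(month_of_index(1:n_mon) %in% season)
  feas1 <- feas1[feas1 >= 13L & feas1 <= n_mon - 24L]
  if (cfg$events_per_pixel == 1L) {
    if (!length(feas1)) stop("invalid `end_year`: record too short for one event")
    return(feas1[sample.int(length(feas1), 1L)])
  }
  gmin <- cfg$event_gap_range[1]; gmax <- cfg$event_gap_range[2]
  feasA <- feas1[feas1 <= n_mon - 24L - gmin]
  if (length(feasA)) {
    for (try in 1:500) {
      m1 <- feasA[sample.int(length(feasA), 1L)]
      g <- sample.int(gmax - gmin + 1L, 1L) + gmin - 1L
      m2 <- m1 + g
      if (m2 <= n_mon - 24L && month_of_index(m2) %in% season) return(c(m1, m2))
    }
  }
  # deterministic fallback: first feasible pair
  for (m1 in feasA) for (g in gmin:gmax) {
    m2 <- m1 + g
    if (m2 <= n_mon - 24L && month_of_index(m2) %in% season) return(c(m1, m2))
  }
  stop("invalid `event_gap_range`: no feasible two-event schedule in this record")
}

#' Simulate a synthetic fire-recovery scene with known ground truth
#'
#' Generates a co-registered set of inputs for the full analysis pipeline: a
#' raw 16-day EVI cube with quality flags, a monthly burned-area record (burn
#' day-of-year and burn-date uncertainty), a land-cover code map, monthly
#' climate series on a coarser cell grid, and a truth ledger recording every
#' injected parameter. The undisturbed signal is
#' `seasonal + trend + AR(1) noise`; from each fire event's month `t0` onward
#' the deficit `a * exp(-b * (t - t0))` (in whole months since the event) is
#' added, a later event replacing the deficit of the earlier one. Values are
#' clamped to `[0, 1]`. Low-quality observations are darkened multiplicatively,
#' emulating cloud contamination.
#'
#' @param config a [sim_config()].
#' @return a `fire_scene` list: `evi` (raw [evi_cube()] with quality flags),
#'   `burns` (data.frame of burn records), `landcover_codes` (matrix),
#'   `climate` (data.frame of monthly cell series), `ledger` (list with
#'   `pixels` and `events` data.frames) and `config`.
#' @export
simulate_scene <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)

  dates <- composite_dates(cfg$start_year, cfg$end_year)
  n_t <- length(dates)
  doy <- rep(composite_doys(), times = cfg$end_year - cfg$start_year + 1L)
  yearfrac <- as.integer(format(dates, "%Y")) - cfg$start_year + (doy - 1) / 365.25
  mi_t <- composite_month_index(dates, cfg$start_year)
  n_mon <- n_record_months(cfg$start_year, cfg$end_year)
  n_rows <- cfg$grid_rows; n_cols <- cfg$grid_cols
  n_px <- n_rows * n_cols

  # pixel table (column-major ids)
  rc <- pixel_rowcol(seq_len(n_px), n_rows)
  landcover <- sample(cfg$landcover_categories, n_px, replace = TRUE)
  code_tab <- lcc_code_table()
  lc_codes <- vapply(landcover, function(cat) {
    cands <- code_tab$code[code_tab$category == cat]
    cands[sample.int(length(cands), 1L)]
  }, integer(1))
  lc_map <- matrix(lc_codes, n_rows, n_cols)

  base <- seasonal_evi(doy, cfg) + cfg$trend_slope * yearfrac

  if (cfg$noise_sd > 0) {
    E <- matrix(0, n_t, n_px)
    E[1, ] <- stats::rnorm(n_px, 0, cfg$noise_sd)
    innov <- cfg$noise_sd * sqrt(1 - cfg$ar1_coeff^2)
    for (t in 2:n_t) {
      E[t, ] <- cfg$ar1_coeff * E[t - 1, ] + stats::rnorm(n_px, 0, innov)
    }
  } else {
    E <- matrix(0, n_t, n_px)
  }

  season <- hemisphere_fire_season(cfg$hemisphere)
  n_ev_px <- round(cfg$event_pixel_fraction * n_px)
  event_px <- if (cfg$events_per_pixel == 0L || n_ev_px == 0L) integer(0) else
    sort(sample.int(n_px, n_ev_px))

  ev_list <- vector("list", length(event_px))
  V <- matrix(base, n_t, n_px) + E
  for (k in seq_along(event_px)) {
    p <- event_px[k]
    m_ev <- sample_event_months(cfg, n_mon, season)
    a <- stats::runif(length(m_ev), cfg$a_true_range[1], cfg$a_true_range[2])
    b <- stats::runif(length(m_ev), cfg$b_true_range[1], cfg$b_true_range[2])
    if (length(m_ev) == 2L && cfg$b2_coupling == "offset") {
      b[2] <- b[1] + cfg$b2_offset
    }
    term <- numeric(n_t)
    for (e in seq_along(m_ev)) {
      after <- mi_t >= m_ev[e]
      term[after] <- a[e] * exp(-b[e] * (mi_t[after] - m_ev[e]))
    }
    V[, p] <- V[, p] + term
    yr <- year_of_index(m_ev, cfg$start_year)
    mo <- month_of_index(m_ev)
    dim_days <- days_in_month(yr, mo)
    day_in <- vapply(dim_days, function(d) sample.int(d, 1L) - 1L, integer(1))
    doy0 <- as.integer(format(as.Date(sprintf("%d-%02d-01", yr, mo)), "%j"))
    unc <- cfg$burn_uncertainty_range[1] +
      vapply(seq_along(m_ev), function(i) {
        sample.int(cfg$burn_uncertainty_range[2] - cfg$burn_uncertainty_range[1] + 1L, 1L) - 1L
      }, integer(1))
    ev_list[[k]] <- data.frame(
      pixel = p, row = rc$row[p], col = rc$col[p], event = seq_along(m_ev),
      year = yr, month = mo, month_index = m_ev,
      burn_doy = doy0 + day_in, uncertainty_days = unc,
      a_true = a, b_true = b
    )
  }
  events <- if (length(ev_list)) do.call(rbind, ev_list) else
    data.frame(pixel = integer(0), row = integer(0), col = integer(0),
               event = integer(0), year = integer(0), month = integer(0),
               month_index = integer(0), burn_doy = integer(0),
               uncertainty_days = integer(0), a_true = numeric(0),
               b_true = numeric(0))

  V <- clamp01(V)
  Q <- matrix(stats::runif(n_t * n_px) < cfg$cloud_fraction, n_t, n_px)
  V_obs <- V
  nq <- sum(Q)
  if (nq > 0) V_obs[Q] <- clamp01(V[Q] * stats::runif(nq, 0.3, 0.8))

  cube <- evi_cube(array(V_obs, c(n_t, n_rows, n_cols)), dates,
                   quality = array(Q, c(n_t, n_rows, n_cols)),
                   state = "raw", start_year = cfg$start_year)

  climate <- simulate_climate(cfg)

  pixels <- data.frame(
    pixel = seq_len(n_px), row = rc$row, col = rc$col,
    landcover = landcover, landcover_code = lc_codes,
    trend_slope = cfg$trend_slope,
    seasonal_mean = cfg$seasonal_mean, seasonal_amplitude = cfg$seasonal_amplitude
  )

  structure(list(
    evi = cube,
    burns = events[, c("pixel", "row", "col", "year", "month", "month_index",
                       "burn_doy", "uncertainty_days")],
    landcover_codes = lc_map,
    climate = climate,
    ledger = list(pixels = pixels, events = events),
    config = cfg
  ), class = "fire_scene")
}

# monthly climate series per coarse cell, with optional injected seasonal
# standardized anomalies
simulate_climate <- function(cfg) {
  cr <- ceiling(cfg$grid_rows / cfg$climate_cell_size)
  cc <- ceiling(cfg$grid_cols / cfg$climate_cell_size)
  ny <- cfg$end_year - cfg$start_year + 1L
  months <- rep(1:12, times = ny)
  years <- rep(cfg$start_year:cfg$end_year, each = 12L)
  n_m <- length(months)
  pc <- precip_climatology(months, cfg$hemisphere)
  tc <- temp_climatology(months, cfg$hemisphere)

  cells <- expand.grid(cell_row = seq_len(cr), cell_col = seq_len(cc))
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    precip <- pmax(0, pc + stats::rnorm(n_m, 0, precip_noise_frac() * pc))
    temp <- tc + stats::rnorm(n_m, 0, temp_noise_sd())
    out[[i]] <- data.frame(
      cell = i, cell_row = cells$cell_row[i], cell_col = cells$cell_col[i],
      year = years, month = months, precip = precip, temp = temp,
      hemisphere = cfg$hemisphere
    )
  }
  clim <- do.call(rbind, out)

  spec <- cfg$climate_anomaly_spec
  if (!is.null(spec) && nrow(spec)) {
    smap <- season_month_sets()
    for (i in seq_len(nrow(spec))) {
      mons <- smap[[spec$season[i]]]
      # a season instance is labelled by the year of its mid/late months
      # (DJF of year y = Dec y-1, Jan y, Feb y)
      tgt <- if (spec$season[i] == "DJF") {
        (clim$month == 12L & clim$year == spec$year[i] - 1L) |
          (clim$month %in% c(1L, 2L) & clim$year == spec$year[i])
      } else {
        clim$month %in% mons & clim$year == spec$year[i]
      }
      if (spec$variable[i] == "temp") {
        # seasonal aggregate is the 3-month mean; shift every month by z * sd(agg)
        sd_agg <- temp_noise_sd() / sqrt(3)
        clim$temp[tgt] <- clim$temp[tgt] + spec$z[i] * sd_agg
      } else {
        # seasonal aggregate is the 3-month sum
        sd_agg <- precip_noise_frac() *
          sqrt(sum(precip_climatology(mons, cfg$hemisphere)^2))
        clim$precip[tgt] <- pmax(0, clim$precip[tgt] + spec$z[i] * sd_agg / 3)
      }
    }
  }
  clim
}
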