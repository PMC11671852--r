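# Meteorological seasons (3-month blocks). A season instance is labelled by
# the year of its January for DJF (Dec y-1, Jan y, Feb y) and by the calendar
# year otherwise.

season_codes <- function() c("DJF", "MAM", "JJA", "SON")

#' Meteorological season of a calendar month
#'
#' @param month month number 1-12.
#' @return `"DJF"`, `"MAM"`, `"JJA"` or `"SON"`.
#' @export
season_of_month <- function(month) {
  c("DJF", "DJF", "MAM", "MAM", "MAM", "JJA",
    "JJA", "JJA", "SON", "SON", "SON", "DJF")[month]
}

season_instance_year <- function(year, month) year + (month == 12L)

#' Hemisphere-local season name
#'
#' Season labels flip across the equator (DJF is boreal winter, austral
#' summer); the labelling never changes the underlying z-scores.
#'
#' @param season `"DJF"`, `"MAM"`, `"JJA"` or `"SON"`.
#' @param hemisphere `"north"` or `"south"`.
#' @return local name: winter/spring/summer/autumn.
#' @export
local_season_name <- function(season, hemisphere) {
  north <- c(DJF = "winter", MAM = "spring", JJA = "summer", SON = "autumn")
  south <- c(DJF = "summer", MAM = "autumn", JJA = "winter", SON = "spring")
  unname(ifelse(hemisphere == "south", south[season], north[season]))
}

# per-instance seasonal aggregates: precipitation summed, temperature averaged
seasonal_instances <- function(climate) {
  season <- season_of_month(climate$month)
  iyear <- season_instance_year(climate$year, climate$month)
  key <- paste(climate$cell, season, iyear, sep = "\r")
  n <- tapply(climate$precip, key, length)
  keep <- names(n)[n == 3L]  # complete 3-month instances only
  idx <- key %in% keep
  agg_p <- tapply(climate$precip[idx], key[idx], sum)
  agg_t <- tapply(climate$temp[idx], key[idx], mean)
  parts <- do.call(rbind, strsplit(names(agg_p), "\r", fixed = TRUE))
  data.frame(cell = as.integer(parts[, 1]), season = parts[, 2],
             instance_year = as.integer(parts[, 3]),
             precip_sum = as.numeric(agg_p), temp_mean = as.numeric(agg_t))
}

#' Seasonal climatology (mean and standard deviation per season)
#'
#' Aggregates the monthly record into 3-month season instances (precipitation
#' summed, temperature averaged within each instance) and returns, per climate
#' cell and season, the mean and sample standard deviation (n-1 over the ~22
#' instances of a 22-year record). Seasons with zero spread are flagged
#' degenerate: no anomaly can be standardized against them.
#'
#' @param climate monthly climate data.frame (`cell`, `year`, `month`,
#'   `precip`, `temp`, `hemisphere`), e.g. from [simulate_scene()].
#' @return a `seasonal_climatology` data.frame: cell, season, local_name,
#'   n_instances, precip_mean, precip_sd, temp_mean, temp_sd,
#'   degenerate_precip, degenerate_temp.
#' @export
seasonal_climatology <- function(climate) {
  inst <- seasonal_instances(climate)
  hemi <- climate$hemisphere[match(inst$cell, climate$cell)]
  key <- paste(inst$cell, inst$season, sep = "\r")
  stat <- function(v, f) as.numeric(tapply(v, key, f))
  nm <- names(tapply(inst$precip_sum, key, length))
  parts <- do.call(rbind, strsplit(nm, "\r", fixed = TRUE))
  out <- data.frame(
    cell = as.integer(parts[, 1]), season = parts[, 2],
    n_instances = as.integer(tapply(inst$precip_sum, key, length)),
    precip_mean = stat(inst$precip_sum, mean),
    precip_sd = stat(inst$precip_sum, stats::sd),
    temp_mean = stat(inst$temp_mean, mean),
    temp_sd = stat(inst$temp_mean, stats::sd)
  )
  out$local_name <- local_season_name(out$season,
                                      hemi[match(out$cell, inst$cell)])
  out$degenerate_precip <- out$precip_sd == 0
  out$degenerate_temp <- out$temp_sd == 0
  class(out) <- c("seasonal_climatology", "data.frame")
  out
}

#' Seasonal standardized anomalies (z-scores)
#'
#' For every complete season instance, `z = (aggregate - seasonal mean) /
#' seasonal sd`. Instances of degenerate seasons (zero sd) are masked `NA`.
#'
#' @param climate monthly climate data.frame.
#' @param climatology a [seasonal_climatology()] of the same record.
#' @return data.frame: cell, season, instance_year, z_precip, z_temp.
#' @export
standardized_anomaly <- function(climate, climatology) {
  inst <- seasonal_instances(climate)
  i <- match(paste(inst$cell, inst$season),
             paste(climatology$cell, climatology$season))
  z_p <- (inst$precip_sum - climatology$precip_mean[i]) / climatology$precip_sd[i]
  z_t <- (inst$temp_mean - climatology$temp_mean[i]) / climatology$temp_sd[i]
  z_p[climatology$degenerate_precip[i]] <- NA_real_
  z_t[climatology$degenerate_temp[i]] <- NA_real_
  data.frame(cell = inst$cell, season = inst$season,
             instance_year = inst$instance_year,
             z_precip = z_p, z_temp = z_t)
}

# every month of the record inherits the z of the season instance containing it
monthly_z <- function(climate, anomalies, start_year) {
  season <- season_of_month(climate$month)
  iyear <- season_instance_year(climate$year, climate$month)
  i <- match(paste(climate$cell, season, iyear),
             paste(anomalies$cell, anomalies$season, anomalies$instance_year))
  data.frame(cell = climate$cell,
             month_index = (climate$year - start_year) * 12L + climate$month,
             z_precip = anomalies$z_precip[i],
             z_temp = anomalies$z_temp[i])
}

#' Post-fire quarterly climate-anomaly profile
#'
#' For one fire event, averages the seasonal z-scores inherited by the 12
#' months following the fire month into four quarters: Q1 = months 1-3 after
#' the fire, Q2 = 4-6, Q3 = 7-9, Q4 = 10-12. Quarters reaching beyond the
#' record (or into masked z) are `NA`.
#'
#' @param zm a [monthly_z()]-style table for one climate cell (columns
#'   `month_index`, `z_precip`, `z_temp`).
#' @param fire_month month index of the fire.
#' @return one-row data.frame with `precip_q1..q4` and `temp_q1..q4`.
#' @export
postfire_profile <- function(zm, fire_month) {
  zm <- zm[order(zm$month_index), ]
  res <- as.list(stats::setNames(rep(NA_real_, 8L),
                                 c(paste0("precip_q", 1:4), paste0("temp_q", 1:4))))
  for (q in 1:4) {
    mi <- fire_month + (3L * (q - 1L) + 1L):(3L * q)
    rows <- match(mi, zm$month_index)
    if (anyNA(rows)) next
    res[[paste0("precip_q", q)]] <- mean(zm$z_precip[rows])
    res[[paste0("temp_q", q)]] <- mean(zm$z_temp[rows])
  }
  as.data.frame(res)
}

#' Nearest climate cell of a pixel
#'
#' Climate fields live on a coarser grid (`cell_size` pixels per cell); each
#' pixel reads the cell containing it, which is also the nearest cell centre.
#'
#' @param row,col pixel coordinates.
#' @param cell_size pixels per climate cell along each axis.
#' @param n_cell_rows number of climate cell rows.
#' @return integer cell id (column-major over the cell grid).
#' @export
nearest_climate_cell <- function(row, col, cell_size, n_cell_rows) {
  cr <- ceiling(row / cell_size)
  cc <- ceiling(col / cell_size)
  (cc - 1L) * n_cell_rows + cr
}

#' Post-fire anomaly profiles for every paired event
#'
#' @param climate monthly climate table of the scene.
#' @param pairs a [select_twice_burned()] `pairs` table.
#' @param cell_size pixels per climate cell.
#' @param start_year first calendar year of the record.
#' @return data.frame, one row per pixel x event, with the quarterly z
#'   profiles of precipitation and temperature.
#' @export
scene_postfire_profiles <- function(climate, pairs, cell_size, start_year) {
  climatology <- seasonal_climatology(climate)
  anomalies <- standardized_anomaly(climate, climatology)
  zm <- monthly_z(climate, anomalies, start_year)
  n_cell_rows <- max(climate$cell_row)
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    cell <- nearest_climate_cell(pairs$row[i], pairs$col[i], cell_size, n_cell_rows)
    zc <- zm[zm$cell == cell, ]
    for (e in 1:2) {
      fm <- if (e == 1L) pairs$m1[i] else pairs$m2[i]
      prof <- postfire_profile(zc, fm)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(pixel = pairs$pixel[i], event = e, cell = cell,
                   fire_month = fm), prof)
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' Group mean anomalies by quarter, event, contrast group and land cover
#'
#' @param profiles a [scene_postfire_profiles()] table.
#' @param pairs a grouped [pair_events()] table (after
#'   [select_extreme_diffs()]).
#' @return long data.frame: variable, quarter, event, group, landcover,
#'   mean_z, n. Empty cells are omitted (with a warning when a whole group
#'   vanishes).
#' @export
group_anomalies <- function(profiles, pairs) {
  m <- merge(profiles, pairs[, c("pixel", "landcover", "group")], by = "pixel")
  if (!nrow(m)) {
    warning("no overlap between profiles and pairs")
    return(data.frame())
  }
  out <- list()
  for (v in c("precip", "temp")) for (q in 1:4) {
    colnm <- sprintf("%s_q%d", v, q)
    vals <- m[[colnm]]
    ok <- is.finite(vals)
    if (!any(ok)) next
    key <- factor(paste(m$event[ok], m$group[ok], m$landcover[ok], sep = "\r"))
    mu <- tapply(vals[ok], key, mean)
    nn <- tapply(vals[ok], key, length)
    parts <- do.call(rbind, strsplit(names(mu), "\r", fixed = TRUE))
    out[[length(out) + 1L]] <- data.frame(
      variable = v, quarter = q,
      event = as.integer(parts[, 1]), group = parts[, 2],
      landcover = parts[, 3],
      mean_z = as.numeric(mu), n = as.integer(nn)
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
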