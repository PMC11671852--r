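#' Write a simulated scene to a directory of portable text files
#'
#' Serializes every component of a [simulate_scene()] result: the EVI cube and
#' quality flags as a long-format CSV (`time_index, date, row, col, evi,
#' low_quality`), burned-area records, the land-cover code map, the monthly
#' climate series and both truth-ledger tables as CSV, and the generating
#' configuration as YAML. [read_scene()] reproduces the arrays to within float
#' representation.
#'
#' @param scene a `fire_scene`.
#' @param directory output directory (created if missing).
#' @return invisibly, the vector of files written.
#' @export
write_scene <- function(scene, directory) {
  stopifnot(inherits(scene, "fire_scene"))
  ok <- dir.exists(directory) || dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(directory, 2L) != 0L) {
    stop("cannot write to directory: ", directory)
  }
  d <- dim(scene$evi$values)
  rc <- expand.grid(row = seq_len(d[2]), col = seq_len(d[3]))
  evi_df <- data.frame(
    time_index = rep(seq_len(d[1]), times = d[2] * d[3]),
    date = rep(as.character(scene$evi$dates), times = d[2] * d[3]),
    row = rep(rc$row, each = d[1]),
    col = rep(rc$col, each = d[1]),
    evi = as.vector(scene$evi$values),
    low_quality = as.integer(as.vector(scene$evi$quality))
  )
  lc_df <- data.frame(
    row = rc$row, col = rc$col,
    code = as.vector(scene$landcover_codes)
  )
  paths <- file.path(directory, c(
    "evi.csv", "burns.csv", "landcover.csv", "climate.csv",
    "ledger_events.csv", "ledger_pixels.csv", "config.yaml"
  ))
  utils::write.csv(evi_df, paths[1], row.names = FALSE)
  utils::write.csv(scene$burns, paths[2], row.names = FALSE)
  utils::write.csv(lc_df, paths[3], row.names = FALSE)
  utils::write.csv(scene$climate, paths[4], row.names = FALSE)
  utils::write.csv(scene$ledger$events, paths[5], row.names = FALSE)
  utils::write.csv(scene$ledger$pixels, paths[6], row.names = FALSE)
  cfg <- scene$config
  cfg_list <- unclass(cfg)
  if (!is.null(cfg_list$climate_anomaly_spec)) {
    cfg_list$climate_anomaly_spec <- lapply(
      seq_len(nrow(cfg$climate_anomaly_spec)),
      function(i) as.list(cfg$climate_anomaly_spec[i, ])
    )
  }
  yaml::write_yaml(cfg_list, paths[7])
  invisible(paths)
}

#' Read a scene written by [write_scene()]
#'
#' @param directory directory holding the scene files.
#' @return a `fire_scene` list equivalent to the one written.
#' @export
read_scene <- function(directory) {
  pth <- function(f) file.path(directory, f)
  cfg_list <- yaml::read_yaml(pth("config.yaml"))
  if (!is.null(cfg_list$climate_anomaly_spec)) {
    cfg_list$climate_anomaly_spec <-
      do.call(rbind, lapply(cfg_list$climate_anomaly_spec, as.data.frame))
  }
  cfg <- do.call(sim_config, cfg_list[setdiff(names(cfg_list), "cadence")])
  evi_df <- utils::read.csv(pth("evi.csv"))
  n_t <- max(evi_df$time_index)
  n_rows <- max(evi_df$row); n_cols <- max(evi_df$col)
  ord <- order(evi_df$col, evi_df$row, evi_df$time_index)
  vals <- array(evi_df$evi[ord], c(n_t, n_rows, n_cols))
  qual <- array(evi_df$low_quality[ord] == 1L, c(n_t, n_rows, n_cols))
  dates <- as.Date(evi_df$date[ord][seq_len(n_t)])
  cube <- evi_cube(vals, dates, quality = qual, state = "raw",
                   start_year = cfg$start_year)
  lc_df <- utils::read.csv(pth("landcover.csv"))
  lc <- matrix(NA_integer_, n_rows, n_cols)
  lc[cbind(lc_df$row, lc_df$col)] <- lc_df$code
  structure(list(
    evi = cube,
    burns = utils::read.csv(pth("burns.csv")),
    landcover_codes = lc,
    climate = utils::read.csv(pth("climate.csv")),
    ledger = list(
      pixels = utils::read.csv(pth("ledger_pixels.csv")),
      events = utils::read.csv(pth("ledger_events.csv"))
    ),
    config = cfg
  ), class = "fire_scene")
}
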