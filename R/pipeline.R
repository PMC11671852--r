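#' Default configuration of the end-to-end pipeline
#'
#' Bundles all stage parameters at their standard values: 7-day burn-date
#' uncertainty cutoff, 48-month (4-year) recurrence gap, 24-60 month (2-5
#' year) fitting windows with the 0.25 adjusted r-squared screen, 3-month
#' severity search, 3-month pre-fire median, 25th-75th IQR contrast selection,
#' quantile regression at tau 0.01/0.99, and the 3-month FFT cutoff / 0.5
#' LOESS span of the pre-processing chain.
#'
#' @param sim a [sim_config()] describing the scene (or scene to simulate).
#' @param region fire-season region passed to [region_season()].
#' @param ... overrides for any pipeline parameter (see the returned list).
#' @return a `run_config` list.
#' @export
default_run_config <- function(sim = sim_config(), region = "mediterranean", ...) {
  cfg <- list(
    sim = sim,
    region = region,
    smooth = TRUE, detrend = TRUE,
    keep_period_months = 3, loess_span = 0.5,
    max_uncertainty_days = 7,
    min_gap_months = 48, min_tail_months = 24,
    pair_mode = "exactly_two",
    severity_search_months = 3,
    windows = c(24, 36, 48, 60), r2_min = 0.25,
    intercept = TRUE, min_points = 12,
    validity_rule = "both_valid",
    iqr_bounds = c(0.25, 0.75),
    taus = c(0.01, 0.99),
    n_bins = 6L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown run_config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; top-level keys are [default_run_config()] fields,
#'   with `sim` holding [sim_config()] fields.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim_args <- raw$sim %||% list()
  if (!is.null(sim_args$climate_anomaly_spec)) {
    sim_args$climate_anomaly_spec <-
      do.call(rbind, lapply(sim_args$climate_anomaly_spec, as.data.frame))
  }
  raw$sim <- NULL
  do.call(default_run_config,
          c(list(sim = do.call(sim_config, sim_args)), raw))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# attribute each burned-but-unpaired pixel to exactly one exclusion rule
attribute_exclusions <- function(history, flagged, season, cfg, sel) {
  burned <- sort(unique(history$pixel))
  paired <- sel$pairs$pixel
  out <- list()
  sel_reason <- stats::setNames(as.character(sel$exclusions$reason),
                                sel$exclusions$pixel)
  for (p in setdiff(burned, paired)) {
    raw <- history[history$pixel == p, ]
    raw_in <- sum(raw$month %in% season$months)
    filt_in <- sum(raw$month %in% season$months &
                     raw$uncertainty_days <= cfg$max_uncertainty_days)
    reason <- if (!is.na(sel_reason[as.character(p)]) &&
                  sel_reason[as.character(p)] %in% c("gap", "tail")) {
      sel_reason[as.character(p)]
    } else if (raw_in == 2L && filt_in < 2L) {
      "uncertainty"
    } else if (nrow(raw) == 2L && raw_in < 2L) {
      "season"
    } else {
      "count"
    }
    out[[length(out) + 1L]] <- data.frame(pixel = p, reason = reason)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(pixel = integer(0), reason = character(0))
}

#' Run the full analysis pipeline on a (simulated) scene
#'
#' Executes simulate -> pre-process -> fire-history filtering -> recovery
#' fitting -> modulation analyses -> climate anomalies with one configuration,
#' optionally persisting every product as CSV plus a YAML run report. The run
#' is fully determined by the configuration (all randomness flows from
#' `config$sim$seed`), so identical configs give identical outputs.
#'
#' @param config a [default_run_config()].
#' @param out_dir optional output directory for the CSV products and
#'   `report.yaml`.
#' @param scene optional pre-built scene (defaults to
#'   `simulate_scene(config$sim)`).
#' @return invisibly, a list with every stage product (`scene`, `cube`, `gy`,
#'   `landcover`, `frequency`, `selection`, `exclusions`, `fits`, `pairs`,
#'   `grouped`, `wilcoxon`, `quantile_fits`, `prefire_bins`, `profiles`,
#'   `climate_summary`, `report`).
#' @export
run_pipeline <- function(config, out_dir = NULL, scene = NULL) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  if (is.null(scene)) scene <- simulate_scene(cfg$sim)
  season <- region_season(cfg$region)

  cube <- preprocess_cube(scene$evi, smooth = cfg$smooth, detrend = cfg$detrend,
                          keep_period_months = cfg$keep_period_months,
                          span_fraction = cfg$loess_span)
  landcover <- aggregate_landcover(scene$landcover_codes)

  history <- fire_history(scene$burns)
  filtered <- filter_burn_uncertainty(history, cfg$max_uncertainty_days)
  flagged <- flag_in_season(filtered, season)
  frequency <- fire_frequency(flagged)
  n_mon <- n_record_months(cfg$sim$start_year, cfg$sim$end_year)
  sel <- select_twice_burned(flagged, n_mon,
                             min_gap_months = cfg$min_gap_months,
                             min_tail_months = cfg$min_tail_months,
                             mode = cfg$pair_mode)
  exclusions <- attribute_exclusions(history, flagged, season, cfg, sel)

  gy <- compute_gorgeous_year(cube)
  fits <- fit_scene_recovery(cube, gy, sel$pairs, landcover = landcover,
                             search_months = cfg$severity_search_months,
                             windows = cfg$windows, r2_min = cfg$r2_min,
                             intercept = cfg$intercept,
                             min_points = cfg$min_points)

  pairs <- if (!is.null(fits)) pair_events(fits, rule = cfg$validity_rule) else NULL
  wil <- if (!is.null(pairs) && nrow(pairs) >= 5L)
    wilcoxon_signed_rank(pairs$b_diff) else NULL
  grouped <- if (!is.null(pairs) && nrow(pairs))
    select_extreme_diffs(pairs, cfg$iqr_bounds[1], cfg$iqr_bounds[2]) else pairs

  long <- if (!is.null(grouped) && nrow(grouped)) pairs_long(grouped) else NULL
  qr_fits <- NULL
  if (!is.null(long)) {
    ok <- is.finite(long$a_rel) & is.finite(long$b)
    for (e in 1:2) {
      sub <- long[ok & long$event == e, ]
      if (nrow(sub) >= 20L && diff(range(sub$a_rel)) > 0) {
        for (tau in cfg$taus) {
          f <- quantile_regression(sub$a_rel, sub$b, tau)
          qr_fits <- rbind(qr_fits, data.frame(
            event = e, tau = tau, intercept = f$intercept,
            slope = f$slope, pinball_loss = f$pinball_loss, n = f$n))
        }
      }
    }
  }
  bins <- if (!is.null(long)) bin_prefire(long, cfg$n_bins) else NULL

  keep_pairs <- if (is.null(grouped)) sel$pairs[0, ] else
    sel$pairs[sel$pairs$pixel %in% grouped$pixel, ]
  profiles <- if (nrow(keep_pairs))
    scene_postfire_profiles(scene$climate, keep_pairs,
                            cfg$sim$climate_cell_size, cfg$sim$start_year) else NULL
  clim_sum <- if (!is.null(profiles) && !is.null(grouped) && nrow(grouped))
    group_anomalies(profiles, grouped) else NULL

  n_pairs_out <- if (is.null(sel$pairs)) 0L else nrow(sel$pairs)
  report <- list(
    parameters = cfg[setdiff(names(cfg), "sim")],
    sim = unclass(cfg$sim)[setdiff(names(cfg$sim), "climate_anomaly_spec")],
    counts = list(
      pixels_total = cfg$sim$grid_rows * cfg$sim$grid_cols,
      pixels_burned = length(unique(scene$burns$pixel)),
      excluded = as.list(table(exclusions$reason)),
      pairs_selected = n_pairs_out,
      fits_valid = if (is.null(fits)) 0L else sum(fits$valid),
      pairs_eligible = if (is.null(pairs)) 0L else nrow(pairs),
      group_sizes = if (is.null(grouped) || !nrow(grouped)) list() else
        as.list(table(grouped$group))
    )
  )

  res <- list(scene = scene, cube = cube, gy = gy, landcover = landcover,
              frequency = frequency, selection = sel, exclusions = exclusions,
              fits = fits, pairs = pairs, grouped = grouped, wilcoxon = wil,
              quantile_fits = qr_fits, prefire_bins = bins,
              profiles = profiles, climate_summary = clim_sum, report = report)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, name) if (!is.null(df) && nrow(df))
      utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
    wr(res$fits, "fits.csv")
    wr(res$selection$pairs, "pairs_selected.csv")
    wr(res$exclusions, "exclusions.csv")
    wr(res$frequency$table, "fire_frequency.csv")
    wr(res$grouped, "event_pairs.csv")
    wr(res$quantile_fits, "quantile_fits.csv")
    wr(res$prefire_bins, "prefire_bins.csv")
    wr(res$climate_summary, "climate_summary.csv")
    if (!is.null(wil)) {
      utils::write.csv(data.frame(statistic = wil$statistic,
                                  p_value = wil$p_value, n = wil$n_used,
                                  method = wil$method),
                       file.path(out_dir, "wilcoxon.csv"), row.names = FALSE)
    }
    yaml::write_yaml(report, file.path(out_dir, "report.yaml"))
  }
  invisible(res)
}
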