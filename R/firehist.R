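#' Fire-season definition for a study region
#'
#' Extended fire seasons: Mediterranean basin and California, June-October;
#' Australia, October-February; South Africa and Chile, December-April.
#'
#' @param region one of `"mediterranean"`, `"california"`, `"australia"`,
#'   `"south_africa"`, `"chile"`, or `"custom"` (then supply `months`).
#' @param months for `region = "custom"`, an ordered vector of month numbers
#'   (may wrap the year boundary).
#' @param hemisphere hemisphere of the region; inferred for the named regions.
#' @return a `region_season` list with `region`, `months`, `hemisphere`.
#' @export
region_season <- function(region = c("mediterranean", "california", "australia",
                                     "south_africa", "chile", "custom"),
                          months = NULL, hemisphere = NULL) {
  region <- match.arg(region)
  defs <- list(
    mediterranean = list(months = 6:10, hemisphere = "north"),
    california    = list(months = 6:10, hemisphere = "north"),
    australia     = list(months = c(10L, 11L, 12L, 1L, 2L), hemisphere = "south"),
    south_africa  = list(months = c(12L, 1L, 2L, 3L, 4L), hemisphere = "south"),
    chile         = list(months = c(12L, 1L, 2L, 3L, 4L), hemisphere = "south")
  )
  if (region == "custom") {
    if (is.null(months) || !length(months) || !all(months %in% 1:12)) {
      stop("custom region requires `months` with codes in 1..12")
    }
    if (is.null(hemisphere)) hemisphere <- "north"
  } else {
    d <- defs[[region]]
    months <- d$months
    if (is.null(hemisphere)) hemisphere <- d$hemisphere
  }
  structure(list(region = region, months = as.integer(months),
                 hemisphere = hemisphere),
            class = "region_season")
}

#' Build per-pixel fire histories from burned-area records
#'
#' @param burns data.frame of burn records with columns `pixel`, `row`, `col`,
#'   `year`, `month`, `month_index`, `burn_doy`, `uncertainty_days` (as written
#'   by [simulate_scene()]).
#' @return a `fire_history` data.frame of events ordered by pixel and date,
#'   with an `in_season` column initialized to `NA`.
#' @export
fire_history <- function(burns) {
  ev <- burns[order(burns$pixel, burns$month_index), , drop = FALSE]
  if (any(ev$uncertainty_days < 0)) stop("negative burn-date uncertainty")
  ev$in_season <- NA
  class(ev) <- c("fire_history", "data.frame")
  ev
}

#' Drop events with burn-date uncertainty beyond a threshold
#'
#' Events with uncertainty strictly greater than `max_days` are removed; the
#' boundary value is kept.
#'
#' @param events a [fire_history()] data.frame.
#' @param max_days maximum accepted burn-date uncertainty, days (default 7).
#' @return the filtered events.
#' @export
filter_burn_uncertainty <- function(events, max_days = 7) {
  if (any(events$uncertainty_days < 0)) stop("negative burn-date uncertainty")
  events[events$uncertainty_days <= max_days, , drop = FALSE]
}

#' Flag events inside the regional fire season
#'
#' @param events a [fire_history()] data.frame.
#' @param season a [region_season()]; year-wrapping seasons (e.g. Oct-Feb) are
#'   handled by month-set membership.
#' @return the events with `in_season` set.
#' @export
flag_in_season <- function(events, season) {
  stopifnot(inherits(season, "region_season"))
  events$in_season <- events$month %in% season$months
  events
}

#' Fire frequency per pixel and relative-frequency table
#'
#' Counts in-season events per pixel and tabulates the share of burned pixels
#' by burn count (1, 2, >= 3).
#'
#' @param events filtered, season-flagged events.
#' @return list with `counts` (data.frame pixel, row, col, fire_count) and
#'   `table` (data.frame fire_count, n_pixels, share).
#' @export
fire_frequency <- function(events) {
  ev <- events[!is.na(events$in_season) & events$in_season, , drop = FALSE]
  if (!nrow(ev)) {
    return(list(
      counts = data.frame(pixel = integer(0), row = integer(0),
                          col = integer(0), fire_count = integer(0)),
      table = data.frame(fire_count = character(0), n_pixels = integer(0),
                         share = numeric(0))
    ))
  }
  agg <- stats::aggregate(list(fire_count = ev$month_index),
                          by = list(pixel = ev$pixel, row = ev$row, col = ev$col),
                          FUN = length)
  agg <- agg[order(agg$pixel), ]
  cls <- cut(agg$fire_count, breaks = c(0.5, 1.5, 2.5, Inf),
             labels = c("1", "2", ">=3"))
  tb <- table(cls)
  list(
    counts = agg,
    table = data.frame(fire_count = names(tb),
                       n_pixels = as.integer(tb),
                       share = as.numeric(tb) / nrow(agg))
  )
}

#' Select twice-burned pixels and their event pair
#'
#' Returns the pixels with exactly two in-season events at least
#' `min_gap_months` apart (48 months = 4 years by default) that also leave at
#' least `min_tail_months` of record after the second event for recovery
#' fitting. Every excluded pixel is attributed to exactly one named rule.
#'
#' @param events filtered, season-flagged events.
#' @param n_months_record total number of months in the record.
#' @param min_gap_months minimum E1-E2 separation, months.
#' @param min_tail_months minimum record after E2, months (the shortest
#'   fitting window).
#' @param mode `"exactly_two"` (pixels with three or more in-season events are
#'   excluded) or `"first_last"` (use the first and last events of pixels with
#'   two or more).
#' @return list with `pairs` (data.frame pixel, row, col, m1, m2, gap_months,
#'   doy1, doy2) and `exclusions` (data.frame pixel, reason with levels
#'   uncertainty/season/count/gap/tail).
#' @export
select_twice_burned <- function(events, n_months_record,
                                min_gap_months = 48, min_tail_months = 24,
                                mode = c("exactly_two", "first_last")) {
  mode <- match.arg(mode)
  if (anyNA(events$in_season)) {
    stop("events must be season-flagged before selection (see flag_in_season)")
  }
  pixels <- sort(unique(events$pixel))
  rows <- events$row[match(pixels, events$pixel)]
  cols <- events$col[match(pixels, events$pixel)]
  pair_list <- list(); excl <- list()
  for (i in seq_along(pixels)) {
    p <- pixels[i]
    ev <- events[events$pixel == p & events$in_season, , drop = FALSE]
    n_in <- nrow(ev)
    use <- if (mode == "exactly_two" && n_in == 2L) ev else
      if (mode == "first_last" && n_in >= 2L) ev[c(1L, n_in), ] else NULL
    if (is.null(use)) {
      excl[[length(excl) + 1L]] <- data.frame(pixel = p, reason = "count")
      next
    }
    gap <- use$month_index[2] - use$month_index[1]
    if (gap < min_gap_months) {
      excl[[length(excl) + 1L]] <- data.frame(pixel = p, reason = "gap")
      next
    }
    if (n_months_record - use$month_index[2] < min_tail_months) {
      excl[[length(excl) + 1L]] <- data.frame(pixel = p, reason = "tail")
      next
    }
    pair_list[[length(pair_list) + 1L]] <- data.frame(
      pixel = p, row = rows[i], col = cols[i],
      m1 = use$month_index[1], m2 = use$month_index[2], gap_months = gap,
      doy1 = use$burn_doy[1], doy2 = use$burn_doy[2]
    )
  }
  empty_pairs <- data.frame(pixel = integer(0), row = integer(0), col = integer(0),
                            m1 = integer(0), m2 = integer(0),
                            gap_months = integer(0), doy1 = integer(0),
                            doy2 = integer(0))
  list(
    pairs = if (length(pair_list)) do.call(rbind, pair_list) else empty_pairs,
    exclusions = if (length(excl)) do.call(rbind, excl) else
      data.frame(pixel = integer(0), reason = character(0))
  )
}
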