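#' @keywords internal
"_PACKAGE"

# MODIS-like composite calendar: 23 fixed 16-day composites per year starting
# Jan 1 (day-of-year 1, 17, ..., 353); the last composite absorbs the leap day.

composite_doys <- function() seq(1L, by = 16L, length.out = 23L)

#' Composite start dates for a span of calendar years
#'
#' Enumerates the 23 fixed 16-day composite start dates of each year in
#' `[start_year, end_year]` (both inclusive), the cadence of MOD13A1-style
#' vegetation-index products.
#'
#' @param start_year,end_year first and last calendar year of the record.
#' @return a `Date` vector of length `23 * (end_year - start_year + 1)`.
#' @export
composite_dates <- function(start_year, end_year) {
  years <- seq.int(start_year, end_year)
  as.Date(unlist(lapply(years, function(y) {
    as.character(as.Date(sprintf("%d-01-01", y)) + (composite_doys() - 1L))
  })))
}

# calendar-month index, 1 = January of start_year
month_index_of_date <- function(dates, start_year) {
  lt <- as.POSIXlt(dates)
  (lt$year + 1900L - start_year) * 12L + lt$mon + 1L
}

# month index of a composite by its NOMINAL day-of-year under a fixed 365-day
# year, so that composite k of every year maps to the same calendar month
# (the leap day being absorbed by the composite calendar)
composite_month_index <- function(dates, start_year) {
  year <- as.integer(format(dates, "%Y"))
  doy <- as.integer(dates - as.Date(sprintf("%d-01-01", year))) + 1L
  ref_month <- as.POSIXlt(as.Date("2001-01-01") + (doy - 1L))$mon + 1L
  (year - start_year) * 12L + ref_month
}

n_record_months <- function(start_year, end_year) 12L * (end_year - start_year + 1L)

month_of_index <- function(mi) ((mi - 1L) %% 12L) + 1L

year_of_index <- function(mi, start_year) start_year + (mi - 1L) %/% 12L

clamp01 <- function(x) pmin(1, pmax(0, x))

days_in_month <- function(year, month) {
  as.integer(as.Date(sprintf(
    "%d-%02d-01", year + (month == 12L), ifelse(month == 12L, 1L, month + 1L)
  )) - as.Date(sprintf("%d-%02d-01", year, month)))
}

# column-major pixel indexing consistent with array(dim = c(t, rows, cols))
pixel_index <- function(row, col, n_rows) (col - 1L) * n_rows + row

pixel_rowcol <- function(pixel, n_rows) {
  data.frame(
    row = ((pixel - 1L) %% n_rows) + 1L,
    col = ((pixel - 1L) %/% n_rows) + 1L
  )
}
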