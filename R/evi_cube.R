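#' Gridded vegetation-index time-series cube
#'
#' Container for an EVI record on a `(time, row, col)` grid together with its
#' time axis, optional per-observation quality flags and a processing-state
#' tag. The state tag enforces the fixed pre-processing order
#' fill -> smooth -> detrend -> monthly aggregation.
#'
#' @param values numeric array with `dim = c(n_time, n_rows, n_cols)`, EVI in `[0, 1]`.
#' @param dates `Date` vector (composite start dates) or, for monthly cubes,
#'   first-of-month dates; strictly increasing.
#' @param quality optional integer/logical array of the same dim; `TRUE`/1 marks
#'   a low-quality observation.
#' @param state processing state, one of `"raw"`, `"gapfilled"`, `"smoothed"`,
#'   `"detrended"`, `"monthly"`.
#' @param start_year first calendar year of the record.
#' @return an object of class `evi_cube`.
#' @export
evi_cube <- function(values, dates, quality = NULL, state = "raw",
                     start_year = as.integer(format(min(dates), "%Y"))) {
  stopifnot(is.array(values), length(dim(values)) == 3L,
            dim(values)[1] == length(dates))
  if (is.unsorted(dates, strictly = TRUE)) {
    stop("`dates` must be strictly increasing")
  }
  state <- match.arg(state, c("raw", "gapfilled", "smoothed", "detrended", "monthly"))
  if (!is.null(quality)) stopifnot(all(dim(quality) == dim(values)))
  structure(
    list(values = values, dates = dates, quality = quality, state = state,
         start_year = as.integer(start_year)),
    class = "evi_cube"
  )
}

#' @export
print.evi_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<evi_cube> %d time steps x %d x %d pixels, state = %s\n",
              d[1], d[2], d[3], x$state))
  cat(sprintf("  time: %s .. %s\n", min(x$dates), max(x$dates)))
  invisible(x)
}

# internal: flatten to a (time x pixel) matrix, pixels column-major over (row, col)
cube_matrix <- function(cube) {
  d <- dim(cube$values)
  matrix(cube$values, nrow = d[1], ncol = d[2] * d[3])
}

matrix_to_cube_values <- function(m, d) array(m, dim = d)

assert_state <- function(cube, allowed, op) {
  if (!cube$state %in% allowed) {
    stop(sprintf("%s() requires cube state %s, got \"%s\"",
                 op, paste(sprintf('"%s"', allowed), collapse = " or "),
                 cube$state))
  }
  invisible(TRUE)
}

masked_pixels <- function(cube) {
  mp <- attr(cube, "masked")
  if (is.null(mp)) matrix(FALSE, dim(cube$values)[2], dim(cube$values)[3]) else mp
}
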