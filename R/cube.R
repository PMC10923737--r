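#' Raster time-series cube
#'
#' The universal currency of the pipeline: a single variable observed on a
#' fixed (row, col) grid at an ordered sequence of dates. Values are stored
#' as a numeric array with dimensions `c(rows, cols, time)` (row 0-of-grid at
#' the north edge), missingness as a logical mask of the same shape
#' (`TRUE` = missing), never as a sentinel value inside `values`.
#'
#' @param values numeric array, dim `c(rows, cols, time)`.
#' @param dates `Date` vector of length `dim(values)[3]`, strictly increasing.
#' @param variable one of `"NDVI"`, `"LST"`, `"VCI"`, `"TCI"`, `"VHI"`.
#' @param mask logical array, same dim as `values`; default all `FALSE`.
#' @param step time-step kind: `"daily"` or `"composite_8day"`. For
#'   `composite_8day` every date must fall on a MODIS composite start
#'   (day-of-year 1, 9, ..., 361).
#' @param units unit string; defaults to `"K"` for LST and
#'   `"dimensionless"` otherwise.
#'
#' @return an object of class `vhi_cube`.
#' @export
raster_cube <- function(values, dates, variable,
                        mask = NULL, step = c("daily", "composite_8day"),
                        units = NULL) {
  step <- match.arg(step)
  variable <- match.arg(variable, c("NDVI", "LST", "VCI", "TCI", "VHI"))
  if (length(dim(values)) == 2L) dim(values) <- c(dim(values), 1L)
  if (length(dim(values)) != 3L)
    stop("`values` must be a (rows, cols, time) array")
  dates <- as.Date(dates)
  if (length(dates) != dim(values)[3])
    stop("length(dates) must equal the time dimension of `values`")
  if (anyDuplicated(dates))
    stop("duplicate timestamps in time axis")
  if (is.unsorted(dates, strictly = TRUE))
    stop("time axis must be strictly increasing")
  if (step == "composite_8day" && !all(doy_of(dates) %in% composite_doys()))
    stop("composite_8day dates must start on day-of-year 1, 9, ..., 361")
  if (is.null(mask)) {
    mask <- is.na(values)
  } else {
    if (!identical(dim(mask), dim(values)))
      stop("mask and values dimensions differ")
    mask <- mask | is.na(values)
  }
  storage.mode(mask) <- "logical"
  if (any(!is.finite(values[!mask])))
    stop("non-finite values present outside the mask")
  if (is.null(units))
    units <- if (variable == "LST") "K" else "dimensionless"
  structure(
    list(variable = variable, values = values, mask = mask,
         dates = dates, step = step, units = units),
    class = "vhi_cube"
  )
}

#' @export
print.vhi_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<vhi_cube> %s [%s]: %d x %d grid, %d frames (%s)\n",
              x$variable, x$units, d[1], d[2], d[3], x$step))
  cat(sprintf("  %s .. %s | %.2f%% masked\n",
              format(x$dates[1]), format(x$dates[d[3]]),
              100 * mean(x$mask)))
  invisible(x)
}

#' @export
dim.vhi_cube <- function(x) dim(x$values)

is_cube <- function(x) inherits(x, "vhi_cube")

#' Number of frames in a cube
#' @param cube a `vhi_cube`.
#' @return integer frame count.
#' @export
n_frames <- function(cube) dim(cube$values)[3]

#' Extract one frame as a matrix
#' @param cube a `vhi_cube`.
#' @param t frame index (1-based).
#' @param na_masked replace masked cells with `NA`?
#' @return rows x cols matrix.
#' @export
cube_frame <- function(cube, t, na_masked = TRUE) {
  f <- cube$values[, , t, drop = TRUE]
  if (na_masked && any(cube$mask[, , t])) f[cube$mask[, , t]] <- NA_real_
  f
}

#' Subset a cube along the time axis
#' @param cube a `vhi_cube`.
#' @param idx integer frame indices (kept in the given order; must be sorted).
#' @return a `vhi_cube`.
#' @export
cube_window <- function(cube, idx) {
  raster_cube(cube$values[, , idx, drop = FALSE], cube$dates[idx],
              cube$variable, mask = cube$mask[, , idx, drop = FALSE],
              step = cube$step, units = cube$units)
}

# Replace values, keeping axes; optionally a new variable name / mask.
cube_with <- function(cube, values, variable = cube$variable, mask = NULL,
                      units = NULL) {
  raster_cube(values, cube$dates, variable,
              mask = if (is.null(mask)) array(FALSE, dim(values)) else mask,
              step = cube$step, units = units)
}

stopifnot_aligned <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values)))
    stop("cubes have different grid/time dimensions")
  if (!identical(a$dates, b$dates))
    stop("cubes have misaligned time axes")
  invisible(TRUE)
}

doy_of <- function(dates) {
  as.integer(format(as.Date(dates), "%j"))
}

composite_doys <- function() seq(1L, 361L, by = 8L)
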