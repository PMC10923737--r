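#' Build the MODIS 8-day composite calendar
#'
#' MODIS compositing restarts at January 1 every calendar year: periods start
#' on day-of-year 1, 9, ..., 361 and span 8 days each, except the final
#' period of each year which is truncated to 5 days (6 in leap years). The
#' returned calendar contains every period whose start date lies in
#' `[start_date, end_date)`.
#'
#' @param start_date,end_date calendar dates (coerced with [as.Date()]).
#' @return a data.frame of class `vhi_calendar` with columns `start` and
#'   `end` (end exclusive).
#' @export
build_calendar <- function(start_date, end_date) {
  start_date <- as.Date(start_date); end_date <- as.Date(end_date)
  if (start_date >= end_date)
    stop("start_date must precede end_date")
  years <- seq(as.integer(format(start_date, "%Y")),
               as.integer(format(end_date, "%Y")))
  starts <- as.Date(unlist(lapply(years, function(y) {
    as.character(as.Date(sprintf("%d-01-01", y)) + (composite_doys() - 1L))
  })))
  ends <- c(starts[-1], max(starts) + 8L)
  # truncate the trailing period of each year at Jan 1 of the next year
  jan1 <- as.Date(sprintf("%d-01-01", years + 1L))
  for (i in seq_along(ends)) {
    nxt <- jan1[jan1 > starts[i]][1]
    if (ends[i] > nxt) ends[i] <- nxt
  }
  keep <- starts >= start_date & starts < end_date
  out <- data.frame(start = starts[keep], end = ends[keep])
  class(out) <- c("vhi_calendar", "data.frame")
  out
}

#' Average a daily cube onto the 8-day composite calendar
#'
#' Each output frame is the per-pixel arithmetic mean of the unmasked daily
#' values falling inside the period; a pixel with no unmasked daily value in
#' a period is masked in the output.
#'
#' @param daily a daily [raster_cube()].
#' @param calendar a [build_calendar()] result.
#' @return a `composite_8day` [raster_cube()] with one frame per period.
#' @export
compose_8day <- function(daily, calendar) {
  stopifnot(is_cube(daily), inherits(calendar, "vhi_calendar"))
  np <- nrow(calendar)
  d <- dim(daily$values)
  any_overlap <- FALSE
  vals <- array(NA_real_, c(d[1], d[2], np))
  mask <- array(TRUE, c(d[1], d[2], np))
  for (p in seq_len(np)) {
    sel <- which(daily$dates >= calendar$start[p] &
                 daily$dates < calendar$end[p])
    if (length(sel) == 0) next
    any_overlap <- TRUE
    v <- daily$values[, , sel, drop = FALSE]
    m <- daily$mask[, , sel, drop = FALSE]
    v[m] <- 0
    cnt <- rowSums(!m, dims = 2)
    s <- rowSums(v, dims = 2)
    f <- s / cnt                       # NaN where cnt == 0
    miss <- cnt == 0
    f[miss] <- NA_real_
    vals[, , p] <- f
    mask[, , p] <- miss
  }
  if (!any_overlap)
    stop("daily cube does not overlap the composite calendar")
  raster_cube(vals, calendar$start, daily$variable, mask = mask,
              step = "composite_8day", units = daily$units)
}

# 1-D gap fill: linear interpolation between nearest unmasked neighbours,
# nearest-neighbour extension at the edges (stats::approx rule = 2).
fill_line <- function(v, miss) {
  obs <- which(!miss)
  if (length(obs) == 0) return(v)          # caller decides the fallback
  if (length(obs) == length(v)) return(v)
  if (length(obs) == 1L) { v[miss] <- v[obs]; return(v) }
  v[miss] <- stats::approx(obs, v[obs], xout = which(miss),
                           method = "linear", rule = 2)$y
  v
}

#' Fill masked cells by linear interpolation
#'
#' `mode = "spatial"` scans each row of each frame left to right and fills
#' masked runs linearly between the nearest observed neighbours on the row
#' (nearest-neighbour extension at row edges); rows with no observation fall
#' back to column-wise interpolation and, failing that, the frame mean.
#' `mode = "temporal"` applies the same 1-D rule along each pixel's time
#' series. Observed cells are never altered; the output mask is all-`FALSE`.
#'
#' @param cube a [raster_cube()].
#' @param mode `"spatial"` (default) or `"temporal"`.
#' @return a gap-free [raster_cube()].
#' @export
fill_gaps <- function(cube, mode = c("spatial", "temporal")) {
  mode <- match.arg(mode)
  stopifnot(is_cube(cube))
  if (!any(cube$mask)) {
    return(cube_with(cube, cube$values, mask = array(FALSE, dim(cube$values)),
                     units = cube$units))
  }
  d <- dim(cube$values)
  vals <- cube$values
  mask <- cube$mask
  vals[mask] <- NA_real_
  if (mode == "temporal") {
    for (r in seq_len(d[1])) for (c in seq_len(d[2])) {
      m <- mask[r, c, ]
      if (!any(m)) next
      if (all(m))
        stop(sprintf("pixel (%d, %d) is entirely masked; cannot interpolate",
                     r, c))
      vals[r, c, ] <- fill_line(vals[r, c, ], m)
    }
  } else {
    for (t in seq_len(d[3])) {
      m <- matrix(mask[, , t], d[1], d[2])
      if (!any(m)) next
      if (all(m))
        stop(sprintf("frame %d (%s) is entirely masked; cannot interpolate",
                     t, format(cube$dates[t])))
      f <- matrix(vals[, , t], d[1], d[2])
      orig <- f
      for (r in seq_len(d[1])) {
        if (!any(m[r, ])) next
        if (all(m[r, ])) next            # handled by the column fallback
        f[r, ] <- fill_line(f[r, ], m[r, ])
      }
      if (any(is.na(f))) {               # fully-masked rows remain
        for (c in seq_len(d[2])) {
          nas <- is.na(f[, c])
          if (!any(nas)) next
          col <- orig[, c]
          filled <- fill_line(col, is.na(col))
          f[nas, c] <- filled[nas]
        }
        f[is.na(f)] <- mean(orig, na.rm = TRUE)
      }
      vals[, , t] <- f
    }
  }
  cube_with(cube, vals, mask = array(FALSE, d), units = cube$units)
}
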