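#' Write a raster cube to disk
#'
#' Two on-disk layouts are supported: a single NetCDF classic file with
#' dimensions `(time, y, x)`, a CF-style `_FillValue` and a
#' `days since 1970-01-01` time coordinate; or a directory of single-band
#' float32 TIFF frames named `<variable>_<YYYY-MM-DD>.tif` (masked cells
#' stored as NaN).
#'
#' @param cube a [raster_cube()].
#' @param path output file (`netcdf`) or directory (`geotiff_stack`).
#' @param format `"netcdf"` or `"geotiff_stack"`.
#' @param tag optional character metadata tag (e.g. a configuration hash)
#'   recorded in the NetCDF global attributes or in a `TAG` sidecar file for
#'   TIFF stacks.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path, format = c("netcdf", "geotiff_stack"),
                       tag = NULL) {
  format <- match.arg(format)
  stopifnot(is_cube(cube))
  d <- dim(cube$values)
  if (format == "netcdf") {
    vals <- cube$values
    vals[cube$mask] <- NC_FILL_FLOAT
    # C-order (time, y, x): x fastest
    flat <- as.vector(aperm(vals, c(2, 1, 3)))
    gatts <- list(Conventions = "CF-1.6",
                  source = "vhicast",
                  step_kind = cube$step)
    if (!is.null(tag)) gatts$vhicast_tag <- as.character(tag)
    vars <- list(
      list(name = "time", dimids = 0L,
           atts = list(units = "days since 1970-01-01",
                       calendar = "standard"),
           type = NC_INT, data = as.integer(cube$dates)),
      list(name = cube$variable, dimids = c(0L, 1L, 2L),
           atts = list(`_FillValue` = NC_FILL_FLOAT, units = cube$units),
           type = NC_FLOAT, data = flat)
    )
    ok <- tryCatch({
      nc_write_file(path, dims = list(time = d[3], y = d[1], x = d[2]),
                    gatts = gatts, vars = vars)
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) stop("cannot write NetCDF file '", path, "': ",
                          conditionMessage(ok))
  } else {
    if (!dir.exists(path)) {
      ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
      if (!ok) stop("cannot create output directory: ", path)
    }
    for (t in seq_len(d[3])) {
      f <- cube_frame(cube, t, na_masked = TRUE)
      tif_write_frame(f, file.path(path, sprintf("%s_%s.tif", cube$variable,
                                                 format(cube$dates[t]))))
    }
    if (!is.null(tag))
      writeLines(as.character(tag), file.path(path, "TAG"))
  }
  invisible(path)
}

#' Read a raster cube from disk
#'
#' Accepts either a NetCDF classic file with a time coordinate or a directory
#' of single-band TIFF frames with ISO dates in their filenames. Frames are
#' sorted by date; no-data cells (fill value / NaN) are flagged in the mask.
#'
#' @param path NetCDF file or TIFF-stack directory.
#' @param variable variable to read; for NetCDF defaults to the single
#'   non-coordinate variable present.
#' @return a [raster_cube()].
#' @export
read_cube <- function(path, variable = NULL) {
  if (dir.exists(path)) {
    read_cube_tiff_stack(path, variable)
  } else if (file.exists(path)) {
    read_cube_netcdf(path, variable)
  } else {
    stop("no such file or directory: ", path)
  }
}

read_cube_netcdf <- function(path, variable = NULL) {
  nc <- nc_read_file(path)
  data_vars <- setdiff(names(nc$vars), names(nc$dims))
  data_vars <- setdiff(data_vars, "time")
  if (is.null(variable)) {
    if (length(data_vars) != 1L)
      stop("NetCDF file has ", length(data_vars),
           " data variables; specify `variable`")
    variable <- data_vars
  }
  v <- nc$vars[[variable]]
  if (is.null(v)) stop("variable '", variable, "' not found in ", path)
  tv <- nc$vars[["time"]]
  if (is.null(tv)) stop("NetCDF file lacks a time coordinate: ", path)
  dates <- as.Date(tv$data, origin = "1970-01-01")
  shape <- unname(v$shape)               # (time, y, x) row-major
  arr <- array(v$data, dim = rev(shape)) # column-major: (x, y, time)
  arr <- aperm(arr, c(2, 1, 3))          # -> (y, x, time)
  fill <- v$atts[["_FillValue"]]
  mask <- is.nan(arr)
  if (!is.null(fill))
    mask <- mask | (!is.na(arr) & abs(arr - fill) <= 1e-6 * abs(fill))
  arr[mask] <- NA_real_
  ord <- order(dates)
  if (anyDuplicated(dates)) stop("duplicate timestamps in ", path)
  step <- nc$gatts[["step_kind"]]
  if (is.null(step)) {
    step <- if (all(doy_of(dates) %in% composite_doys()) &&
                length(dates) > 1) "composite_8day" else "daily"
  }
  units <- v$atts[["units"]]
  raster_cube(arr[, , ord, drop = FALSE], dates[ord], variable,
              mask = mask[, , ord, drop = FALSE], step = step, units = units)
}

read_cube_tiff_stack <- function(path, variable = NULL) {
  files <- list.files(path, pattern = "\\.tif$", full.names = TRUE)
  if (length(files) == 0) stop("no .tif frames found in ", path)
  base <- sub("\\.tif$", "", basename(files))
  m <- regmatches(base, regexpr("\\d{4}-\\d{2}-\\d{2}", base))
  if (length(m) != length(files))
    stop("every TIFF filename must contain an ISO date (YYYY-MM-DD)")
  dates <- as.Date(m)
  if (anyDuplicated(dates)) stop("duplicate timestamps in TIFF stack ", path)
  if (is.null(variable)) {
    vars <- unique(sub("_\\d{4}-\\d{2}-\\d{2}.*$", "", base))
    variable <- if (length(vars) == 1L && vars %in%
                    c("NDVI", "LST", "VCI", "TCI", "VHI")) vars else "NDVI"
  }
  ord <- order(dates)
  frames <- lapply(files[ord], tif_read_frame)
  shp <- vapply(frames, dim, integer(2))
  if (any(shp[1, ] != shp[1, 1]) || any(shp[2, ] != shp[2, 1]))
    stop("inconsistent grid shapes across TIFF frames in ", path)
  arr <- array(unlist(frames), dim = c(shp[1, 1], shp[2, 1], length(frames)))
  mask <- is.na(arr) | is.nan(arr)
  arr[mask] <- NA_real_
  step <- if (length(dates) > 1 &&
              all(doy_of(dates) %in% composite_doys()))
    "composite_8day" else "daily"
  raster_cube(arr, dates[ord], variable, mask = mask, step = step)
}
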