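#' Normalized difference vegetation index from RED/NIR reflectance
#'
#' `(NIR - RED) / (NIR + RED)`, masked (NA) where the denominator is zero.
#' A utility for users starting from surface reflectance; the main pipeline
#' consumes NDVI products directly.
#'
#' @param red,nir nonnegative reflectance grids of identical shape.
#' @return numeric grid of NDVI values in `[-1, 1]` (NA where undefined).
#' @export
compute_ndvi <- function(red, nir) {
  if (!identical(dim(red), dim(nir)) || length(red) != length(nir))
    stop("red and nir grids have different shapes")
  if (any(red < 0, na.rm = TRUE) || any(nir < 0, na.rm = TRUE))
    stop("reflectance must be nonnegative")
  den <- nir + red
  out <- (nir - red) / den
  out[den == 0] <- NA_real_
  out
}

#' Min-max reference statistics for VCI/TCI normalization
#'
#' `scope = "image"`: one scalar min/max pair per frame, taken over all
#' pixels of that frame (the traditional image-based calculation).
#' `scope = "global"`: one min/max pair per pixel, taken over the whole time
#' series (the global-scale calculation; Kogan's original definition).
#' `scope = "global_scalar"`: a single scalar pair over all pixels and all
#' frames (an alternative reading of "extracted from the whole dataset").
#'
#' @param cube a gap-free [raster_cube()] (run [fill_gaps()] first).
#' @param scope `"image"`, `"global"` or `"global_scalar"`.
#' @return a `vhi_norm_stats` list with fields `scope`, `minimum`, `maximum`
#'   (scalars per frame for image scope, per-pixel matrices for global
#'   scope, scalars for global_scalar).
#' @export
normalization_stats <- function(cube,
                                scope = c("image", "global",
                                          "global_scalar")) {
  scope <- match.arg(scope)
  stopifnot(is_cube(cube))
  if (any(cube$mask))
    stop("cube contains masked cells; run fill_gaps() before ",
         "normalization_stats()")
  d <- dim(cube$values)
  if (scope == "image") {
    mn <- apply(cube$values, 3, min)
    mx <- apply(cube$values, 3, max)
  } else if (scope == "global") {
    mn <- apply(cube$values, c(1, 2), min)
    mx <- apply(cube$values, c(1, 2), max)
  } else {
    mn <- min(cube$values)
    mx <- max(cube$values)
  }
  structure(list(scope = scope, minimum = mn, maximum = mx,
                 variable = cube$variable, dim = d),
            class = "vhi_norm_stats")
}

# Broadcast stats to the full (rows, cols, time) array shape.
stats_arrays <- function(stats, d) {
  if (stats$scope == "image") {
    if (length(stats$minimum) != d[3])
      stop("image-scope stats cover ", length(stats$minimum),
           " frames but the cube has ", d[3])
    mn <- aperm(array(stats$minimum, c(d[3], d[1], d[2])), c(2, 3, 1))
    mx <- aperm(array(stats$maximum, c(d[3], d[1], d[2])), c(2, 3, 1))
  } else if (stats$scope == "global") {
    if (!identical(dim(stats$minimum), d[1:2]))
      stop("global-scope stats grid does not match the cube grid")
    mn <- array(stats$minimum, d)
    mx <- array(stats$maximum, d)
  } else {
    mn <- array(stats$minimum, d)
    mx <- array(stats$maximum, d)
  }
  list(mn = mn, mx = mx)
}

min_max_scale <- function(values, stats, invert) {
  d <- dim(values)
  s <- stats_arrays(stats, d)
  rng <- s$mx - s$mn
  degen <- rng <= 0
  rng[degen] <- 1
  out <- if (invert) (s$mx - values) / rng else (values - s$mn) / rng
  out[degen] <- 0.5
  pmin(pmax(out, 0), 1)
}

#' Vegetation Condition Index
#'
#' `VCI = (NDVI - NDVI_min) / (NDVI_max - NDVI_min)` with the scope-dependent
#' reference minima/maxima; degenerate cells (max = min) map to 0.5; results
#' are clipped to `[0, 1]`.
#'
#' @param ndvi a gap-free NDVI [raster_cube()].
#' @param stats a [normalization_stats()] result (any scope).
#' @return a VCI [raster_cube()].
#' @export
compute_vci <- function(ndvi, stats) {
  stopifnot(is_cube(ndvi), inherits(stats, "vhi_norm_stats"))
  cube_with(ndvi, min_max_scale(ndvi$values, stats, invert = FALSE),
            variable = "VCI")
}

#' Thermal Condition Index
#'
#' `TCI = (LST_max - LST) / (LST_max - LST_min)`: the inverted min-max
#' rescaling, so hot frames (thermal stress) score low. Degenerate cells map
#' to 0.5; results are clipped to `[0, 1]`.
#'
#' @param lst a gap-free LST [raster_cube()] (Kelvin).
#' @param stats a [normalization_stats()] result for the LST cube.
#' @return a TCI [raster_cube()].
#' @export
compute_tci <- function(lst, stats) {
  stopifnot(is_cube(lst), inherits(stats, "vhi_norm_stats"))
  cube_with(lst, min_max_scale(lst$values, stats, invert = TRUE),
            variable = "TCI")
}

#' Vegetation Health Index
#'
#' `VHI = alpha * VCI + (1 - alpha) * TCI`, elementwise on aligned cubes.
#' The conventional weight is `alpha = 0.5` (the appropriate weighting of
#' the two components being generally unknown).
#'
#' @param vci,tci aligned VCI/TCI [raster_cube()]s.
#' @param alpha weight of the VCI component, in `[0, 1]`.
#' @return a VHI [raster_cube()].
#' @export
compute_vhi <- function(vci, tci, alpha = 0.5) {
  stopifnot(is_cube(vci), is_cube(tci))
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  stopifnot_aligned(vci, tci)
  cube_with(vci, alpha * vci$values + (1 - alpha) * tci$values,
            variable = "VHI")
}

#' Classify a VHI value into a drought-severity class
#'
#' Standard VHI classes: no drought above 0.50, mild in (0.35, 0.50],
#' moderate in (0.20, 0.35], severe in (0.10, 0.20], extreme at or below
#' 0.10 (intervals closed on their upper end below 0.50, making the
#' printed, endpoint-overlapping class bounds deterministic).
#'
#' @param vhi_value numeric vector of VHI values in `[0, 1]`.
#' @return factor with levels `none`, `mild`, `moderate`, `severe`,
#'   `extreme`.
#' @export
classify_drought <- function(vhi_value) {
  if (any(is.na(vhi_value)) || any(vhi_value < 0) || any(vhi_value > 1))
    stop("VHI values must lie in [0, 1]")
  cut(vhi_value, breaks = c(-Inf, 0.10, 0.20, 0.35, 0.50, Inf),
      labels = c("extreme", "severe", "moderate", "mild", "none"),
      right = TRUE)
}
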