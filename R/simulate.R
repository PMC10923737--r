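# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. seed = NULL uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Configuration for the synthetic NDVI/LST generator
#'
#' Defaults emulate the statistical structure of a 10-year MODIS record over
#' a semi-arid mid-latitude region: an annual seasonal cycle (period 365
#' days, which becomes about 46 steps per year after 8-day compositing),
#' smooth spatially correlated baseline/amplitude/phase fields, NDVI-LST
#' anticorrelation, additive AR(1) noise and uniformly random missing pixels.
#'
#' @param grid_size integer `(rows, cols)`.
#' @param start_date,end_date simulation covers `[start_date, end_date)`
#'   at daily resolution.
#' @param ndvi_baseline_range range the smooth per-pixel NDVI baseline field
#'   is scaled to.
#' @param ndvi_seasonal_amplitude peak seasonal NDVI departure (the per-pixel
#'   amplitude field varies smoothly between 50% and 100% of it).
#' @param lst_mean_K,lst_seasonal_amplitude_K mean and seasonal amplitude of
#'   LST, Kelvin.
#' @param anticorrelation_strength in `[0, 1]`: weight of the linear coupling
#'   of LST to the NDVI anomaly (scaled by `lst_seasonal_amplitude_K` Kelvin
#'   per NDVI unit).
#' @param spatial_correlation_length Gaussian smoothing length (pixels) of
#'   the baseline/amplitude/phase fields.
#' @param noise_sd innovation standard deviation of the NDVI AR(1) noise
#'   (NDVI units; the LST noise uses `10 * noise_sd` Kelvin).
#' @param ar1_coefficient AR(1) coefficient in `[0, 1)`.
#' @param missing_fraction fraction of cells masked by [inject_missing()]
#'   when the generator output is degraded.
#' @param frame_range_jitter stationary standard deviation of a slowly
#'   varying (AR(1), coefficient 0.9) multiplicative perturbation of each
#'   day's anomaly amplitude, shared by all pixels of the frame. This makes
#'   the per-frame dynamic range fluctuate from frame to frame, as
#'   atmospheric and surface conditions do in real imagery — the situation
#'   in which image-based and global-scale normalization genuinely differ.
#'   Set to 0 for a clean seasonal field.
#' @param seed integer RNG seed.
#' @return a `vhi_sim_config` list.
#' @export
simulation_config <- function(grid_size = c(16L, 16L),
                              start_date = "2012-01-01",
                              end_date = "2022-01-01",
                              ndvi_baseline_range = c(0.05, 0.75),
                              ndvi_seasonal_amplitude = 0.25,
                              lst_mean_K = 290,
                              lst_seasonal_amplitude_K = 15,
                              anticorrelation_strength = 0.8,
                              spatial_correlation_length = 4,
                              noise_sd = 0.02,
                              ar1_coefficient = 0.7,
                              missing_fraction = 0.05,
                              frame_range_jitter = 0.15,
                              seed = 1L) {
  cfg <- list(grid_size = as.integer(grid_size),
              start_date = as.Date(start_date), end_date = as.Date(end_date),
              ndvi_baseline_range = ndvi_baseline_range,
              ndvi_seasonal_amplitude = ndvi_seasonal_amplitude,
              lst_mean_K = lst_mean_K,
              lst_seasonal_amplitude_K = lst_seasonal_amplitude_K,
              anticorrelation_strength = anticorrelation_strength,
              spatial_correlation_length = spatial_correlation_length,
              noise_sd = noise_sd, ar1_coefficient = ar1_coefficient,
              missing_fraction = missing_fraction,
              frame_range_jitter = frame_range_jitter,
              seed = as.integer(seed))
  stopifnot(cfg$end_date > cfg$start_date,
            cfg$ndvi_seasonal_amplitude >= 0,
            cfg$lst_seasonal_amplitude_K >= 0,
            cfg$anticorrelation_strength >= 0,
            cfg$anticorrelation_strength <= 1,
            cfg$ar1_coefficient >= 0, cfg$ar1_coefficient < 1,
            cfg$missing_fraction >= 0, cfg$frame_range_jitter >= 0)
  if (cfg$missing_fraction >= 1)
    stop("missing_fraction must be < 1")
  class(cfg) <- "vhi_sim_config"
  cfg
}

# Gaussian-smoothed standard-normal field, rescaled to [0, 1]. Smoothing is
# separable with per-position kernel renormalization at the edges.
smooth_field <- function(nr, nc, corr_len) {
  w <- matrix(rnorm(nr * nc), nr, nc)
  if (corr_len <= 0) return((w - min(w)) / max(diff(range(w)), 1e-12))
  band <- function(n) {
    k <- outer(seq_len(n), seq_len(n), function(i, j)
      exp(-(i - j)^2 / (2 * corr_len^2)))
    k / rowSums(k)
  }
  f <- band(nr) %*% w %*% t(band(nc))
  (f - min(f)) / max(diff(range(f)), 1e-12)
}

# AR(1) noise matrix (npix x ntime) with innovation sd `sd`, stationary start.
ar1_noise <- function(npix, ntime, coef, sd) {
  if (sd == 0) return(matrix(0, npix, ntime))
  e <- matrix(rnorm(npix * ntime, sd = sd), npix, ntime)
  e[, 1] <- e[, 1] / sqrt(max(1 - coef^2, 1e-12))
  if (coef > 0) for (t in 2:ntime) e[, t] <- coef * e[, t - 1] + e[, t]
  e
}

#' Generate paired daily NDVI and LST cubes
#'
#' Per pixel p and day t:
#' `ndvi(p,t) = base(p) + A(p) sin(2 pi doy(t)/365 + phi(p)) + eps(p,t)`
#' with smooth spatial fields `base`, `A`, `phi` and AR(1) noise `eps`;
#' `lst(p,t) = lst_mean + lst_amp sin(2 pi doy(t)/365 + phi(p) + pi)
#'  - strength * lst_amp * (ndvi(p,t) - base(p)) + AR(1) noise`, so LST is
#' seasonally and anomalously anticorrelated with NDVI. NDVI is clipped to
#' `[-1, 1]` and LST floored at 1 K. No cells are masked; use
#' [inject_missing()] to degrade the cubes.
#'
#' @param config a [simulation_config()].
#' @return list with elements `ndvi` and `lst`, both daily [raster_cube()]s.
#' @export
generate_daily_cubes <- function(config) {
  stopifnot(inherits(config, "vhi_sim_config"))
  nr <- config$grid_size[1]; nc <- config$grid_size[2]
  dates <- seq(config$start_date, config$end_date - 1L, by = "day")
  nt <- length(dates); np <- nr * nc
  doy <- doy_of(dates)
  with_seed(config$seed, {
    base <- smooth_field(nr, nc, config$spatial_correlation_length)
    base <- config$ndvi_baseline_range[1] +
      base * diff(config$ndvi_baseline_range)
    amp <- smooth_field(nr, nc, config$spatial_correlation_length)
    amp <- config$ndvi_seasonal_amplitude * (0.5 + 0.5 * amp)
    phase <- (smooth_field(nr, nc, config$spatial_correlation_length) - 0.5) *
      (pi / 4)
    eps_n <- ar1_noise(np, nt, config$ar1_coefficient, config$noise_sd)
    eps_l <- ar1_noise(np, nt, config$ar1_coefficient, 10 * config$noise_sd)
    # slowly varying per-frame amplitude perturbation (shared by all pixels)
    jit <- function() {
      if (config$frame_range_jitter == 0) return(rep(1, nt))
      pmax(1 + as.vector(ar1_noise(1L, nt, 0.9, config$frame_range_jitter *
                                     sqrt(1 - 0.9^2))), 0.2)
    }
    jn <- jit(); jl <- jit()
    season <- outer(as.vector(phase), 2 * pi * doy / 365, "+")
    ndvi <- as.vector(base) +
      rep(jn, each = np) * (as.vector(amp) * sin(season) + eps_n)
    lst <- config$lst_mean_K +
      rep(jl, each = np) * config$lst_seasonal_amplitude_K * sin(season + pi) -
      config$anticorrelation_strength * config$lst_seasonal_amplitude_K *
        (ndvi - as.vector(base)) +
      eps_l
    ndvi <- pmin(pmax(ndvi, -1), 1)
    lst <- pmax(lst, 1)
    list(
      ndvi = raster_cube(array(ndvi, c(nr, nc, nt)), dates, "NDVI"),
      lst = raster_cube(array(lst, c(nr, nc, nt)), dates, "LST")
    )
  })
}

#' Mask a random fraction of cells
#'
#' Masks a uniformly sampled fraction of `(row, col, time)` cells while
#' guaranteeing that no frame and no pixel time-series becomes entirely
#' masked (one randomly chosen cell per frame and per series is protected).
#' Values under the mask are retained, so recovery against the truth can be
#' tested after gap filling.
#'
#' @param cube a [raster_cube()].
#' @param fraction fraction of cells to mask, in `[0, 1)`.
#' @param seed integer RNG seed (`NULL` = current stream).
#' @return the cube with an augmented mask.
#' @export
inject_missing <- function(cube, fraction, seed = NULL) {
  stopifnot(is_cube(cube))
  if (fraction < 0 || fraction >= 1)
    stop("fraction must be in [0, 1)")
  if (fraction == 0) return(cube)
  d <- dim(cube$values)
  ncell <- prod(d)
  n <- round(fraction * ncell)
  with_seed(seed, {
    pix <- matrix(seq_len(d[1] * d[2]), d[1], d[2])
    # one protected cell per pixel series and per frame
    prot_series <- as.vector(pix) +
      (sample.int(d[3], d[1] * d[2], replace = TRUE) - 1L) * d[1] * d[2]
    prot_frame <- sample.int(d[1] * d[2], d[3], replace = TRUE) +
      (seq_len(d[3]) - 1L) * d[1] * d[2]
    protected <- unique(c(prot_series, prot_frame))
    pool <- setdiff(seq_len(ncell), protected)
    if (n > length(pool))
      stop("fraction ", fraction, " cannot be reached without masking a ",
           "whole frame or pixel series on this cube")
    sel <- sample(pool, n)
    mask <- cube$mask
    mask[sel] <- TRUE
    out <- cube
    out$mask <- mask
    out
  })
}
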