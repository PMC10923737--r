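eval_values <- function(x) {
  if (is_cube(x)) {
    if (any(x$mask)) stop("evaluation input contains masked cells")
    x$values
  } else as.array(x)
}

check_eval_pair <- function(y_pred, y_true) {
  p <- eval_values(y_pred); t <- eval_values(y_true)
  if (length(p) != length(t) ||
      (!is.null(dim(p)) && !is.null(dim(t)) && !identical(dim(p), dim(t))))
    stop("prediction and truth shapes differ")
  if (length(p) == 0) stop("empty evaluation input")
  list(p = as.numeric(p), t = as.numeric(t))
}

#' Root mean squared error
#'
#' `sqrt(mean((y_pred - y_true)^2))`, pooled over all time steps and pixels.
#'
#' @param y_pred,y_true aligned cubes or numeric arrays.
#' @return nonnegative scalar.
#' @export
rmse <- function(y_pred, y_true) {
  v <- check_eval_pair(y_pred, y_true)
  sqrt(mean((v$p - v$t)^2))
}

#' Mean absolute error
#'
#' `mean(|y_pred - y_true|)`, pooled over all time steps and pixels.
#'
#' @inheritParams rmse
#' @return nonnegative scalar.
#' @export
mae <- function(y_pred, y_true) {
  v <- check_eval_pair(y_pred, y_true)
  mean(abs(v$p - v$t))
}

#' Mean absolute percentage error
#'
#' `100 * mean(|y_pred - y_true| / max(|y_true|, zero_floor))`. The floor
#' keeps the metric finite where the true value approaches zero (the ratio
#' is undefined at `y_true = 0`); 0.01 is scale-appropriate for indices on
#' `[0, 1]`.
#'
#' @inheritParams rmse
#' @param zero_floor positive denominator floor (default 0.01).
#' @return nonnegative scalar, in percent.
#' @export
mape <- function(y_pred, y_true, zero_floor = 0.01) {
  if (zero_floor <= 0) stop("zero_floor must be positive")
  v <- check_eval_pair(y_pred, y_true)
  100 * mean(abs(v$p - v$t) / pmax(abs(v$t), zero_floor))
}

#' Per-pixel RMSE map and histogram
#'
#' RMSE over the time dimension at each pixel, plus a histogram of the map
#' (bin width 0.005 by default, resolving the 0.02-0.04 band where
#' well-trained VHI forecasts concentrate).
#'
#' @inheritParams rmse
#' @param bin_width histogram bin width.
#' @return list with `map` (rows x cols matrix) and `histogram` (data frame
#'   of `lower`, `upper`, `count`; counts sum to the pixel count).
#' @export
rmse_map <- function(y_pred, y_true, bin_width = 0.005) {
  p <- eval_values(y_pred); t <- eval_values(y_true)
  if (length(dim(p)) == 2L) dim(p) <- c(dim(p), 1L)
  if (length(dim(t)) == 2L) dim(t) <- c(dim(t), 1L)
  if (!identical(dim(p), dim(t)))
    stop("prediction and truth shapes differ")
  map <- sqrt(apply((p - t)^2, c(1, 2), mean))
  breaks <- seq(0, max(map) + bin_width, by = bin_width)
  h <- hist(map, breaks = breaks, plot = FALSE, right = FALSE)
  list(map = map,
       histogram = data.frame(lower = head(h$breaks, -1),
                              upper = h$breaks[-1], count = h$counts))
}

#' Score a forecast
#'
#' Pools RMSE/MAE/MAPE over all test time steps and pixels (or averages
#' per-frame RMSE/MAE/MAPE when `per_image = TRUE`; the two differ for
#' RMSE) and attaches the per-pixel RMSE map and histogram.
#'
#' @param fc a forecast result from [forecast_separate()] /
#'   [forecast_iterative()] (one horizon's element), or a list with `pred`
#'   and `truth` cubes.
#' @param per_image average per-frame metrics instead of pooling.
#' @param zero_floor MAPE denominator floor.
#' @param bin_width RMSE-map histogram bin width.
#' @param metadata optional named list (scope, layers, seed, ...) carried
#'   into the report.
#' @return a `vhi_report` list with `rmse`, `mae`, `mape`, `rmse_map`,
#'   `histogram` and `metadata`.
#' @export
evaluate_forecast <- function(fc, per_image = FALSE, zero_floor = 0.01,
                              bin_width = 0.005, metadata = list()) {
  p <- fc$pred; t <- fc$truth
  if (per_image) {
    nt <- n_frames(p)
    per <- vapply(seq_len(nt), function(i) {
      c(rmse(cube_frame(p, i), cube_frame(t, i)),
        mae(cube_frame(p, i), cube_frame(t, i)),
        mape(cube_frame(p, i), cube_frame(t, i), zero_floor))
    }, numeric(3))
    m <- rowMeans(per)
  } else {
    m <- c(rmse(p, t), mae(p, t), mape(p, t, zero_floor))
  }
  rm_ <- rmse_map(p, t, bin_width)
  meta <- c(list(strategy = fc$strategy, horizon = fc$horizon), metadata)
  structure(list(rmse = m[1], mae = m[2], mape = m[3],
                 rmse_map = rm_$map, histogram = rm_$histogram,
                 metadata = meta),
            class = "vhi_report")
}

#' @export
print.vhi_report <- function(x, ...) {
  cat(sprintf("<vhi_report> %s k=%s: RMSE %.4f | MAE %.4f | MAPE %.2f%%\n",
              x$metadata$strategy %||% "?", x$metadata$horizon %||% "?",
              x$rmse, x$mae, x$mape))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reference forecasting baselines
#'
#' Persistence predicts the last observed input frame at every horizon;
#' climatology predicts the per-pixel mean of the training-partition frames
#' sharing the same within-year composite index.
#'
#' @param vhi gap-free composite VHI [raster_cube()].
#' @param split a [temporal_split()].
#' @param L window length.
#' @param horizons integer vector of horizons to score.
#' @param partition partition to evaluate on (default `"test"`).
#' @return nested list: `$persistence[[k]]` and `$climatology[[k]]` are
#'   `vhi_report`s.
#' @export
baselines <- function(vhi, split, L, horizons, partition = "test") {
  stopifnot(is_cube(vhi))
  d <- dim(vhi$values); P <- d[1] * d[2]
  flat <- matrix(vhi$values, P, d[3])
  cidx <- match(doy_of(vhi$dates), composite_doys())
  if (any(is.na(cidx)))
    stop("baselines require a composite_8day cube")
  if (length(split$train) < length(composite_doys()))
    stop("climatology needs a training partition of at least one year (",
         length(composite_doys()), " composites)")
  clim <- matrix(NA_real_, P, length(composite_doys()))
  for (ci in sort(unique(cidx[split$train]))) {
    sel <- split$train[cidx[split$train] == ci]
    clim[, ci] <- rowMeans(flat[, sel, drop = FALSE])
  }
  out <- list(persistence = list(), climatology = list())
  for (k in horizons) {
    w <- make_windows(vhi, L, k, split)
    sel <- which(w$partition == partition)
    truth <- w$targets[, sel, drop = FALSE]
    pers <- w$inputs[, w$L, sel, drop = TRUE]
    if (is.null(dim(pers))) pers <- matrix(pers, ncol = length(sel))
    ci_t <- cidx[w$target_idx[sel]]
    if (any(is.na(clim[, ci_t])))
      stop("climatology undefined for some target composite indices; the ",
           "training partition does not cover a full year")
    climp <- clim[, ci_t, drop = FALSE]
    key <- as.character(k)
    out$persistence[[key]] <- evaluate_forecast(
      forecast_result("persistence", k, pers, truth, w, sel))
    out$climatology[[key]] <- evaluate_forecast(
      forecast_result("climatology", k, climp, truth, w, sel))
  }
  out
}
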