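#' Temporal train/validation/test split
#'
#' Splits `T` consecutive time indices into contiguous, ordered, disjoint
#' partitions: the first `floor(f_train * T)` frames train the models, the
#' next `floor(f_val * T)` validate them, and the remainder is held out for
#' testing.
#'
#' @param T number of time steps.
#' @param fractions length-3 numeric summing to 1 (default 0.8/0.1/0.1).
#' @return list with integer index vectors `train`, `validation`, `test`.
#' @export
temporal_split <- function(T, fractions = c(0.8, 0.1, 0.1)) {
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be three numbers summing to 1")
  T <- as.integer(T)
  n_tr <- floor(fractions[1] * T)
  n_va <- floor(fractions[2] * T)
  n_te <- T - n_tr - n_va
  if (n_tr < 1 || n_va < 1 || n_te < 1)
    stop("split produces an empty partition (", n_tr, "/", n_va, "/", n_te,
         "); need T >= ", ceiling(1 / min(fractions[fractions > 0])))
  list(train = seq_len(n_tr),
       validation = seq(n_tr + 1L, n_tr + n_va),
       test = seq(n_tr + n_va + 1L, T))
}

#' Build a windowed forecasting dataset
#'
#' Slides a window of `L` consecutive frames with stride 1 inside each
#' partition, pairing the frames at times `t .. t+L-1` with the target frame
#' at `t+L+k-1`. Windows never cross a partition boundary, so no test-target
#' time index can appear inside a training input window. Each partition of
#' length `T_p` yields `T_p - L - k + 1` samples.
#'
#' @param vhi a gap-free composite [raster_cube()] (typically VHI).
#' @param L window length (number of input frames).
#' @param k forecast horizon in composite steps.
#' @param split a [temporal_split()] of `n_frames(vhi)`.
#' @return a `vhi_windows` object with fields `inputs` (`P x L x n` array of
#'   flattened frames), `targets` (`P x n`), `partition` (factor),
#'   `target_idx`/`input_start` (global frame indices), grid shape and the
#'   cube's dates.
#' @export
make_windows <- function(vhi, L, k, split) {
  stopifnot(is_cube(vhi))
  if (any(vhi$mask)) stop("windowed cube must be gap-free; run fill_gaps()")
  if (L < 1 || k < 1) stop("L and k must be positive")
  d <- dim(vhi$values)
  P <- d[1] * d[2]
  flat <- matrix(vhi$values, P, d[3])
  parts <- c("train", "validation", "test")
  inputs <- list(); targets <- list(); labs <- list()
  starts <- list(); tidx <- list()
  for (pn in parts) {
    idx <- split[[pn]]
    n_p <- length(idx) - L - k + 1L
    if (n_p < 1L)
      stop("partition '", pn, "' has ", length(idx),
           " frames; needs at least ", L + k, " for L = ", L, ", k = ", k)
    xi <- array(0, c(P, L, n_p))
    ti <- matrix(0, P, n_p)
    for (s in seq_len(n_p)) {
      xi[, , s] <- flat[, idx[s:(s + L - 1L)], drop = FALSE]
      ti[, s] <- flat[, idx[s + L + k - 1L]]
    }
    inputs[[pn]] <- xi; targets[[pn]] <- ti
    labs[[pn]] <- rep(pn, n_p)
    starts[[pn]] <- idx[seq_len(n_p)]
    tidx[[pn]] <- idx[seq_len(n_p) + L + k - 1L]
  }
  structure(list(
    inputs = array(unlist(inputs), c(P, L, sum(lengths(labs)))),
    targets = matrix(unlist(targets), P),
    partition = factor(unlist(labs), levels = parts),
    input_start = unlist(starts, use.names = FALSE),
    target_idx = unlist(tidx, use.names = FALSE),
    horizon = as.integer(k), L = as.integer(L),
    rows = d[1], cols = d[2], dates = vhi$dates, variable = vhi$variable
  ), class = "vhi_windows")
}

#' @export
print.vhi_windows <- function(x, ...) {
  cat(sprintf("<vhi_windows> L=%d, k=%d, %d x %d grid: %s samples\n",
              x$L, x$horizon, x$rows, x$cols,
              paste(table(x$partition), collapse = "/")))
  invisible(x)
}

forecast_result <- function(strategy, k, pred, truth, windows, sel) {
  d <- c(windows$rows, windows$cols, ncol(pred))
  dates <- windows$dates[windows$target_idx[sel]]
  list(strategy = strategy, horizon = k,
       pred = raster_cube(array(pred, d), dates, windows$variable,
                          step = "composite_8day"),
       truth = raster_cube(array(truth, d), dates, windows$variable,
                           step = "composite_8day"))
}

#' Separate (direct) multi-step forecasting
#'
#' Each horizon is forecast by its own dedicated model, trained to map an
#' observed window directly to the k-step-ahead target; inputs are always
#' observed frames.
#'
#' @param models named list mapping horizon (as character) to a trained
#'   model of that horizon.
#' @param vhi gap-free composite VHI [raster_cube()].
#' @param split a [temporal_split()].
#' @param L window length.
#' @param horizons integer vector of requested horizons.
#' @param partition partition to forecast (default `"test"`).
#' @return named list (by horizon) of forecast results, each with `pred`
#'   and `truth` cubes on identical time axes.
#' @export
forecast_separate <- function(models, vhi, split, L, horizons,
                              partition = "test") {
  out <- list()
  for (k in horizons) {
    key <- as.character(k)
    if (is.null(models[[key]]))
      stop("no trained model supplied for horizon ", k)
    model <- models[[key]]
    h <- model_horizon(model)
    if (!is.na(h) && h != k)
      stop("model supplied for horizon ", k, " was trained for horizon ", h)
    w <- make_windows(vhi, L, k, split)
    sel <- which(w$partition == partition)
    pred <- predict_frames(model, w$inputs[, , sel, drop = FALSE],
                           w$rows, w$cols)
    out[[key]] <- forecast_result("separate", k, pred,
                                  w$targets[, sel, drop = FALSE], w, sel)
  }
  out
}

#' Iterative multi-step forecasting
#'
#' Applies a 1-step model repeatedly: horizon 1 is a direct application to
#' the observed window; each further horizon drops the oldest frame and
#' appends the previous prediction (clipped to `[0, 1]`) before reapplying
#' the same model.
#'
#' @param model_1step a trained model with `horizon = 1`.
#' @inheritParams forecast_separate
#' @param max_horizon largest horizon to roll out to.
#' @return named list (by horizon) of forecast results.
#' @export
forecast_iterative <- function(model_1step, vhi, split, L, max_horizon,
                               partition = "test") {
  if (max_horizon < 1) stop("max_horizon must be >= 1")
  h <- model_horizon(model_1step)
  if (!is.na(h) && h != 1L)
    stop("iterative forecasting requires a 1-step model")
  w1 <- make_windows(vhi, L, max_horizon, split)  # validates feasibility
  w <- make_windows(vhi, L, 1L, split)
  sel <- which(w$partition == partition)
  X <- w$inputs[, , sel, drop = FALSE]
  d <- dim(vhi$values); P <- d[1] * d[2]
  flat <- matrix(vhi$values, P, d[3])
  out <- list()
  n_active <- length(sel)
  for (j in seq_len(max_horizon)) {
    if (n_active < 1) break
    Xa <- X[, , seq_len(n_active), drop = FALSE]
    pred <- predict_frames(model_1step, Xa, w$rows, w$cols)
    sel_j <- sel[seq_len(n_active)]
    truth_idx <- w$input_start[sel_j] + L + j - 1L
    truth <- flat[, truth_idx, drop = FALSE]
    wj <- w; wj$target_idx <- w$input_start + L + j - 1L
    out[[as.character(j)]] <-
      forecast_result("iterative", j, pred, truth, wj, sel_j)
    # roll the windows forward: drop the oldest frame, append the forecast
    X[, seq_len(L - 1L), ] <- X[, 2:L, , drop = FALSE]
    for (s in seq_len(n_active)) X[, L, s] <- pred[, s]
    n_active <- n_active - 1L
  }
  out
}
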