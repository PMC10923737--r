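#' Pipeline run configuration
#'
#' Collects every knob of the forecasting pipeline. Defaults follow the
#' reference setup: window of 6 composite frames, horizons 1-3, 16 filters,
#' kernel 3, at most 100 epochs with patience 20, 80/10/10 temporal split,
#' VHI weight alpha = 0.5.
#'
#' @param grid_size integer `(rows, cols)`.
#' @param window_length input window length L (default 6).
#' @param horizons integer vector of forecast horizons (default 1:3).
#' @param normalization_scope `"image"`, `"global"` or `"global_scalar"`.
#' @param layers ConvLSTM depth in 1:3 (may be a vector to compare depths).
#' @param filters,kernel_size ConvLSTM width and kernel (defaults 16 and 3).
#' @param max_epochs,patience training protocol (defaults 100 and 20).
#' @param split_fractions train/validation/test fractions (must sum to 1).
#' @param seed master seed; all stage seeds are derived from it.
#' @param alpha VHI weight on VCI (default 0.5).
#' @param batch_size,learning_rate optimizer settings.
#' @param fill_mode gap-fill direction, `"spatial"` or `"temporal"`.
#' @return a `vhi_run_config` list.
#' @export
run_config <- function(grid_size = c(16L, 16L), window_length = 6L,
                       horizons = 1:3,
                       normalization_scope = c("global", "image",
                                               "global_scalar"),
                       layers = 1L, filters = 16L, kernel_size = 3L,
                       max_epochs = 100L, patience = 20L,
                       split_fractions = c(0.8, 0.1, 0.1), seed = 42L,
                       alpha = 0.5, batch_size = 8L, learning_rate = 1e-3,
                       fill_mode = c("spatial", "temporal")) {
  normalization_scope <- match.arg(normalization_scope)
  fill_mode <- match.arg(fill_mode)
  if (abs(sum(split_fractions) - 1) > 1e-8)
    stop("split fractions must sum to 1")
  if (window_length < 1) stop("window_length must be >= 1")
  if (length(horizons) == 0) stop("horizons must be nonempty")
  if (!all(layers %in% 1:3)) stop("layers must be in 1:3")
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  structure(list(grid_size = as.integer(grid_size),
                 window_length = as.integer(window_length),
                 horizons = sort(unique(as.integer(horizons))),
                 normalization_scope = normalization_scope,
                 layers = as.integer(layers), filters = as.integer(filters),
                 kernel_size = as.integer(kernel_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 split_fractions = split_fractions, seed = as.integer(seed),
                 alpha = alpha, batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, fill_mode = fill_mode),
            class = "vhi_run_config")
}

#' Synthetic VHI benchmark
#'
#' Builds the reference synthetic benchmark used throughout the package's
#' examples and checks: a 16 x 16 grid simulated daily over ten years
#' (2012-01-01 to 2022-01-01) with the default [simulation_config()]
#' conditions, 5% of cells masked, composited to the 460-period 8-day
#' calendar, gap-filled, and turned into VHI cubes under both global-scale
#' and image-based normalization, with the standard 80/10/10 temporal split.
#'
#' @param seed master seed for the simulation and the masking.
#' @param grid_size grid shape (default `c(16, 16)`).
#' @return list with `vhi` (list of `global` and `image` cubes), `split`,
#'   and the gap-filled `ndvi` and `lst` composite cubes.
#' @export
synthetic_benchmark <- function(seed, grid_size = c(16L, 16L)) {
  sim <- simulation_config(grid_size = grid_size, seed = seed)
  cubes <- generate_daily_cubes(sim)
  ndvi <- inject_missing(cubes$ndvi, sim$missing_fraction,
                         seed = (sim$seed + 1L) %% .Machine$integer.max)
  lst <- inject_missing(cubes$lst, sim$missing_fraction,
                        seed = (sim$seed + 2L) %% .Machine$integer.max)
  cal <- build_calendar(sim$start_date, sim$end_date)
  nd8 <- fill_gaps(compose_8day(ndvi, cal))
  ls8 <- fill_gaps(compose_8day(lst, cal))
  mk <- function(scope)
    compute_vhi(compute_vci(nd8, normalization_stats(nd8, scope)),
                compute_tci(ls8, normalization_stats(ls8, scope)), 0.5)
  list(vhi = list(global = mk("global"), image = mk("image")),
       split = temporal_split(n_frames(nd8)), ndvi = nd8, lst = ls8)
}

# Stable short hash of a configuration, for tagging output artifacts.
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(names(unlist(config)), unlist(config), sep = "=",
                   collapse = ";"), f)
  unname(substr(tools::md5sum(f), 1, 12))
}

log_msg <- function(..., logfile = NULL) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  paste0(...))
  message(line)
  if (!is.null(logfile)) cat(line, "\n", file = logfile, append = TRUE)
}

with_stage <- function(stage, logfile, expr) {
  log_msg("stage ", stage, " ...", logfile = logfile)
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full forecasting pipeline
#'
#' Chains preprocessing (8-day compositing + gap fill), index computation,
#' window construction, model training, both forecasting strategies and
#' evaluation for every requested (scope, strategy, horizon, layers)
#' combination. Fully reproducible given `config$seed`.
#'
#' @param config a [run_config()].
#' @param ndvi,lst daily input [raster_cube()]s, or paths readable by
#'   [read_cube()]. Omit both and pass `simulate` to run on synthetic data.
#' @param simulate optional [simulation_config()]; generates daily cubes
#'   (degraded by its `missing_fraction`) instead of reading inputs.
#' @param scopes normalization scopes to run (default: the config's one).
#' @param strategies forecasting strategies (default both).
#' @param outdir optional output directory: metrics CSV
#'   (`scope,strategy,horizon,layers,rmse,mae,mape`), per-horizon prediction
#'   cubes (NetCDF), index cubes, a `run.log`, and a JSON stats sidecar.
#'   Every artifact is tagged with the config hash.
#' @return list with `metrics` (data frame), `reports` (nested list of
#'   `vhi_report`s), `baseline_reports`, `models`, and `config_hash`.
#' @export
run_pipeline <- function(config, ndvi = NULL, lst = NULL, simulate = NULL,
                         scopes = config$normalization_scope,
                         strategies = c("iterative", "separate"),
                         outdir = NULL) {
  stopifnot(inherits(config, "vhi_run_config"))
  hash <- config_hash(config)
  logfile <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    logfile <- file.path(outdir, "run.log")
  }
  log_msg("run ", hash, " starting", logfile = logfile)

  cubes <- with_stage("input", logfile, {
    if (!is.null(simulate)) {
      sim <- generate_daily_cubes(simulate)
      if (simulate$missing_fraction > 0) {
        sim$ndvi <- inject_missing(sim$ndvi, simulate$missing_fraction,
                                   seed = simulate$seed + 1L)
        sim$lst <- inject_missing(sim$lst, simulate$missing_fraction,
                                  seed = simulate$seed + 2L)
      }
      sim
    } else {
      list(ndvi = if (is_cube(ndvi)) ndvi else read_cube(ndvi, "NDVI"),
           lst = if (is_cube(lst)) lst else read_cube(lst, "LST"))
    }
  })

  comp <- with_stage("preprocess", logfile, {
    cal <- build_calendar(min(cubes$ndvi$dates), max(cubes$ndvi$dates) + 1L)
    ndvi8 <- if (cubes$ndvi$step == "daily")
      compose_8day(cubes$ndvi, cal) else cubes$ndvi
    lst8 <- if (cubes$lst$step == "daily")
      compose_8day(cubes$lst, cal) else cubes$lst
    list(ndvi = fill_gaps(ndvi8, config$fill_mode),
         lst = fill_gaps(lst8, config$fill_mode))
  })

  T <- n_frames(comp$ndvi)
  split <- temporal_split(T, config$split_fractions)
  metrics <- NULL
  reports <- list(); basereps <- list(); models_out <- list()

  for (scope in scopes) {
    vhi <- with_stage(paste0("indices[", scope, "]"), logfile, {
      sn <- normalization_stats(comp$ndvi, scope)
      sl <- normalization_stats(comp$lst, scope)
      v <- compute_vhi(compute_vci(comp$ndvi, sn),
                       compute_tci(comp$lst, sl), config$alpha)
      if (!is.null(outdir)) {
        write_cube(v, file.path(outdir, sprintf("vhi_%s.nc", scope)),
                   "netcdf", tag = hash)
        jsonlite::write_json(
          list(scope = scope, variable = c("NDVI", "LST"),
               ndvi_min = sn$minimum, ndvi_max = sn$maximum,
               lst_min = sl$minimum, lst_max = sl$maximum, tag = hash),
          file.path(outdir, sprintf("stats_%s.json", scope)),
          digits = NA, auto_unbox = TRUE)
      }
      v
    })

    basereps[[scope]] <- with_stage("baselines", logfile,
      baselines(vhi, split, config$window_length, config$horizons))

    for (nlay in config$layers) {
      models <- list()
      need_k <- if ("separate" %in% strategies) config$horizons else 1L
      need_k <- sort(unique(c(1L, need_k)))
      for (k in need_k) {
        models[[as.character(k)]] <-
          with_stage(sprintf("train[%s,L%d,k%d]", scope, nlay, k), logfile, {
            w <- make_windows(vhi, config$window_length, k, split)
            spec <- convlstm_spec(nlay, config$filters, config$kernel_size,
                                  horizon = k)
            seed_lk <- (config$seed + 101L * nlay + 11L * k +
                          1009L * match(scope, scopes)) %% .Machine$integer.max
            m <- build_model(spec, seed = seed_lk)
            train(m, w, training_protocol(config$max_epochs,
                                          config$patience,
                                          config$batch_size,
                                          config$learning_rate,
                                          seed = seed_lk + 1L))
          })
      }
      models_out[[scope]][[as.character(nlay)]] <- models
      for (strategy in strategies) {
        fcs <- with_stage(sprintf("forecast[%s,%s,L%d]", scope, strategy,
                                  nlay), logfile, {
          if (strategy == "iterative")
            forecast_iterative(models[["1"]], vhi, split,
                               config$window_length, max(config$horizons))
          else
            forecast_separate(models, vhi, split, config$window_length,
                              config$horizons)
        })
        for (k in config$horizons) {
          fc <- fcs[[as.character(k)]]
          if (is.null(fc)) next
          rep <- evaluate_forecast(fc, metadata = list(
            scope = scope, layers = nlay, seed = config$seed, tag = hash))
          reports[[scope]][[strategy]][[as.character(nlay)]][[
            as.character(k)]] <- rep
          metrics <- rbind(metrics, data.frame(
            scope = scope, strategy = strategy, horizon = k, layers = nlay,
            rmse = rep$rmse, mae = rep$mae, mape = rep$mape))
          if (!is.null(outdir))
            write_cube(fc$pred, file.path(outdir,
              sprintf("pred_%s_%s_L%d_k%d.nc", scope, strategy, nlay, k)),
              "netcdf", tag = hash)
        }
      }
    }
  }

  if (!is.null(outdir)) {
    write.csv(metrics, file.path(outdir, "metrics.csv"), row.names = FALSE)
    writeLines(hash, file.path(outdir, "config_hash.txt"))
  }
  log_msg("run ", hash, " done", logfile = logfile)
  list(metrics = metrics, reports = reports, baseline_reports = basereps,
       models = models_out, split = split, config_hash = hash)
}
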