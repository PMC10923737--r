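# Shared fixture builders. Everything is generated in code; nothing is read
# from disk.

composite_dates <- function(n, from = "2012-01-01") {
  cal <- build_calendar(from, as.Date(from) + ceiling(n / 46 + 1) * 366)
  cal$start[seq_len(n)]
}

# Small composite-step cube with controllable values.
make_composite_cube <- function(values, variable = "VHI",
                                from = "2012-01-01") {
  d <- dim(values)
  raster_cube(values, composite_dates(d[3], from), variable,
              step = "composite_8day")
}

random_cube <- function(rows, cols, nt, seed = 1, variable = "NDVI",
                        lo = -0.2, hi = 0.9, daily = FALSE,
                        from = "2012-01-01") {
  set.seed(seed)
  vals <- array(runif(rows * cols * nt, lo, hi), c(rows, cols, nt))
  if (daily) {
    raster_cube(vals, seq(as.Date(from), by = "day", length.out = nt),
                variable, step = "daily")
  } else {
    make_composite_cube(vals, variable, from)
  }
}

random_kernel <- function(k, cin, f, sd = 0.3) {
  array(rnorm(k * k * cin * f, sd = sd), c(k, k, cin, f))
}

random_cell_params <- function(k, cin, f, rows = NULL, cols = NULL,
                               peepholes = FALSE, seed = 1) {
  set.seed(seed)
  peep <- function() if (peepholes) array(rnorm(rows * cols * f, sd = 0.3),
                                          c(rows, cols, f)) else NULL
  cell_params(
    W_xi = random_kernel(k, cin, f), W_xf = random_kernel(k, cin, f),
    W_xo = random_kernel(k, cin, f), W_xc = random_kernel(k, cin, f),
    W_hi = random_kernel(k, f, f), W_hf = random_kernel(k, f, f),
    W_ho = random_kernel(k, f, f), W_hc = random_kernel(k, f, f),
    b_i = rnorm(f, sd = 0.1), b_f = rnorm(f, sd = 0.1),
    b_o = rnorm(f, sd = 0.1), b_c = rnorm(f, sd = 0.1),
    W_ci = peep(), W_cf = peep(), W_co = peep()
  )
}

# Explicit-loop same-padding cross-correlation oracle: x (rows, cols, Cin),
# kernel (k, k, Cin, F) -> (rows, cols, F). Independent of the im2col path.
conv_oracle <- function(x, kernel) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  d <- dim(x); k <- dim(kernel)[1]; f <- dim(kernel)[4]; pad <- k %/% 2
  out <- array(0, c(d[1], d[2], f))
  for (fi in seq_len(f))
    for (r in seq_len(d[1]))
      for (c in seq_len(d[2])) {
        acc <- 0
        for (dr in -pad:pad)
          for (dc in -pad:pad) {
            rr <- r + dr; cc <- c + dc
            if (rr >= 1 && rr <= d[1] && cc >= 1 && cc <= d[2])
              for (ch in seq_len(d[3]))
                acc <- acc + kernel[dr + pad + 1, dc + pad + 1, ch, fi] *
                  x[rr, cc, ch]
          }
        out[r, c, fi] <- acc
      }
  out
}

# Oracle cell step built on conv_oracle and the printed gate formulas.
cell_step_oracle <- function(x, state, p) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  sig <- function(z) 1 / (1 + exp(-z))
  add_b <- function(a, b) sweep(a, 3, b, "+")
  pp <- function(W, cc) if (is.null(W)) 0 else W * cc
  i <- sig(add_b(conv_oracle(x, p$W_xi) + conv_oracle(state$h, p$W_hi),
                 p$b_i) + pp(p$W_ci, state$c))
  f <- sig(add_b(conv_oracle(x, p$W_xf) + conv_oracle(state$h, p$W_hf),
                 p$b_f) + pp(p$W_cf, state$c))
  g <- tanh(add_b(conv_oracle(x, p$W_xc) + conv_oracle(state$h, p$W_hc),
                  p$b_c))
  cn <- f * state$c + i * g
  o <- sig(add_b(conv_oracle(x, p$W_xo) + conv_oracle(state$h, p$W_ho),
                 p$b_o) + pp(p$W_co, cn))
  list(h = o * tanh(cn), c = cn, i = i, f = f, o = o)
}

quick_protocol <- function(epochs = 3, seed = 0)
  training_protocol(max_epochs = epochs, patience = epochs - 1, seed = seed)

# ---- shared acceptance benchmark (computed once per session) ---------------

.bench_cache <- new.env(parent = emptyenv())

acceptance_benchmark <- function(seed) {
  key <- paste0("bench", seed)
  if (is.null(.bench_cache[[key]]))
    .bench_cache[[key]] <- synthetic_benchmark(seed)
  .bench_cache[[key]]
}

acceptance_model <- function(seed, scope) {
  key <- paste0("model", seed, scope)
  if (is.null(.bench_cache[[key]])) {
    bench <- acceptance_benchmark(seed)
    w <- make_windows(bench$vhi[[scope]], 6, 1, bench$split)
    m <- build_model(convlstm_spec(layers = 1, horizon = 1), seed = seed)
    .bench_cache[[key]] <- train(m, w, training_protocol(seed = seed))
  }
  .bench_cache[[key]]
}
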