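#' ConvLSTM model specification
#'
#' Describes a stacked ConvLSTM forecasting network: 1-3 ConvLSTM layers
#' (intermediate layers emit their full hidden sequence to the layer above),
#' a 1-channel convolutional output head over the last hidden state, and the
#' horizon the model is trained for. The network consumes a window of L
#' single-channel frames and emits one frame of the same spatial shape
#' (same-padding convolutions); predictions are clipped to `[0, 1]` at
#' inference.
#'
#' @param layers number of stacked ConvLSTM layers, 1, 2 or 3.
#' @param filters hidden channels per layer (default 16).
#' @param kernel_size odd convolution kernel size (default 3).
#' @param horizon forecast horizon (in composite steps) the model targets.
#' @param peepholes logical; the gate equations of the original formulation
#'   include Hadamard peephole terms reading the cell state. They are
#'   available in [cell_step()] but mainstream ConvLSTM implementations omit
#'   them, and the training path requires `FALSE`.
#' @return a `convlstm_spec` list.
#' @export
convlstm_spec <- function(layers = 1L, filters = 16L, kernel_size = 3L,
                          horizon = 1L, peepholes = FALSE) {
  layers <- as.integer(layers)
  if (!layers %in% 1:3) stop("layers must be 1, 2 or 3")
  if (kernel_size %% 2 != 1 || kernel_size < 1)
    stop("kernel_size must be an odd positive integer")
  if (filters < 1) stop("filters must be positive")
  if (horizon < 1) stop("horizon must be >= 1")
  structure(list(layers = layers, filters = as.integer(filters),
                 kernel_size = as.integer(kernel_size),
                 horizon = as.integer(horizon),
                 peepholes = isTRUE(peepholes)),
            class = "convlstm_spec")
}

glorot <- function(nin, nout, n) {
  lim <- sqrt(6 / (nin + nout))
  runif(n, -lim, lim)
}

#' Build (initialize) a ConvLSTM model
#'
#' Gate kernels are packed per layer into a single input-to-gate matrix
#' `Wx` (`k^2 * C_in` x `4 * filters`) and hidden-to-gate matrix `Wh`
#' (`k^2 * filters` x `4 * filters`), gate order i, f, g (candidate), o.
#' Initialization is Glorot-uniform with the forget-gate bias set to 1.
#'
#' @param spec a [convlstm_spec()].
#' @param seed integer seed for the weight initialization.
#' @return a `convlstm_model` handle.
#' @export
build_model <- function(spec, seed = 0L) {
  stopifnot(inherits(spec, "convlstm_spec"))
  if (spec$peepholes)
    stop("the training network does not support peephole connections; ",
         "use cell_step() for the peephole cell form")
  Fh <- spec$filters; k2 <- spec$kernel_size^2
  with_seed(seed, {
    layers <- lapply(seq_len(spec$layers), function(l) {
      cin <- if (l == 1) 1L else Fh
      b <- rep(0, 4 * Fh)
      b[(Fh + 1):(2 * Fh)] <- 1            # forget-gate bias
      list(
        Wx = matrix(glorot(k2 * cin, Fh, k2 * cin * 4 * Fh), k2 * cin),
        Wh = matrix(glorot(k2 * Fh, Fh, k2 * Fh * 4 * Fh), k2 * Fh),
        b = b
      )
    })
    head <- list(W = glorot(k2 * Fh, 1, k2 * Fh), b = 0)
    structure(list(spec = spec, layers = layers, head = head,
                   trained = FALSE, history = NULL),
              class = "convlstm_model")
  })
}

#' Trainable parameter count of a ConvLSTM model
#'
#' Per layer: `4 * (k^2 * (C_in + F) * F + F)` (four gates, each with an
#' input kernel, a hidden kernel and a bias), with `C_in = 1` for the first
#' layer and `C_in = F` above; plus the `k^2 * F + 1` head parameters.
#'
#' @param model a [build_model()] handle.
#' @return integer parameter count.
#' @export
count_params <- function(model) {
  stopifnot(inherits(model, "convlstm_model"))
  n <- sum(vapply(model$layers, function(l)
    length(l$Wx) + length(l$Wh) + length(l$b), numeric(1)))
  as.integer(n + length(model$head$W) + 1L)
}

#' @export
print.convlstm_model <- function(x, ...) {
  s <- x$spec
  cat(sprintf(
    "<convlstm_model> %d layer(s), %d filters, kernel %d, horizon %d: %d parameters%s\n",
    s$layers, s$filters, s$kernel_size, s$horizon, count_params(x),
    if (x$trained) sprintf(" (trained, %d epochs)", nrow(x$history)) else ""))
  invisible(x)
}

# --- cell-level primitive ----------------------------------------------------

#' Parameters of a single ConvLSTM cell
#'
#' Kernels follow the gate equations of the cell: input-to-gate kernels
#' `W_xi, W_xf, W_xo, W_xc` (arrays `k x k x C_in x F`), hidden-to-gate
#' kernels `W_hi, W_hf, W_ho, W_hc` (`k x k x F x F`), optional Hadamard
#' peephole weights `W_ci, W_cf, W_co` (same shape as the cell state,
#' `rows x cols x F`) and biases `b_i, b_f, b_o, b_c` (length `F`).
#'
#' @param W_xi,W_xf,W_xo,W_xc,W_hi,W_hf,W_ho,W_hc convolution kernels.
#' @param b_i,b_f,b_o,b_c gate biases.
#' @param W_ci,W_cf,W_co optional peephole weights (`NULL` = disabled).
#' @return a `cell_params` list.
#' @export
cell_params <- function(W_xi, W_xf, W_xo, W_xc, W_hi, W_hf, W_ho, W_hc,
                        b_i, b_f, b_o, b_c,
                        W_ci = NULL, W_cf = NULL, W_co = NULL) {
  p <- list(W_xi = W_xi, W_xf = W_xf, W_xo = W_xo, W_xc = W_xc,
            W_hi = W_hi, W_hf = W_hf, W_ho = W_ho, W_hc = W_hc,
            b_i = b_i, b_f = b_f, b_o = b_o, b_c = b_c,
            W_ci = W_ci, W_cf = W_cf, W_co = W_co)
  k <- dim(W_xi)[1]
  if (k %% 2 != 1) stop("kernel spatial size must be odd")
  if (!all(vapply(p[1:12], function(w) all(is.finite(w)), logical(1))))
    stop("non-finite cell parameters")
  class(p) <- "cell_params"
  p
}

# im2col neighbour index (1-based, sentinel P + 1) for a rows x cols grid.
patch_index <- function(rows, cols, k) {
  pad <- k %/% 2
  P <- rows * cols
  offs <- expand.grid(dr = -pad:pad, dc = -pad:pad)
  r <- rep(seq_len(rows), cols)
  c <- rep(seq_len(cols), each = rows)
  idx <- matrix(P + 1L, P, k * k)
  for (o in seq_len(k * k)) {
    rr <- r + offs$dr[o]; cc <- c + offs$dc[o]
    ok <- rr >= 1 & rr <= rows & cc >= 1 & cc <= cols
    idx[ok, o] <- rr[ok] + (cc[ok] - 1L) * rows
  }
  idx
}

# X: P x C matrix -> P x (C * k2) patch matrix, column (ch-1)*k2 + o.
im2col_r <- function(X, idx) {
  k2 <- ncol(idx)
  Xp <- rbind(X, 0)
  M <- Xp[as.vector(idx), , drop = FALSE]
  dim(M) <- c(nrow(X), k2 * ncol(X))
  M
}

# kernel array (k, k, Cin, F) -> packed (k2 * Cin) x F matrix whose row
# order matches im2col_r's column order.
pack_kernel <- function(W) {
  d <- dim(W)
  matrix(W, d[1] * d[2] * d[3], d[4])
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' One ConvLSTM cell step
#'
#' Evaluates the gate equations for one time step:
#' `i = sigma(W_xi * x + W_hi * h + W_ci o c + b_i)`,
#' `f = sigma(W_xf * x + W_hf * h + W_cf o c + b_f)`,
#' `c' = f o c + i o tanh(W_xc * x + W_hc * h + b_c)`,
#' `o = sigma(W_xo * x + W_ho * h + W_co o c' + b_o)`,
#' `h' = o o tanh(c')`, where `*` is a same-padding convolution and `o` the
#' Hadamard product. Peephole terms are zero when the peephole weights are
#' `NULL`. This is the reference cell used by the oracle tests; the training
#' loop runs an equivalent compiled path.
#'
#' @param x input frame: `rows x cols` matrix or `rows x cols x C_in` array.
#' @param state list with hidden `h` and cell memory `c`, both
#'   `rows x cols x F` arrays (e.g. from [init_state()]).
#' @param params a [cell_params()] object.
#' @return list with the new `h` and `c` plus the gate fields `i`, `f`, `o`.
#' @export
cell_step <- function(x, state, params) {
  stopifnot(inherits(params, "cell_params"))
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  if (any(!is.finite(x)) || any(!is.finite(state$h)) ||
      any(!is.finite(state$c)))
    stop("non-finite values in cell input or state")
  d <- dim(x); rows <- d[1]; cols <- d[2]
  Fh <- dim(params$W_hi)[4]
  P <- rows * cols
  k <- dim(params$W_xi)[1]
  idx <- patch_index(rows, cols, k)
  Xm <- matrix(x, P)
  Hm <- matrix(state$h, P)
  Cm <- matrix(state$c, P)
  px <- im2col_r(Xm, idx)
  ph <- im2col_r(Hm, idx)
  conv <- function(Wx, Wh, b)
    px %*% pack_kernel(Wx) + ph %*% pack_kernel(Wh) +
      matrix(b, P, Fh, byrow = TRUE)
  peep <- function(W) if (is.null(W)) 0 else matrix(W, P) * Cm
  i <- sigmoid(conv(params$W_xi, params$W_hi, params$b_i) + peep(params$W_ci))
  f <- sigmoid(conv(params$W_xf, params$W_hf, params$b_f) + peep(params$W_cf))
  g <- tanh(conv(params$W_xc, params$W_hc, params$b_c))
  cn <- f * Cm + i * g
  o_pre <- conv(params$W_xo, params$W_ho, params$b_o)
  if (!is.null(params$W_co)) o_pre <- o_pre + matrix(params$W_co, P) * cn
  o <- sigmoid(o_pre)
  h <- o * tanh(cn)
  shape <- function(m) array(m, c(rows, cols, Fh))
  list(h = shape(h), c = shape(cn), i = shape(i), f = shape(f), o = shape(o))
}

#' Zero initial cell state
#' @param rows,cols grid shape.
#' @param filters hidden channels.
#' @return list of zero `h` and `c` arrays.
#' @export
init_state <- function(rows, cols, filters) {
  z <- array(0, c(rows, cols, filters))
  list(h = z, c = z)
}

# Forward pass through the stacked network for a window array (P, L, B),
# returning raw (unclipped) predictions as a P x B matrix.
model_forward <- function(model, x, rows, cols) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  out <- clstm_predict_cpp(x, model$layers, model$head$W, model$head$b,
                           rows, cols, model$spec$kernel_size)
  out$pred
}

#' Predict target frames for a window dataset
#'
#' Runs the network on each input window and clips predictions to `[0, 1]`.
#'
#' @param model a trained `convlstm_model`, or any function mapping a
#'   `(P, L, n)` window array to a `P x n` prediction matrix (useful as a
#'   reference predictor, e.g. persistence).
#' @param x window array `(P, L, n)` (see [make_windows()]) or a
#'   `vhi_windows` object, in which case all its samples are predicted.
#' @param rows,cols grid shape (taken from `x` when it is a `vhi_windows`).
#' @return `P x n` matrix of predicted frames.
#' @export
predict_frames <- function(model, x, rows = NULL, cols = NULL) {
  if (inherits(x, "vhi_windows")) {
    rows <- x$rows; cols <- x$cols; x <- x$inputs
  }
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  pred <- if (is.function(model)) model(x)
          else model_forward(model, x, rows, cols)
  pred <- matrix(pred, ncol = dim(x)[3])   # guard against dropped dims
  pmin(pmax(pred, 0), 1)
}

model_horizon <- function(model) {
  if (is.function(model)) NA_integer_ else model$spec$horizon
}
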