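test_that("zero-parameter cell step has the closed-form gate values", {
  k <- 3; f <- 2; rows <- 4; cols <- 4
  zk <- function(cin) array(0, c(k, k, cin, f))
  p <- cell_params(zk(1), zk(1), zk(1), zk(1), zk(f), zk(f), zk(f), zk(f),
                   rep(0, f), rep(0, f), rep(0, f), rep(0, f))
  c0 <- array(rnorm(rows * cols * f), c(rows, cols, f))
  st <- list(h = array(0, c(rows, cols, f)), c = c0)
  x <- matrix(rnorm(rows * cols), rows, cols)
  out <- cell_step(x, st, p)
  expect_equal(out$i, array(0.5, dim(c0)))
  expect_equal(out$f, array(0.5, dim(c0)))
  expect_equal(out$o, array(0.5, dim(c0)))
  expect_equal(out$c, 0.5 * c0)
  expect_equal(out$h, 0.5 * tanh(0.5 * c0))
})

test_that("cell step with zero input, state and biases yields a zero hidden", {
  set.seed(31)
  p <- random_cell_params(3, 1, 4)
  p$b_i[] <- 0; p$b_f[] <- 0; p$b_o[] <- 0; p$b_c[] <- 0
  out <- cell_step(matrix(0, 5, 5), init_state(5, 5, 4), p)
  expect_equal(out$h, array(0, c(5, 5, 4)))
  expect_equal(out$c, array(0, c(5, 5, 4)))
})

test_that("cell step matches the explicit-loop oracle on random 5x5 grids", {
  for (seed in 1:3) {
    for (peep in c(FALSE, TRUE)) {
      p <- random_cell_params(3, 2, 3, rows = 5, cols = 5,
                              peepholes = peep, seed = seed)
      set.seed(seed + 100)
      x <- array(rnorm(5 * 5 * 2), c(5, 5, 2))
      st <- list(h = array(rnorm(75, sd = 0.5), c(5, 5, 3)),
                 c = array(rnorm(75, sd = 0.5), c(5, 5, 3)))
      got <- cell_step(x, st, p)
      want <- cell_step_oracle(x, st, p)
      expect_lt(max(abs(got$h - want$h)), 1e-5)
      expect_lt(max(abs(got$c - want$c)), 1e-5)
      expect_lt(max(abs(got$i - want$i)), 1e-5)
    }
  }
})

test_that("on a 1x1 grid the cell reduces to a scalar LSTM step", {
  set.seed(32)
  w <- as.list(rnorm(8, sd = 0.5)); names(w) <-
    c("xi", "xf", "xo", "xc", "hi", "hf", "ho", "hc")
  b <- as.list(rnorm(4, sd = 0.2)); names(b) <- c("i", "f", "o", "c")
  mk <- function(v) array(v, c(1, 1, 1, 1))
  p <- cell_params(mk(w$xi), mk(w$xf), mk(w$xo), mk(w$xc),
                   mk(w$hi), mk(w$hf), mk(w$ho), mk(w$hc),
                   b$i, b$f, b$o, b$c)
  x <- 0.7; h0 <- 0.3; c0 <- -0.4
  out <- cell_step(matrix(x, 1, 1),
                   list(h = array(h0, c(1, 1, 1)), c = array(c0, c(1, 1, 1))),
                   p)
  sig <- function(z) 1 / (1 + exp(-z))
  i <- sig(w$xi * x + w$hi * h0 + b$i)
  f <- sig(w$xf * x + w$hf * h0 + b$f)
  g <- tanh(w$xc * x + w$hc * h0 + b$c)
  cn <- f * c0 + i * g
  o <- sig(w$xo * x + w$ho * h0 + b$o)
  expect_equal(as.numeric(out$c), cn, tolerance = 1e-12)
  expect_equal(as.numeric(out$h), o * tanh(cn), tolerance = 1e-12)
})

test_that("parameter counts match the symbolic formula", {
  # 1 layer: 4*(k^2*(Cin+F)*F + F) + head, k=3, Cin=1, F=16
  m1 <- build_model(convlstm_spec(1))
  expect_equal(count_params(m1), 4 * (9 * (1 + 16) * 16 + 16) + (9 * 16 + 1))
  # 3 layers: Cin=F for layers 2-3
  m3 <- build_model(convlstm_spec(3))
  expect_equal(count_params(m3),
               4 * (9 * (1 + 16) * 16 + 16) +
                 2 * 4 * (9 * (16 + 16) * 16 + 16) + (9 * 16 + 1))
})

test_that("the network preserves the spatial shape for any grid", {
  m <- build_model(convlstm_spec(2, filters = 4), seed = 2)
  for (dims in list(c(3, 3), c(5, 8))) {
    x <- array(runif(prod(dims) * 4 * 2), c(prod(dims), 4, 2))
    pred <- predict_frames(m, x, dims[1], dims[2])
    expect_equal(dim(pred), c(prod(dims), 2))
    expect_true(all(pred >= 0 & pred <= 1))
  }
})

test_that("the compiled forward pass equals composing cell_step plus head", {
  set.seed(33)
  rows <- 5; cols <- 4; L <- 3; f <- 4; k <- 3
  m <- build_model(convlstm_spec(1, filters = f), seed = 7)
  W <- m$layers[[1]]
  # unpack the packed gate matrices into per-gate kernels (order i,f,g,o)
  blk <- function(M, j, cin) array(M[, ((j - 1) * f + 1):(j * f)],
                                   c(k, k, cin, f))
  p <- cell_params(
    W_xi = blk(W$Wx, 1, 1), W_xf = blk(W$Wx, 2, 1),
    W_xc = blk(W$Wx, 3, 1), W_xo = blk(W$Wx, 4, 1),
    W_hi = blk(W$Wh, 1, f), W_hf = blk(W$Wh, 2, f),
    W_hc = blk(W$Wh, 3, f), W_ho = blk(W$Wh, 4, f),
    b_i = W$b[1:f], b_f = W$b[(f + 1):(2 * f)],
    b_c = W$b[(2 * f + 1):(3 * f)], b_o = W$b[(3 * f + 1):(4 * f)])
  xs <- array(runif(rows * cols * L), c(rows * cols, L, 1))
  st <- init_state(rows, cols, f)
  for (t in seq_len(L))
    st <- cell_step(matrix(xs[, t, 1], rows, cols), st, p)
  idx <- vhicast:::patch_index(rows, cols, k)
  y_ref <- vhicast:::im2col_r(matrix(st$h, rows * cols), idx) %*%
    m$head$W + m$head$b
  y_cpp <- vhicast:::model_forward(m, xs, rows, cols)
  expect_lt(max(abs(y_cpp - y_ref)), 1e-4)   # compiled path is float32
})

test_that("compiled gradients agree with finite differences", {
  set.seed(34)
  rows <- 3; cols <- 3; L <- 2; B <- 2
  m <- build_model(convlstm_spec(2, filters = 2), seed = 9)
  x <- array(runif(rows * cols * L * B), c(rows * cols, L, B))
  targ <- matrix(runif(rows * cols * B), rows * cols, B)
  out <- vhicast:::clstm_grad_cpp(x, m$layers, m$head$W, m$head$b,
                                  rows, cols, 3, targ)
  loss_at <- function(model) vhicast:::clstm_loss_cpp(
    x, model$layers, model$head$W, model$head$b, rows, cols, 3, targ)$loss
  eps <- 1e-2
  check <- function(get, set, grad, n_probe = 6) {
    vals <- get(m)
    ii <- sample(length(vals), min(n_probe, length(vals)))
    for (i in ii) {
      up <- m; dn <- m
      vu <- vals; vu[i] <- vu[i] + eps
      vd <- vals; vd[i] <- vd[i] - eps
      up <- set(up, vu); dn <- set(dn, vd)
      fd <- (loss_at(up) - loss_at(dn)) / (2 * eps)
      expect_lt(abs(grad[i] - fd), pmax(0.05 * abs(fd), 2e-3))
    }
  }
  check(function(m) m$layers[[1]]$Wx,
        function(m, v) { m$layers[[1]]$Wx[] <- v; m },
        out$grad_layers[[1]]$Wx)
  check(function(m) m$layers[[2]]$Wh,
        function(m, v) { m$layers[[2]]$Wh[] <- v; m },
        out$grad_layers[[2]]$Wh)
  check(function(m) m$layers[[1]]$b,
        function(m, v) { m$layers[[1]]$b <- v; m },
        as.numeric(out$grad_layers[[1]]$b))
  check(function(m) m$head$W,
        function(m, v) { m$head$W <- v; m },
        as.numeric(out$grad_Whead))
})

test_that("model construction validates its specification", {
  expect_error(convlstm_spec(4), "layers")
  expect_error(convlstm_spec(1, kernel_size = 4), "odd")
  expect_error(build_model(convlstm_spec(1, peepholes = TRUE)), "peephole")
})
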