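#' Training protocol for a ConvLSTM model
#'
#' Loss is pixelwise mean squared error; optimization uses Adam. The model
#' is evaluated on the validation partition after every epoch and training
#' stops at `max_epochs` or as soon as the validation loss has not improved
#' (by any amount) for `patience` consecutive epochs; the best-validation
#' weights are restored.
#'
#' @param max_epochs maximum training epochs (default 100).
#' @param patience consecutive non-improving epochs tolerated (default 20);
#'   must be smaller than `max_epochs`.
#' @param batch_size minibatch size (default 8).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param seed integer seed controlling weight initialization order-of-use
#'   and minibatch shuffling.
#' @return a `training_protocol` list.
#' @export
training_protocol <- function(max_epochs = 100L, patience = 20L,
                              batch_size = 8L, learning_rate = 1e-3,
                              seed = 0L) {
  if (patience >= max_epochs)
    stop("patience must be smaller than max_epochs")
  structure(list(max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "training_protocol")
}

#' Early-stopping monitor
#'
#' Tracks the best validation loss seen so far; `update(val)` returns `TRUE`
#' when the loss has not improved (by any amount) for `patience` consecutive
#' updates. Used by [train()] and exposed for inspecting stop-rule behaviour
#' on arbitrary loss sequences.
#'
#' @param patience consecutive non-improving updates tolerated.
#' @return list with functions `update(val)` -> stop flag, `improved()`,
#'   and `best()`.
#' @export
early_stopper <- function(patience) {
  best <- Inf; wait <- 0L; last_improved <- FALSE
  list(
    update = function(val) {
      if (val < best) {
        best <<- val; wait <<- 0L; last_improved <<- TRUE
        FALSE
      } else {
        wait <<- wait + 1L; last_improved <<- FALSE
        wait >= patience
      }
    },
    improved = function() last_improved,
    best = function() best
  )
}

#' Number of epochs a loss sequence would run
#'
#' Applies the early-stopping rule of [train()] to a precomputed validation
#' loss sequence: training stops after the first epoch that completes
#' `patience` consecutive non-improving evaluations, or at the end of the
#' sequence.
#'
#' @param val_losses numeric vector of per-epoch validation losses.
#' @param patience consecutive non-improving epochs tolerated.
#' @return integer epoch count.
#' @export
epochs_run <- function(val_losses, patience) {
  es <- early_stopper(patience)
  for (i in seq_along(val_losses)) if (es$update(val_losses[i])) return(i)
  length(val_losses)
}

adam_init <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

model_param_list <- function(model) {
  out <- list()
  for (l in seq_along(model$layers)) {
    out[[paste0("Wx", l)]] <- model$layers[[l]]$Wx
    out[[paste0("Wh", l)]] <- model$layers[[l]]$Wh
    out[[paste0("b", l)]] <- model$layers[[l]]$b
  }
  out$Whead <- model$head$W
  out$bhead <- model$head$b
  out
}

model_set_params <- function(model, params) {
  for (l in seq_along(model$layers)) {
    model$layers[[l]]$Wx <- params[[paste0("Wx", l)]]
    model$layers[[l]]$Wh <- params[[paste0("Wh", l)]]
    model$layers[[l]]$b <- params[[paste0("b", l)]]
  }
  model$head$W <- params$Whead
  model$head$b <- params$bhead
  model
}

grad_param_list <- function(out, nl) {
  g <- list()
  for (l in seq_len(nl)) {
    gl <- out$grad_layers[[l]]
    g[[paste0("Wx", l)]] <- gl$Wx
    g[[paste0("Wh", l)]] <- gl$Wh
    g[[paste0("b", l)]] <- as.numeric(gl$b)
  }
  g$Whead <- as.numeric(out$grad_Whead)
  g$bhead <- out$grad_bhead
  g
}

dataset_loss <- function(model, inputs, targets, rows, cols, chunk = 32L) {
  n <- dim(inputs)[3]
  sse <- 0
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    out <- clstm_loss_cpp(inputs[, , s:e, drop = FALSE], model$layers,
                          model$head$W, model$head$b, rows, cols,
                          model$spec$kernel_size,
                          targets[, s:e, drop = FALSE])
    sse <- sse + out$loss * (e - s + 1L)
  }
  sse / n
}

#' Train a ConvLSTM model
#'
#' Minimizes pixelwise MSE on the training partition with Adam; see
#' [training_protocol()] for the early-stopping rule. Deterministic given
#' the protocol seed and the model's initialization seed.
#'
#' @param model a [build_model()] handle.
#' @param dataset a [make_windows()] dataset with nonempty train and
#'   validation partitions; the dataset horizon must match the model spec.
#' @param protocol a [training_protocol()].
#' @return the trained model, with a `history` data frame of per-epoch
#'   train/validation losses.
#' @export
train <- function(model, dataset, protocol = training_protocol()) {
  stopifnot(inherits(model, "convlstm_model"),
            inherits(dataset, "vhi_windows"),
            inherits(protocol, "training_protocol"))
  if (dataset$horizon != model$spec$horizon)
    stop("dataset horizon (", dataset$horizon,
         ") does not match model horizon (", model$spec$horizon, ")")
  tr <- which(dataset$partition == "train")
  va <- which(dataset$partition == "validation")
  if (length(tr) == 0 || length(va) == 0)
    stop("train and validation partitions must be nonempty")
  rows <- dataset$rows; cols <- dataset$cols
  xin <- dataset$inputs; targ <- dataset$targets
  lr <- protocol$learning_rate
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  nl <- model$spec$layers

  with_seed(protocol$seed, {
    params <- model_param_list(model)
    opt <- adam_init(params)
    step <- 0
    es <- early_stopper(protocol$patience)
    best_params <- params
    history <- data.frame(epoch = integer(), train_loss = numeric(),
                          val_loss = numeric())
    for (epoch in seq_len(protocol$max_epochs)) {
      model <- model_set_params(model, params)
      ord <- tr[sample.int(length(tr))]
      ep_loss <- 0
      for (s in seq(1, length(ord), by = protocol$batch_size)) {
        e <- min(s + protocol$batch_size - 1L, length(ord))
        sel <- ord[s:e]
        out <- clstm_grad_cpp(xin[, , sel, drop = FALSE], model$layers,
                              model$head$W, model$head$b, rows, cols,
                              model$spec$kernel_size,
                              targ[, sel, drop = FALSE])
        if (!is.finite(out$loss))
          stop("training loss diverged (NaN/Inf) at epoch ", epoch)
        ep_loss <- ep_loss + out$loss * length(sel)
        g <- grad_param_list(out, nl)
        step <- step + 1
        corr <- sqrt(1 - beta2^step) / (1 - beta1^step)
        for (nm in names(params)) {
          opt[[nm]]$m <- beta1 * opt[[nm]]$m + (1 - beta1) * g[[nm]]
          opt[[nm]]$v <- beta2 * opt[[nm]]$v + (1 - beta2) * g[[nm]]^2
          params[[nm]] <- params[[nm]] -
            lr * corr * opt[[nm]]$m / (sqrt(opt[[nm]]$v) + eps)
        }
        model <- model_set_params(model, params)
      }
      val <- dataset_loss(model, xin[, , va, drop = FALSE],
                          targ[, va, drop = FALSE], rows, cols)
      history <- rbind(history,
                       data.frame(epoch = epoch,
                                  train_loss = ep_loss / length(tr),
                                  val_loss = val))
      stop_now <- es$update(val)
      if (es$improved()) best_params <- params
      if (stop_now) break
    }
    model <- model_set_params(model, best_params)
    model$trained <- TRUE
    model$history <- history
    model$protocol <- protocol
    model
  })
}
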