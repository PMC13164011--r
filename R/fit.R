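# Model fitting: Adam optimisation of the categorical cross-entropy with
# early stopping on validation loss and best-checkpoint restoration.

#' Training configuration
#'
#' Defaults follow the studied protocol: Adam with initial learning rate
#' 0.001, batch size 16, at most 300 epochs, early stopping on validation
#' loss with patience 20 (strict improvement required) and restoration of
#' the best-validation checkpoint.
#'
#' @param learning_rate Adam step size.
#' @param batch_size Mini-batch size.
#' @param max_epochs Maximum number of epochs.
#' @param patience Epochs without strict validation-loss improvement before
#'   stopping.
#' @param monitor Monitored quantity (validation loss).
#' @param restore_best Restore the best-validation checkpoint after training.
#' @param seed Default seed controlling initialisation, batch shuffling and
#'   dropout.
#' @return An object of class `training_config`.
#' @export
training_config <- function(learning_rate = 0.001, batch_size = 16L,
                            max_epochs = 300L, patience = 20L,
                            monitor = "val_loss", restore_best = TRUE,
                            seed = 1L) {
  if (learning_rate <= 0 || batch_size < 1L || max_epochs < 1L || patience < 1L)
    stop("training parameters must be positive", call. = FALSE)
  if (patience >= max_epochs)
    stop("patience must be smaller than max_epochs", call. = FALSE)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), monitor = monitor,
                 restore_best = isTRUE(restore_best),
                 seed = as.integer(seed)),
            class = "training_config")
}

.xent <- function(probs, Y) {
  -mean(log(rowSums(probs * Y) + 1e-12))
}

.adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0L)
}

.adam_step <- function(params, grads, state, lr, b1 = 0.9, b2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - b1^state$t
  c2 <- 1 - b2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

# Inference-mode mean cross-entropy loss on stacked data.
.eval_loss <- function(kind, params, cfg, S) {
  n <- nrow(S$Y)
  fw <- .nn_forward(kind, params, cfg, S$P, S$V, n, train = FALSE)
  .xent(fw$probs, S$Y)
}

#' Fit a tactile grasp classifier
#'
#' Trains one of the six architectures (the dual-branch Transformer fusion
#' model, its single-modality ablations, or the RNN/CNN/LSTM baselines) on
#' preprocessed model inputs by Adam optimisation of the categorical
#' cross-entropy. When validation inputs are supplied, early stopping
#' monitors the validation loss (strict improvement resets the patience
#' counter) and the best-validation parameters are restored; otherwise the
#' training loss is monitored.
#'
#' @param train A `model_input_set` (or list of `model_input`s) to train on.
#' @param kind Architecture: one of `"fusion"`, `"pressure_only"`,
#'   `"vibration_only"`, `"rnn"`, `"cnn"`, `"lstm"`.
#' @param val Optional validation `model_input_set`.
#' @param net A [network_config()].
#' @param training A [training_config()].
#' @param seed Seed controlling initialisation, shuffling and dropout
#'   (defaults to the training config's seed).
#' @return An object of class `graspnet` with the learned `params`, the
#'   per-epoch loss `history`, `best_epoch`, `best_val_loss` and the
#'   achieved trainable-parameter count `n_params`.
#' @examples
#' cfg <- sim_config(n_per_class = 6, seed = 7)
#' inputs <- preprocess_dataset(simulate_grasp_dataset(cfg))
#' fit <- graspnet(inputs, kind = "fusion",
#'                 training = training_config(max_epochs = 3, patience = 2))
#' predict(fit, inputs, type = "class")
#' @export
graspnet <- function(train, kind = "fusion", val = NULL,
                     net = network_config(), training = training_config(),
                     seed = training$seed) {
  kind <- match.arg(kind, .model_kinds)
  if (length(train) == 0L) stop("empty training set", call. = FALSE)
  S <- .stack_inputs(train, net)
  SV <- if (!is.null(val) && length(val)) .stack_inputs(val, net) else NULL
  cl <- match.call()

  local_seed(seed, {
    model <- build_model(kind, net)
    params <- model$params
    state <- .adam_init(params)
    n <- length(train)
    T <- net$T
    best_loss <- Inf
    best_params <- params
    best_epoch <- 0L
    wait <- 0L
    hist_train <- numeric(0)
    hist_val <- numeric(0)

    for (epoch in seq_len(training$max_epochs)) {
      ord <- sample.int(n)
      batch_losses <- numeric(0)
      for (start in seq(1L, n, by = training$batch_size)) {
        bidx <- ord[start:min(start + training$batch_size - 1L, n)]
        B <- length(bidx)
        rows <- as.vector(vapply(bidx, .sample_rows, integer(T), T = T))
        Xp <- S$P[rows, , drop = FALSE]
        Xv <- S$V[rows, , drop = FALSE]
        Yb <- S$Y[bidx, , drop = FALSE]
        fw <- .nn_forward(kind, params, net, Xp, Xv, B, train = TRUE)
        batch_losses <- c(batch_losses, .xent(fw$probs, Yb))
        dlogits <- (fw$probs - Yb) / B
        grads <- .nn_backward(dlogits, fw$cache, kind, params, net, B)
        upd <- .adam_step(params, grads, state, training$learning_rate)
        params <- upd$params
        state <- upd$state
      }
      hist_train <- c(hist_train, mean(batch_losses))
      mon <- if (is.null(SV)) hist_train[epoch]
             else .eval_loss(kind, params, net, SV)
      hist_val <- c(hist_val, if (is.null(SV)) NA_real_ else mon)
      if (mon < best_loss) {                 # strict improvement resets patience
        best_loss <- mon
        best_params <- params
        best_epoch <- epoch
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= training$patience) break
      }
    }
    if (training$restore_best) params <- best_params

    structure(list(
      kind = kind, params = params, net = net, training = training,
      history = data.frame(epoch = seq_along(hist_train),
                           train_loss = hist_train, val_loss = hist_val),
      best_epoch = best_epoch, best_val_loss = best_loss,
      n_params = model$n_params, levels = class_levels(), seed = seed,
      call = cl), class = "graspnet")
  })
}

#' Predict from a fitted grasp classifier
#'
#' @param object A [graspnet()] fit.
#' @param newdata A `model_input_set`, list of `model_input`s, or a single
#'   `model_input`.
#' @param type `"prob"` for class probabilities, `"class"` for labels.
#' @param ... Unused.
#' @return A numeric matrix of probabilities (rows sum to 1) or a character
#'   vector of predicted labels.
#' @export
predict.graspnet <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "model_input")) newdata <- list(newdata)
  S <- .stack_inputs(newdata, object$net)
  n <- length(newdata)
  fw <- .nn_forward(object$kind, object$params, object$net, S$P, S$V, n,
                    train = FALSE)
  probs <- fw$probs
  dimnames(probs) <- list(S$ids, object$levels)
  if (type == "prob") probs
  else object$levels[max.col(probs, ties.method = "first")]
}

#' Mean cross-entropy loss of a fitted model on a data set
#'
#' @param object A [graspnet()] fit.
#' @param data A `model_input_set` or list of `model_input`s.
#' @return Scalar mean categorical cross-entropy.
#' @export
evaluate_loss <- function(object, data) {
  S <- .stack_inputs(data, object$net)
  .eval_loss(object$kind, object$params, object$net, S)
}

#' @export
print.graspnet <- function(x, ...) {
  cat(sprintf("graspnet %s classifier (%s trainable parameters)\n",
              x$kind, format(x$n_params, big.mark = ",")))
  cat(sprintf("  trained %d epochs, best epoch %d (monitored loss %.4f)\n",
              nrow(x$history), x$best_epoch, x$best_val_loss))
  invisible(x)
}

#' @export
summary.graspnet <- function(object, ...) {
  print(object)
  h <- object$history
  cat(sprintf("  final train loss %.4f", h$train_loss[nrow(h)]))
  if (!all(is.na(h$val_loss)))
    cat(sprintf(", final val loss %.4f", h$val_loss[nrow(h)]))
  cat("\n  classes:", paste(object$levels, collapse = ", "), "\n")
  invisible(object)
}

#' @export
coef.graspnet <- function(object, ...) object$params

#' Plot training and validation loss curves
#' @param x A [graspnet()] fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.graspnet <- function(x, ...) {
  h <- x$history
  ylim <- range(c(h$train_loss, h$val_loss), na.rm = TRUE)
  graphics::plot(h$epoch, h$train_loss, type = "l", col = "steelblue",
                 xlab = "epoch", ylab = "cross-entropy loss", ylim = ylim, ...)
  if (!all(is.na(h$val_loss)))
    graphics::lines(h$epoch, h$val_loss, col = "firebrick")
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"),
                   col = c("steelblue", "firebrick"), lty = 1, bty = "n")
  invisible(x)
}
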