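# Optimization protocol: MSE objective, Adam with the conventional default
# step size, epoch cap with patience-based early stopping on validation
# loss, best-checkpoint restoration.

#' Training configuration
#'
#' Defaults follow the standard protocol: up to 300 epochs, stopping when 25
#' epochs pass without a new best validation loss (strict improvement; ties
#' do not reset patience), Adam at learning rate 0.001 with moments
#' (0.9, 0.999).  Batch size is not part of the published protocol and is
#' exposed here (default 16).  `normalize = TRUE` toggles max-scaling of
#' inputs/targets by the training-set maximum before optimization
#' (predictions are rescaled back); the default is no normalization since
#' generated corpora already share a fixed amplitude convention.
#'
#' @param max_epochs epoch cap.
#' @param patience epochs without improvement before stopping.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param seed shuffling seed (per-epoch order is derived from it).
#' @param task `"conversion"` (spectrum to spectrum) or `"quantification"`
#'   (spectrum to concentration vector); informational, recorded in the
#'   history.
#' @param normalize logical, see above.
#' @param verbose print per-epoch losses.
#' @export
train_config <- function(max_epochs = 300L, patience = 25L, batch_size = 16L,
                         learning_rate = 1e-3, seed = 1L,
                         task = c("conversion", "quantification"),
                         normalize = FALSE, verbose = FALSE) {
  stopifnot(max_epochs >= 1, patience >= 1, batch_size >= 1)
  structure(list(max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 task = match.arg(task), normalize = isTRUE(normalize),
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

eval_mse <- function(net, x, y, batch_size = 64L, scale = 1) {
  tot <- 0
  for (s in seq(1, nrow(x), by = batch_size)) {
    e <- min(s + batch_size - 1, nrow(x))
    pred <- net_forward(net, x[s:e, , drop = FALSE] / scale,
                        training = FALSE)$Y * scale
    tot <- tot + sum((pred - y[s:e, , drop = FALSE])^2)
  }
  tot / length(y)
}

#' Train a network
#'
#' Minimizes MSE with Adam, evaluating validation MSE after every epoch.
#' Training stops at `max_epochs` or as soon as `patience` consecutive
#' epochs pass without a strict improvement of the best validation loss; the
#' parameters from the best validation epoch are restored before returning.
#'
#' @param net a `fieldlift_net` from [build_network()].
#' @param train,val lists with matrices `x` (inputs, samples x input_len)
#'   and `y` (targets).
#' @param cfg a [train_config()].
#' @return list with `net` (trained, best-epoch parameters) and `history`
#'   (class `train_history`): per-epoch train/validation losses,
#'   `best_epoch`, `best_val_loss`, `stopped_reason` (`"max_epochs"` or
#'   `"early_stop"`).
#' @export
train_model <- function(net, train, val, cfg = train_config()) {
  stopifnot(inherits(net, "fieldlift_net"))
  if (!nrow(train$x %||% matrix(nrow = 0, ncol = 0)) || !nrow(val$x))
    stopf("empty dataset: train and val must contain at least one sample")
  if (ncol(train$x) != net$spec$input_len)
    stopf("dimension mismatch: network expects input_len %d, got %d",
          net$spec$input_len, ncol(train$x))
  scale <- if (cfg$normalize) max(abs(train$x), abs(train$y)) else 1
  opt <- adam_init(net$params, lr = cfg$learning_rate)
  n <- nrow(train$x)
  best_val <- Inf; best_params <- net$params; best_epoch <- 0L
  since_best <- 0L; reason <- "max_epochs"
  tr_loss <- val_loss <- numeric(0)
  # training owns all of its stochasticity (shuffling and dropout masks):
  # everything below draws from a stream derived from cfg$seed
  with_seed(derive_seed(cfg$seed, "steps"),
  for (epoch in seq_len(cfg$max_epochs)) {
    idx <- with_seed(derive_seed(cfg$seed, paste0("epoch", epoch)),
                     sample.int(n))
    ep_loss <- 0
    for (s in seq(1, n, by = cfg$batch_size)) {
      rows <- idx[s:min(s + cfg$batch_size - 1, n)]
      xb <- train$x[rows, , drop = FALSE] / scale
      yb <- train$y[rows, , drop = FALSE] / scale
      fw <- net_forward(net, xb, training = TRUE)
      diff <- fw$Y - yb
      loss <- mean(diff * diff)
      if (!is.finite(loss))
        stopf("non-finite training loss at epoch %d (architecture %s); aborting",
              epoch, net$architecture)
      grads <- net_backward(net, fw, 2 * diff / length(diff))
      st <- adam_step(opt, net$params, grads)
      opt <- st$opt; net$params <- st$params
      ep_loss <- ep_loss + loss * length(rows)
    }
    tr_loss[epoch] <- ep_loss / n
    val_loss[epoch] <- eval_mse(net, val$x, val$y, scale = scale)
    if (cfg$verbose)
      message(sprintf("epoch %3d  train %.6g  val %.6g", epoch,
                      tr_loss[epoch], val_loss[epoch]))
    if (val_loss[epoch] < best_val) {
      best_val <- val_loss[epoch]; best_epoch <- epoch
      best_params <- net$params; since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= cfg$patience) { reason <- "early_stop"; break }
    }
  })
  net$params <- best_params
  history <- structure(list(
    train_loss = tr_loss, val_loss = val_loss,
    best_epoch = best_epoch, best_val_loss = best_val,
    stopped_reason = reason, n_epochs = length(tr_loss),
    task = cfg$task, scale = scale,
    architecture = net$architecture), class = "train_history")
  net$scale <- scale
  list(net = net, history = history)
}

#' @export
print.train_history <- function(x, ...) {
  cat(sprintf("<train_history:%s> %d epochs (%s), best val %.6g @ epoch %d\n",
              x$architecture, x$n_epochs, x$stopped_reason,
              x$best_val_loss, x$best_epoch))
  invisible(x)
}
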