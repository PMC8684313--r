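# Training: one-hot targets, the per-unit cross-entropy summed over unrolled
# timesteps, uniform weight initialization normalized by kernel size, the
# stepped learning-rate schedule, and Adam over truncated backpropagation
# through time (the truncation horizon is the full unroll).

#' One-hot target vector
#' @param label 0-based class index.
#' @param n_classes number of classes N.
#' @return numeric vector with a single 1 at position `label + 1`.
#' @export
one_hot <- function(label, n_classes) {
  label <- as.integer(label)
  if (label < 0L || label >= n_classes)
    occ_error("occrnn_domain_error", "label %d outside 0..%d",
              label, n_classes - 1L)
  y <- numeric(n_classes)
  y[label + 1L] <- 1
  y
}

one_hot_matrix <- function(labels, n_classes) {
  y <- matrix(0, length(labels), n_classes)
  y[cbind(seq_along(labels), as.integer(labels) + 1L)] <- 1
  y
}

#' Temporal cross-entropy loss
#'
#' `J = -sum_t sum_i [y_i log yhat_i(t) + (1 - y_i) log(1 - yhat_i(t))]`,
#' the per-unit binary cross-entropy of every readout, summed across all
#' timesteps and output units. Log arguments are clamped at `eps`, so a
#' readout exactly matching a one-hot target contributes 0.
#'
#' @param readouts list of probability vectors (or 1-row matrices), one per
#'   timestep.
#' @param y one-hot target vector.
#' @param eps clamping constant for the logs.
#' @return scalar loss, >= 0.
#' @export
temporal_loss <- function(readouts, y, eps = 1e-12) {
  if (!is.list(readouts)) readouts <- list(readouts)
  total <- 0
  for (p in readouts) {
    p <- as.numeric(p)
    if (length(p) != length(y))
      occ_error("occrnn_shape_error", "readout length %d vs target %d",
                length(p), length(y))
    pc <- clamp(p, eps, 1 - eps)
    total <- total - sum(y * log(pc) + (1 - y) * log(1 - pc))
  }
  total
}

#' Re-initialize a network's weights
#'
#' Kernel entries are drawn from `U(-1/sqrt(fan_in), 1/sqrt(fan_in))` with
#' `fan_in = k^2 * C_in` (a uniform distribution normalized by the kernel
#' size); biases are set to zero. Deterministic given the seed.
#' @param network an `occ_network`.
#' @param seed integer seed.
#' @export
init_weights <- function(network, seed) {
  build_network(network$spec, seed = seed)
}

#' Training configuration
#'
#' @param lr initial learning rate (0.004).
#' @param epochs training epochs.
#' @param batch minibatch size (500).
#' @param lr_cut_epochs epochs at which the learning rate is cut to 10%
#'   (default 75 and 90).
#' @param lr_cut_factor multiplicative cut (0.1).
#' @param seed integer seed for shuffling.
#' @param cut_mode `"successive"` applies each cut on top of the previous one
#'   (0.004 -> 4e-4 -> 4e-5); `"from_initial"` makes every cut relative to the
#'   initial rate.
#' @param beta1,beta2,adam_eps Adam moment parameters (conventional defaults).
#' @export
train_config <- function(lr = 0.004, epochs = 100L, batch = 500L,
                         lr_cut_epochs = c(75L, 90L), lr_cut_factor = 0.1,
                         seed = 1L, cut_mode = c("successive", "from_initial"),
                         beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8) {
  cut_mode <- match.arg(cut_mode)
  if (lr <= 0) occ_error("occrnn_config_error", "lr must be > 0")
  if (epochs < 0L) occ_error("occrnn_config_error", "epochs must be >= 0")
  structure(list(lr = lr, epochs = as.integer(epochs), batch = as.integer(batch),
                 lr_cut_epochs = as.integer(lr_cut_epochs),
                 lr_cut_factor = lr_cut_factor, seed = as.integer(seed),
                 cut_mode = cut_mode, beta1 = beta1, beta2 = beta2,
                 adam_eps = adam_eps),
            class = "train_config")
}

#' Learning rate at a given epoch
#' @param epoch 0-based epoch index.
#' @param config a [train_config()].
#' @export
lr_at <- function(epoch, config) {
  ncuts <- sum(epoch >= config$lr_cut_epochs)
  if (config$cut_mode == "successive")
    config$lr * config$lr_cut_factor^ncuts
  else
    config$lr * if (ncuts > 0) config$lr_cut_factor else 1
}

#' Train a network with Adam over BPTT
#'
#' Minimizes the batch-mean of [temporal_loss()] over minibatches. The forward
#' pass runs in train mode (batch statistics, running statistics updated); the
#' recurrent graph is unrolled for the spec's `tau` steps (feedforward
#' networks and the GLM are time-invariant and train on a single step with the
#' loss scaled by `tau`).
#'
#' @param net an `occ_network` (see [build_network()]).
#' @param x input array (H, W, C, N).
#' @param labels 0-based class labels, length N.
#' @param config a [train_config()].
#' @param test_x,test_labels optional held-out set; the final-timestep test
#'   error is recorded per epoch.
#' @param verbose print per-epoch progress.
#' @return list: `net` (trained), `history` (data frame with epoch, loss, lr,
#'   test_error).
#' @export
train_network <- function(net, x, labels, config = train_config(),
                          test_x = NULL, test_labels = NULL, verbose = FALSE) {
  x <- as_nchw(x)
  n <- dim(x)[4]
  if (n == 0L) occ_error("occrnn_config_error", "empty training set")
  if (length(labels) != n)
    occ_error("occrnn_shape_error", "%d inputs vs %d labels", n, length(labels))
  spec <- net$spec
  y_all <- one_hot_matrix(labels, spec$n_classes)
  params <- collect_params(net)
  mstate <- zero_like(params)
  vstate <- zero_like(params)
  step <- 0L
  hist <- vector("list", config$epochs)
  train_tau <- if (spec$glm || !is_recurrent(spec)) 1L else spec$tau

  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs) - 1L) {
      lr <- lr_at(epoch, config)
      ord <- sample.int(n)
      ep_loss <- 0; nb <- 0L
      for (start in seq(1L, n, by = config$batch)) {
        idx <- ord[start:min(start + config$batch - 1L, n)]
        if (length(idx) < 2L && !spec$glm) next  # batch-norm needs >= 2
        xb <- x[, , , idx, drop = FALSE]
        fw <- forward_pass(net, xb, tau = if (is_recurrent(spec)) train_tau else spec$tau,
                           mode = "train")
        net <- fw$net
        bw <- backward_pass(net, fw$trace, y_all[idx, , drop = FALSE],
                            mode = "train")
        if (!is.finite(bw$loss))
          occ_error("occrnn_divergence",
                    "non-finite loss at epoch %d, step %d (lr %g)",
                    epoch, step, lr)
        step <- step + 1L
        params <- collect_params(net)
        for (nm in names(params)) {
          g <- bw$grads[[nm]]
          mstate[[nm]] <- config$beta1 * mstate[[nm]] + (1 - config$beta1) * g
          vstate[[nm]] <- config$beta2 * vstate[[nm]] + (1 - config$beta2) * g^2
          mh <- mstate[[nm]] / (1 - config$beta1^step)
          vh <- vstate[[nm]] / (1 - config$beta2^step)
          params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + config$adam_eps)
        }
        net <- set_params(net, params)
        ep_loss <- ep_loss + bw$loss; nb <- nb + 1L
      }
      terr <- NA_real_
      if (!is.null(test_x))
        terr <- error_rate(predict_network(net, test_x)$labels, test_labels)
      hist[[epoch + 1L]] <- data.frame(epoch = epoch, loss = ep_loss / max(nb, 1L),
                                       lr = lr, test_error = terr)
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  lr %g  test_err %s",
                        epoch, ep_loss / max(nb, 1L), lr,
                        ifelse(is.na(terr), "-", sprintf("%.3f", terr))))
    }
  })
  history <- if (config$epochs > 0) do.call(rbind, hist) else
    data.frame(epoch = integer(), loss = numeric(), lr = numeric(),
               test_error = numeric())
  list(net = net, history = history)
}
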