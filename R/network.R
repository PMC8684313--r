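# The network family: stacks of recurrent convolutional layers with bottom-up
# (B), lateral (L) and top-down (T) streams, 2x2 max pooling between layers,
# global average pooling and a softmax readout; plus a GLM baseline (one fully
# connected layer with sigmoid outputs). Recurrent streams read the previous
# timestep's layer state (post-ReLU, pre-pool, at native resolution); the
# top-down stream upsamples the layer above by a stride-2 transposed
# convolution with a 3x3 kernel. At t = 1 all recurrent inputs are zero
# tensors and contribute nothing, so a one-step unroll equals the feedforward
# pass with the same bottom-up weights.

ARCH_TABLE <- list(
  "B"   = list(connections = "B", kernel = 3L, maps = 32L, layers = 2L),
  "B-F" = list(connections = "B", kernel = 3L, maps = 64L, layers = 2L),
  "B-K" = list(connections = "B", kernel = 6L, maps = 32L, layers = 2L),
  "B-D" = list(connections = "B", kernel = 3L, maps = 32L, layers = 4L),
  "BT"  = list(connections = c("B", "T"), kernel = 3L, maps = 32L, layers = 2L),
  "BL"  = list(connections = c("B", "L"), kernel = 3L, maps = 32L, layers = 2L),
  "BLT" = list(connections = c("B", "L", "T"), kernel = 3L, maps = 32L, layers = 2L),
  "GLM" = list(connections = character(), glm = TRUE)
)

#' Declarative network specification
#'
#' @param connections subset of `c("B", "L", "T")`; `"B"` alone gives a
#'   feedforward network.
#' @param kernel square convolution kernel size (3 by default; 6 for the B-K
#'   control). The top-down transposed convolution always uses a 3x3 kernel.
#' @param maps feature maps per hidden layer (32; 64 for B-F).
#' @param layers number of hidden layers (2; 4 for B-D).
#' @param in_channels input channels (1 mono / 2 stereo grayscale; 3/6 color).
#' @param n_classes readout classes.
#' @param tau unroll steps (default 4). Feedforward specs ignore tau.
#' @param glm if TRUE, a single fully connected layer with sigmoid outputs on
#'   the flattened image; all convolutional settings are ignored.
#' @param canvas input (W, H) in pixels.
#' @return object of class `network_spec`.
#' @export
network_spec <- function(connections = "B", kernel = 3L, maps = 32L,
                         layers = 2L, in_channels = 1L, n_classes = 10L,
                         tau = 4L, glm = FALSE, canvas = c(32L, 32L)) {
  connections <- unique(match.arg(connections, c("B", "L", "T"),
                                  several.ok = TRUE))
  if (!glm && !"B" %in% connections)
    occ_error("occrnn_config_error", "bottom-up connections are mandatory")
  if ("T" %in% connections && layers < 2L)
    occ_error("occrnn_config_error", "top-down connections require >= 2 layers")
  if (tau < 1L) occ_error("occrnn_config_error", "tau must be >= 1")
  if (!glm && any(canvas %% 2^layers != 0))
    occ_error("occrnn_config_error",
              "canvas %dx%d not divisible by 2^%d for pooling",
              canvas[1], canvas[2], layers)
  structure(list(connections = connections, kernel = as.integer(kernel),
                 maps = as.integer(maps), layers = as.integer(layers),
                 in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes), tau = as.integer(tau),
                 glm = isTRUE(glm), canvas = as.integer(canvas)),
            class = "network_spec")
}

#' Named architecture from the model family
#'
#' One of `B`, `B-F`, `B-K`, `B-D`, `BT`, `BL`, `BLT`, `GLM`.
#' @param name architecture name.
#' @param in_channels,n_classes,tau,canvas,maps see [network_spec()]; `maps`
#'   overrides the family default to allow scaled-down experiments.
#' @export
arch_spec <- function(name, in_channels = 1L, n_classes = 10L, tau = 4L,
                      canvas = c(32L, 32L), maps = NULL) {
  if (!name %in% names(ARCH_TABLE))
    occ_error("occrnn_config_error", "unknown architecture '%s'", name)
  a <- ARCH_TABLE[[name]]
  if (isTRUE(a$glm))
    return(network_spec(connections = "B", glm = TRUE,
                        in_channels = in_channels, n_classes = n_classes,
                        tau = 1L, canvas = canvas))
  network_spec(connections = a$connections, kernel = a$kernel,
               maps = maps %||% a$maps, layers = a$layers,
               in_channels = in_channels, n_classes = n_classes,
               tau = tau, canvas = canvas)
}

is_recurrent <- function(spec) any(c("L", "T") %in% spec$connections)

layer_in_channels <- function(spec, l) {
  if (l == 1L) spec$in_channels else spec$maps
}

#' Count learnable parameters of a specification
#'
#' Counts convolutional, transposed-convolutional and fully connected weights
#' and biases (each stream carries its own bias). Batch-normalization
#' gamma/beta are learnable but excluded by default, matching the published
#' per-model totals.
#'
#' @param spec a [network_spec()].
#' @param include_bn include batch-norm parameters.
#' @return integer parameter count.
#' @export
count_learnable_parameters <- function(spec, include_bn = FALSE) {
  if (spec$glm) {
    d <- prod(spec$canvas) * spec$in_channels
    return(as.integer(d * spec$n_classes + spec$n_classes))
  }
  k <- spec$kernel; m <- spec$maps
  total <- 0L
  for (l in seq_len(spec$layers)) {
    cin <- layer_in_channels(spec, l)
    total <- total + k * k * cin * m + m                      # bottom-up
    if ("L" %in% spec$connections)
      total <- total + k * k * m * m + m                      # lateral
    if ("T" %in% spec$connections && l < spec$layers)
      total <- total + 3L * 3L * m * m + m                    # top-down (3x3)
    if (include_bn) {
      total <- total + 2L * cin                               # bn on B stream
      if ("L" %in% spec$connections) total <- total + 2L * m
      if ("T" %in% spec$connections && l < spec$layers) total <- total + 2L * m
    }
  }
  total + m * spec$n_classes + spec$n_classes                  # GAP readout
}

uniform_kernel <- function(dims, fan_in) {
  bound <- 1 / sqrt(fan_in)
  array(runif(prod(dims), -bound, bound), dims)
}

# Batch-norm parameters: gamma/beta are shared across timesteps; running
# statistics are kept per timestep (states[[t]]), because the activation
# distribution of a recurrent layer changes with the unroll step. Evaluation
# at timesteps beyond the trained horizon clamps to the last recorded step.
new_bn_params <- function(c_in) {
  list(gamma = rep(1, c_in), beta = rep(0, c_in), states = list())
}

bn_state_at <- function(bnp, t) {
  n <- length(bnp$states)
  if (n == 0L) NULL else bnp$states[[min(t, n)]]
}

#' Build a network from a specification
#'
#' Kernel entries are drawn from a uniform distribution normalized by the
#' kernel size, `U(-1/sqrt(fan_in), 1/sqrt(fan_in))` with
#' `fan_in = k^2 * C_in`; biases start at zero; batch-norm gamma/beta start at
#' 1/0 with separate parameters per input stream.
#'
#' @param spec a [network_spec()].
#' @param seed integer seed for the weight draw.
#' @return object of class `occ_network`.
#' @export
build_network <- function(spec, seed = 1L) {
  net <- structure(list(spec = spec, layers = list(), fc = NULL), class = "occ_network")
  with_seed(seed, {
    if (spec$glm) {
      d <- prod(spec$canvas) * spec$in_channels
      net$fc <- list(W = matrix(runif(d * spec$n_classes,
                                      -1 / sqrt(d), 1 / sqrt(d)),
                                d, spec$n_classes),
                     b = numeric(spec$n_classes))
      return(net)
    }
    k <- spec$kernel; m <- spec$maps
    for (l in seq_len(spec$layers)) {
      cin <- layer_in_channels(spec, l)
      lay <- list(
        w_B = uniform_kernel(c(k, k, cin, m), k * k * cin),
        b_B = numeric(m),
        bn_B = new_bn_params(cin)
      )
      if ("L" %in% spec$connections) {
        lay$w_L <- uniform_kernel(c(k, k, m, m), k * k * m)
        lay$b_L <- numeric(m)
        lay$bn_L <- new_bn_params(m)
      }
      if ("T" %in% spec$connections && l < spec$layers) {
        lay$w_T <- uniform_kernel(c(3L, 3L, m, m), 3 * 3 * m)
        lay$b_T <- numeric(m)
        lay$bn_T <- new_bn_params(m)
      }
      net$layers[[l]] <- lay
    }
    net$fc <- list(W = matrix(runif(m * spec$n_classes,
                                    -1 / sqrt(m), 1 / sqrt(m)),
                              m, spec$n_classes),
                   b = numeric(spec$n_classes))
  })
  net
}

#' @export
print.occ_network <- function(x, ...) {
  s <- x$spec
  nm <- if (s$glm) "GLM" else paste(sort(s$connections), collapse = "")
  cat(sprintf("<occ_network %s: %d layers x %d maps, k=%d, %d ch -> %d classes, tau=%d, %d params>\n",
              nm, s$layers, s$maps, s$kernel, s$in_channels, s$n_classes,
              s$tau, count_learnable_parameters(s)))
  invisible(x)
}

#' Single-stream preactivation
#'
#' `z = w_B' h_below + [w_L' h_same_prev] + [w_T' h_above_prev] + b`, where
#' the optional recurrent inputs may be NULL (the zero state at t = 1), and
#' the top-down term is a stride-2 transposed convolution that doubles the
#' spatial resolution of the layer above.
#'
#' @param h_below batch-normalized bottom-up input.
#' @param h_same_prev batch-normalized previous-step same-layer state or NULL.
#' @param h_above_prev batch-normalized previous-step layer-above state or NULL.
#' @param weights list with `w_B`, `b_B` and optionally `w_L`, `b_L`, `w_T`,
#'   `b_T`.
#' @export
preactivation <- function(h_below, h_same_prev = NULL, h_above_prev = NULL,
                          weights) {
  z <- conv2d(h_below, weights$w_B, weights$b_B)
  if (!is.null(h_same_prev)) {
    if (is.null(weights$w_L))
      occ_error("occrnn_shape_error", "lateral input given but no w_L")
    z <- z + conv2d(h_same_prev, weights$w_L, weights$b_L)
  }
  if (!is.null(h_above_prev)) {
    if (is.null(weights$w_T))
      occ_error("occrnn_shape_error", "top-down input given but no w_T")
    z <- z + conv_transpose2d(h_above_prev, weights$w_T, weights$b_T)
  }
  z
}

# layer spatial size: layer l runs at canvas / 2^(l-1)
layer_hw <- function(spec, l) {
  c(spec$canvas[2], spec$canvas[1]) %/% (2L^(l - 1L))
}

#' Run a network forward, unrolled over time
#'
#' @param net an `occ_network`.
#' @param x input array (H, W, C, N), or a list of such arrays (one per
#'   timestep) for sequence presentation with persistent state.
#' @param tau number of timesteps; defaults to the spec (or the sequence
#'   length when `x` is a list).
#' @param mode `"eval"` (running batch-norm statistics) or `"train"` (batch
#'   statistics; updates running statistics).
#' @param keep_z also record preactivations in the trace.
#' @return list: `trace` (class `occ_trace`: per-step states `a`,
#'   readouts/logits/gap, bn statistics and pooling indices needed for
#'   backward) and `net` (with updated running statistics in train mode).
#' @export
forward_pass <- function(net, x, tau = NULL, mode = c("eval", "train"),
                         keep_z = FALSE) {
  mode <- match.arg(mode)
  spec <- net$spec
  seq_input <- is.list(x)
  tau <- tau %||% (if (seq_input) length(x) else spec$tau)
  if (seq_input && length(x) != tau)
    occ_error("occrnn_shape_error", "sequence length %d != tau %d",
              length(x), tau)
  if (spec$glm) return(forward_glm(net, x, tau))
  if (!is_recurrent(spec) && !seq_input) {
    res <- forward_steps(net, list(as_nchw(x)), 1L, mode, keep_z)
    res$trace <- replicate_trace(res$trace, tau)
    return(res)
  }
  xs <- if (seq_input) lapply(x, as_nchw) else
    rep(list(as_nchw(x)), tau)
  forward_steps(net, xs, tau, mode, keep_z)
}

forward_glm <- function(net, x, tau) {
  x <- as_nchw(if (is.list(x)) x[[1]] else x)
  d <- dim(x)
  xf <- matrix(x, nrow = d[1] * d[2] * d[3], ncol = d[4])
  logits <- t(xf) %*% net$fc$W +
    matrix(net$fc$b, d[4], length(net$fc$b), byrow = TRUE)
  yhat <- sigmoid(logits)
  trace <- structure(list(readouts = rep(list(yhat), tau),
                          logits = rep(list(logits), tau),
                          gap = rep(list(t(xf)), tau),
                          a = NULL, tau = tau, glm = TRUE),
                     class = "occ_trace")
  list(trace = trace, net = net)
}

replicate_trace <- function(trace, tau) {
  trace$readouts <- rep(trace$readouts[1], tau)
  trace$logits <- rep(trace$logits[1], tau)
  trace$gap <- rep(trace$gap[1], tau)
  trace$replicated <- TRUE
  trace$tau <- tau
  trace
}

forward_steps <- function(net, xs, tau, mode, keep_z) {
  spec <- net$spec
  L <- spec$layers
  N <- dim(xs[[1]])[4]
  has_L <- "L" %in% spec$connections
  has_T <- "T" %in% spec$connections
  a_prev <- NULL  # zero state at t = 1: recurrent streams contribute nothing
  trace <- structure(list(a = vector("list", tau), z = if (keep_z) vector("list", tau),
                          inputs = xs, bottom = vector("list", tau),
                          pool_idx = vector("list", tau),
                          top_pool = vector("list", tau),
                          bn = vector("list", tau),
                          gap = vector("list", tau),
                          logits = vector("list", tau),
                          readouts = vector("list", tau),
                          tau = tau, glm = FALSE, replicated = FALSE),
                     class = "occ_trace")
  for (t in seq_len(tau)) {
    a_t <- vector("list", L)
    z_t <- if (keep_z) vector("list", L)
    bottom_t <- vector("list", L)
    pool_t <- vector("list", L)
    bn_t <- vector("list", L)
    for (l in seq_len(L)) {
      if (l == 1L) {
        below <- xs[[t]]
        pool_t[[l]] <- NULL
      } else {
        pl <- maxpool2(a_t[[l - 1L]])
        below <- pl$y
        pool_t[[l]] <- pl$idx
      }
      bottom_t[[l]] <- below
      lay <- net$layers[[l]]
      bnB <- bn_transform(below, lay$bn_B$gamma, lay$bn_B$beta, mode,
                          bn_state_at(lay$bn_B, t))
      if (mode == "train") net$layers[[l]]$bn_B$states[[t]] <- bnB$state
      h_same <- NULL; h_above <- NULL
      bn_t[[l]] <- list(B = list(mu = bnB$mu, sd = bnB$sd))
      if (has_L && !is.null(a_prev)) {
        bnL <- bn_transform(a_prev[[l]], lay$bn_L$gamma, lay$bn_L$beta, mode,
                            bn_state_at(lay$bn_L, t))
        if (mode == "train") net$layers[[l]]$bn_L$states[[t]] <- bnL$state
        h_same <- bnL$h
        bn_t[[l]]$L <- list(mu = bnL$mu, sd = bnL$sd)
      }
      if (has_T && l < L && !is.null(a_prev)) {
        bnT <- bn_transform(a_prev[[l + 1L]], lay$bn_T$gamma, lay$bn_T$beta,
                            mode, bn_state_at(lay$bn_T, t))
        if (mode == "train") net$layers[[l]]$bn_T$states[[t]] <- bnT$state
        h_above <- bnT$h
        bn_t[[l]]$T <- list(mu = bnT$mu, sd = bnT$sd)
      }
      z <- preactivation(bnB$h, h_same, h_above, lay)
      if (keep_z) z_t[[l]] <- z
      a_t[[l]] <- relu(z)
    }
    top <- maxpool2(a_t[[L]])
    ro <- gap_softmax_readout(top$y, net$fc)
    trace$a[[t]] <- a_t
    if (keep_z) trace$z[[t]] <- z_t
    trace$bottom[[t]] <- bottom_t
    trace$pool_idx[[t]] <- pool_t
    trace$top_pool[[t]] <- list(idx = top$idx, dim = dim(a_t[[L]]),
                                pooled_dim = dim(top$y))
    trace$bn[[t]] <- bn_t
    trace$gap[[t]] <- ro$gap
    trace$logits[[t]] <- ro$logits
    trace$readouts[[t]] <- ro$yhat
    a_prev <- a_t
  }
  list(trace = trace, net = net)
}

#' Unroll a network on a single input
#'
#' Convenience wrapper around [forward_pass()] returning just the trace.
#' @inheritParams forward_pass
#' @export
unroll <- function(net, x, tau = NULL, mode = "eval", keep_z = TRUE) {
  forward_pass(net, x, tau = tau, mode = mode, keep_z = keep_z)$trace
}

#' Class predictions of a network
#'
#' @param net an `occ_network`.
#' @param x input array (H, W, C, N).
#' @param timestep `"final"` or a 1-based timestep index.
#' @return list: `labels` (0-based predicted classes, ties broken toward the
#'   lowest index), `probs` (readout matrix at the chosen step).
#' @export
predict_network <- function(net, x, timestep = "final") {
  trace <- forward_pass(net, x, mode = "eval")$trace
  t_idx <- if (identical(timestep, "final")) trace$tau else as.integer(timestep)
  probs <- trace$readouts[[t_idx]]
  list(labels = row_argmax0(probs), probs = probs)
}

#' Save a trained network checkpoint
#'
#' Weights go into an RDS container next to a JSON echo of the specification.
#' @param net an `occ_network`.
#' @param path checkpoint path (`.rds`).
#' @export
save_checkpoint <- function(net, path) {
  saveRDS(net, path)
  jsonlite::write_json(unclass(net$spec), paste0(path, ".spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path))
    occ_error("occrnn_format_error", "checkpoint not found: %s", path)
  readRDS(path)
}
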