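# Hand-written backpropagation through the unrolled computation graph.
# Gradients flow: readout -> GAP -> pre-GAP pooling -> top layer, then
# backwards over timesteps and layers; a layer's state gradient accumulates
# contributions from the bottom-up path into the layer above (same timestep),
# from the lateral stream (next timestep, same layer) and from the top-down
# stream (next timestep, layer below). Batch-norm backward matches the exact
# forward form (batch statistics in train mode).

# ---- parameter flattening ----------------------------------------------------

collect_params <- function(net) {
  out <- list()
  if (!net$spec$glm) {
    for (l in seq_along(net$layers)) {
      lay <- net$layers[[l]]
      pre <- sprintf("L%d.", l)
      out[[paste0(pre, "w_B")]] <- lay$w_B
      out[[paste0(pre, "b_B")]] <- lay$b_B
      out[[paste0(pre, "bn_B.gamma")]] <- lay$bn_B$gamma
      out[[paste0(pre, "bn_B.beta")]] <- lay$bn_B$beta
      if (!is.null(lay$w_L)) {
        out[[paste0(pre, "w_L")]] <- lay$w_L
        out[[paste0(pre, "b_L")]] <- lay$b_L
        out[[paste0(pre, "bn_L.gamma")]] <- lay$bn_L$gamma
        out[[paste0(pre, "bn_L.beta")]] <- lay$bn_L$beta
      }
      if (!is.null(lay$w_T)) {
        out[[paste0(pre, "w_T")]] <- lay$w_T
        out[[paste0(pre, "b_T")]] <- lay$b_T
        out[[paste0(pre, "bn_T.gamma")]] <- lay$bn_T$gamma
        out[[paste0(pre, "bn_T.beta")]] <- lay$bn_T$beta
      }
    }
  }
  out[["fc.W"]] <- net$fc$W
  out[["fc.b"]] <- net$fc$b
  out
}

set_params <- function(net, params) {
  if (!net$spec$glm) {
    for (l in seq_along(net$layers)) {
      pre <- sprintf("L%d.", l)
      net$layers[[l]]$w_B <- params[[paste0(pre, "w_B")]]
      net$layers[[l]]$b_B <- params[[paste0(pre, "b_B")]]
      net$layers[[l]]$bn_B$gamma <- params[[paste0(pre, "bn_B.gamma")]]
      net$layers[[l]]$bn_B$beta <- params[[paste0(pre, "bn_B.beta")]]
      if (!is.null(net$layers[[l]]$w_L)) {
        net$layers[[l]]$w_L <- params[[paste0(pre, "w_L")]]
        net$layers[[l]]$b_L <- params[[paste0(pre, "b_L")]]
        net$layers[[l]]$bn_L$gamma <- params[[paste0(pre, "bn_L.gamma")]]
        net$layers[[l]]$bn_L$beta <- params[[paste0(pre, "bn_L.beta")]]
      }
      if (!is.null(net$layers[[l]]$w_T)) {
        net$layers[[l]]$w_T <- params[[paste0(pre, "w_T")]]
        net$layers[[l]]$b_T <- params[[paste0(pre, "b_T")]]
        net$layers[[l]]$bn_T$gamma <- params[[paste0(pre, "bn_T.gamma")]]
        net$layers[[l]]$bn_T$beta <- params[[paste0(pre, "bn_T.beta")]]
      }
    }
  }
  net$fc$W <- params[["fc.W"]]
  net$fc$b <- params[["fc.b"]]
  net
}

zero_like <- function(params) lapply(params, function(p) p * 0)

# ---- loss gradients ----------------------------------------------------------

# gradient of the per-unit cross-entropy (Eq. 10 form) wrt the softmax logits,
# for one timestep; yhat are softmax rows, y one-hot rows. `weight` scales the
# contribution (batch mean, replicated feedforward steps).
logit_grad_softmax <- function(yhat, y, weight, eps = 1e-12) {
  yc <- clamp(yhat, eps, 1 - eps)
  dyhat <- weight * (-y / yc + (1 - y) / (1 - yc))
  yhat * (dyhat - rowSums(dyhat * yhat))
}

logit_grad_sigmoid <- function(yhat, y, weight, eps = 1e-12) {
  yc <- clamp(yhat, eps, 1 - eps)
  dyhat <- weight * (-y / yc + (1 - y) / (1 - yc))
  dyhat * yhat * (1 - yhat)
}

# batch-mean temporal loss of a trace (Eq. 10 summed over steps, averaged
# over the minibatch)
trace_loss <- function(trace, y_onehot, eps = 1e-12) {
  total <- 0
  for (t in seq_along(trace$readouts)) {
    yc <- clamp(trace$readouts[[t]], eps, 1 - eps)
    total <- total + sum(-(y_onehot * log(yc) + (1 - y_onehot) * log(1 - yc)))
  }
  w <- if (isTRUE(trace$replicated)) trace$tau / length(trace$readouts) else 1
  w * total / nrow(y_onehot)
}

# ---- full backward pass ------------------------------------------------------

#' Gradients of the temporal loss for one minibatch
#'
#' @param net the network used for the forward pass.
#' @param trace trace returned by [forward_pass()] on the same minibatch.
#' @param y_onehot one-hot target matrix (N x n_classes).
#' @param mode batch-norm mode used in the forward pass.
#' @return list: `grads` (flat named list parallel to `collect_params`),
#'   `loss` (batch-mean temporal loss).
#' @keywords internal
backward_pass <- function(net, trace, y_onehot, mode = c("train", "eval")) {
  mode <- match.arg(mode)
  spec <- net$spec
  N <- nrow(y_onehot)
  loss <- trace_loss(trace, y_onehot)
  grads <- zero_like(collect_params(net))

  if (spec$glm) {
    dlog <- logit_grad_sigmoid(trace$readouts[[1]], y_onehot, trace$tau / N)
    grads[["fc.W"]] <- t(trace$gap[[1]]) %*% dlog
    grads[["fc.b"]] <- colSums(dlog)
    return(list(grads = grads, loss = loss))
  }

  L <- spec$layers
  stored <- length(trace$a)
  weight <- if (isTRUE(trace$replicated)) trace$tau else 1
  has_L <- "L" %in% spec$connections
  has_T <- "T" %in% spec$connections
  bn_bwd <- if (mode == "train") bn_backward else bn_backward_eval

  # accumulated state gradients grad_a[[t]][[l]]
  ga <- vector("list", stored)
  for (t in seq_len(stored)) ga[[t]] <- vector("list", L)
  acc <- function(t, l, g) {
    ga[[t]][[l]] <<- if (is.null(ga[[t]][[l]])) g else ga[[t]][[l]] + g
  }

  # readout gradient per stored timestep
  for (t in seq_len(stored)) {
    dlog <- logit_grad_softmax(trace$readouts[[t]], y_onehot, weight / N)
    grads[["fc.W"]] <- grads[["fc.W"]] + t(trace$gap[[t]]) %*% dlog
    grads[["fc.b"]] <- grads[["fc.b"]] + colSums(dlog)
    dgap <- dlog %*% t(net$fc$W)               # N x M
    tp <- trace$top_pool[[t]]
    hp <- tp$pooled_dim[1] * tp$pooled_dim[2]
    dpool <- aperm(array(t(dgap) / hp,
                         c(tp$pooled_dim[3], tp$pooled_dim[4],
                           tp$pooled_dim[1], tp$pooled_dim[2])),
                   c(3, 4, 1, 2))
    acc(t, L, maxpool2_backward(dpool, tp$idx, tp$dim))
  }

  for (t in rev(seq_len(stored))) {
    for (l in rev(seq_len(L))) {
      g <- ga[[t]][[l]]
      if (is.null(g)) next
      a <- trace$a[[t]][[l]]
      dz <- g * (a > 0)
      lay <- net$layers[[l]]
      pre <- sprintf("L%d.", l)
      st <- trace$bn[[t]][[l]]

      # bottom-up stream
      x_in <- trace$bottom[[t]][[l]]
      hB <- bn_apply_stats(x_in, lay$bn_B$gamma, lay$bn_B$beta,
                           st$B$mu, st$B$sd)
      gB <- conv2d_backward(hB, lay$w_B, dz, same_pad(spec$kernel))
      grads[[paste0(pre, "w_B")]] <- grads[[paste0(pre, "w_B")]] + gB$dw
      grads[[paste0(pre, "b_B")]] <- grads[[paste0(pre, "b_B")]] + gB$db
      bb <- bn_bwd(x_in, gB$dx, lay$bn_B$gamma, st$B$mu, st$B$sd)
      grads[[paste0(pre, "bn_B.gamma")]] <-
        grads[[paste0(pre, "bn_B.gamma")]] + bb$dgamma
      grads[[paste0(pre, "bn_B.beta")]] <-
        grads[[paste0(pre, "bn_B.beta")]] + bb$dbeta
      if (l > 1L) {
        dprev <- maxpool2_backward(bb$da, trace$pool_idx[[t]][[l]],
                                   dim(trace$a[[t]][[l - 1L]]))
        acc(t, l - 1L, dprev)
      }

      # lateral stream reads a(t-1, l)
      if (has_L && t > 1L && !is.null(st$L)) {
        x_lat <- trace$a[[t - 1L]][[l]]
        hL <- bn_apply_stats(x_lat, lay$bn_L$gamma, lay$bn_L$beta,
                             st$L$mu, st$L$sd)
        gL <- conv2d_backward(hL, lay$w_L, dz, same_pad(spec$kernel))
        grads[[paste0(pre, "w_L")]] <- grads[[paste0(pre, "w_L")]] + gL$dw
        grads[[paste0(pre, "b_L")]] <- grads[[paste0(pre, "b_L")]] + gL$db
        bl <- bn_bwd(x_lat, gL$dx, lay$bn_L$gamma, st$L$mu, st$L$sd)
        grads[[paste0(pre, "bn_L.gamma")]] <-
          grads[[paste0(pre, "bn_L.gamma")]] + bl$dgamma
        grads[[paste0(pre, "bn_L.beta")]] <-
          grads[[paste0(pre, "bn_L.beta")]] + bl$dbeta
        acc(t - 1L, l, bl$da)
      }

      # top-down stream reads a(t-1, l+1)
      if (has_T && l < L && t > 1L && !is.null(st$T)) {
        x_td <- trace$a[[t - 1L]][[l + 1L]]
        hT <- bn_apply_stats(x_td, lay$bn_T$gamma, lay$bn_T$beta,
                             st$T$mu, st$T$sd)
        gT <- conv_transpose2d_backward(hT, lay$w_T, dz)
        grads[[paste0(pre, "w_T")]] <- grads[[paste0(pre, "w_T")]] + gT$dw
        grads[[paste0(pre, "b_T")]] <- grads[[paste0(pre, "b_T")]] + gT$db
        bt <- bn_bwd(x_td, gT$dx, lay$bn_T$gamma, st$T$mu, st$T$sd)
        grads[[paste0(pre, "bn_T.gamma")]] <-
          grads[[paste0(pre, "bn_T.gamma")]] + bt$dgamma
        grads[[paste0(pre, "bn_T.beta")]] <-
          grads[[paste0(pre, "bn_T.beta")]] + bt$dbeta
        acc(t - 1L, l + 1L, bt$da)
      }
    }
  }
  list(grads = grads, loss = loss)
}
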