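# Independent reference implementations used as test oracles. These are
# deliberately written as plain per-pixel loops, sharing no code with the
# package's vectorized/compiled path.

# direct per-pixel stride-1 convolution with zero padding
ref_conv <- function(x, w, b, pad_before, pad_after = pad_before) {
  d <- dim(x); k <- dim(w)[1]; cout <- dim(w)[4]
  Ho <- d[1] + pad_before + pad_after - k + 1
  Wo <- d[2] + pad_before + pad_after - k + 1
  out <- array(0, c(Ho, Wo, cout, d[4]))
  for (n in seq_len(d[4])) for (co in seq_len(cout))
    for (i in seq_len(Ho)) for (j in seq_len(Wo)) {
      s <- b[co]
      for (ki in seq_len(k)) for (kj in seq_len(k)) for (c in seq_len(d[3])) {
        ii <- i + ki - 1 - pad_before; jj <- j + kj - 1 - pad_before
        if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2])
          s <- s + x[ii, jj, c, n] * w[ki, kj, c, co]
      }
      out[i, j, co, n] <- s
    }
  out
}

# transposed stride-2 conv as used for the top-down stream: zero-stuff, pad
# (1 before, 2 after), convolve with the spatially flipped kernel
ref_conv_transpose <- function(x, w, b) {
  d <- dim(x); k <- dim(w)[1]
  xs <- array(0, c(2 * d[1] - 1 + 3, 2 * d[2] - 1 + 3, d[3], d[4]))
  xs[1 + seq(1, 2 * d[1] - 1, 2), 1 + seq(1, 2 * d[2] - 1, 2), , ] <- x
  wf <- w[k:1, k:1, , , drop = FALSE]
  ref_conv(xs, wf, b, pad_before = 0, pad_after = 0)
}

ref_pool <- function(x) {
  d <- dim(x)
  out <- array(0, c(d[1] / 2, d[2] / 2, d[3], d[4]))
  for (n in seq_len(d[4])) for (c in seq_len(d[3]))
    for (i in seq_len(d[1] / 2)) for (j in seq_len(d[2] / 2))
      out[i, j, c, n] <- max(x[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), c, n])
  out
}

# batch norm with batch statistics: per map over (H, W, N), biased SD,
# eps added to the SD
ref_bn <- function(a, gamma, beta, eps = 1e-5) {
  d <- dim(a)
  out <- a
  for (c in seq_len(d[3])) {
    v <- a[, , c, , drop = FALSE]
    mu <- mean(v)
    sdv <- sqrt(mean((v - mu)^2))
    out[, , c, ] <- gamma[c] * (v - mu) / (sdv + eps) + beta[c]
  }
  out
}

ref_softmax <- function(z) exp(z) / sum(exp(z))

# full reference forward pass of a (possibly recurrent) two-stream network,
# evaluated step by step with batch statistics; recurrent inputs are zero
# tensors at the first step and contribute nothing there.
ref_forward <- function(net, x, tau) {
  spec <- net$spec
  L <- spec$layers
  pad <- (spec$kernel - 1) %/% 2
  a_prev <- NULL
  readouts <- vector("list", tau)
  states <- vector("list", tau)
  for (t in seq_len(tau)) {
    a_t <- vector("list", L)
    for (l in seq_len(L)) {
      lay <- net$layers[[l]]
      below <- if (l == 1) x else ref_pool(a_t[[l - 1]])
      z <- ref_conv(ref_bn(below, lay$bn_B$gamma, lay$bn_B$beta),
                    lay$w_B, lay$b_B, pad)
      if (!is.null(lay$w_L) && t > 1)
        z <- z + ref_conv(ref_bn(a_prev[[l]], lay$bn_L$gamma, lay$bn_L$beta),
                          lay$w_L, lay$b_L, pad)
      if (!is.null(lay$w_T) && l < L && t > 1)
        z <- z + ref_conv_transpose(
          ref_bn(a_prev[[l + 1]], lay$bn_T$gamma, lay$bn_T$beta),
          lay$w_T, lay$b_T)
      a_t[[l]] <- pmax(z, 0)
    }
    top <- ref_pool(a_t[[L]])
    d <- dim(top)
    yh <- matrix(0, d[4], ncol(net$fc$W))
    for (n in seq_len(d[4])) {
      g <- vapply(seq_len(d[3]), function(m) mean(top[, , m, n]), 0)
      yh[n, ] <- ref_softmax(as.numeric(g %*% net$fc$W) + net$fc$b)
    }
    readouts[[t]] <- yh
    states[[t]] <- a_t
    a_prev <- a_t
  }
  list(readouts = readouts, states = states)
}

# exhaustive two-sample KS statistic from first principles
ref_ks_D <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(vapply(pts, function(p) abs(mean(x <= p) - mean(y <= p)), 0))
}

# Gini coefficient by direct evaluation of the sorted-index formula
ref_gini <- function(x) {
  x <- sort(as.numeric(x))
  n <- length(x)
  sum((2 * seq_len(n) - n - 1) * x) / (n * sum(x))
}
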