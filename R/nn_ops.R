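# Tensor primitives used by the network family. All image tensors are
# column-major R arrays with dim (H, W, C, N); kernels are (k, k, Cin, Cout).
# Convolutions are stride-1 "same" convolutions; downsampling happens only in
# the 2x2/2x2 max-pooling between layers, and upsampling only in the stride-2
# transposed convolution of the top-down stream.

as_nchw <- function(x) {
  d <- dim(x)
  if (is.null(d)) occ_error("occrnn_shape_error", "expected an array input")
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == 3L) dim(x) <- c(d, 1L)
  else if (length(d) != 4L) occ_error("occrnn_shape_error", "expected 2-4 dim array")
  x
}

# same-size padding: odd kernels pad (k-1)/2 on each side; even kernels pad
# floor((k-1)/2) before and ceil((k-1)/2) after (6x6 -> 2 before, 3 after).
same_pad <- function(k) {
  before <- (k - 1L) %/% 2L
  after <- k - 1L - before
  c(before, after, before, after)
}

#' Stride-1 2D convolution (cross-correlation) with explicit zero padding
#' @param x input array (H, W, Cin, N).
#' @param w kernel array (k, k, Cin, Cout).
#' @param b bias vector of length Cout.
#' @param pad integer vector (top, bottom, left, right) or a single value.
#' @return array (Ho, Wo, Cout, N).
#' @keywords internal
conv2d <- function(x, w, b = NULL, pad = same_pad(dim(w)[1])) {
  x <- as_nchw(x)
  if (length(pad) == 1L) pad <- rep(pad, 4L)
  if (is.null(b)) b <- numeric(dim(w)[4])
  if (dim(x)[3] != dim(w)[3])
    occ_error("occrnn_shape_error", "conv2d: %d input channels vs kernel %d",
              dim(x)[3], dim(w)[3])
  cpp_conv2d_fwd(x, dim(x), w, dim(w), b, as.integer(pad))
}

conv2d_backward <- function(x, w, dz, pad = same_pad(dim(w)[1]), need_dx = TRUE) {
  x <- as_nchw(x)
  if (length(pad) == 1L) pad <- rep(pad, 4L)
  cpp_conv2d_bwd(x, dim(x), w, dim(w), dz, as.integer(pad), need_dx)
}

flip_kernel <- function(w) {
  k <- dim(w)[1]
  w[k:1, k:1, , , drop = FALSE]
}

# zero-stuffing used by the stride-2 transposed convolution
zero_stuff2 <- function(x) {
  d <- dim(x)
  out <- array(0, c(2L * d[1] - 1L, 2L * d[2] - 1L, d[3], d[4]))
  out[seq(1L, 2L * d[1] - 1L, 2L), seq(1L, 2L * d[2] - 1L, 2L), , ] <- x
  out
}

#' Transposed 2D convolution, kernel 3, stride 2 (exact x2 upsampling)
#'
#' Implemented as the adjoint of a stride-2 convolution: the input is
#' zero-stuffed, padded (1 before, 2 after), and convolved with the spatially
#' flipped kernel, which maps (h, w) to exactly (2h, 2w).
#' @param x input array (H, W, Cin, N) (the layer-above state).
#' @param w kernel array (3, 3, Cin, Cout).
#' @param b bias vector length Cout.
#' @keywords internal
conv_transpose2d <- function(x, w, b = NULL) {
  xs <- zero_stuff2(as_nchw(x))
  conv2d(xs, flip_kernel(w), b, pad = c(1L, 2L, 1L, 2L))
}

conv_transpose2d_backward <- function(x, w, dz) {
  xs <- zero_stuff2(as_nchw(x))
  g <- conv2d_backward(xs, flip_kernel(w), dz, pad = c(1L, 2L, 1L, 2L))
  d <- dim(as_nchw(x))
  dxs <- g$dx
  dx <- dxs[seq(1L, 2L * d[1] - 1L, 2L), seq(1L, 2L * d[2] - 1L, 2L), , ,
            drop = FALSE]
  dim(dx) <- d
  list(dw = flip_kernel(g$dw), db = g$db, dx = dx)
}

#' 2x2 max pooling with stride 2
#' @param x array (H, W, C, N) with even spatial dims.
#' @return list with pooled array `y` and argmax index vector `idx` for the
#'   backward pass.
#' @keywords internal
maxpool2 <- function(x) {
  x <- as_nchw(x)
  cpp_maxpool_fwd(x, dim(x))
}

maxpool2_backward <- function(dy, idx, xdim) {
  cpp_maxpool_bwd(dy, idx, as.integer(xdim))
}

relu <- function(z) {
  z[z < 0] <- 0
  z
}

#' Batch normalization of a stream input
#'
#' Normalizes each feature map using the minibatch mean and standard
#' deviation: `h = gamma * (a - mu) / (sd + eps) + beta`, with `eps` added to
#' the standard deviation (not the variance). Statistics are computed over the
#' spatial positions and the batch. In `"train"` mode batch statistics are
#' used and exponentially smoothed running statistics are updated; `"eval"`
#' mode applies the stored running statistics.
#'
#' @param a input: array (H, W, C, N) or a plain numeric vector (treated as a
#'   single-map batch).
#' @param gamma,beta per-map scale and shift (learnable).
#' @param mode `"train"` or `"eval"`.
#' @param state list with running `mean` and `sd` per map (NULL starts at
#'   mean 0, sd 1).
#' @param eps numeric guard added to the batch standard deviation.
#' @param momentum running-statistics update weight.
#' @return list: `h` (normalized output, same shape as `a`), `state` (updated
#'   running statistics), `mu`, `sd` (statistics used; needed for backward).
#' @export
bn_transform <- function(a, gamma, beta, mode = c("train", "eval"),
                         state = NULL, eps = 1e-5, momentum = 0.1) {
  mode <- match.arg(mode)
  vec_in <- is.null(dim(a))
  if (vec_in) a <- array(a, c(1L, 1L, 1L, length(a)))
  a <- as_nchw(a)
  d <- dim(a)
  C <- d[3]
  if (length(gamma) != C || length(beta) != C)
    occ_error("occrnn_shape_error", "bn: gamma/beta length %d, %d maps",
              length(gamma), C)
  if (is.null(state)) state <- list(mean = numeric(C), sd = rep(1, C))
  if (mode == "train") {
    if (d[4] < 2L)
      occ_error("occrnn_config_error", "bn: train mode needs batch size >= 2")
    st <- cpp_bn_stats(a, d)
    mu <- st$mu
    sdv <- st$sd
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$sd <- (1 - momentum) * state$sd + momentum * sdv
  } else {
    mu <- state$mean
    sdv <- state$sd
  }
  scale <- gamma / (sdv + eps)
  shift <- beta - mu * scale
  h <- cpp_channel_affine(a, d, scale, shift)
  if (vec_in) h <- as.numeric(h)
  list(h = h, state = state, mu = mu, sd = sdv)
}

# exact backward for bn_transform in train mode (batch statistics).
# dh: upstream gradient, same shape as a. With s = sd + eps and
# xhat = (a - mu)/s:
#   da = (gamma/s) * (g - mean(g) - xhat * (s/sd) * mean(g * xhat))
# which is a channel-wise affine combination of g and a; the d/d(sd) term
# vanishes where the batch is constant (sd == 0).
bn_backward <- function(a, dh, gamma, mu, sdv, eps = 1e-5) {
  a <- as_nchw(a)
  d <- dim(a)
  m <- d[1] * d[2] * d[4]
  g <- as_nchw(dh)
  s <- sdv + eps
  sums <- cpp_bn_bwd_sums(a, g, d)
  gbar <- sums$sg / m
  gxhat_sum <- (sums$sgx - mu * sums$sg) / s
  gxhat_bar <- gxhat_sum / m
  ratio <- ifelse(sdv > 0, s / sdv, 0)
  G <- gamma / s
  K <- ratio * gxhat_bar
  A <- G
  B <- -G * K / s
  D <- G * (mu * K / s - gbar)
  da <- cpp_bn_bwd_combine(a, g, d, A, B, D)
  list(da = da, dgamma = gxhat_sum, dbeta = sums$sg)
}

# eval-mode bn is an affine map per channel; backward is linear
bn_backward_eval <- function(a, dh, gamma, mu, sdv, eps = 1e-5) {
  a <- as_nchw(a)
  d <- dim(a)
  g <- as_nchw(dh)
  s <- sdv + eps
  sums <- cpp_bn_bwd_sums(a, g, d)
  gxhat_sum <- (sums$sgx - mu * sums$sg) / s
  da <- cpp_channel_affine(g, d, gamma / s, numeric(d[3]))
  list(da = da, dgamma = gxhat_sum, dbeta = sums$sg)
}

bn_apply_stats <- function(a, gamma, beta, mu, sdv, eps = 1e-5) {
  a <- as_nchw(a)
  scale <- gamma / (sdv + eps)
  shift <- beta - mu * scale
  cpp_channel_affine(a, dim(a), scale, shift)
}

softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Global average pooling followed by the softmax readout
#'
#' Computes the spatial mean of each feature map, applies the fully connected
#' readout and the softmax, so that each row of the result is a probability
#' distribution over classes.
#'
#' @param a_top top-layer feature maps, array (h, w, M, N).
#' @param fc list with `W` (M x n_classes) and `b` (length n_classes).
#' @return list: `gap` (N x M pooled features), `logits`, `yhat` (N x
#'   n_classes softmax rows).
#' @export
gap_softmax_readout <- function(a_top, fc) {
  a_top <- as_nchw(a_top)
  d <- dim(a_top)
  ax <- aperm(a_top, c(1, 2, 4, 3))
  dim(ax) <- c(d[1] * d[2], d[4] * d[3])
  g <- colMeans(ax)                 # (N*M)
  gap <- matrix(g, nrow = d[4], ncol = d[3])  # N x M
  logits <- gap %*% fc$W + matrix(fc$b, d[4], length(fc$b), byrow = TRUE)
  list(gap = gap, logits = logits, yhat = softmax_rows(logits))
}

# bilinear resize of a single-channel image (used for glyph scaling and CAM
# upsampling); samples at pixel centers, clamped at the borders.
resize_bilinear <- function(img, out_h, out_w) {
  in_h <- nrow(img); in_w <- ncol(img)
  if (out_h == in_h && out_w == in_w) return(img)
  sy <- in_h / out_h; sx <- in_w / out_w
  yc <- clamp((seq_len(out_h) - 0.5) * sy - 0.5, 0, in_h - 1)
  xc <- clamp((seq_len(out_w) - 0.5) * sx - 0.5, 0, in_w - 1)
  y0 <- pmin(floor(yc), in_h - 1); y1 <- pmin(y0 + 1, in_h - 1)
  x0 <- pmin(floor(xc), in_w - 1); x1 <- pmin(x0 + 1, in_w - 1)
  wy <- yc - y0; wx <- xc - x0
  a00 <- img[y0 + 1, x0 + 1, drop = FALSE]
  a01 <- img[y0 + 1, x1 + 1, drop = FALSE]
  a10 <- img[y1 + 1, x0 + 1, drop = FALSE]
  a11 <- img[y1 + 1, x1 + 1, drop = FALSE]
  wyM <- matrix(wy, out_h, out_w)
  wxM <- matrix(wx, out_h, out_w, byrow = TRUE)
  a00 * (1 - wyM) * (1 - wxM) + a01 * (1 - wyM) * wxM +
    a10 * wyM * (1 - wxM) + a11 * wyM * wxM
}
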