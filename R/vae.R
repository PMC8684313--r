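# A small dense variational autoencoder used to build smooth class-to-class
# image morphs: symmetric encoder/decoder with two hidden layers (default
# 784-500-500, latent size 20), Bernoulli reconstruction loss plus KL, Adam.

#' Build a dense variational autoencoder
#'
#' @param input_dim flattened image dimension (784 for 28x28).
#' @param hidden sizes of the two hidden layers (default 500, 500).
#' @param latent latent code size (default 20).
#' @param seed weight-initialization seed.
#' @return object of class `occ_vae`.
#' @export
vae_build <- function(input_dim = 784L, hidden = c(500L, 500L), latent = 20L,
                      seed = 1L) {
  dense <- function(nin, nout) {
    b <- 1 / sqrt(nin)
    list(W = matrix(runif(nin * nout, -b, b), nin, nout), b = numeric(nout))
  }
  with_seed(seed, {
    p <- list(
      enc1 = dense(input_dim, hidden[1]),
      enc2 = dense(hidden[1], hidden[2]),
      mu = dense(hidden[2], latent),
      lv = dense(hidden[2], latent),
      dec1 = dense(latent, hidden[2]),
      dec2 = dense(hidden[2], hidden[1]),
      out = dense(hidden[1], input_dim)
    )
  })
  structure(list(params = p, input_dim = as.integer(input_dim),
                 hidden = as.integer(hidden), latent = as.integer(latent)),
            class = "occ_vae")
}

vae_affine <- function(x, layer) {
  x %*% layer$W + matrix(layer$b, nrow(x), length(layer$b), byrow = TRUE)
}

vae_forward <- function(vae, x, epsn = NULL) {
  p <- vae$params
  h1 <- relu(vae_affine(x, p$enc1))
  h2 <- relu(vae_affine(h1, p$enc2))
  mu <- vae_affine(h2, p$mu)
  lv <- vae_affine(h2, p$lv)
  if (is.null(epsn)) epsn <- matrix(0, nrow(x), ncol(mu))
  z <- mu + exp(lv / 2) * epsn
  d1 <- relu(vae_affine(z, p$dec1))
  d2 <- relu(vae_affine(d1, p$dec2))
  xhat <- sigmoid(vae_affine(d2, p$out))
  list(h1 = h1, h2 = h2, mu = mu, lv = lv, eps = epsn, z = z,
       d1 = d1, d2 = d2, xhat = xhat)
}

vae_loss_value <- function(x, fw, eps = 1e-12) {
  xh <- clamp(fw$xhat, eps, 1 - eps)
  bce <- -sum(x * log(xh) + (1 - x) * log(1 - xh))
  kl <- -0.5 * sum(1 + fw$lv - fw$mu^2 - exp(fw$lv))
  (bce + kl) / nrow(x)
}

vae_backward <- function(vae, x, fw) {
  p <- vae$params
  n <- nrow(x)
  g <- list()
  dense_bwd <- function(xin, dout, layer, act = NULL) {
    list(dW = t(xin) %*% dout, db = colSums(dout), dx = dout %*% t(layer$W))
  }
  dlog_out <- (fw$xhat - x) / n
  go <- dense_bwd(fw$d2, dlog_out, p$out)
  g$out <- go[c("dW", "db")]
  dd2 <- go$dx * (fw$d2 > 0)
  g2 <- dense_bwd(fw$d1, dd2, p$dec2)
  g$dec2 <- g2[c("dW", "db")]
  dd1 <- g2$dx * (fw$d1 > 0)
  g1 <- dense_bwd(fw$z, dd1, p$dec1)
  g$dec1 <- g1[c("dW", "db")]
  dz <- g1$dx
  dmu <- dz + fw$mu / n
  dlv <- dz * fw$eps * 0.5 * exp(fw$lv / 2) + 0.5 * (exp(fw$lv) - 1) / n
  gm <- dense_bwd(fw$h2, dmu, p$mu)
  gl <- dense_bwd(fw$h2, dlv, p$lv)
  g$mu <- gm[c("dW", "db")]
  g$lv <- gl[c("dW", "db")]
  dh2 <- (gm$dx + gl$dx) * (fw$h2 > 0)
  ge2 <- dense_bwd(fw$h1, dh2, p$enc2)
  g$enc2 <- ge2[c("dW", "db")]
  dh1 <- ge2$dx * (fw$h1 > 0)
  ge1 <- dense_bwd(x, dh1, p$enc1)
  g$enc1 <- ge1[c("dW", "db")]
  g
}

#' Train a variational autoencoder
#'
#' Adam on the Bernoulli reconstruction loss plus KL divergence; defaults
#' follow the morphing setup (batch 128, learning rate 1e-3).
#'
#' @param vae an `occ_vae`.
#' @param x training matrix (N x input_dim), intensities in \[0, 1\].
#' @param epochs training epochs (100 at full scale; tests scale down).
#' @param batch minibatch size.
#' @param lr learning rate.
#' @param seed seed for shuffling and the reparameterization noise.
#' @return list: `vae` (trained), `history` (per-epoch mean loss).
#' @export
vae_train <- function(vae, x, epochs = 100L, batch = 128L, lr = 1e-3,
                      seed = 1L) {
  n <- nrow(x)
  m <- rapply(vae$params, function(p) p * 0, how = "replace")
  v <- m
  step <- 0
  hist <- numeric(epochs)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; nb <- 0
      for (s in seq(1, n, by = batch)) {
        idx <- ord[s:min(s + batch - 1, n)]
        xb <- x[idx, , drop = FALSE]
        epsn <- matrix(rnorm(length(idx) * vae$latent), length(idx))
        fw <- vae_forward(vae, xb, epsn)
        loss <- vae_loss_value(xb, fw)
        if (!is.finite(loss))
          occ_error("occrnn_divergence", "VAE loss diverged at epoch %d", ep)
        g <- vae_backward(vae, xb, fw)
        step <- step + 1
        for (lname in names(vae$params)) {
          for (pn in c("W", "b")) {
            gn <- if (pn == "W") "dW" else "db"
            grad <- g[[lname]][[gn]]
            m[[lname]][[pn]] <- 0.9 * m[[lname]][[pn]] + 0.1 * grad
            v[[lname]][[pn]] <- 0.999 * v[[lname]][[pn]] + 0.001 * grad^2
            mh <- m[[lname]][[pn]] / (1 - 0.9^step)
            vh <- v[[lname]][[pn]] / (1 - 0.999^step)
            vae$params[[lname]][[pn]] <- vae$params[[lname]][[pn]] -
              lr * mh / (sqrt(vh) + 1e-8)
          }
        }
        ep_loss <- ep_loss + loss; nb <- nb + 1
      }
      hist[ep] <- ep_loss / max(nb, 1)
    }
  })
  list(vae = vae, history = hist)
}

#' Encode images to latent means
#' @param vae a trained `occ_vae`.
#' @param x matrix (N x input_dim).
#' @return matrix (N x latent) of posterior means.
#' @export
vae_encode <- function(vae, x) {
  p <- vae$params
  h1 <- relu(vae_affine(x, p$enc1))
  h2 <- relu(vae_affine(h1, p$enc2))
  vae_affine(h2, p$mu)
}

#' Decode latent codes to images
#' @param vae a trained `occ_vae`.
#' @param z matrix (N x latent).
#' @return matrix (N x input_dim) with values in (0, 1).
#' @export
vae_decode <- function(vae, z) {
  p <- vae$params
  d1 <- relu(vae_affine(z, p$dec1))
  d2 <- relu(vae_affine(d1, p$dec2))
  sigmoid(vae_affine(d2, p$out))
}
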