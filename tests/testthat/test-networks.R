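# Network family: parameter counting, batch norm, preactivations, readout,
# unrolling, and exact reductions between recurrent and feedforward paths.

test_that("closed-form parameter identities hold across the family", {
  for (ch in c(1L, 2L, 3L, 6L)) for (ncls in c(10L, 79L)) {
    b <- count_learnable_parameters(arch_spec("B", ch, ncls))
    k <- 3L; m <- 32L
    expect_equal(b, k^2 * ch * m + m + k^2 * m^2 + m + m * ncls + ncls)
    expect_equal(count_learnable_parameters(arch_spec("BL", ch, ncls)),
                 b + 2L * (k^2 * m^2 + m))
    expect_equal(count_learnable_parameters(arch_spec("BT", ch, ncls)),
                 b + (k^2 * m^2 + m))
    expect_equal(count_learnable_parameters(arch_spec("BLT", ch, ncls)),
                 b + 3L * (k^2 * m^2 + m))
    expect_equal(count_learnable_parameters(arch_spec("GLM", ch, ncls)),
                 32L * 32L * ch * ncls + ncls)
  }
  # batch-norm parameters are counted only on demand
  sp <- arch_spec("BLT", 1L, 10L)
  expect_equal(count_learnable_parameters(sp, include_bn = TRUE) -
                 count_learnable_parameters(sp),
               2L * (1L + 32L) + 2L * 2L * 32L +   # bn on B streams + L streams
                 2L * 32L)                          # bn on the T stream
})

test_that("built networks expose exactly the counted parameters", {
  for (nm in c("B", "B-K", "B-D", "BT", "BL", "BLT", "GLM")) {
    spec <- arch_spec(nm, in_channels = 2L, n_classes = 10L)
    net <- build_network(spec, seed = 1)
    p <- occrnn:::collect_params(net)
    n_no_bn <- sum(lengths(p[!grepl("bn_", names(p))]))
    expect_equal(n_no_bn, count_learnable_parameters(spec), info = nm)
    expect_equal(sum(lengths(p)),
                 count_learnable_parameters(spec, include_bn = TRUE),
                 info = nm)
  }
})

test_that("bn_transform normalizes with batch statistics and eps on the SD", {
  set.seed(10)
  a <- array(rnorm(4 * 4 * 3 * 8, mean = 2, sd = 3), c(4, 4, 3, 8))
  out <- bn_transform(a, gamma = rep(1, 3), beta = rep(0, 3), mode = "train")
  for (c in 1:3) {
    v <- out$h[, , c, ]
    expect_equal(mean(v), 0, tolerance = 1e-10)
    expect_equal(sd(v) * sqrt(length(v) - 1) / sqrt(length(v)), 1,
                 tolerance = 1e-3)  # biased SD, eps-deflated
  }

  # constant batch: sd -> 0 guarded by eps, output ~ beta
  cst <- bn_transform(array(5, c(2, 2, 1, 4)), 1, 0.7, mode = "train")
  expect_equal(as.numeric(cst$h), rep(0.7, 16))

  # two-number closed form: batch {0, 2}, gamma 2, beta 1
  two <- bn_transform(c(0, 2), gamma = 2, beta = 1, mode = "train")
  expect_equal(two$h, c(2 * (0 - 1) / (1 + 1e-5) + 1,
                        2 * (2 - 1) / (1 + 1e-5) + 1))

  expect_error(bn_transform(array(1, c(2, 2, 1, 1)), 1, 0, mode = "train"),
               class = "occrnn_config_error")

  # eval mode applies stored running statistics
  ev <- bn_transform(c(0, 2), gamma = 1, beta = 0, mode = "eval",
                     state = list(mean = 1, sd = 2))
  expect_equal(ev$h, c((0 - 1) / (2 + 1e-5), (2 - 1) / (2 + 1e-5)))
})

test_that("preactivation combines streams per the layer equations", {
  w0 <- array(0, c(3, 3, 1, 1))
  x <- array(runif(16), c(4, 4, 1, 1))
  z <- preactivation(x, weights = list(w_B = w0, b_B = 0.25))
  expect_equal(as.numeric(z), rep(0.25, 16))   # zero weights -> bias

  # single pixel, 1x1 kernels: w_B h_below + w_L h_same + b = 3.6
  w_b <- array(1, c(1, 1, 1, 1)); w_l <- array(0.5, c(1, 1, 1, 1))
  z1 <- preactivation(array(2, c(1, 1, 1, 1)),
                      h_same_prev = array(3, c(1, 1, 1, 1)),
                      weights = list(w_B = w_b, b_B = 0.1, w_L = w_l, b_L = 0))
  expect_equal(as.numeric(z1), 3.6)

  # zero recurrent state (NULL) leaves only the bottom-up term + bias
  z0 <- preactivation(array(2, c(1, 1, 1, 1)),
                      weights = list(w_B = w_b, b_B = 0.1, w_L = w_l, b_L = 9))
  expect_equal(as.numeric(z0), 2.1)

  expect_error(preactivation(x, h_same_prev = x, weights = list(w_B = w0, b_B = 0)),
               class = "occrnn_shape_error")
})

test_that("GAP/softmax readout produces normalized class distributions", {
  set.seed(11)
  a <- array(rnorm(8 * 8 * 4 * 5), c(8, 8, 4, 5))
  fc <- list(W = matrix(rnorm(4 * 3), 4, 3), b = rnorm(3))
  ro <- gap_softmax_readout(a, fc)
  expect_equal(rowSums(ro$yhat), rep(1, 5))
  expect_equal(ro$gap[2, 3], mean(a[, , 3, 2]))

  # equal logits -> uniform; logits (0, ln 2) -> (1/3, 2/3)
  a1 <- array(c(0, log(2)), c(1, 1, 2, 1))
  ro1 <- gap_softmax_readout(a1, list(W = diag(2), b = c(0, 0)))
  expect_equal(as.numeric(ro1$yhat), c(1 / 3, 2 / 3))
  ro2 <- gap_softmax_readout(array(1, c(2, 2, 3, 1)),
                             list(W = matrix(1, 3, 4), b = rep(0, 4)))
  expect_equal(as.numeric(ro2$yhat), rep(0.25, 4))
})

test_that("feedforward nets are time-invariant; recurrent nets reduce exactly", {
  set.seed(12)
  x <- array(runif(8 * 8 * 1 * 3), c(8, 8, 1, 3))
  specB <- network_spec("B", maps = 4, in_channels = 1, n_classes = 5,
                        tau = 4, canvas = c(8, 8))
  netB <- build_network(specB, seed = 20)
  specR <- network_spec(c("B", "L", "T"), maps = 4, in_channels = 1,
                        n_classes = 5, tau = 4, canvas = c(8, 8))
  netR <- build_network(specR, seed = 21)
  # share bottom-up weights and readout with the feedforward control
  for (l in 1:2) {
    netB$layers[[l]]$w_B <- netR$layers[[l]]$w_B
    netB$layers[[l]]$b_B <- netR$layers[[l]]$b_B
  }
  netB$fc <- netR$fc
  trB <- forward_pass(netB, x)$trace
  for (t in 2:4) expect_identical(trB$readouts[[t]], trB$readouts[[1]])

  # tau = 1: recurrent terms vanish at the first step
  tr1 <- forward_pass(netR, x, tau = 1)$trace
  trB1 <- forward_pass(netB, x, tau = 1)$trace
  expect_equal(tr1$readouts[[1]], trB1$readouts[[1]], tolerance = 1e-12)

  # zeroed recurrent weights and biases: all steps equal the feedforward pass
  netR0 <- netR
  for (l in 1:2) {
    if (!is.null(netR0$layers[[l]]$w_L)) {
      netR0$layers[[l]]$w_L[] <- 0; netR0$layers[[l]]$b_L[] <- 0
    }
    if (!is.null(netR0$layers[[l]]$w_T)) {
      netR0$layers[[l]]$w_T[] <- 0; netR0$layers[[l]]$b_T[] <- 0
    }
  }
  tr0 <- forward_pass(netR0, x, tau = 4)$trace
  for (t in 1:4)
    expect_equal(tr0$readouts[[t]], trB$readouts[[1]], tolerance = 1e-12)
})

test_that("forward pass matches the per-pixel reference evaluation", {
  set.seed(13)
  x <- array(runif(4 * 4 * 1 * 3), c(4, 4, 1, 3))
  spec <- network_spec(c("B", "L", "T"), maps = 2, in_channels = 1,
                       n_classes = 3, tau = 3, canvas = c(4, 4))
  net <- build_network(spec, seed = 30)
  got <- forward_pass(net, x, mode = "train", keep_z = TRUE)$trace
  want <- ref_forward(net, x, tau = 3)
  for (t in 1:3) {
    expect_equal(got$readouts[[t]], want$readouts[[t]], tolerance = 1e-6)
    for (l in 1:2)
      expect_equal(got$a[[t]][[l]], want$states[[t]][[l]], tolerance = 1e-6)
  }
  # readouts are probability vectors at every step
  for (t in 1:3) expect_equal(rowSums(got$readouts[[t]]), rep(1, 3))
})

test_that("spatial contract: lateral preserves, top-down upsamples exactly", {
  spec <- network_spec(c("B", "L", "T"), maps = 3, in_channels = 1,
                       n_classes = 4, tau = 2, canvas = c(8, 8))
  net <- build_network(spec, seed = 31)
  tr <- forward_pass(net, array(runif(64), c(8, 8, 1, 2)))$trace
  expect_equal(dim(tr$a[[1]][[1]])[1:2], c(8, 8))   # layer 1 native
  expect_equal(dim(tr$a[[1]][[2]])[1:2], c(4, 4))   # layer 2 after pooling
  # transposed conv: layer-2 resolution -> layer-1 resolution
  up <- occrnn:::conv_transpose2d(tr$a[[1]][[2]], net$layers[[1]]$w_T,
                                  net$layers[[1]]$b_T)
  expect_equal(dim(up)[1:2], c(8, 8))
})

test_that("GLM builds a single sigmoid layer on the flattened image", {
  spec <- arch_spec("GLM", in_channels = 2, n_classes = 10, canvas = c(16, 16))
  net <- build_network(spec, seed = 32)
  x <- array(runif(16 * 16 * 2 * 3), c(16, 16, 2, 3))
  tr <- forward_pass(net, x)$trace
  expect_equal(dim(tr$readouts[[1]]), c(3, 10))
  expect_true(all(tr$readouts[[1]] > 0 & tr$readouts[[1]] < 1))
  xf <- matrix(x, ncol = 3)
  manual <- 1 / (1 + exp(-(t(xf) %*% net$fc$W +
                             matrix(net$fc$b, 3, 10, byrow = TRUE))))
  expect_equal(tr$readouts[[1]], manual, tolerance = 1e-12)
})

test_that("checkpoints round-trip and invalid specs are rejected", {
  spec <- network_spec("B", maps = 2, in_channels = 1, n_classes = 3,
                       canvas = c(8, 8))
  net <- build_network(spec, seed = 33)
  tmp <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(net, tmp)
  back <- load_checkpoint(tmp)
  expect_equal(occrnn:::collect_params(back), occrnn:::collect_params(net))
  expect_true(file.exists(paste0(tmp, ".spec.json")))
  expect_error(load_checkpoint("no/such/file.rds"),
               class = "occrnn_format_error")
  expect_error(network_spec("T", layers = 1), class = "occrnn_config_error")
  expect_error(network_spec("B", tau = 0), class = "occrnn_config_error")
  expect_error(arch_spec("nope"), class = "occrnn_config_error")
})
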