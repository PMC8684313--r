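# Hysteresis: morph construction, sequence runs with persistent state,
# boundary/width arithmetic, bistability, and width statistics.

make_run <- function(pred, class_a, class_b, direction) {
  # endpoint probabilities consistent with the restricted predictions
  pb <- ifelse(pred == class_b, 0.9, 0.1)
  structure(list(direction = direction, predicted = pred,
                 endpoint_probs = cbind(1 - pb, pb),
                 class_a = class_a, class_b = class_b, length = length(pred)),
            class = "sequence_run")
}

test_that("blended morphs: 45 series, exact endpoints, exact cross-fade", {
  corpus <- generate_synthetic_glyphs(8, seed = 27, size = 16)
  series <- blended_morphs(corpus)
  expect_equal(length(series), choose(10, 2))  # 45 transitions

  # independent prototype computation: nearest sample to the class centroid
  proto <- function(cls) {
    idx <- which(corpus$labels == cls)
    flat <- matrix(corpus$bitmaps[, , idx], nrow = 16 * 16)
    cent <- rowMeans(flat)
    matrix(flat[, which.min(colSums((flat - cent)^2))], 16, 16)
  }
  s <- series[[3]]  # pair (0, 3)
  expect_equal(dim(s$frames)[3], 40L)
  expect_equal(s$frames[, , 1], proto(s$class_a))     # alpha = 0
  expect_equal(s$frames[, , 40], proto(s$class_b))    # alpha = 1
  alpha <- 20 / 39                                     # nearest-to-mid index
  expect_equal(s$frames[, , 21],
               (1 - alpha) * proto(s$class_a) + alpha * proto(s$class_b))
})

test_that("latent morphs decode 40 in-range frames per pair", {
  corpus <- generate_synthetic_glyphs(6, n_classes = 4, seed = 28, size = 12)
  d <- dim(corpus$bitmaps)
  x <- t(matrix(corpus$bitmaps, nrow = d[1] * d[2]))
  vae <- vae_build(input_dim = 144, hidden = c(48, 48), latent = 8, seed = 1)
  vae <- vae_train(vae, x, epochs = 3, batch = 12, lr = 1e-3, seed = 1)$vae
  series <- latent_morphs(corpus, vae = vae)
  expect_equal(length(series), choose(4, 2))
  s <- series[[1]]
  expect_equal(dim(s$frames), c(12, 12, 40))
  expect_true(all(s$frames >= 0 & s$frames <= 1))
  # endpoints reproduce the decodes of the class-mean latents
  mu <- vae_encode(vae, x)
  za <- colMeans(mu[corpus$labels == s$class_a, ])
  expect_equal(s$frames[, , 1],
               matrix(vae_decode(vae, matrix(za, 1)), 12, 12),
               tolerance = 1e-10)
})

test_that("VAE training reduces its loss", {
  corpus <- generate_synthetic_glyphs(8, n_classes = 3, seed = 29, size = 12)
  x <- t(matrix(corpus$bitmaps, nrow = 144))
  vae <- vae_build(input_dim = 144, hidden = c(32, 32), latent = 6, seed = 2)
  r <- vae_train(vae, x, epochs = 5, batch = 8, seed = 2)
  expect_lt(r$history[5], r$history[1])
})

test_that("stateless networks reverse exactly and measure width 0", {
  corpus <- generate_synthetic_glyphs(6, seed = 30, size = 16)
  series <- blended_morphs(corpus)[[1]]
  spec <- network_spec("B", maps = 4, in_channels = 1, n_classes = 10,
                       tau = 4, canvas = c(16, 16))
  net <- build_network(spec, seed = 80)
  fwd <- run_sequence(net, series, "forward")
  bwd <- run_sequence(net, series, "backward")
  expect_equal(bwd$predicted, rev(fwd$predicted))      # no memory
  expect_equal(bwd$endpoint_probs, fwd$endpoint_probs[40:1, ])

  # constant series -> constant prediction
  const_series <- series; const_series$frames[] <- series$frames[, , 1]
  cr <- run_sequence(net, const_series, "forward")
  expect_equal(length(unique(cr$predicted)), 1L)

  expect_error(run_sequence(net, list(frames = array(0, c(8, 8, 4))),
                            "forward"),
               class = "occrnn_shape_error")
})

test_that("sequence runs agree with a stepwise trace on a tiny BL net", {
  spec <- network_spec(c("B", "L"), maps = 2, in_channels = 1, n_classes = 3,
                       tau = 3, canvas = c(4, 4))
  net <- build_network(spec, seed = 81)
  set.seed(31)
  frames <- array(runif(4 * 4 * 3), c(4, 4, 3))
  series <- structure(list(frames = frames, class_a = 0L, class_b = 1L,
                           method = "blended"), class = "morph_series")
  run <- run_sequence(net, series, "forward")
  inputs <- lapply(1:3, function(t) array(frames[, , t], c(4, 4, 1, 1)))
  tr <- forward_pass(net, inputs, mode = "eval")$trace
  want <- vapply(tr$readouts, function(r) which.max(r) - 1L, 0L)
  expect_equal(run$predicted, want)
  expect_equal(run$endpoint_probs[, 1], vapply(tr$readouts, `[`, 0, 1))
})

test_that("boundary and width arithmetic match constructed runs", {
  L <- 40L
  # forward switches (sustained) at frame 18; backward at presentation step 15,
  # i.e. frame coordinate 40 - 15 = 25 -> width 7
  fwd <- make_run(c(rep(0L, 18), rep(1L, 22)), 0L, 1L, "forward")
  bwd <- make_run(c(rep(1L, 15), rep(0L, 25)), 0L, 1L, "backward")
  h <- analyze_hysteresis(fwd, bwd)
  expect_equal(h$boundary_fwd, 18L)
  expect_equal(h$boundary_bwd, 25L)
  expect_equal(h$width, 7)
  expect_true(h$bistable)
  expect_false(h$non_switching)

  # swapping the arguments leaves the measure unchanged
  h2 <- analyze_hysteresis(bwd, fwd)
  expect_equal(h2$width, 7)

  # identical predictions in frame coordinates (shared threshold) -> width 0
  fwd0 <- make_run(c(rep(0L, 20), rep(1L, 20)), 0L, 1L, "forward")
  bwd0 <- make_run(c(rep(1L, 20), rep(0L, 20)), 0L, 1L, "backward")
  expect_equal(analyze_hysteresis(fwd0, bwd0)$width, 0)

  # a third class inside the window breaks bistability
  p3 <- c(rep(0L, 18), rep(7L, 4), rep(1L, 18))
  h3 <- analyze_hysteresis(make_run(p3, 0L, 1L, "forward"), bwd, sustain = 2)
  expect_false(h3$bistable)
  expect_gte(length(h3$classes_involved), 3L)

  # non-switching runs are flagged, width undefined
  hn <- analyze_hysteresis(make_run(rep(0L, 40), 0L, 1L, "forward"), bwd)
  expect_true(hn$non_switching)
  expect_true(is.na(hn$width))

  # flicker shorter than the sustain window is ignored
  pf <- c(rep(0L, 10), 1L, rep(0L, 9), rep(1L, 20))
  hf <- analyze_hysteresis(make_run(pf, 0L, 1L, "forward"), bwd)
  expect_equal(hf$boundary_fwd, 20L)

  expect_error(analyze_hysteresis(fwd0, fwd0), class = "occrnn_config_error")
})

test_that("width statistics: means, ANOVA, and degenerate groups", {
  ws <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  r <- width_stats(ws)
  expect_equal(r$summary$mean, c(2, 2))
  expect_equal(r$anova$F, 0)
  expect_equal(r$anova$p, 1)

  r2 <- width_stats(list(a = c(1, 1, 1), b = c(5, 5, 5)))
  expect_lt(r2$anova$p, 0.01)                          # between >> within

  set.seed(32)
  g1 <- rnorm(10, 5); g2 <- rnorm(12, 9); g3 <- rnorm(8, 5.2)
  r3 <- width_stats(list(x = g1, y = g2, z = g3))
  expect_equal(r3$summary$mean, c(mean(g1), mean(g2), mean(g3)))
  expect_equal(r3$anova$df, c(2, 27))
  # closed form agrees with the stats-package ANOVA on non-degenerate data
  ref <- stats::oneway.test(w ~ g,
                            data.frame(w = c(g1, g2, g3),
                                       g = rep(c("x", "y", "z"),
                                               c(10, 12, 8))),
                            var.equal = TRUE)
  expect_equal(r3$anova$F, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r3$anova$p, ref$p.value, tolerance = 1e-12)
  expect_equal(nrow(r3$pairwise), 3L)

  expect_error(width_stats(list(a = 1:3)), class = "occrnn_config_error")
  expect_error(width_stats(list(a = 1:3, b = 2)), class = "occrnn_config_error")
})
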