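# Perceptual hysteresis: build 40-frame class-to-class morph sequences
# (pixel-blended prototypes or decoded latent interpolations), run a network
# over them frame-by-frame with persistent recurrent state in both directions,
# and quantify decision boundaries, bistability and hysteresis width.

MORPH_LEN <- 40L

new_morph_series <- function(frames, class_a, class_b, method) {
  structure(list(frames = frames, class_a = class_a, class_b = class_b,
                 method = method),
            class = "morph_series")
}

#' Pixel-blended morph sequences between class prototypes
#'
#' For every class the prototype is the sample with the smallest Euclidean
#' distance to the raw-pixel class centroid; for each unordered class pair the
#' prototypes are superimposed and linearly cross-faded over 40 frames
#' (`alpha_t = t/39`). A 10-class corpus yields `choose(10, 2) = 45` series.
#'
#' @param corpus a [glyph_corpus()].
#' @return list of `morph_series`.
#' @export
blended_morphs <- function(corpus) {
  n_cls <- corpus$n_classes
  d <- dim(corpus$bitmaps)
  protos <- vector("list", n_cls)
  for (cls in seq_len(n_cls) - 1L) {
    idx <- which(corpus$labels == cls)
    if (length(idx) == 0L)
      occ_error("occrnn_config_error", "class %d empty", cls)
    flat <- matrix(corpus$bitmaps[, , idx], nrow = d[1] * d[2])
    cent <- rowMeans(flat)
    dist2 <- colSums((flat - cent)^2)
    protos[[cls + 1L]] <- matrix(flat[, which.min(dist2)], d[1], d[2])
  }
  pairs <- combn(seq_len(n_cls) - 1L, 2)
  alphas <- (seq_len(MORPH_LEN) - 1) / (MORPH_LEN - 1)
  lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    frames <- array(0, c(d[1], d[2], MORPH_LEN))
    for (t in seq_len(MORPH_LEN))
      frames[, , t] <- (1 - alphas[t]) * protos[[a + 1L]] +
        alphas[t] * protos[[b + 1L]]
    new_morph_series(frames, a, b, "blended")
  })
}

#' Latent-interpolated morph sequences via a variational autoencoder
#'
#' Trains (or reuses) a dense VAE on the corpus, represents each class by its
#' mean latent code, and decodes 40 equally spaced points on the latent
#' segment between every class pair.
#'
#' @param corpus a [glyph_corpus()].
#' @param vae optional pre-trained [vae_build()] model.
#' @param epochs,batch,lr,seed VAE training configuration (defaults follow the
#'   morphing setup; pass fewer epochs for scaled-down runs).
#' @return list of `morph_series` (45 for 10 classes).
#' @export
latent_morphs <- function(corpus, vae = NULL, epochs = 100L, batch = 128L,
                          lr = 1e-3, seed = 1L) {
  d <- dim(corpus$bitmaps)
  x <- t(matrix(corpus$bitmaps, nrow = d[1] * d[2]))
  if (is.null(vae)) {
    vae <- vae_build(input_dim = d[1] * d[2], seed = seed)
    vae <- vae_train(vae, x, epochs = epochs, batch = batch, lr = lr,
                     seed = seed)$vae
  }
  mu <- vae_encode(vae, x)
  reps <- class_centroids(mu, corpus$labels, corpus$n_classes)
  pairs <- combn(seq_len(corpus$n_classes) - 1L, 2)
  alphas <- (seq_len(MORPH_LEN) - 1) / (MORPH_LEN - 1)
  lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    z <- outer(1 - alphas, reps[a + 1L, ]) + outer(alphas, reps[b + 1L, ])
    dec <- vae_decode(vae, z)
    frames <- array(0, c(d[1], d[2], MORPH_LEN))
    for (t in seq_len(MORPH_LEN))
      frames[, , t] <- matrix(dec[t, ], d[1], d[2])
    new_morph_series(frames, a, b, "latent")
  })
}

#' Run a network over a morph sequence with persistent state
#'
#' The network is unrolled for the length of the series with one frame
#' presented per timestep (recurrent state carries across frames). The
#' backward direction presents the frames in reverse order.
#'
#' @param net an `occ_network` with a single input channel and canvas matching
#'   the frames.
#' @param series a `morph_series`.
#' @param direction `"forward"` or `"backward"`.
#' @return object of class `sequence_run`: per-step predicted class (0-based)
#'   and the softmax probabilities of the two endpoint classes.
#' @export
run_sequence <- function(net, series, direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  d <- dim(series$frames)
  if (net$spec$in_channels != 1L || any(net$spec$canvas != d[c(2, 1)]))
    occ_error("occrnn_shape_error",
              "network expects %dx%d x %d channels; frames are %dx%d x 1",
              net$spec$canvas[2], net$spec$canvas[1], net$spec$in_channels,
              d[1], d[2])
  ord <- if (direction == "forward") seq_len(d[3]) else rev(seq_len(d[3]))
  inputs <- lapply(ord, function(t) array(series$frames[, , t], c(d[1], d[2], 1L, 1L)))
  trace <- forward_pass(net, inputs, mode = "eval")$trace
  probs <- do.call(rbind, lapply(trace$readouts, as.numeric))
  predicted <- apply(probs, 1L, argmax0)
  structure(list(direction = direction, predicted = predicted,
                 endpoint_probs = probs[, c(series$class_a, series$class_b) + 1L,
                                        drop = FALSE],
                 class_a = series$class_a, class_b = series$class_b,
                 length = d[3]),
            class = "sequence_run")
}

# first sustained switch (>= `sustain` consecutive steps) from the starting
# endpoint class to the other, judged on the restricted two-class argmax;
# returns the 0-based step index in presentation order, or NA
first_sustained_switch <- function(run, start_class, sustain = 2L) {
  other_wins <- if (start_class == run$class_a)
    run$endpoint_probs[, 2] > run$endpoint_probs[, 1]
  else
    run$endpoint_probs[, 1] > run$endpoint_probs[, 2]
  n <- length(other_wins)
  for (t in seq_len(n)) {
    if (!other_wins[t]) next
    upper <- min(n, t + sustain - 1L)
    if (all(other_wins[t:upper]) && (upper - t + 1L) >= min(sustain, n - t + 1L))
      return(t - 1L)
  }
  NA_integer_
}

#' Quantify hysteresis from a forward and a backward run
#'
#' The decision boundary of each run is the first sustained switch (two or
#' more consecutive steps) from the starting endpoint class to the other. The
#' backward boundary is mapped back to shared frame coordinates, so a width of
#' 0 means the same image triggers the switch in both directions. A pair of
#' runs is bistable when, ignoring the first and last three steps of each run,
#' only the two endpoint classes are ever predicted.
#'
#' The switch happens between two consecutive frames; boundaries are indexed
#' by the first frame on the far side of the crossing, so the forward boundary
#' is the frame index of its first sustained switch and the backward boundary
#' (presentation step `b` over reversed frames) maps to frame coordinate
#' `L - b`. A stateless network switching at a fixed frame threshold then has
#' width exactly 0.
#'
#' @param fwd,bwd `sequence_run` objects for the same series, one per
#'   direction (order-insensitive).
#' @param ignore_edges steps ignored at both ends for the bistability window.
#' @param sustain consecutive steps required to call a switch.
#' @return object of class `hysteresis_result`: `boundary_fwd`,
#'   `boundary_bwd` (both in frame coordinates), `width`, `bistable`,
#'   `non_switching`, `classes_involved`.
#' @export
analyze_hysteresis <- function(fwd, bwd, ignore_edges = 3L, sustain = 2L) {
  if (fwd$class_a != bwd$class_a || fwd$class_b != bwd$class_b ||
      fwd$length != bwd$length)
    occ_error("occrnn_config_error", "runs are not from the same series")
  if (fwd$direction == "backward" && bwd$direction == "forward") {
    tmp <- fwd; fwd <- bwd; bwd <- tmp
  }
  if (fwd$direction != "forward" || bwd$direction != "backward")
    occ_error("occrnn_config_error", "need one forward and one backward run")
  L <- fwd$length
  b_f <- first_sustained_switch(fwd, fwd$class_a, sustain)
  b_b_pres <- first_sustained_switch(bwd, bwd$class_b, sustain)
  b_b <- if (is.na(b_b_pres)) NA_integer_ else L - b_b_pres
  win <- (ignore_edges + 1L):(L - ignore_edges)
  preds <- c(fwd$predicted[win], bwd$predicted[win])
  classes_involved <- sort(unique(preds))
  bistable <- all(preds %in% c(fwd$class_a, fwd$class_b))
  non_switching <- is.na(b_f) || is.na(b_b)
  width <- if (non_switching) NA_real_ else abs(b_f - b_b)
  structure(list(boundary_fwd = b_f, boundary_bwd = b_b, width = width,
                 bistable = bistable, non_switching = non_switching,
                 classes_involved = classes_involved,
                 class_a = fwd$class_a, class_b = fwd$class_b),
            class = "hysteresis_result")
}

#' Run the full hysteresis experiment for one network
#'
#' @param net an `occ_network`.
#' @param series list of `morph_series` (e.g. [blended_morphs()]).
#' @return data frame with one row per series: endpoint classes, boundaries,
#'   width, bistability, number of classes involved.
#' @export
hysteresis_experiment <- function(net, series) {
  rows <- lapply(series, function(s) {
    fwd <- run_sequence(net, s, "forward")
    bwd <- run_sequence(net, s, "backward")
    h <- analyze_hysteresis(fwd, bwd)
    data.frame(class_a = s$class_a, class_b = s$class_b,
               boundary_fwd = h$boundary_fwd, boundary_bwd = h$boundary_bwd,
               width = h$width, bistable = h$bistable,
               non_switching = h$non_switching,
               n_classes_involved = length(h$classes_involved))
  })
  do.call(rbind, rows)
}

#' Hysteresis width statistics across architectures
#'
#' Means and standard deviations of widths over bistable series per
#' architecture, a one-way ANOVA for an architecture effect on width, and
#' pairwise two-sample t-tests (pooled variance).
#'
#' @param widths_by_arch named list of numeric width vectors (bistable series
#'   only).
#' @return list: `summary` data frame, `anova` (F, df, p), `pairwise` data
#'   frame.
#' @export
width_stats <- function(widths_by_arch) {
  widths_by_arch <- lapply(widths_by_arch, function(w) w[!is.na(w)])
  if (length(widths_by_arch) < 2L || any(lengths(widths_by_arch) < 2L))
    occ_error("occrnn_config_error",
              "need >= 2 architectures with >= 2 widths each")
  summ <- data.frame(arch = names(widths_by_arch),
                     n = lengths(widths_by_arch),
                     mean = vapply(widths_by_arch, mean, 0),
                     sd = vapply(widths_by_arch, sd, 0))
  # one-way ANOVA in closed form (robust to zero within-group variance)
  all_w <- unlist(widths_by_arch, use.names = FALSE)
  k <- length(widths_by_arch)
  n <- length(all_w)
  grand <- mean(all_w)
  ssb <- sum(lengths(widths_by_arch) *
               (vapply(widths_by_arch, mean, 0) - grand)^2)
  ssw <- sum(vapply(widths_by_arch, function(w) sum((w - mean(w))^2), 0))
  df1 <- k - 1L; df2 <- n - k
  if (ssw == 0) {
    f_stat <- if (ssb == 0) 0 else Inf
    p <- if (ssb == 0) 1 else 0
  } else {
    f_stat <- (ssb / df1) / (ssw / df2)
    p <- stats::pf(f_stat, df1, df2, lower.tail = FALSE)
  }
  pw <- combn(names(widths_by_arch), 2)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(pw)), function(j) {
    a <- widths_by_arch[[pw[1, j]]]; b <- widths_by_arch[[pw[2, j]]]
    tt <- tryCatch(t.test(a, b, var.equal = TRUE),
                   error = function(e) list(statistic = NA_real_,
                                            parameter = NA_real_,
                                            p.value = NA_real_))
    data.frame(arch_a = pw[1, j], arch_b = pw[2, j],
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  }))
  list(summary = summ, anova = list(F = f_stat, df = c(df1, df2), p = p),
       pairwise = pairwise)
}
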