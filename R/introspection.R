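# Introspection of the learned representation: class activation maps per
# timestep and their Gini concentration, activation mass by ground-truth pixel
# type, latent (post-GAP) distances to unoccluded class centroids, and a
# deterministic 2-D embedding for visualization.

#' Class activation map
#'
#' Weighted sum of the top-layer feature maps using the readout weights of one
#' class, bilinearly upsampled to the input resolution. Computed from the
#' pre-pool top-layer state at native resolution.
#'
#' @param top_layer_maps array (h, w, M) or (h, w, M, N) of top-layer maps at
#'   one timestep.
#' @param readout_weights matrix (M x n_classes) of GAP readout weights.
#' @param class 0-based class index.
#' @param out_hw target (H, W) of the upsampled map; NULL keeps native size.
#' @param rectify clip negative values at zero.
#' @return matrix (H x W) for a single stimulus, or array (H, W, N).
#' @export
cam <- function(top_layer_maps, readout_weights, class, out_hw = NULL,
                rectify = FALSE) {
  if (class < 0 || class >= ncol(readout_weights))
    occ_error("occrnn_domain_error", "class %d out of range", class)
  a <- top_layer_maps
  if (length(dim(a)) == 3L) dim(a) <- c(dim(a), 1L)
  d <- dim(a)
  w <- readout_weights[, class + 1L]
  flat <- matrix(a, nrow = d[1] * d[2], ncol = d[3] * d[4])
  # weight each map with the class readout column, sum over maps per sample
  m <- matrix(0, d[1] * d[2], d[4])
  for (n in seq_len(d[4]))
    m[, n] <- flat[, (n - 1L) * d[3] + seq_len(d[3]), drop = FALSE] %*% w
  out <- array(m, c(d[1], d[2], d[4]))
  if (!is.null(out_hw)) {
    up <- array(0, c(out_hw[1], out_hw[2], d[4]))
    for (n in seq_len(d[4]))
      up[, , n] <- resize_bilinear(out[, , n], out_hw[1], out_hw[2])
    out <- up
  }
  if (rectify) out[out < 0] <- 0
  if (dim(out)[3] == 1L) out <- out[, , 1L] else out
}

#' CAM for one timestep of a trace
#'
#' @param net the network that produced the trace.
#' @param trace an `occ_trace` from [forward_pass()].
#' @param t 1-based timestep.
#' @param class 0-based class; NULL uses the network's final prediction per
#'   stimulus.
#' @param upsample upsample to the input canvas.
#' @export
cam_from_trace <- function(net, trace, t, class = NULL, upsample = TRUE) {
  L <- net$spec$layers
  stored <- length(trace$a)
  a_top <- trace$a[[min(t, stored)]][[L]]
  d <- dim(a_top)
  out_hw <- if (upsample) c(net$spec$canvas[2], net$spec$canvas[1]) else NULL
  if (!is.null(class))
    return(cam(a_top, net$fc$W, class, out_hw))
  final_pred <- row_argmax0(trace$readouts[[length(trace$readouts)]])
  res <- array(0, c(out_hw %||% d[1:2], d[4]))
  for (n in seq_len(d[4])) {
    res[, , n] <- cam(a_top[, , , n, drop = FALSE], net$fc$W, final_pred[n],
                      out_hw)
  }
  if (d[4] == 1L) res[, , 1L] else res
}

#' Gini concentration coefficient
#'
#' `gc = sum_i (2i - n - 1) x_(i) / (n sum_i x_i)` over the ascending sort of
#' the flattened non-negative values: 0 for perfectly uniform mass and
#' `(n-1)/n` when all mass sits on one element.
#'
#' @param values non-negative numeric values (not all zero); activation maps
#'   should be shifted by their minimum first (see [cam_gini()]).
#' @return coefficient in `[0, 1)`.
#' @export
gini <- function(values) {
  x <- as.numeric(values)
  if (any(x < 0))
    occ_error("occrnn_domain_error", "gini requires non-negative values")
  s <- sum(x)
  if (s == 0)
    occ_error("occrnn_domain_error", "gini undefined for all-zero input")
  x <- sort(x)
  n <- length(x)
  sum((2 * seq_len(n) - n - 1) * x) / (n * s)
}

#' Gini coefficient of an activation map
#'
#' Shifts the flattened map by its minimum (activation maps can be negative)
#' and applies [gini()].
#' @param map numeric matrix or array.
#' @export
cam_gini <- function(map) {
  v <- as.numeric(map) - min(map)
  if (sum(v) == 0) return(0)
  gini(v)
}

#' Mean activation mass per pixel, by ground-truth pixel type
#'
#' Normalizes the map to a total mass of 100% and reports, for each of the
#' four pixel types (background, occluder, overlap, target), the average mass
#' captured by one pixel of that type. Types with no pixels are `NA` and
#' flagged.
#'
#' @param cam_map non-negative activation map (H x W); shifted by its minimum
#'   if any value is negative.
#' @param segmentation integer matrix (H x W) with codes 0 background,
#'   1 occluder, 2 overlap, 3 target.
#' @return named numeric vector (percent per pixel) with attribute
#'   `missing_types`.
#' @export
activation_mass_by_pixel_type <- function(cam_map, segmentation) {
  if (!all(dim(cam_map) == dim(segmentation)))
    occ_error("occrnn_shape_error", "map and segmentation sizes differ")
  m <- cam_map - min(min(cam_map), 0)
  total <- sum(m)
  if (total == 0)
    occ_error("occrnn_domain_error", "activation map has zero total mass")
  types <- c(background = SEG_BACKGROUND, occluder = SEG_OCCLUDER,
             overlap = SEG_OVERLAP, target = SEG_TARGET)
  out <- vapply(types, function(code) {
    npix <- sum(segmentation == code)
    if (npix == 0) return(NA_real_)
    100 * sum(m[segmentation == code]) / total / npix
  }, 0)
  attr(out, "missing_types") <- names(out)[is.na(out)]
  out
}

#' Per-class centroids of latent points
#'
#' @param latent_points matrix (N x d) of pooled feature vectors.
#' @param labels 0-based class labels, length N.
#' @param n_classes number of classes; every class must be represented.
#' @return matrix (n_classes x d); row i is the centroid of class i - 1.
#' @export
class_centroids <- function(latent_points, labels, n_classes = max(labels) + 1L) {
  latent_points <- as.matrix(latent_points)
  missing <- setdiff(seq_len(n_classes) - 1L, unique(labels))
  if (length(missing) > 0)
    occ_error("occrnn_domain_error", "no latent points for class(es) %s",
              paste(missing, collapse = ", "))
  out <- matrix(0, n_classes, ncol(latent_points))
  for (cls in seq_len(n_classes) - 1L)
    out[cls + 1L, ] <- colMeans(latent_points[labels == cls, , drop = FALSE])
  out
}

#' Relative latent distance to target versus occluder centroid
#'
#' Euclidean distance ratio `dist(a, centroid_target) / dist(a,
#' centroid_occluder)`; values below 1 indicate relative proximity to the
#' unoccluded target representation.
#'
#' @param a latent point.
#' @param centroid_target,centroid_occluder centroids of the same dimension.
#' @return non-negative ratio; `Inf` (with a warning) for a zero denominator.
#' @export
relative_distance <- function(a, centroid_target, centroid_occluder) {
  if (length(a) != length(centroid_target) ||
      length(a) != length(centroid_occluder))
    occ_error("occrnn_shape_error", "dimension mismatch")
  num <- sqrt(sum((a - centroid_target)^2))
  den <- sqrt(sum((a - centroid_occluder)^2))
  if (den == 0) {
    warning("zero distance to occluder centroid; relative distance infinite")
    return(Inf)
  }
  num / den
}

#' Deterministic 2-D embedding of latent points
#'
#' Library-backed principal-component projection onto the first two
#' components, fit independently per call (one fit per timestep when mapping a
#' trace). Deterministic; the seed is recorded for interface compatibility
#' with stochastic embedders.
#'
#' @param latent_points matrix (N x d), N >= 2.
#' @param seed recorded seed.
#' @return N x 2 coordinate matrix with attribute `seed`.
#' @export
embed_2d <- function(latent_points, seed = 1L) {
  latent_points <- as.matrix(latent_points)
  if (nrow(latent_points) < 2L)
    occ_error("occrnn_domain_error", "need at least 2 points")
  p <- prcomp(latent_points, center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(p$x))
  out <- matrix(0, nrow(latent_points), 2L)
  out[, seq_len(k)] <- p$x[, seq_len(k)]
  attr(out, "seed") <- seed
  out
}

#' Pooled (GAP) latent vectors per timestep
#'
#' @param net an `occ_network`.
#' @param x input array (H, W, C, N).
#' @param tau unroll steps (default: spec).
#' @return list over timesteps of (N x M) latent matrices.
#' @export
gap_latents <- function(net, x, tau = NULL) {
  forward_pass(net, x, tau = tau, mode = "eval")$trace$gap
}
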