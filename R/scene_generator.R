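# Stereoscopic 2.5D occlusion scene simulator: a target glyph and (by default)
# two occluders are placed at decreasing viewing distances, scaled by a
# pinhole-camera model, shifted by binocular parallax, composited back-to-front
# and segmented per pixel. Scenes outside the configured occlusion bounds are
# rejected during dataset sampling.

#' Pinhole stereo camera model
#'
#' @param focal_px pixel focal length; the scene geometry is defined only in
#'   relative terms, so the default 64 is a convention that maps one
#'   target-plane centimetre to 1.28 px at the 50 cm fixation distance on the
#'   default 32 px canvas.
#' @param canvas integer (W, H) canvas size in pixels.
#' @param interocular_cm interocular distance (6.8 cm).
#' @param fixation_cm distance of the fixation/target plane (50 cm).
#' @return object of class `camera_model`.
#' @export
camera_model <- function(focal_px = 64, canvas = c(32L, 32L),
                         interocular_cm = 6.8, fixation_cm = 50) {
  if (focal_px <= 0 || interocular_cm <= 0)
    occ_error("occrnn_config_error", "focal_px and interocular_cm must be > 0")
  structure(list(focal_px = focal_px, canvas = as.integer(canvas),
                 interocular_cm = interocular_cm, fixation_cm = fixation_cm),
            class = "camera_model")
}

#' Scene specification
#'
#' @param variant `"centered"` (target fixed at the canvas center, occluders
#'   standing on the virtual floor with uniformly drawn x positions) or
#'   `"random"` (all positions uniform over the canvas).
#' @param n_occluders number of occluding objects (default 2).
#' @param distances_cm per-object depths, target first; defaults to
#'   `c(50, 40, 30)`: 10 cm less for every added object.
#' @param floor_offset_cm virtual floor below the line of sight (5 cm).
#' @param virtual_size_cm object height in cm; the default 15 makes the target
#'   span ~60% of a 32 px canvas at the default camera.
#' @param occlusion_bounds accepted occlusion range (default 20%..80%).
#' @param mask_threshold glyph binarization threshold for occlusion accounting.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(variant = c("centered", "random"), n_occluders = 2L,
                       distances_cm = NULL, floor_offset_cm = 5,
                       virtual_size_cm = 15,
                       occlusion_bounds = c(0.20, 0.80),
                       mask_threshold = 0.1) {
  variant <- match.arg(variant)
  if (is.null(distances_cm)) distances_cm <- 50 - 10 * (0:n_occluders)
  if (length(distances_cm) != n_occluders + 1L)
    occ_error("occrnn_config_error", "need %d distances, got %d",
              n_occluders + 1L, length(distances_cm))
  if (any(diff(distances_cm) >= 0))
    occ_error("occrnn_config_error", "distances must strictly decrease")
  if (occlusion_bounds[1] < 0 || occlusion_bounds[2] > 1 ||
      occlusion_bounds[1] >= occlusion_bounds[2])
    occ_error("occrnn_config_error", "invalid occlusion bounds")
  structure(list(variant = variant, n_occluders = as.integer(n_occluders),
                 distances_cm = distances_cm, floor_offset_cm = floor_offset_cm,
                 virtual_size_cm = virtual_size_cm,
                 occlusion_bounds = occlusion_bounds,
                 mask_threshold = mask_threshold),
            class = "scene_spec")
}

#' Perspective scaling of an object size
#'
#' Pinhole model: `size_px = focal_px * size_cm / distance_cm`.
#' @param size_cm physical (virtual) size.
#' @param distance_cm viewing distance (> 0).
#' @param camera a [camera_model()].
#' @export
perspective_scale <- function(size_cm, distance_cm, camera) {
  if (any(distance_cm <= 0))
    occ_error("occrnn_domain_error", "distance must be > 0")
  camera$focal_px * size_cm / distance_cm
}

#' Binocular disparity of an object at a given depth
#'
#' `shift_px = focal_px * interocular_cm * (1/distance - 1/fixation)`; zero at
#' the fixation depth, so the target is always presented at zero disparity.
#' @inheritParams perspective_scale
#' @export
disparity_shift <- function(distance_cm, camera) {
  if (any(distance_cm <= 0))
    occ_error("occrnn_domain_error", "distance must be > 0")
  camera$focal_px * camera$interocular_cm *
    (1 / distance_cm - 1 / camera$fixation_cm)
}

# px <-> cm conversion at a given depth (image position relative to center)
px_per_cm <- function(camera, distance_cm) camera$focal_px / distance_cm

#' Place target and occluders in a scene
#'
#' Draws object classes (pairwise distinct), glyph instances and world
#' positions. In the centered variant the target sits at the canvas center and
#' each occluder stands on the virtual floor at its own depth with a uniform x
#' position; in the random variant all positions are uniform such that the
#' rendered footprint stays inside the canvas. Uses the current RNG state.
#'
#' @param spec a [scene_spec()].
#' @param corpus a [glyph_corpus()] with at least `n_occluders + 1` classes.
#' @param camera a [camera_model()].
#' @return list of placed objects ordered back-to-front (target first).
#' @export
place_scene <- function(spec, corpus, camera) {
  n_obj <- spec$n_occluders + 1L
  if (corpus$n_classes < n_obj)
    occ_error("occrnn_config_error",
              "corpus has %d classes; need at least %d", corpus$n_classes, n_obj)
  classes <- sample.int(corpus$n_classes, n_obj) - 1L  # distinct by construction
  wc <- camera$canvas[1]; hc <- camera$canvas[2]
  placed <- vector("list", n_obj)
  for (o in seq_len(n_obj)) {
    z <- spec$distances_cm[o]
    cls <- classes[o]
    pool <- which(corpus$labels == cls)
    if (length(pool) == 0L)
      occ_error("occrnn_config_error", "corpus has no glyph of class %d", cls)
    gi <- pool[sample.int(length(pool), 1L)]
    size_px <- perspective_scale(spec$virtual_size_cm, z, camera)
    half <- size_px / 2
    ppc <- px_per_cm(camera, z)
    ux <- if (wc - 2 * half > 0) runif(1, half, wc - half) else wc / 2
    if (o == 1L && spec$variant == "centered") {
      x_cm <- 0; y_cm <- 0
    } else if (spec$variant == "centered") {
      x_cm <- (ux - wc / 2) / ppc
      y_cm <- spec$floor_offset_cm - spec$virtual_size_cm / 2
    } else {
      uy <- if (hc - 2 * half > 0) runif(1, half, hc - half) else hc / 2
      x_cm <- (ux - wc / 2) / ppc
      y_cm <- (uy - hc / 2) / ppc
    }
    placed[[o]] <- list(label = cls, glyph_index = gi, distance_cm = z,
                        world_x_cm = x_cm, world_y_cm = y_cm,
                        scale_px_per_cm = ppc,
                        size_px = size_px,
                        disparity_px = disparity_shift(z, camera))
  }
  placed
}

# paint one glyph onto canvas/owner matrices; returns updated state and the
# footprint mask of this object on the canvas
paint_object <- function(canvas_img, owner, glyph_bitmap, size_px,
                         center_x, center_y, obj_id, mask_threshold) {
  hc <- nrow(canvas_img); wc <- ncol(canvas_img)
  sp <- max(1L, as.integer(round(size_px)))
  g <- resize_bilinear(glyph_bitmap, sp, sp)
  top <- as.integer(round(center_y - sp / 2))   # 0-based row of first pixel
  left <- as.integer(round(center_x - sp / 2))
  rows <- (top + 1L):(top + sp)
  cols <- (left + 1L):(left + sp)
  rsel <- rows >= 1L & rows <= hc
  csel <- cols >= 1L & cols <= wc
  footprint <- matrix(FALSE, hc, wc)
  if (any(rsel) && any(csel)) {
    gsub <- g[rsel, csel, drop = FALSE]
    m <- gsub > mask_threshold
    rr <- rows[rsel]; cc <- cols[csel]
    sub_img <- canvas_img[rr, cc, drop = FALSE]
    sub_owner <- owner[rr, cc, drop = FALSE]
    sub_img[m] <- gsub[m]
    sub_owner[m] <- obj_id
    canvas_img[rr, cc] <- sub_img
    owner[rr, cc] <- sub_owner
    fp <- footprint[rr, cc, drop = FALSE]
    fp[m] <- TRUE
    footprint[rr, cc] <- fp
  }
  list(img = canvas_img, owner = owner, footprint = footprint)
}

SEG_BACKGROUND <- 0L
SEG_OCCLUDER <- 1L
SEG_OVERLAP <- 2L
SEG_TARGET <- 3L

#' Render a placed scene into a stereo image pair with segmentation
#'
#' Painter's algorithm per eye (nearer objects overwrite), with each object
#' shifted horizontally by +disparity/2 in the left eye and -disparity/2 in
#' the right eye (rounded to integer pixels). The per-eye segmentation labels
#' pixels as background (0), occluder (1), overlap (2: target pixels covered
#' by an occluder) and target (3: visible target pixels).
#'
#' @param placed output of [place_scene()], ordered back-to-front.
#' @param corpus the glyph corpus the placement refers to.
#' @param camera a [camera_model()].
#' @param spec a [scene_spec()].
#' @return object of class `stereo_scene`.
#' @export
render_stereo <- function(placed, corpus, camera, spec) {
  wc <- camera$canvas[1]; hc <- camera$canvas[2]
  eyes <- list(left = +0.5, right = -0.5)
  imgs <- list(); segs <- list()
  for (e in names(eyes)) {
    img <- matrix(0, hc, wc)
    owner <- matrix(0L, hc, wc)
    target_fp <- NULL
    for (o in seq_along(placed)) {
      p <- placed[[o]]
      cx <- wc / 2 + p$world_x_cm * p$scale_px_per_cm +
        eyes[[e]] * p$disparity_px
      cy <- hc / 2 + p$world_y_cm * p$scale_px_per_cm
      st <- paint_object(img, owner, corpus$bitmaps[, , p$glyph_index],
                         p$size_px, cx, cy, o, spec$mask_threshold)
      img <- st$img; owner <- st$owner
      if (o == 1L) target_fp <- st$footprint
    }
    seg <- matrix(SEG_BACKGROUND, hc, wc)
    seg[owner > 1L] <- SEG_OCCLUDER
    seg[target_fp & owner > 1L] <- SEG_OVERLAP
    seg[target_fp & owner == 1L] <- SEG_TARGET
    imgs[[e]] <- img
    segs[[e]] <- seg
  }
  scene <- structure(list(left = imgs$left, right = imgs$right,
                          seg_left = segs$left, seg_right = segs$right,
                          target_label = placed[[1]]$label,
                          occluder_labels = vapply(placed[-1], `[[`, 0L, "label"),
                          placed = placed),
                     class = "stereo_scene")
  scene$occlusion_fraction <- occlusion_fraction(scene)
  scene
}

#' Occlusion fraction of a rendered scene
#'
#' Per eye: `overlap / (overlap + visible target)`, i.e. the fraction of
#' target-object pixels hidden by occluders; the returned value is the mean
#' over the two eyes. `mode = "ratio"` instead returns the literal
#' occluded-to-visible pixel ratio.
#'
#' @param scene a `stereo_scene`.
#' @param mode `"fraction"` (default) or `"ratio"`.
#' @export
occlusion_fraction <- function(scene, mode = c("fraction", "ratio")) {
  mode <- match.arg(mode)
  per_eye <- vapply(list(scene$seg_left, scene$seg_right), function(seg) {
    ov <- sum(seg == SEG_OVERLAP)
    vis <- sum(seg == SEG_TARGET)
    if (ov + vis == 0L)
      occ_error("occrnn_degenerate_scene", "target has no mask pixels")
    if (mode == "fraction") ov / (ov + vis)
    else if (vis == 0L) Inf else ov / vis
  }, 0)
  mean(per_eye)
}

#' Sample an occlusion dataset by rejection
#'
#' Renders scenes until `n_scenes` have an occlusion fraction inside
#' `spec$occlusion_bounds`; everything outside the bounds is rejected.
#' Deterministic given `seed`.
#'
#' @param spec a [scene_spec()].
#' @param corpus a [glyph_corpus()].
#' @param n_scenes number of accepted scenes; if `NULL`,
#'   `length(corpus) * occluders_per_target` scenes are drawn with targets
#'   cycling through the corpus.
#' @param occluders_per_target scenes per corpus glyph when `n_scenes` is NULL.
#' @param camera a [camera_model()].
#' @param seed integer seed.
#' @param max_tries_factor retry budget: at most `max_tries_factor * n_scenes`
#'   attempts before a sampling-exhausted error.
#' @return object of class `occ_dataset`: `scenes` (list of `stereo_scene`),
#'   `meta` (one data frame row per scene), the spec, camera, seed and the
#'   empirical acceptance rate.
#' @export
sample_dataset <- function(spec, corpus, n_scenes = NULL,
                           occluders_per_target = NULL,
                           camera = camera_model(), seed = 1L,
                           max_tries_factor = 200L) {
  cycle_targets <- is.null(n_scenes)
  if (cycle_targets) {
    if (is.null(occluders_per_target))
      occ_error("occrnn_config_error",
                "give n_scenes or occluders_per_target")
    n_scenes <- length(corpus) * occluders_per_target
  }
  n_scenes <- as.integer(n_scenes)
  if (n_scenes < 0L) occ_error("occrnn_config_error", "n_scenes must be >= 0")
  scenes <- vector("list", n_scenes)
  rows <- vector("list", n_scenes)
  attempts <- 0L
  with_seed(seed, {
    accepted <- 0L
    budget <- max(1L, max_tries_factor * max(1L, n_scenes))
    while (accepted < n_scenes) {
      if (attempts >= budget)
        occ_error("occrnn_sampling_exhausted",
                  "rejection sampling exhausted after %d attempts (%d/%d accepted; bounds [%g, %g])",
                  attempts, accepted, n_scenes,
                  spec$occlusion_bounds[1], spec$occlusion_bounds[2])
      attempts <- attempts + 1L
      placed <- place_scene(spec, corpus, camera)
      if (cycle_targets) {
        # deterministic target cycling through the corpus
        gi <- ((accepted) %% length(corpus)) + 1L
        placed[[1]]$glyph_index <- gi
        placed[[1]]$label <- corpus$labels[gi]
        if (placed[[1]]$label %in% vapply(placed[-1], `[[`, 0L, "label")) next
      }
      sc <- render_stereo(placed, corpus, camera, spec)
      fr <- sc$occlusion_fraction
      if (fr < spec$occlusion_bounds[1] || fr > spec$occlusion_bounds[2]) next
      accepted <- accepted + 1L
      scenes[[accepted]] <- sc
      occ <- sc$occluder_labels
      rows[[accepted]] <- data.frame(
        scene_id = accepted, target_label = sc$target_label,
        occ1_label = occ[1] %||% NA_integer_,
        occ2_label = if (length(occ) >= 2) occ[2] else NA_integer_,
        occlusion_fraction = fr, variant = spec$variant,
        target_x_cm = placed[[1]]$world_x_cm,
        target_y_cm = placed[[1]]$world_y_cm,
        target_z_cm = placed[[1]]$distance_cm,
        seed = seed)
    }
  })
  meta <- if (n_scenes > 0) do.call(rbind, rows) else
    data.frame(scene_id = integer(), target_label = integer(),
               occ1_label = integer(), occ2_label = integer(),
               occlusion_fraction = numeric(), variant = character(),
               target_x_cm = numeric(), target_y_cm = numeric(),
               target_z_cm = numeric(), seed = integer())
  structure(list(scenes = scenes, meta = meta, spec = spec, camera = camera,
                 seed = seed,
                 acceptance_rate = if (attempts > 0) n_scenes / attempts else NA_real_),
            class = "occ_dataset")
}

#' @export
length.occ_dataset <- function(x) length(x$scenes)

#' @export
print.occ_dataset <- function(x, ...) {
  cat(sprintf("<occ_dataset: %d scenes, variant %s, acceptance %.2f>\n",
              length(x$scenes), x$spec$variant, x$acceptance_rate))
  invisible(x)
}

#' Stack a dataset into model-ready arrays
#'
#' @param ds an `occ_dataset`.
#' @param stereo if TRUE channels are (left, right); otherwise left eye only.
#' @return list: `x` array (H, W, channels, N), `y` integer labels (0-based).
#' @export
dataset_to_arrays <- function(ds, stereo = TRUE) {
  n <- length(ds$scenes)
  hc <- ds$camera$canvas[2]; wc <- ds$camera$canvas[1]
  ch <- if (stereo) 2L else 1L
  x <- array(0, c(hc, wc, ch, n))
  for (i in seq_len(n)) {
    x[, , 1L, i] <- ds$scenes[[i]]$left
    if (stereo) x[, , 2L, i] <- ds$scenes[[i]]$right
  }
  list(x = x, y = ds$meta$target_label)
}

#' Write a dataset to disk (PGM images + CSV metadata + JSON sidecar)
#' @param ds an `occ_dataset`.
#' @param dir output directory (created if missing).
#' @param images write per-eye PGM images (TRUE) or metadata only.
#' @export
save_dataset <- function(ds, dir, images = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(ds$meta, file.path(dir, "meta.csv"), row.names = FALSE)
  sidecar <- list(spec = unclass(ds$spec), camera = unclass(ds$camera),
                  seed = ds$seed, n_scenes = length(ds$scenes),
                  acceptance_rate = ds$acceptance_rate)
  jsonlite::write_json(sidecar, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  if (images && length(ds$scenes) > 0) {
    imdir <- file.path(dir, "images")
    dir.create(imdir, showWarnings = FALSE)
    for (i in seq_along(ds$scenes)) {
      write_pgm(ds$scenes[[i]]$left,
                file.path(imdir, sprintf("scene_%05d_L.pgm", i)))
      write_pgm(ds$scenes[[i]]$right,
                file.path(imdir, sprintf("scene_%05d_R.pgm", i)))
    }
  }
  invisible(dir)
}

#' Load a dataset directory written by [save_dataset()]
#' @param dir dataset directory.
#' @param stereo channel layout of the returned array.
#' @return list with `x`, `y`, `meta`, `config`.
#' @export
load_dataset <- function(dir, stereo = TRUE) {
  meta <- read.csv(file.path(dir, "meta.csv"))
  config <- jsonlite::read_json(file.path(dir, "config.json"),
                                simplifyVector = TRUE)
  n <- nrow(meta)
  hc <- config$camera$canvas[2]; wc <- config$camera$canvas[1]
  ch <- if (stereo) 2L else 1L
  x <- array(0, c(hc, wc, ch, n))
  for (i in seq_len(n)) {
    x[, , 1L, i] <- read_pgm(file.path(dir, "images",
                                       sprintf("scene_%05d_L.pgm", i)))
    if (stereo)
      x[, , 2L, i] <- read_pgm(file.path(dir, "images",
                                         sprintf("scene_%05d_R.pgm", i)))
  }
  list(x = x, y = meta$target_label, meta = meta, config = config)
}

#' Image-pyramid downsample plus center crop
#'
#' Utility for loading pre-rendered high-resolution content: repeated 2x2 mean
#' pooling down to at most the requested size, a bilinear resize to the exact
#' intermediate size, then a center crop.
#' @param img numeric matrix.
#' @param down_h,down_w intermediate size after downsampling.
#' @param crop_h,crop_w final center-crop size.
#' @export
downsample_center_crop <- function(img, down_h, down_w, crop_h, crop_w) {
  while (nrow(img) >= 2 * down_h && ncol(img) >= 2 * down_w &&
         nrow(img) %% 2 == 0 && ncol(img) %% 2 == 0) {
    img <- 0.25 * (img[seq(1, nrow(img), 2), seq(1, ncol(img), 2)] +
                   img[seq(2, nrow(img), 2), seq(1, ncol(img), 2)] +
                   img[seq(1, nrow(img), 2), seq(2, ncol(img), 2)] +
                   img[seq(2, nrow(img), 2), seq(2, ncol(img), 2)])
  }
  img <- resize_bilinear(img, down_h, down_w)
  r0 <- (down_h - crop_h) %/% 2L
  c0 <- (down_w - crop_w) %/% 2L
  img[(r0 + 1L):(r0 + crop_h), (c0 + 1L):(c0 + crop_w), drop = FALSE]
}
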