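# Scene generator: pinhole scaling, disparity, placement, painter's
# compositing, segmentation, occlusion accounting and rejection sampling.

cam64 <- camera_model()  # focal 64, canvas 32x32, 6.8 cm, fixation 50 cm

test_that("perspective_scale follows the pinhole model", {
  expect_equal(perspective_scale(10, 50, cam64), 12.8)
  expect_equal(perspective_scale(7, 60, cam64),
               perspective_scale(7, 30, cam64) / 2)   # doubling Z halves size
  expect_equal(perspective_scale(5, 40, cam64) / perspective_scale(5, 50, cam64),
               50 / 40)
  expect_error(perspective_scale(10, 0, cam64), class = "occrnn_domain_error")
})

test_that("disparity is zero at fixation and grows toward the viewer", {
  expect_equal(disparity_shift(50, cam64), 0)           # target: zero disparity
  expect_equal(disparity_shift(40, cam64), 64 * 6.8 * (1 / 40 - 1 / 50))
  expect_equal(disparity_shift(40, cam64), 2.176)
  expect_true(abs(disparity_shift(30, cam64)) > abs(disparity_shift(40, cam64)))
  expect_true(abs(disparity_shift(40, cam64)) > 0)
})

test_that("placement keeps labels distinct and footprints inside the canvas", {
  corpus <- generate_synthetic_glyphs(5, seed = 5)
  cam <- camera_model(focal_px = 32, canvas = c(16L, 16L))
  spec_r <- scene_spec(variant = "random")
  spec_c <- scene_spec(variant = "centered")

  withr::with_seed(42, {
    for (i in 1:200) {
      pl <- place_scene(spec_r, corpus, cam)
      labs <- vapply(pl, `[[`, 0L, "label")
      expect_equal(length(unique(labs)), 3L)   # pairwise distinct classes
      for (p in pl) {
        ppc <- cam$focal_px / p$distance_cm
        cx <- 16 / 2 + p$world_x_cm * ppc
        cy <- 16 / 2 + p$world_y_cm * ppc
        half <- p$size_px / 2
        expect_true(cx - half >= -0.51 && cx + half <= 16.51)
        expect_true(cy - half >= -0.51 && cy + half <= 16.51)
      }
    }
    pc <- place_scene(spec_c, corpus, cam)
    expect_equal(pc[[1]]$world_x_cm, 0)  # target centered
    expect_equal(pc[[1]]$world_y_cm, 0)
    # occluder y fixed by floor geometry at its depth
    expect_equal(pc[[2]]$world_y_cm, 5 - spec_c$virtual_size_cm / 2)
  })

  small <- generate_synthetic_glyphs(2, n_classes = 2, seed = 1)
  expect_error(place_scene(spec_r, small, cam), class = "occrnn_config_error")
})

test_that("painter's compositing, segmentation partition and overlap counts", {
  # square fixture: all-ones glyphs render as solid axis-aligned squares
  sq <- array(1, c(28, 28, 3))
  corpus <- glyph_corpus(sq, 0:2, 3L)
  cam <- camera_model(focal_px = 64, canvas = c(32L, 32L))
  spec <- scene_spec(variant = "centered", virtual_size_cm = 8)
  placed <- list(
    list(label = 0L, glyph_index = 1L, distance_cm = 50, world_x_cm = 0,
         world_y_cm = 0, scale_px_per_cm = 64 / 50,
         size_px = 64 * 8 / 50, disparity_px = 0),
    list(label = 1L, glyph_index = 2L, distance_cm = 40, world_x_cm = -2,
         world_y_cm = 0, scale_px_per_cm = 64 / 40,
         size_px = 64 * 8 / 40, disparity_px = 0),
    list(label = 2L, glyph_index = 3L, distance_cm = 30, world_x_cm = 3,
         world_y_cm = 1, scale_px_per_cm = 64 / 30,
         size_px = 64 * 8 / 30, disparity_px = 0)
  )
  sc <- render_stereo(placed, corpus, cam, spec)

  # independent set-arithmetic oracle for the footprints
  square <- function(center_x_px, center_y_px, size_px) {
    s <- max(1L, as.integer(round(size_px)))
    top <- as.integer(round(center_y_px - s / 2))
    left <- as.integer(round(center_x_px - s / 2))
    m <- matrix(FALSE, 32, 32)
    rr <- intersect((top + 1):(top + s), 1:32)
    cc <- intersect((left + 1):(left + s), 1:32)
    m[rr, cc] <- TRUE
    m
  }
  tg <- square(16 + 0 * 64 / 50, 16, 64 * 8 / 50)
  o1 <- square(16 - 2 * 64 / 40, 16, 64 * 8 / 40)
  o2 <- square(16 + 3 * 64 / 30, 16 + 1 * 64 / 30, 64 * 8 / 30)
  expect_equal(sum(sc$seg_left == 2), sum(tg & (o1 | o2)))    # overlap
  expect_equal(sum(sc$seg_left == 3), sum(tg & !(o1 | o2)))   # visible target
  expect_true(all(sc$seg_left %in% 0:3))                      # partition

  # depth ordering: the nearest object's intensity wins everywhere it covers
  corpus2 <- glyph_corpus(array(rep(c(0.5, 0.7, 0.9), each = 28 * 28),
                                c(28, 28, 3)), 0:2, 3L)
  sc2 <- render_stereo(placed, corpus2, cam, spec)
  expect_true(all(abs(sc2$left[o2] - 0.9) < 1e-9))
  expect_true(all(abs(sc2$left[o1 & !o2] - 0.7) < 1e-9))
  expect_true(all(abs(sc2$left[tg & !o1 & !o2] - 0.5) < 1e-9))

  # zero occluders: only zero-disparity content, eyes identical
  sc0 <- render_stereo(placed[1], corpus, cam, spec)
  expect_identical(sc0$left, sc0$right)
  expect_equal(sc0$occlusion_fraction, 0)
})

test_that("occlusion_fraction counts overlap against the target mask", {
  fake_scene <- function(overlap, visible) {
    seg <- matrix(0L, 10, 10)
    if (overlap > 0) seg[seq_len(overlap)] <- 2L
    if (visible > 0) seg[overlap + seq_len(visible)] <- 3L
    structure(list(seg_left = seg, seg_right = seg), class = "stereo_scene")
  }
  expect_equal(occlusion_fraction(fake_scene(0, 40)), 0)
  expect_equal(occlusion_fraction(fake_scene(40, 0)), 1)   # fully covered
  expect_equal(occlusion_fraction(fake_scene(30, 70)), 0.3)
  expect_equal(occlusion_fraction(fake_scene(30, 70), mode = "ratio"), 3 / 7)
  expect_error(occlusion_fraction(fake_scene(0, 0)),
               class = "occrnn_degenerate_scene")
})

test_that("rejection sampling respects bounds and is seed-deterministic", {
  corpus <- generate_synthetic_glyphs(10, seed = 6)
  cam <- camera_model(focal_px = 32, canvas = c(16L, 16L))
  spec <- scene_spec(variant = "random")

  expect_equal(length(sample_dataset(spec, corpus, 0, camera = cam, seed = 1)),
               0L)

  d1 <- sample_dataset(spec, corpus, 60, camera = cam, seed = 9)
  d2 <- sample_dataset(spec, corpus, 60, camera = cam, seed = 9)
  expect_identical(d1$meta, d2$meta)

  expect_true(all(d1$meta$occlusion_fraction >= 0.2 &
                  d1$meta$occlusion_fraction <= 0.8))

  # zero-disparity target: footprint pixel-identical across eyes
  for (sc in d1$scenes[1:20]) {
    expect_identical(sc$seg_left %in% c(2L, 3L), sc$seg_right %in% c(2L, 3L))
  }

  # unattainable bounds exhaust the retry budget with diagnostics
  tight <- scene_spec(variant = "random", occlusion_bounds = c(0.799, 0.8))
  expect_error(sample_dataset(tight, corpus, 5, camera = cam, seed = 1,
                              max_tries_factor = 3L),
               class = "occrnn_sampling_exhausted")
})

test_that("datasets round-trip through disk and stack into arrays", {
  corpus <- generate_synthetic_glyphs(10, seed = 6)
  cam <- camera_model(focal_px = 32, canvas = c(16L, 16L))
  ds <- sample_dataset(scene_spec(variant = "centered"), corpus, 8,
                       camera = cam, seed = 2)
  arr <- dataset_to_arrays(ds)
  expect_equal(dim(arr$x), c(16, 16, 2, 8))
  expect_equal(arr$y, ds$meta$target_label)
  expect_equal(arr$x[, , 1, 3], ds$scenes[[3]]$left)

  tmp <- withr::local_tempdir()
  save_dataset(ds, tmp)
  back <- load_dataset(tmp)
  expect_equal(back$y, arr$y)
  expect_equal(back$x, arr$x, tolerance = 1 / 254)  # PGM quantization
  expect_true(file.exists(file.path(tmp, "config.json")))
})

test_that("downsample + center crop returns the requested window", {
  img <- matrix(runif(240 * 320), 240, 320)
  out <- downsample_center_crop(img, 60, 80, 32, 32)
  expect_equal(dim(out), c(32, 32))
})
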