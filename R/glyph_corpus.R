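# Class-labelled grayscale object bitmaps: either parsed from IDX container
# files (the MNIST on-disk format) or generated procedurally, so that every
# downstream experiment runs without downloading any dataset.

#' Construct a glyph corpus
#'
#' @param bitmaps array (H, W, N) of intensities in \[0, 1\].
#' @param labels integer vector of 0-based class indices, length N.
#' @param n_classes number of classes.
#' @param source `"idx_file"` or `"synthetic"`.
#' @param split `"train"` or `"test"`.
#' @return object of class `glyph_corpus`.
#' @export
glyph_corpus <- function(bitmaps, labels, n_classes,
                         source = c("synthetic", "idx_file"),
                         split = c("train", "test")) {
  source <- match.arg(source)
  split <- match.arg(split)
  if (length(dim(bitmaps)) != 3L)
    occ_error("occrnn_shape_error", "bitmaps must be an (H, W, N) array")
  n <- dim(bitmaps)[3]
  labels <- as.integer(labels)
  if (length(labels) != n)
    occ_error("occrnn_shape_error", "%d bitmaps but %d labels", n, length(labels))
  if (n > 0 && (min(bitmaps) < 0 || max(bitmaps) > 1))
    occ_error("occrnn_format_error", "glyph intensities must lie in [0, 1]")
  if (n > 0 && any(labels < 0L | labels >= n_classes))
    occ_error("occrnn_format_error", "labels must lie in 0..%d", n_classes - 1L)
  structure(list(bitmaps = bitmaps, labels = labels,
                 n_classes = as.integer(n_classes),
                 source = source, split = split),
            class = "glyph_corpus")
}

#' @export
length.glyph_corpus <- function(x) dim(x$bitmaps)[3]

#' @export
print.glyph_corpus <- function(x, ...) {
  d <- dim(x$bitmaps)
  cat(sprintf("<glyph_corpus: %d glyphs, %dx%d px, %d classes, %s/%s>\n",
              d[3], d[1], d[2], x$n_classes, x$source, x$split))
  invisible(x)
}

#' Extract one glyph
#' @param corpus a `glyph_corpus`.
#' @param i index (1-based).
#' @return list with `label`, `bitmap`, `source`.
#' @export
get_glyph <- function(corpus, i) {
  list(label = corpus$labels[i],
       bitmap = corpus$bitmaps[, , i],
       source = corpus$source)
}

# --- synthetic glyph templates ------------------------------------------------
# Ten parametric stroke shapes on a centered [-1, 1]^2 frame, mutually distinct
# but with soft grayscale edges like pen strokes on a black background.
# Each template is a set of line segments and/or circles; a pixel's intensity
# falls off linearly with distance from the nearest primitive.

glyph_templates <- function() {
  seg <- function(...) matrix(c(...), ncol = 4, byrow = TRUE)
  list(
    ring     = list(circles = matrix(c(0, 0, 0.60), ncol = 3)),
    cross    = list(segments = seg(-0.65, 0, 0.65, 0,   0, -0.65, 0, 0.65)),
    saltire  = list(segments = seg(-0.55, -0.55, 0.55, 0.55,
                                   -0.55, 0.55, 0.55, -0.55)),
    bars     = list(segments = seg(-0.65, -0.35, 0.65, -0.35,
                                   -0.65, 0.35, 0.65, 0.35)),
    vbar     = list(segments = seg(0, -0.70, 0, 0.70)),
    wedge    = list(segments = seg(-0.60, 0.50, 0.60, 0.50,
                                   0.60, 0.50, 0, -0.60,
                                   0, -0.60, -0.60, 0.50)),
    square   = list(segments = seg(-0.55, -0.55, 0.55, -0.55,
                                   0.55, -0.55, 0.55, 0.55,
                                   0.55, 0.55, -0.55, 0.55,
                                   -0.55, 0.55, -0.55, -0.55)),
    tee      = list(segments = seg(-0.60, -0.55, 0.60, -0.55,
                                   0, -0.55, 0, 0.65)),
    ell      = list(segments = seg(-0.45, -0.60, -0.45, 0.55,
                                   -0.45, 0.55, 0.55, 0.55)),
    zigzag   = list(segments = seg(-0.55, -0.55, 0.55, -0.55,
                                   0.55, -0.55, -0.55, 0.55,
                                   -0.55, 0.55, 0.55, 0.55))
  )
}

dist_to_segment <- function(px, py, x1, y1, x2, y2) {
  vx <- x2 - x1; vy <- y2 - y1
  len2 <- vx^2 + vy^2
  if (len2 == 0) return(sqrt((px - x1)^2 + (py - y1)^2))
  t <- clamp(((px - x1) * vx + (py - y1) * vy) / len2, 0, 1)
  sqrt((px - x1 - t * vx)^2 + (py - y1 - t * vy)^2)
}

render_template <- function(tpl, size, rot = 0, tx = 0, ty = 0,
                            stroke = 0.09, level = 1) {
  half <- (size - 1) / 2
  gx <- (col(matrix(0, size, size)) - 1 - half) / half
  gy <- (row(matrix(0, size, size)) - 1 - half) / half
  # inverse transform: rotate by -rot, then un-translate
  cs <- cos(-rot); sn <- sin(-rot)
  px <- cs * (gx - tx) - sn * (gy - ty)
  py <- sn * (gx - tx) + cs * (gy - ty)
  d <- matrix(Inf, size, size)
  if (!is.null(tpl$segments))
    for (r in seq_len(nrow(tpl$segments))) {
      s <- tpl$segments[r, ]
      d <- pmin(d, dist_to_segment(px, py, s[1], s[2], s[3], s[4]))
    }
  if (!is.null(tpl$circles))
    for (r in seq_len(nrow(tpl$circles))) {
      cc <- tpl$circles[r, ]
      d <- pmin(d, abs(sqrt((px - cc[1])^2 + (py - cc[2])^2) - cc[3]))
    }
  edge <- 1.0 / ((size - 1) / 2)  # ~1 px soft edge
  clamp((stroke + edge - d) / edge, 0, 1) * level
}

#' Generate a synthetic glyph corpus
#'
#' Ten distinct parametric stroke shapes (ring, cross, saltire, double bar,
#' vertical bar, wedge, square, T, L, zigzag) stand in for handwritten digit
#' classes. Each sample is perturbed by a rotation (within +-15 degrees), a
#' translation (within +-2 px), stroke-thickness jitter and a stroke-intensity
#' jitter, giving in-class variability while keeping classes separable.
#'
#' @param n_per_class samples per class (>= 0).
#' @param n_classes number of classes (2..10).
#' @param seed integer seed; the corpus is a pure function of the arguments.
#' @param size bitmap side length in pixels (default 28).
#' @param split corpus split tag.
#' @return a [glyph_corpus()].
#' @export
generate_synthetic_glyphs <- function(n_per_class, n_classes = 10L, seed = 1L,
                                      size = 28L, split = "train") {
  tpls <- glyph_templates()
  if (n_classes < 2L || n_classes > length(tpls))
    occ_error("occrnn_config_error",
              "n_classes must be in 2..%d, got %d", length(tpls), n_classes)
  if (n_per_class < 0L)
    occ_error("occrnn_config_error", "n_per_class must be >= 0")
  n <- n_per_class * n_classes
  bitmaps <- array(0, c(size, size, n))
  labels <- integer(n)
  if (n > 0) {
    with_seed(seed, {
      idx <- 1L
      for (cls in seq_len(n_classes) - 1L) {
        for (s in seq_len(n_per_class)) {
          rot <- runif(1, -15, 15) * pi / 180
          tx <- runif(1, -2, 2) / ((size - 1) / 2)
          ty <- runif(1, -2, 2) / ((size - 1) / 2)
          stroke <- 0.09 * runif(1, 0.75, 1.3)
          level <- runif(1, 0.75, 1)
          bitmaps[, , idx] <- render_template(tpls[[cls + 1L]], size,
                                              rot, tx, ty, stroke, level)
          labels[idx] <- cls
          idx <- idx + 1L
        }
      }
    })
  }
  glyph_corpus(bitmaps, labels, n_classes, source = "synthetic", split = split)
}

#' Binary support mask of a glyph
#'
#' @param glyph a glyph (list with `bitmap`) or a plain bitmap matrix.
#' @param threshold intensity threshold; the mask is TRUE strictly above it.
#'   The default 0.1 keeps faint strokes as object pixels.
#' @return logical matrix (H x W).
#' @export
glyph_mask <- function(glyph, threshold = 0.1) {
  bm <- if (is.list(glyph)) glyph$bitmap else glyph
  bm > threshold
}

# --- IDX container format (big-endian, as distributed with MNIST) -------------

IDX_MAGIC_IMAGES <- 2051L  # 0x00000803
IDX_MAGIC_LABELS <- 2049L  # 0x00000801

#' Read an IDX image/label file pair into a corpus
#'
#' @param image_path path to an IDX image file (magic 0x00000803).
#' @param label_path path to an IDX label file (magic 0x00000801).
#' @param n_classes number of classes (default: max label + 1).
#' @param split split tag.
#' @return a [glyph_corpus()]; pixel byte `b` maps to intensity `b / 255`.
#' @export
read_idx <- function(image_path, label_path, n_classes = NULL, split = "train") {
  for (p in c(image_path, label_path))
    if (!file.exists(p))
      occ_error("occrnn_format_error", "file not found: %s", p)
  icon <- file(image_path, "rb"); on.exit(close(icon), add = TRUE)
  magic <- readBin(icon, "integer", 1, size = 4, endian = "big")
  if (!identical(magic, IDX_MAGIC_IMAGES))
    occ_error("occrnn_format_error", "bad magic %d in image file %s",
              magic, image_path)
  hdr <- readBin(icon, "integer", 3, size = 4, endian = "big")
  n <- hdr[1]; h <- hdr[2]; w <- hdr[3]
  payload <- readBin(icon, "integer", n * h * w, size = 1, signed = FALSE)
  if (length(payload) != n * h * w)
    occ_error("occrnn_format_error",
              "truncated image payload in %s: header says %d images (%d bytes), found %d bytes",
              image_path, n, n * h * w, length(payload))
  lcon <- file(label_path, "rb"); on.exit(close(lcon), add = TRUE)
  lmagic <- readBin(lcon, "integer", 1, size = 4, endian = "big")
  if (!identical(lmagic, IDX_MAGIC_LABELS))
    occ_error("occrnn_format_error", "bad magic %d in label file %s",
              lmagic, label_path)
  nl <- readBin(lcon, "integer", 1, size = 4, endian = "big")
  labels <- readBin(lcon, "integer", nl, size = 1, signed = FALSE)
  if (length(labels) != nl)
    occ_error("occrnn_format_error", "truncated label payload in %s", label_path)
  if (nl != n)
    occ_error("occrnn_format_error",
              "image/label count mismatch: %d images in %s, %d labels in %s",
              n, image_path, nl, label_path)
  # IDX stores row-major (row index varies slowest within an image)
  bitmaps <- array(0, c(h, w, n))
  if (n > 0) {
    px <- array(payload / 255, c(w, h, n))
    bitmaps <- aperm(px, c(2, 1, 3))
  }
  glyph_corpus(bitmaps, labels,
               n_classes %||% (if (n > 0) max(labels) + 1L else 0L),
               source = "idx_file", split = split)
}

#' Write a corpus as an IDX image/label file pair
#' @param corpus a [glyph_corpus()].
#' @param image_path,label_path output paths.
#' @return invisibly, the two paths.
#' @export
write_idx <- function(corpus, image_path, label_path) {
  d <- dim(corpus$bitmaps)
  icon <- file(image_path, "wb"); on.exit(close(icon), add = TRUE)
  writeBin(c(IDX_MAGIC_IMAGES, d[3], d[1], d[2]), icon, size = 4, endian = "big")
  bytes <- as.integer(round(aperm(corpus$bitmaps, c(2, 1, 3)) * 255))
  writeBin(as.raw(bytes), icon)
  lcon <- file(label_path, "wb"); on.exit(close(lcon), add = TRUE)
  writeBin(c(IDX_MAGIC_LABELS, d[3]), lcon, size = 4, endian = "big")
  writeBin(as.raw(corpus$labels), lcon)
  invisible(c(image_path, label_path))
}

# --- plain-text image export --------------------------------------------------

#' Write a grayscale image as a plain-text PGM (P2) file
#'
#' Used for inspecting glyphs and exporting rendered scenes; no binary image
#' library is required.
#' @param img numeric matrix with values in \[0, 1\].
#' @param path output file.
#' @export
write_pgm <- function(img, path) {
  v <- matrix(as.integer(round(clamp(img, 0, 1) * 255)), nrow(img), ncol(img))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(img), nrow(img)), "255"), con)
  writeLines(apply(v, 1L, paste, collapse = " "), con)  # row-major pixel order
  invisible(path)
}

#' Read a plain-text PGM (P2) file
#' @param path input file.
#' @return numeric matrix with values in \[0, 1\].
#' @export
read_pgm <- function(path) {
  txt <- readLines(path)
  txt <- txt[!grepl("^#", txt)]
  tok <- scan(text = paste(txt[-1], collapse = " "), quiet = TRUE)
  w <- tok[1]; h <- tok[2]; maxv <- tok[3]
  matrix(tok[-(1:3)], nrow = h, ncol = w, byrow = TRUE) / maxv
}
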