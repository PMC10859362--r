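# Seeded synthetic image fixtures.
#
# Each class is a distinct (shape, hue) family drawn centered on a white
# background — emulating the layout and photographic conventions of produce
# datasets shot on white paper — with per-image jitter in size, rotation,
# position, hue and additive pixel noise. Generation is deterministic under
# the seed, and images are quantized to 8 bits so that an on-disk PNG
# round-trip is exact.

FIXTURE_SHAPES <- c("disc", "square", "triangle", "ring", "cross", "diamond")

#' Synthetic fixture specification
#'
#' @param num_classes number of classes K (>= 2).
#' @param images_per_class images generated per class (>= 1).
#' @param image_size square image side length in pixels (>= 32).
#' @param seed integer seed; generation is byte-identical under the same
#'   seed.
#' @param noise_sd standard deviation of additive Gaussian pixel noise
#'   (pixel units in `[0, 1]`).
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(num_classes = 5L, images_per_class = 20L,
                         image_size = 100L, seed = 1L, noise_sd = 0.02) {
  num_classes <- as.integer(num_classes)
  images_per_class <- as.integer(images_per_class)
  image_size <- as.integer(image_size)
  if (num_classes < 2L) stop("`num_classes` must be >= 2", call. = FALSE)
  if (images_per_class < 1L) stop("`images_per_class` must be >= 1",
                                  call. = FALSE)
  if (image_size < 32L) stop("`image_size` must be >= 32", call. = FALSE)
  structure(list(num_classes = num_classes,
                 images_per_class = images_per_class,
                 image_size = image_size, seed = as.integer(seed),
                 noise_sd = noise_sd),
            class = "fixture_spec")
}

# Signed membership test of rotated, scaled shape families on a [-1,1]^2 grid.
shape_mask <- function(shape, n, size, rot, cx, cy) {
  g <- seq(-1, 1, length.out = n)
  xx <- outer(rep(1, n), g) - cx
  yy <- outer(g, rep(1, n)) - cy
  xr <- cos(rot) * xx + sin(rot) * yy
  yr <- -sin(rot) * xx + cos(rot) * yy
  switch(shape,
    disc = sqrt(xr^2 + yr^2) <= size,
    square = pmax(abs(xr), abs(yr)) <= size,
    triangle = (yr >= -size) & (abs(xr) <= (size - yr) / 2),
    ring = {
      r <- sqrt(xr^2 + yr^2)
      r <= size & r >= 0.55 * size
    },
    cross = (abs(xr) <= 0.35 * size & abs(yr) <= size) |
      (abs(yr) <= 0.35 * size & abs(xr) <= size),
    diamond = abs(xr) + abs(yr) <= size,
    stop(sprintf("unknown shape '%s'", shape), call. = FALSE)
  )
}

draw_fixture_image <- function(shape, hue, n, noise_sd) {
  size <- stats::runif(1, 0.30, 0.42)
  rot <- stats::runif(1, 0, 2 * pi)
  cx <- stats::runif(1, -0.08, 0.08)
  cy <- stats::runif(1, -0.08, 0.08)
  h <- (hue + stats::runif(1, -0.02, 0.02)) %% 1
  v <- stats::runif(1, 0.75, 0.95)
  s <- stats::runif(1, 0.75, 0.95)
  rgb <- grDevices::col2rgb(grDevices::hsv(h, s, v)) / 255
  mask <- shape_mask(shape, n, size, rot, cx, cy)
  img <- array(1, dim = c(n, n, 3L))
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[mask] <- rgb[ch]
    img[, , ch] <- plane
  }
  if (noise_sd > 0) {
    img <- img + stats::rnorm(length(img), sd = noise_sd)
    img[img < 0] <- 0
    img[img > 1] <- 1
  }
  round(img * 255) / 255      # 8-bit quantization, matches PNG round-trip
}

#' Generate a synthetic class-per-folder fixture dataset
#'
#' Each class k is assigned a shape (cycled from disc, square, triangle,
#' ring, cross, diamond) and a base hue evenly spaced on the color wheel, so
#' classes are separable by color and form. With `dir` given, images are
#' additionally written as `dir/class<k>/img<i>.png` in the same
#' class-per-folder convention the loader reads.
#'
#' @param spec a [fixture_spec()].
#' @param dir optional output directory for the on-disk fixture tree.
#' @return a `labeled_image_set` with provenance `"synthetic"`.
#' @export
generate_fixture <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  K <- spec$num_classes
  shapes <- rep_len(FIXTURE_SHAPES, K)
  hues <- (seq_len(K) - 1L) / K
  class_names <- sprintf("class%02d_%s", seq_len(K) - 1L, shapes)
  images <- vector("list", K * spec$images_per_class)
  labels <- integer(K * spec$images_per_class)
  withr::with_seed(spec$seed, {
    pos <- 0L
    for (k in seq_len(K)) {
      for (i in seq_len(spec$images_per_class)) {
        pos <- pos + 1L
        images[[pos]] <- draw_fixture_image(shapes[k], hues[k],
                                            spec$image_size, spec$noise_sd)
        labels[pos] <- k - 1L
      }
    }
  })
  ds <- new_labeled_image_set(images, labels, class_names, "synthetic")
  if (!is.null(dir)) {
    for (k in seq_len(K)) {
      d <- file.path(dir, class_names[k])
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
    }
    for (i in seq_along(images)) {
      cls <- class_names[labels[i] + 1L]
      n_in_class <- sum(labels[seq_len(i)] == labels[i])
      png::writePNG(images[[i]],
                    file.path(dir, cls, sprintf("img%03d.png", n_in_class)))
    }
  }
  ds
}
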