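# Class-per-folder image datasets (Fruit-360 convention), stratified
# splitting and preprocessing.
#
# A labeled image set holds decoded images as (h, w, 3) arrays in [0, 1],
# 0-based integer labels, and the lexicographically sorted class names. Class
# index = rank of the subdirectory name under locale-independent (byte order)
# sorting, so label assignment is identical across machines.

new_labeled_image_set <- function(images, labels, class_names, provenance) {
  structure(list(images = images, labels = as.integer(labels),
                 class_names = class_names, provenance = provenance),
            class = "labeled_image_set")
}

#' @export
print.labeled_image_set <- function(x, ...) {
  cat(sprintf("labeled image set: %d images, %d classes (%s)\n",
              length(x$images), length(x$class_names), x$provenance))
  invisible(x)
}

#' @export
length.labeled_image_set <- function(x) length(x$images)

subset_image_set <- function(ds, idx) {
  new_labeled_image_set(ds$images[idx], ds$labels[idx], ds$class_names,
                        ds$provenance)
}

# Decode one image file to an (h, w, 3) array in [0, 1]. PNG via the png
# package; JPEG via EBImage when available. Grayscale is replicated to three
# channels, alpha is dropped.
read_image_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop("JPEG decoding requires the EBImage package", call. = FALSE)
    }
    img <- EBImage::imageData(EBImage::readImage(path))
    if (length(dim(img)) == 3L) img <- aperm(img, c(2L, 1L, 3L))
    else img <- t(img)
  } else {
    stop(sprintf("unsupported image format: %s", path), call. = FALSE)
  }
  if (length(dim(img)) == 2L) img <- array(img, dim = c(dim(img), 1L))
  if (dim(img)[3L] == 1L) img <- img[, , c(1L, 1L, 1L), drop = FALSE]
  if (dim(img)[3L] == 4L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Load a class-per-folder image dataset
#'
#' Reads every decodable image under `root/<class>/*`, assigning class index
#' by the lexicographic (byte-order) rank of the subdirectory name.
#' Undecodable files are skipped with a warning unless `strict = TRUE`.
#'
#' @param root directory containing one subdirectory per class.
#' @param strict error (rather than warn and skip) on undecodable files.
#' @return a `labeled_image_set`.
#' @export
load_image_folder <- function(root, strict = FALSE) {
  if (!dir.exists(root)) stop(sprintf("no such directory: %s", root),
                              call. = FALSE)
  classes <- list.dirs(root, full.names = FALSE, recursive = FALSE)
  classes <- sort(classes, method = "radix")
  if (length(classes) < 2L) {
    stop("dataset root must contain at least 2 class subdirectories",
         call. = FALSE)
  }
  images <- list()
  labels <- integer(0)
  for (k in seq_along(classes)) {
    files <- sort(list.files(file.path(root, classes[k]), full.names = TRUE),
                  method = "radix")
    for (f in files) {
      img <- tryCatch(read_image_file(f), error = function(e) e)
      if (inherits(img, "error")) {
        if (strict) stop(sprintf("failed to decode %s: %s", f,
                                 conditionMessage(img)), call. = FALSE)
        warning(sprintf("skipping undecodable file %s", f), call. = FALSE)
        next
      }
      images[[length(images) + 1L]] <- img
      labels <- c(labels, k - 1L)
    }
  }
  if (length(images) == 0L) stop("no decodable images found", call. = FALSE)
  new_labeled_image_set(images, labels, classes, "disk")
}

#' Stratified dataset split
#'
#' Splits per class under a seeded shuffle. Partition sizes per class follow
#' the largest-remainder rule, so realized proportions are within one image
#' of the requested fractions; partitions are disjoint and their union is the
#' input.
#'
#' @param ds a `labeled_image_set`.
#' @param fractions named or unnamed numeric vector summing to 1, one entry
#'   per partition (e.g. `c(train = 0.8, val = 0.2)`).
#' @param seed integer seed for the per-class shuffles.
#' @return named list of `labeled_image_set` partitions.
#' @export
stratified_split <- function(ds, fractions = c(train = 0.8, val = 0.2),
                             seed = 1L) {
  if (any(fractions <= 0) || abs(sum(fractions) - 1) > 1e-9) {
    stop("`fractions` must be positive and sum to 1", call. = FALSE)
  }
  np <- length(fractions)
  if (is.null(names(fractions))) {
    names(fractions) <- c("train", "val", "test")[seq_len(np)]
  }
  parts <- lapply(seq_len(np), function(i) integer(0))
  names(parts) <- names(fractions)
  withr::with_seed(as.integer(seed), {
    for (k in sort(unique(ds$labels))) {
      idx <- which(ds$labels == k)
      if (length(idx) < np) {
        stop(sprintf("class %s has only %d image(s), fewer than the %d requested partitions",
                     ds$class_names[k + 1L], length(idx), np), call. = FALSE)
      }
      idx <- idx[sample.int(length(idx))]
      sizes <- floor(fractions * length(idx))
      rem <- length(idx) - sum(sizes)
      if (rem > 0L) {
        frac_rem <- fractions * length(idx) - sizes
        bump <- order(frac_rem, decreasing = TRUE)[seq_len(rem)]
        sizes[bump] <- sizes[bump] + 1L
      }
      if (any(sizes < 1L)) {
        stop(sprintf("class %s is too small for the requested split",
                     ds$class_names[k + 1L]), call. = FALSE)
      }
      offset <- 0L
      for (i in seq_len(np)) {
        take <- idx[offset + seq_len(sizes[i])]
        parts[[i]] <- c(parts[[i]], take)
        offset <- offset + sizes[i]
      }
    }
  })
  lapply(parts, function(idx) subset_image_set(ds, sort(idx)))
}

#' Write a split manifest
#'
#' @param parts result of [stratified_split()].
#' @param path CSV output path; columns `index`, `class`, `partition`.
#' @export
write_split_manifest <- function(parts, path) {
  rows <- do.call(rbind, lapply(names(parts), function(nm) {
    p <- parts[[nm]]
    data.frame(class = p$class_names[p$labels + 1L], partition = nm,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

# Separable bilinear interpolation weights mapping `n_in` samples to `n_out`,
# with half-pixel-center alignment. Rows sum to 1.
bilinear_weights <- function(n_in, n_out) {
  W <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  for (o in seq_len(n_out)) {
    src <- (o - 0.5) * scale - 0.5       # 0-based source coordinate
    i0 <- floor(src)
    frac <- src - i0
    lo <- min(max(i0, 0), n_in - 1) + 1
    hi <- min(max(i0 + 1, 0), n_in - 1) + 1
    W[o, lo] <- W[o, lo] + (1 - frac)
    W[o, hi] <- W[o, hi] + frac
  }
  W
}

#' Preprocess one image for the network
#'
#' Resizes with separable bilinear interpolation (half-pixel-center
#' convention) to `size` x `size` and maps pixel values linearly from
#' `[0, 1]` to `[-1, 1]`. Integer input in 0..255 is rescaled to `[0, 1]`
#' first; input
#' containing negative values is taken to be already scaled and is passed
#' through unchanged (which makes the function idempotent).
#'
#' @param image (h, w, 3) numeric array.
#' @param size target side length.
#' @return (size, size, 3) array with values in `[-1, 1]`.
#' @export
preprocess_image <- function(image, size = 100L) {
  if (length(dim(image)) != 3L || dim(image)[3L] != 3L) {
    stop("`image` must be an (h, w, 3) array", call. = FALSE)
  }
  if (max(image) > 1 + 1e-8) image <- image / 255
  already_scaled <- min(image) < -1e-8
  d <- dim(image)
  if (d[1L] != size || d[2L] != size) {
    Wr <- bilinear_weights(d[1L], size)
    Wc <- bilinear_weights(d[2L], size)
    out <- array(0, dim = c(size, size, 3L))
    for (ch in 1:3) out[, , ch] <- Wr %*% image[, , ch] %*% t(Wc)
    image <- out
  }
  if (already_scaled) image else image * 2 - 1
}

# Stack a dataset (or an index subset) into a (b, size, size, 3) batch tensor.
as_batch_tensor <- function(ds, idx = seq_along(ds$images), size = 100L) {
  b <- length(idx)
  out <- array(0, dim = c(b, size, size, 3L))
  for (i in seq_len(b)) {
    out[i, , , ] <- preprocess_image(ds$images[[idx[i]]], size)
  }
  out
}
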