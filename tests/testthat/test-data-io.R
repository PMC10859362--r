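# Image folder IO, splitting, preprocessing, synthetic fixtures.

small_fixture <- function(K = 3, n = 4, size = 32, seed = 1, dir = NULL) {
  generate_fixture(fixture_spec(K, n, size, seed), dir = dir)
}

test_that("fixture generation is deterministic and byte-identical under a seed", {
  a <- small_fixture(seed = 7)
  b <- small_fixture(seed = 7)
  expect_identical(a, b)
  c <- small_fixture(seed = 8)
  expect_false(identical(a$images, c$images))

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  small_fixture(seed = 7, dir = d1)
  small_fixture(seed = 7, dir = d2)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
})

test_that("noise-free fixtures differ only by the declared jitters", {
  ds <- generate_fixture(fixture_spec(2, 3, 32, seed = 3, noise_sd = 0))
  # same class: same shape/hue family, but jitter changes the drawing
  expect_false(identical(ds$images[[1]], ds$images[[2]]))
  # white background everywhere outside the object
  expect_equal(max(ds$images[[1]]), 1)
})

test_that("fixture trees round-trip through the folder loader", {
  dir <- withr::local_tempdir()
  ds <- small_fixture(K = 5, n = 4, dir = dir)
  back <- load_image_folder(dir)
  expect_identical(length(back$images), length(ds$images))
  expect_identical(back$labels, ds$labels)
  expect_identical(back$class_names, ds$class_names)
  # 8-bit PNG round-trip is exact because generation quantizes
  expect_equal(back$images[[1]], ds$images[[1]], tolerance = 1e-12)
})

test_that("loader sorts classes bytewise and rejects degenerate trees", {
  dir <- withr::local_tempdir()
  for (cl in c("zucchini", "Apple", "banana")) {
    dir.create(file.path(dir, cl))
    png::writePNG(array(stats::runif(16 * 16 * 3), c(16, 16, 3)),
                  file.path(dir, cl, "img.png"))
  }
  ds <- load_image_folder(dir)
  expect_identical(ds$class_names, sort(c("zucchini", "Apple", "banana"),
                                        method = "radix"))

  solo <- withr::local_tempdir()
  dir.create(file.path(solo, "only"))
  png::writePNG(array(0.5, c(8, 8, 3)), file.path(solo, "only", "img.png"))
  expect_error(load_image_folder(solo), "at least 2")

  # non-image file is skipped with a warning, not an error
  writeLines("not an image", file.path(dir, "banana", "notes.png"))
  expect_warning(ds2 <- load_image_folder(dir), "skipping")
  expect_identical(length(ds2$images), 3L)
  expect_error(load_image_folder(dir, strict = TRUE), "failed to decode")
})

test_that("JPEG images decode through EBImage to the same layout as PNG", {
  # smooth gradient: JPEG is near-lossless there, unlike on noise
  img <- array(0, c(20, 24, 3))
  img[, , 1] <- outer(seq(0, 1, length.out = 20), rep(1, 24))
  img[, , 2] <- outer(rep(1, 20), seq(0, 1, length.out = 24))
  img[, , 3] <- 0.5
  png_path <- withr::local_tempfile(fileext = ".png")
  jpg_path <- withr::local_tempfile(fileext = ".jpg")
  png::writePNG(img, png_path)
  EBImage::writeImage(EBImage::Image(aperm(img, c(2, 1, 3)),
                                     colormode = "Color"),
                      jpg_path, quality = 100)
  from_png <- fruitnet:::read_image_file(png_path)
  from_jpg <- fruitnet:::read_image_file(jpg_path)
  expect_identical(dim(from_jpg), c(20L, 24L, 3L))
  # lossy codec: agreement only within compression error
  expect_lt(mean(abs(from_jpg - from_png)), 0.02)
})

test_that("stratified split hits exact per-class sizes and is seed-stable", {
  ds <- small_fixture(K = 5, n = 20)
  parts <- stratified_split(ds, c(train = 0.8, val = 0.2), seed = 11)
  expect_identical(length(parts$train$images), 80L)
  expect_identical(length(parts$val$images), 20L)
  for (k in 0:4) {
    expect_identical(sum(parts$train$labels == k), 16L)
    expect_identical(sum(parts$val$labels == k), 4L)
  }
  parts2 <- stratified_split(ds, c(train = 0.8, val = 0.2), seed = 11)
  expect_identical(parts, parts2)
  parts3 <- stratified_split(ds, c(train = 0.8, val = 0.2), seed = 12)
  expect_false(identical(parts$train$labels, parts3$train$labels) &&
                 identical(parts$train$images, parts3$train$images))
})

test_that("split partitions are disjoint with union equal to the input", {
  # random label sets over a dummy image list
  withr::with_seed(21, {
    for (rep_i in 1:25) {
      n <- sample(30:60, 1)
      K <- sample(2:4, 1)
      labels <- sample(0:(K - 1), n, replace = TRUE)
      while (min(tabulate(labels + 1, K)) < 3) {
        labels <- sample(0:(K - 1), n, replace = TRUE)
      }
      imgs <- lapply(seq_len(n), function(i) array(i, c(1, 1, 3)))
      ds <- fruitnet:::new_labeled_image_set(imgs, labels,
                                             paste0("c", 1:K), "synthetic")
      parts <- stratified_split(ds, c(a = 0.5, b = 0.3, c = 0.2),
                                seed = rep_i)
      ids <- lapply(parts, function(p) vapply(p$images, function(m) m[1, 1, 1],
                                              numeric(1)))
      expect_identical(sum(lengths(ids)), n)
      expect_identical(anyDuplicated(unlist(ids)), 0L)
      expect_setequal(unlist(ids), seq_len(n))
    }
  })
  expect_error(stratified_split(small_fixture(K = 2, n = 2),
                                c(a = 0.4, b = 0.3, c = 0.3), seed = 1),
               "fewer than")
})

test_that("preprocessing resizes bilinearly and maps to [-1, 1]", {
  img <- array(stats::runif(100 * 100 * 3), c(100, 100, 3))
  out <- preprocess_image(img, 100)
  expect_identical(dim(out), c(100L, 100L, 3L))
  expect_equal(out, img * 2 - 1, tolerance = 1e-12)

  white <- array(1, c(50, 50, 3))
  expect_true(all(preprocess_image(white, 50) == 1))

  # checkerboard 200x200 -> 100x100 equals the separable bilinear oracle
  cb <- array(0, c(200, 200, 3))
  cb[] <- (outer(1:200, 1:200, function(i, j) (i + j) %% 2))
  got <- preprocess_image(cb, 100)
  want <- oracle_bilinear(cb, 100) * 2 - 1
  expect_equal(got, want, tolerance = 1e-12)

  # idempotence on already-sized, already-scaled input
  expect_equal(preprocess_image(out, 100), out, tolerance = 1e-12)

  # 0..255 integer input is rescaled first
  img255 <- array(255, c(40, 40, 3))
  expect_true(all(preprocess_image(img255, 40) == 1))
})

test_that("split manifest records every image with its partition", {
  ds <- small_fixture(K = 3, n = 6)
  parts <- stratified_split(ds, c(train = 0.5, val = 0.5), seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_split_manifest(parts, path)
  man <- utils::read.csv(path)
  expect_identical(nrow(man), 18L)
  expect_setequal(unique(man$partition), c("train", "val"))
})
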