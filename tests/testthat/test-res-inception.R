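# Res-Inception inverted-residual block.

test_that("block_spec validates its invariants", {
  s <- block_spec(16, 16, stride = 1)
  expect_identical(s$kernels, c(3L, 5L, 7L))
  expect_true(s$use_residual)
  s2 <- block_spec(16, 24, stride = 2)
  expect_identical(s2$kernels, 3L)
  expect_false(s2$use_residual)
  expect_error(block_spec(16, 16, stride = 3), "stride")
  expect_error(block_spec(16, 16, kernels = c(3, 4)), "odd")
  expect_error(block_spec(16, 24, stride = 1, use_residual = TRUE),
               "matching channel counts")
})

test_that("zero weights with a residual skip give the exact identity map", {
  spec <- block_spec(16, 16, stride = 1, expansion = 6)
  params <- fruitnet:::param_zeros_like(withr::with_seed(1, fruitnet:::block_init(spec)))
  x <- seeded_array(2, c(2, 5, 5, 16))
  y <- block_forward(x, params, spec, training = TRUE)$y
  expect_identical(y, x)
  y2 <- block_forward(x, params, spec, training = FALSE)$y
  expect_identical(y2, x)
})

test_that("stride-2 blocks halve spatial dimensions (ceiling division)", {
  spec <- block_spec(16, 24, stride = 2, expansion = 6)
  params <- withr::with_seed(3, fruitnet:::block_init(spec))
  x <- seeded_array(4, c(1, 8, 8, 16))
  expect_identical(dim(block_forward(x, params, spec)$y), c(1L, 4L, 4L, 24L))
  x2 <- seeded_array(5, c(1, 7, 9, 16))
  expect_identical(dim(block_forward(x2, params, spec)$y), c(1L, 4L, 5L, 24L))
})

test_that("shape law holds across strides, expansions and channel widths", {
  for (s in c(1L, 2L)) for (t in c(1L, 6L)) for (cin in c(8L, 16L)) {
    cout <- if (s == 1L) cin else 2L * cin
    spec <- block_spec(cin, cout, stride = s, expansion = t)
    params <- withr::with_seed(s + t + cin, fruitnet:::block_init(spec))
    x <- seeded_array(7, c(2, 6, 6, cin))
    y <- block_forward(x, params, spec)$y
    expect_identical(dim(y), c(2L, as.integer(ceiling(6 / s)),
                               as.integer(ceiling(6 / s)), cout))
  }
})

test_that("convolution primitives match explicit-loop oracles", {
  x <- seeded_array(11, c(1, 6, 6, 8))
  wd <- seeded_array(12, c(3, 3, 8))
  expect_equal(fruitnet:::dwconv_fw(x, wd, stride = 1L), oracle_dwconv(x, wd, 1),
               tolerance = 1e-12)
  expect_equal(fruitnet:::dwconv_fw(x, wd, stride = 2L), oracle_dwconv(x, wd, 2),
               tolerance = 1e-12)
  w5 <- seeded_array(13, c(5, 5, 8))
  expect_equal(fruitnet:::dwconv_fw(x, w5, stride = 1L), oracle_dwconv(x, w5, 1),
               tolerance = 1e-12)
  wc <- seeded_array(14, c(3, 3, 8, 4))
  expect_equal(fruitnet:::conv2d_fw(x, wc, stride = 2L), oracle_conv2d(x, wc, 2),
               tolerance = 1e-10)
  wg <- seeded_array(15, c(3, 3, 2, 8))
  expect_equal(fruitnet:::conv2d_fw(x, wg, stride = 1L, groups = 4L),
               oracle_gconv(x, wg, 4, 1), tolerance = 1e-10)
})

test_that("closed-form parameter count equals the instantiated count", {
  specs <- list()
  for (s in c(1L, 2L)) for (t in c(1L, 6L)) for (cin in c(8L, 16L, 32L)) {
    specs[[length(specs) + 1L]] <- block_spec(cin, cin, stride = s,
                                              expansion = t)
  }
  expect_length(specs, 12L)
  for (spec in specs) {
    built <- withr::with_seed(1, fruitnet:::block_init(spec))
    expect_identical(block_param_count(spec),
                     as.integer(fruitnet:::param_count(built)))
  }
  # hand-checked atoms: depthwise 3x3 on 8 channels = 72 weights, and a
  # pointwise 8 -> 16 projection = 128 weights (plus 2 per normalized channel)
  lone_dw <- block_spec(8, 8, stride = 1, expansion = 1, kernels = 3,
                        use_residual = FALSE)
  expect_identical(block_param_count(lone_dw),
                   72L + 2L * 8L + 8L * 8L + 2L * 8L)
})

test_that("stride-2 path is bit-identical to the plain inverted residual", {
  # at stride 2 the default kernel set collapses to {3}: the Res-Inception
  # additions are inert there
  spec_a <- block_spec(16, 24, stride = 2, expansion = 6)
  spec_b <- block_spec(16, 24, stride = 2, expansion = 6, kernels = 3L)
  pa <- withr::with_seed(21, fruitnet:::block_init(spec_a))
  pb <- withr::with_seed(21, fruitnet:::block_init(spec_b))
  expect_identical(pa, pb)
  x <- seeded_array(22, c(2, 8, 8, 16))
  expect_identical(block_forward(x, pa, spec_a)$y,
                   block_forward(x, pb, spec_b)$y)
})

test_that("block rejects mismatched channels", {
  spec <- block_spec(16, 16, stride = 1)
  params <- withr::with_seed(31, fruitnet:::block_init(spec))
  x <- seeded_array(32, c(1, 4, 4, 8))
  expect_error(block_forward(x, params, spec), "expects 16")
})

test_that("block backward agrees with numeric directional derivatives", {
  spec <- block_spec(4, 4, stride = 1, expansion = 2)
  params <- withr::with_seed(41, fruitnet:::block_init(spec))
  x <- seeded_array(42, c(2, 5, 5, 4))
  R <- seeded_array(43, c(2, 5, 5, 4))
  fw <- block_forward(x, params, spec, training = TRUE, want_cache = TRUE)
  bw <- fruitnet:::block_backward(R, fw$cache, params, spec)
  f <- function(xx) sum(block_forward(xx, params, spec, training = TRUE)$y * R)
  eps <- 1e-6
  for (i in withr::with_seed(44, sample(length(x), 8))) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    expect_equal(bw$dx[i], (f(xp) - f(xm)) / (2 * eps), tolerance = 1e-4)
  }
  # one weight per component family
  fun_w <- function(get, set) {
    w0 <- get(params)
    g <- get(bw$grads)
    i <- withr::with_seed(45, sample(length(w0), 2))
    for (ii in i) {
      p2 <- set(params, ii, eps)
      p3 <- set(params, ii, -eps)
      num <- (sum(block_forward(x, p2, spec, training = TRUE)$y * R) -
                sum(block_forward(x, p3, spec, training = TRUE)$y * R)) /
        (2 * eps)
      expect_equal(g[ii], num, tolerance = 1e-4)
    }
  }
  fun_w(function(p) p$branches$k5$W,
        function(p, i, d) { p$branches$k5$W[i] <- p$branches$k5$W[i] + d; p })
  fun_w(function(p) p$proj$gamma,
        function(p, i, d) { p$proj$gamma[i] <- p$proj$gamma[i] + d; p })
  fun_w(function(p) p$expand$W,
        function(p, i, d) { p$expand$W[i] <- p$expand$W[i] + d; p })
})
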