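# Efficient multi-scale attention module.

test_that("channel groups split and reassemble exactly", {
  x <- seeded_array(11, c(2, 8, 8, 16))
  parts <- split_into_groups(x, 8)
  expect_length(parts, 8)
  for (p in parts) expect_identical(dim(p), c(2L, 8L, 8L, 2L))
  expect_identical(merge_groups(parts), x)

  expect_identical(split_into_groups(x, 1)[[1]], x)

  x2 <- seeded_array(12, c(1, 4, 4, 8))
  expect_identical(merge_groups(split_into_groups(x2, 4)), x2)

  expect_error(split_into_groups(x, 3), "not divisible")
  expect_error(split_into_groups(seeded_array(1, c(1, 2, 2, 10)), 8),
               "c = 10.*g = 8")
})

test_that("directional pooling matches the per-row/per-column mean oracle", {
  const <- array(3, dim = c(2, 3, 4, 2))
  expect_equal(pool_directional(const, "horizontal"),
               array(3, dim = c(2, 3, 1, 2)))
  expect_equal(pool_directional(const, "vertical"),
               array(3, dim = c(2, 1, 4, 2)))

  row <- array(c(4, 6), dim = c(1, 1, 2, 1))
  expect_equal(as.numeric(pool_directional(row, "horizontal")), 5)

  x <- seeded_array(21, c(1, 5, 7, 2))
  expect_equal(pool_directional(x, "horizontal"), oracle_pool_h(x),
               tolerance = 1e-12)
  expect_equal(pool_directional(x, "vertical"), oracle_pool_v(x),
               tolerance = 1e-12)

  expect_error(pool_directional(x, "diagonal"))
})

test_that("global pooling equals the triple-loop mean", {
  const <- array(5, dim = c(3, 4, 6, 2))
  expect_equal(pool_global(const), matrix(5, 3, 2))

  sq <- array(c(1, 3, 2, 4), dim = c(1, 2, 2, 1))   # [[1,2],[3,4]]
  expect_equal(as.numeric(pool_global(sq)), 2.5)

  x <- seeded_array(22, c(1, 6, 6, 4))
  expect_equal(pool_global(x), oracle_pool_global(x), tolerance = 1e-9)
})

test_that("cross-spatial maps follow the descriptor/branch matrix product", {
  # spatially constant 3x3 branch forces a spatially constant first map
  t1 <- seeded_array(31, c(2, 4, 4, 3))
  t3c <- array(rep(seq_len(2 * 3), each = 1), dim = c(2, 1, 1, 3))
  t3c <- t3c[, rep(1, 4), rep(1, 4), , drop = FALSE]
  m <- cross_spatial_maps(t1, t3c)
  expect_lt(max(abs(sweep(m$map1, 1, m$map1[, 1, 1]))), 1e-12)

  # identical branches make the two constructions coincide
  m2 <- cross_spatial_maps(t1, t1)
  expect_equal(m2$map1, m2$map2, tolerance = 1e-12)

  # dense loop oracle
  t3 <- seeded_array(32, c(2, 4, 4, 2))
  t1b <- seeded_array(33, c(2, 4, 4, 2))
  got <- cross_spatial_maps(t1b, t3)
  want <- oracle_cross_maps(t1b, t3)
  expect_equal(got$map1, want$map1, tolerance = 1e-9)
  expect_equal(got$map2, want$map2, tolerance = 1e-9)

  expect_error(cross_spatial_maps(t1, t3), "identical dimensions")
})

test_that("ema_forward preserves shape and matches the straight-line reference", {
  cfg <- ema_config(16L, 8L)
  p <- withr::with_seed(41, fruitnet:::ema_init(cfg))
  x <- seeded_array(42, c(2, 8, 8, 16))
  y <- ema_forward(x, p, cfg)
  expect_identical(dim(y), dim(x))

  expect_error(ema_config(10L, 8L), "not divisible")

  cfg2 <- ema_config(8L, 4L)
  p2 <- withr::with_seed(43, fruitnet:::ema_init(cfg2))
  x2 <- seeded_array(44, c(1, 4, 4, 8))
  expect_equal(ema_forward(x2, p2, cfg2), oracle_ema(x2, p2, 4),
               tolerance = 1e-8)
})

test_that("ema output shape is conserved over the (b, hw, c, g) grid", {
  for (b in c(1L, 2L)) {
    for (hw in c(2L, 4L, 8L)) {
      for (ch in c(8L, 16L, 32L)) {
        for (g in c(1L, 2L, 4L, 8L)) {
          cfg <- ema_config(ch, g)
          p <- withr::with_seed(50 + g, fruitnet:::ema_init(cfg))
          x <- seeded_array(100 * b + 10 * hw + ch + g, c(b, hw, hw, ch))
          y <- ema_forward(x, p, cfg)
          expect_identical(dim(y), c(b, hw, hw, ch))
        }
      }
    }
  }
})

test_that("sigmoid gates are strictly inside (0,1), bounding the output", {
  cfg <- ema_config(16L, 8L)
  p <- withr::with_seed(61, fruitnet:::ema_init(cfg))
  x <- seeded_array(62, c(2, 6, 6, 16))
  fw <- ema_forward(x, p, cfg, want_cache = TRUE)
  gates <- as.numeric(fw$cache$wf)
  expect_true(all(gates > 0 & gates < 1))
  # multiplicative gating by a value in (0,1) can only shrink magnitudes
  expect_true(all(abs(fw$y) <= abs(x) + 1e-12))
})

test_that("degenerate cases (g = 1, 1x1 spatial) run and preserve shape", {
  cfg <- ema_config(4L, 1L)
  p <- withr::with_seed(71, fruitnet:::ema_init(cfg))
  x <- seeded_array(72, c(2, 3, 3, 4))
  expect_identical(dim(ema_forward(x, p, cfg)), dim(x))

  cfg2 <- ema_config(8L, 2L)
  p2 <- withr::with_seed(73, fruitnet:::ema_init(cfg2))
  x2 <- seeded_array(74, c(2, 1, 1, 8))
  expect_identical(dim(ema_forward(x2, p2, cfg2)), dim(x2))
})

test_that("ema backward agrees with numeric directional derivatives", {
  cfg <- ema_config(8L, 2L)
  p <- withr::with_seed(81, fruitnet:::ema_init(cfg))
  x <- seeded_array(82, c(2, 4, 4, 8))
  R <- seeded_array(83, c(2, 4, 4, 8))
  fw <- ema_forward(x, p, cfg, want_cache = TRUE)
  bw <- fruitnet:::ema_backward(R, fw$cache, p, cfg)
  f <- function(xx) sum(ema_forward(xx, p, cfg) * R)
  eps <- 1e-6
  for (i in withr::with_seed(84, sample(length(x), 8))) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    num <- (f(xp) - f(xm)) / (2 * eps)
    expect_equal(bw$dx[i], num, tolerance = 1e-4)
  }
  for (nm in c("W1", "b1", "W3", "b3")) {
    g <- bw$grads[[nm]]
    for (i in withr::with_seed(85, sample(length(p[[nm]]), 4))) {
      p2 <- p; p2[[nm]][i] <- p2[[nm]][i] + eps
      p3 <- p; p3[[nm]][i] <- p3[[nm]][i] - eps
      num <- (sum(ema_forward(x, p2, cfg) * R) -
                sum(ema_forward(x, p3, cfg) * R)) / (2 * eps)
      expect_equal(g[i], num, tolerance = 1e-4)
    }
  }
})
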