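# Independent straight-line oracles used across the suite. These share no
# code with the package implementation: plain nested loops, computed directly
# from the mathematical definitions.

seeded_array <- function(seed, dims, sd = 1) {
  withr::with_seed(seed, array(stats::rnorm(prod(dims), sd = sd), dim = dims))
}

# mean over columns / rows / all positions, by explicit loops
oracle_pool_h <- function(x) {
  d <- dim(x)
  out <- array(0, dim = c(d[1], d[2], 1, d[4]))
  for (b in 1:d[1]) for (i in 1:d[2]) for (ch in 1:d[4]) {
    s <- 0
    for (j in 1:d[3]) s <- s + x[b, i, j, ch]
    out[b, i, 1, ch] <- s / d[3]
  }
  out
}

oracle_pool_v <- function(x) {
  d <- dim(x)
  out <- array(0, dim = c(d[1], 1, d[3], d[4]))
  for (b in 1:d[1]) for (j in 1:d[3]) for (ch in 1:d[4]) {
    s <- 0
    for (i in 1:d[2]) s <- s + x[b, i, j, ch]
    out[b, 1, j, ch] <- s / d[2]
  }
  out
}

oracle_pool_global <- function(x) {
  d <- dim(x)
  out <- matrix(0, d[1], d[4])
  for (b in 1:d[1]) for (ch in 1:d[4]) {
    s <- 0
    for (i in 1:d[2]) for (j in 1:d[3]) s <- s + x[b, i, j, ch]
    out[b, ch] <- s / (d[2] * d[3])
  }
  out
}

oracle_softmax <- function(v) {
  e <- exp(v - max(v))
  e / sum(e)
}

# vector-matrix cross-spatial maps by explicit loops
oracle_cross_maps <- function(t1, t3) {
  d <- dim(t1)
  g1 <- oracle_pool_global(t1)
  g3 <- oracle_pool_global(t3)
  map1 <- array(0, dim = d[1:3])
  map2 <- array(0, dim = d[1:3])
  for (b in 1:d[1]) {
    a1 <- oracle_softmax(g1[b, ])
    a3 <- oracle_softmax(g3[b, ])
    for (i in 1:d[2]) for (j in 1:d[3]) {
      s1 <- 0
      s2 <- 0
      for (ch in 1:d[4]) {
        s1 <- s1 + a1[ch] * t3[b, i, j, ch]
        s2 <- s2 + a3[ch] * t1[b, i, j, ch]
      }
      map1[b, i, j] <- s1
      map2[b, i, j] <- s2
    }
  }
  list(map1 = map1, map2 = map2)
}

# dense "same"-padded convolution by explicit loops; w (k,k,cin,cout)
oracle_conv2d <- function(x, w, stride = 1) {
  d <- dim(x)
  k <- dim(w)[1]
  cout <- dim(w)[4]
  ho <- ceiling(d[2] / stride)
  wo <- ceiling(d[3] / stride)
  pt <- max((ho - 1) * stride + k - d[2], 0) %/% 2
  pl <- max((wo - 1) * stride + k - d[3], 0) %/% 2
  y <- array(0, dim = c(d[1], ho, wo, cout))
  for (b in 1:d[1]) for (io in 1:ho) for (jo in 1:wo) for (co in 1:cout) {
    s <- 0
    for (di in 1:k) for (dj in 1:k) for (ci in 1:d[4]) {
      ii <- (io - 1) * stride - pt + di
      jj <- (jo - 1) * stride - pl + dj
      if (ii >= 1 && ii <= d[2] && jj >= 1 && jj <= d[3]) {
        s <- s + x[b, ii, jj, ci] * w[di, dj, ci, co]
      }
    }
    y[b, io, jo, co] <- s
  }
  y
}

# depthwise convolution by explicit loops; w (k,k,c)
oracle_dwconv <- function(x, w, stride = 1) {
  d <- dim(x)
  k <- dim(w)[1]
  ho <- ceiling(d[2] / stride)
  wo <- ceiling(d[3] / stride)
  pt <- max((ho - 1) * stride + k - d[2], 0) %/% 2
  pl <- max((wo - 1) * stride + k - d[3], 0) %/% 2
  y <- array(0, dim = c(d[1], ho, wo, d[4]))
  for (b in 1:d[1]) for (io in 1:ho) for (jo in 1:wo) for (ch in 1:d[4]) {
    s <- 0
    for (di in 1:k) for (dj in 1:k) {
      ii <- (io - 1) * stride - pt + di
      jj <- (jo - 1) * stride - pl + dj
      if (ii >= 1 && ii <= d[2] && jj >= 1 && jj <= d[3]) {
        s <- s + x[b, ii, jj, ch] * w[di, dj, ch]
      }
    }
    y[b, io, jo, ch] <- s
  }
  y
}

# grouped convolution by explicit loops; w (k,k,cin/g,cout)
oracle_gconv <- function(x, w, groups, stride = 1) {
  d <- dim(x)
  k <- dim(w)[1]
  cout <- dim(w)[4]
  cg_in <- d[4] / groups
  cg_out <- cout / groups
  ho <- ceiling(d[2] / stride)
  wo <- ceiling(d[3] / stride)
  pt <- max((ho - 1) * stride + k - d[2], 0) %/% 2
  pl <- max((wo - 1) * stride + k - d[3], 0) %/% 2
  y <- array(0, dim = c(d[1], ho, wo, cout))
  for (b in 1:d[1]) for (io in 1:ho) for (jo in 1:wo) for (co in 1:cout) {
    grp <- (co - 1) %/% cg_out
    s <- 0
    for (di in 1:k) for (dj in 1:k) for (cl in 1:cg_in) {
      ii <- (io - 1) * stride - pt + di
      jj <- (jo - 1) * stride - pl + dj
      if (ii >= 1 && ii <= d[2] && jj >= 1 && jj <= d[3]) {
        s <- s + x[b, ii, jj, grp * cg_in + cl] * w[di, dj, cl, co]
      }
    }
    y[b, io, jo, co] <- s
  }
  y
}

# Independent EMA reference written from the module description: per-group
# loops, no reuse of any package kernel.
oracle_ema <- function(x, params, groups) {
  d <- dim(x)
  ch <- d[4]
  cg <- ch / groups
  out <- array(0, dim = d)
  sig <- function(v) 1 / (1 + exp(-v))
  for (grp in 1:groups) {
    idx <- ((grp - 1) * cg + 1):(grp * cg)
    xg <- x[, , , idx, drop = FALSE]
    # shared 1x1 conv restricted to this group's channels
    Wg <- matrix(params$W1[1, 1, , idx], nrow = cg, ncol = cg)
    bg <- params$b1[idx]
    ph <- oracle_pool_h(xg)
    pw <- oracle_pool_v(xg)
    zh <- array(0, dim = dim(ph))
    zw <- array(0, dim = dim(pw))
    for (b in 1:d[1]) {
      for (i in 1:d[2]) for (co in 1:cg) {
        zh[b, i, 1, co] <- sum(ph[b, i, 1, ] * Wg[, co]) + bg[co]
      }
      for (j in 1:d[3]) for (co in 1:cg) {
        zw[b, 1, j, co] <- sum(pw[b, 1, j, ] * Wg[, co]) + bg[co]
      }
    }
    t1 <- array(0, dim = dim(xg))
    for (b in 1:d[1]) for (i in 1:d[2]) for (j in 1:d[3]) for (cc in 1:cg) {
      t1[b, i, j, cc] <- xg[b, i, j, cc] * sig(zh[b, i, 1, cc]) *
        sig(zw[b, 1, j, cc])
    }
    W3g <- params$W3[, , , idx, drop = FALSE]
    dim(W3g) <- c(3, 3, cg, cg)
    t3 <- oracle_gconv(xg, W3g, groups = 1)
    for (cc in 1:cg) t3[, , , cc] <- t3[, , , cc] + params$b3[idx[cc]]
    maps <- oracle_cross_maps(t1, t3)
    for (b in 1:d[1]) for (i in 1:d[2]) for (j in 1:d[3]) {
      wgt <- sig(maps$map1[b, i, j] + maps$map2[b, i, j])
      for (cc in 1:cg) out[b, i, j, idx[cc]] <- xg[b, i, j, cc] * wgt
    }
  }
  out
}

# separable bilinear resize with half-pixel centers, by loops
oracle_bilinear <- function(img, size) {
  d <- dim(img)
  interp1 <- function(v, n_out) {
    n_in <- length(v)
    out <- numeric(n_out)
    sc <- n_in / n_out
    for (o in 1:n_out) {
      src <- (o - 0.5) * sc - 0.5
      i0 <- floor(src)
      fr <- src - i0
      lo <- min(max(i0, 0), n_in - 1) + 1
      hi <- min(max(i0 + 1, 0), n_in - 1) + 1
      out[o] <- (1 - fr) * v[lo] + fr * v[hi]
    }
    out
  }
  tmp <- array(0, dim = c(size, d[2], d[3]))
  for (j in 1:d[2]) for (ch in 1:d[3]) tmp[, j, ch] <- interp1(img[, j, ch], size)
  out <- array(0, dim = c(size, size, d[3]))
  for (i in 1:size) for (ch in 1:d[3]) out[i, , ch] <- interp1(tmp[i, , ch], size)
  out
}

# brute-force confusion tally
oracle_confusion <- function(y_true, y_pred, K) {
  cm <- matrix(0L, K, K)
  for (i in seq_along(y_true)) {
    r <- y_true[i] + 1L
    cc <- y_pred[i] + 1L
    cm[r, cc] <- cm[r, cc] + 1L
  }
  cm
}
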