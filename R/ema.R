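# Efficient multi-scale attention (EMA) with cross-spatial learning.
#
# The module splits the channels of a feature map into g groups, extracts a
# directionally pooled 1x1-convolution path and a 3x3-convolution path per
# group, forms two spatial attention maps from matrix products between
# channel-softmaxed global descriptors and the opposite branch, and gates the
# input through a sigmoid of their sum. Output dimensions equal input
# dimensions.

#' EMA module configuration
#'
#' @param channels number of input (= output) channels.
#' @param groups number of channel groups `g` (default 8); must divide
#'   `channels` exactly.
#' @return an object of class `ema_config`.
#' @export
ema_config <- function(channels, groups = 8L) {
  channels <- as.integer(channels)
  groups <- as.integer(groups)
  if (groups < 1L) stop("`groups` must be >= 1", call. = FALSE)
  if (channels %% groups != 0L) {
    stop(sprintf("channel count %d is not divisible by groups g = %d",
                 channels, groups), call. = FALSE)
  }
  structure(list(channels = channels, groups = groups,
                 group_width = channels %/% groups),
            class = "ema_config")
}

#' Split a feature map into channel groups
#'
#' Splits the channel axis into `g` equally sized contiguous groups, preserving
#' channel order. Concatenating the returned maps with [merge_groups()]
#' reconstructs the input exactly.
#'
#' @param x feature map, array (batch, height, width, channels).
#' @param g number of groups; must divide the channel count.
#' @return list of `g` arrays, each (batch, height, width, channels/g).
#' @export
split_into_groups <- function(x, g) {
  d <- check_feature_map(x)
  g <- as.integer(g)
  if (g < 1L || d[4L] %% g != 0L) {
    stop(sprintf("channel count c = %d is not divisible by g = %d",
                 d[4L], g), call. = FALSE)
  }
  cg <- d[4L] %/% g
  lapply(seq_len(g), function(i) {
    x[, , , ((i - 1L) * cg + 1L):(i * cg), drop = FALSE]
  })
}

#' Concatenate channel groups back into one feature map
#'
#' Inverse of [split_into_groups()].
#'
#' @param parts list of feature maps sharing (batch, height, width).
#' @return a single feature map with the concatenated channels.
#' @export
merge_groups <- function(parts) {
  stopifnot(is.list(parts), length(parts) >= 1L)
  d <- dim(parts[[1L]])
  total <- sum(vapply(parts, function(p) dim(p)[4L], integer(1)))
  # channels are outermost in memory, so plain vector concatenation works
  array(unlist(parts, use.names = FALSE), dim = c(d[1:3], total))
}

#' Directional (1-d) average pooling
#'
#' `horizontal` pooling averages over columns, producing one value per
#' (row, channel) — shape (batch, height, 1, channels). `vertical` pooling
#' averages over rows — shape (batch, 1, width, channels).
#'
#' @param x feature map.
#' @param axis `"horizontal"` or `"vertical"`.
#' @return the pooled descriptor, still a 4-d array.
#' @export
pool_directional <- function(x, axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  check_feature_map(x)
  if (axis == "horizontal") cpp_pool_h(x, dim(x)) else cpp_pool_v(x, dim(x))
}

#' 2-d global average pooling
#'
#' Averages each channel over all spatial positions:
#' `z[b, c] = mean_{i,j} x[b, i, j, c]`.
#'
#' @param x feature map.
#' @return matrix (batch, channels).
#' @export
pool_global <- function(x) {
  check_feature_map(x)
  cpp_pool_global(x, dim(x))
}

#' Cross-spatial attention maps
#'
#' Given the 1x1-path output `t1` and the 3x3-path output `t3` of one channel
#' group (batch may be the batch-times-groups folding), the first map is the
#' product of the channel-softmaxed global descriptor of `t1` with `t3`
#' reshaped to (channels, height*width); the second swaps the roles of the two
#' branches. Maps are returned before the sigmoid aggregation.
#'
#' @param t1,t3 feature maps with identical dimensions.
#' @return list with arrays `map1`, `map2` of dim (batch, height, width).
#' @export
cross_spatial_maps <- function(t1, t3) {
  d1 <- check_feature_map(t1, "t1")
  d3 <- check_feature_map(t3, "t3")
  if (!identical(d1, d3)) {
    stop("`t1` and `t3` must have identical dimensions", call. = FALSE)
  }
  a1 <- softmax_rows(pool_global(t1))   # (b, c)
  a3 <- softmax_rows(pool_global(t3))
  b <- d1[1L]; hw <- d1[2L] * d1[3L]; ch <- d1[4L]
  t3m <- matrix(t3, nrow = b * hw, ncol = ch)
  t1m <- matrix(t1, nrow = b * hw, ncol = ch)
  rows <- rep(seq_len(b), times = hw)
  map1 <- rowSums(t3m * a1[rows, , drop = FALSE])
  map2 <- rowSums(t1m * a3[rows, , drop = FALSE])
  list(map1 = array(map1, dim = d1[1:3]),
       map2 = array(map2, dim = d1[1:3]))
}

# --- parameters -------------------------------------------------------------

# The two convolutions are grouped convolutions over the full channel width
# (independent weights per group): W1 (1,1,cg,c) shared between the two pooled
# directions, W3 (3,3,cg,c); both carry per-channel biases.
ema_init <- function(cfg) {
  cg <- cfg$group_width
  list(W1 = init_conv(1L, cg, cfg$channels),
       b1 = rep(0, cfg$channels),
       W3 = init_conv(3L, cg, cfg$channels),
       b3 = rep(0, cfg$channels))
}

ema_param_count <- function(cfg) {
  cg <- cfg$group_width
  (cg * cfg$channels + cfg$channels) + (9L * cg * cfg$channels + cfg$channels)
}

# fold channel groups into the batch axis: (b,h,w,c) -> (b*g,h,w,cg)
fold_groups <- function(x, g) cpp_fold_groups(x, dim(x), g)

unfold_groups <- function(x, g) cpp_unfold_groups(x, dim(x), g)

# grouped 1x1 convolution on the pooled/concatenated descriptor, as block
# matrix products (one small GEMM per group)
gconv1_fw <- function(z, W1, b1, g) {
  d <- dim(z)
  cg <- d[4L] %/% g
  zm <- matrix(z, nrow = prod(d[1:3]), ncol = d[4L])
  ym <- matrix(0, nrow = nrow(zm), ncol = d[4L])
  Wm <- matrix(W1, nrow = cg, ncol = d[4L])
  for (grp in seq_len(g)) {
    cols <- ((grp - 1L) * cg + 1L):(grp * cg)
    ym[, cols] <- zm[, cols, drop = FALSE] %*% Wm[, cols, drop = FALSE]
  }
  ym <- sweep(ym, 2L, b1, "+")
  dim(ym) <- d
  ym
}

gconv1_bw <- function(z, W1, g, dy) {
  d <- dim(z)
  cg <- d[4L] %/% g
  zm <- matrix(z, nrow = prod(d[1:3]), ncol = d[4L])
  dym <- matrix(dy, nrow = prod(d[1:3]), ncol = d[4L])
  Wm <- matrix(W1, nrow = cg, ncol = d[4L])
  dzm <- matrix(0, nrow = nrow(zm), ncol = d[4L])
  dWm <- matrix(0, nrow = cg, ncol = d[4L])
  for (grp in seq_len(g)) {
    cols <- ((grp - 1L) * cg + 1L):(grp * cg)
    dWm[, cols] <- crossprod(zm[, cols, drop = FALSE],
                             dym[, cols, drop = FALSE])
    dzm[, cols] <- dym[, cols, drop = FALSE] %*%
      t(Wm[, cols, drop = FALSE])
  }
  db <- colSums(dym)
  dim(dzm) <- d
  dW <- dWm
  dim(dW) <- dim(W1)
  list(dz = dzm, dW = dW, db = db)
}

#' EMA forward pass
#'
#' Applies the multi-scale attention module: channel-group splitting, the
#' directionally pooled 1x1 path with sigmoid gates, the 3x3 path, two
#' cross-spatial attention maps per group, sigmoid aggregation, and
#' multiplicative gating of the input features. Output dimensions equal input
#' dimensions.
#'
#' @param x feature map (batch, height, width, channels).
#' @param params parameter list from `ema_init()` (elements `W1`, `b1`,
#'   `W3`, `b3`).
#' @param cfg an [ema_config()].
#' @param want_cache keep intermediates for the backward pass.
#' @return the gated feature map; with `want_cache = TRUE`, a list
#'   `(y, cache)`.
#' @export
ema_forward <- function(x, params, cfg, want_cache = FALSE) {
  d <- check_feature_map(x, finite = FALSE)
  if (d[4L] != cfg$channels) {
    stop(sprintf("channel count %d does not match ema_config channels %d",
                 d[4L], cfg$channels), call. = FALSE)
  }
  g <- cfg$groups
  b <- d[1L]; h <- d[2L]; w <- d[3L]; ch <- d[4L]

  # 1x1 path: directional pooling, shared grouped 1x1 conv, sigmoid gates
  ph <- cpp_pool_h(x, d)                               # (b,h,1,c)
  pw <- cpp_pool_v(x, d)                               # (b,1,w,c)
  pwp <- aperm(pw, c(1L, 3L, 2L, 4L))                  # (b,w,1,c)
  z <- array(0, dim = c(b, h + w, 1L, ch))
  z[, seq_len(h), , ] <- ph
  z[, h + seq_len(w), , ] <- pwp
  zc <- gconv1_fw(z, params$W1, params$b1, g)
  sh <- sigmoid(zc[, seq_len(h), , , drop = FALSE])    # (b,h,1,c)
  sw <- sigmoid(aperm(zc[, h + seq_len(w), , , drop = FALSE],
                      c(1L, 3L, 2L, 4L)))              # (b,1,w,c)
  t1 <- cpp_dirgate_fw(x, d, sh, sw)

  # 3x3 path
  t3 <- bias_add(conv2d_fw(x, params$W3, stride = 1L, groups = g), params$b3)

  # cross-spatial maps on the group-folded layout
  t1f <- fold_groups(t1, g)
  t3f <- fold_groups(t3, g)
  d1 <- softmax_rows(cpp_pool_global(t1f, dim(t1f)))
  d3 <- softmax_rows(cpp_pool_global(t3f, dim(t3f)))
  bg <- b * g
  hw <- h * w
  rows <- rep(seq_len(bg), times = hw)
  map1 <- rowSums(matrix(t3f, nrow = bg * hw) * d1[rows, , drop = FALSE])
  map2 <- rowSums(matrix(t1f, nrow = bg * hw) * d3[rows, , drop = FALSE])
  wf <- sigmoid(array(map1 + map2, dim = c(bg, h, w)))

  xf <- fold_groups(x, g)
  yf <- cpp_gate_fw(xf, dim(xf), wf)
  y <- unfold_groups(yf, g)
  if (!want_cache) return(y)
  list(y = y,
       cache = list(x = x, z = z, sh = sh, sw = sw,
                    t1f = t1f, t3f = t3f, xf = xf, wf = wf,
                    d1 = d1, d3 = d3))
}

ema_backward <- function(dy, cache, params, cfg) {
  g <- cfg$groups
  cg <- cfg$group_width
  x <- cache$x
  d <- dim(x)
  b <- d[1L]; h <- d[2L]; w <- d[3L]; ch <- d[4L]
  hw <- h * w
  bg <- b * g

  dyf <- fold_groups(dy, g)
  wf <- cache$wf

  # y_f = x_f * wf (broadcast over group channels)
  gb <- cpp_gate_bw(cache$xf, dim(cache$xf), wf, dyf)
  da <- gb$dw * wf * (1 - wf)      # through sigmoid; = dmap1 = dmap2

  # cross-spatial maps backward (on folded tensors)
  d1 <- cache$d1; d3 <- cache$d3   # (bg, cg) softmaxed descriptors
  rows <- rep(seq_len(bg), times = hw)
  dav <- as.vector(da)
  t1m <- matrix(cache$t1f, nrow = bg * hw, ncol = cg)
  t3m <- matrix(cache$t3f, nrow = bg * hw, ncol = cg)

  # map1 = sum_c d1[bg,c] * t3f[bg,i,j,c];  map2 swaps the branches
  dt3m <- dav * d1[rows, , drop = FALSE]
  dd1 <- rowsum(dav * t3m, group = rows)               # (bg, cg)
  dt1m <- dav * d3[rows, , drop = FALSE]
  dd3 <- rowsum(dav * t1m, group = rows)

  # softmax + global-pool backward
  dz1 <- d1 * (dd1 - rowSums(dd1 * d1))
  dz3 <- d3 * (dd3 - rowSums(dd3 * d3))
  dt1m <- dt1m + dz1[rows, , drop = FALSE] / hw
  dt3m <- dt3m + dz3[rows, , drop = FALSE] / hw
  dim(dt1m) <- c(bg, h, w, cg)
  dim(dt3m) <- c(bg, h, w, cg)
  dt1 <- unfold_groups(dt1m, g)
  dt3 <- unfold_groups(dt3m, g)

  # 3x3 path backward
  bw3 <- conv2d_bw(x, params$W3, dt3, stride = 1L, groups = g)
  db3 <- bias_bw(dt3)
  dx <- unfold_groups(gb$dx, g) + bw3$dx

  # 1x1 path backward: t1 = x * sh * sw (directional broadcast)
  dg <- cpp_dirgate_bw(x, d, cache$sh, cache$sw, dt1)
  dx <- dx + dg$dx
  dzh <- dg$dsh * cache$sh * (1 - cache$sh)
  dzw <- dg$dsw * cache$sw * (1 - cache$sw)
  dzc <- array(0, dim = c(b, h + w, 1L, ch))
  dzc[, seq_len(h), , ] <- dzh
  dzc[, h + seq_len(w), , ] <- aperm(dzw, c(1L, 3L, 2L, 4L))
  bw1 <- gconv1_bw(cache$z, params$W1, g, dzc)

  # pooled descriptors backward: means over one spatial axis
  dph <- bw1$dz[, seq_len(h), , , drop = FALSE] / w
  dpw <- aperm(bw1$dz[, h + seq_len(w), , , drop = FALSE],
               c(1L, 3L, 2L, 4L)) / h
  dx <- dx + dph[, , rep(1L, w), , drop = FALSE] +
    dpw[, rep(1L, h), , , drop = FALSE]

  list(dx = dx,
       grads = list(W1 = bw1$dW, b1 = bw1$db, W3 = bw3$dw, b3 = db3))
}
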