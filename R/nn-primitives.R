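# Low-level tensor primitives. All feature maps are R arrays with
# dim = (batch, height, width, channels), double precision.

#' @useDynLib fruitnet, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# "Same" padding bookkeeping (TensorFlow convention: the extra pixel of an odd
# total pad goes to the bottom/right). Returns output size and leading pad.
same_pad <- function(size, k, stride) {
  out <- ceiling(size / stride)
  total <- max((out - 1L) * stride + k - size, 0L)
  list(out = as.integer(out), beg = as.integer(total %/% 2L))
}

check_feature_map <- function(x, arg = "x", finite = TRUE) {
  if (!is.array(x) || length(dim(x)) != 4L) {
    stop(sprintf("`%s` must be a 4-d array (batch, height, width, channels)", arg),
         call. = FALSE)
  }
  if (finite && !all(is.finite(x))) {
    stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  }
  invisible(dim(x))
}

# --- dense / pointwise / grouped convolution -------------------------------

# w: (k, k, cin/groups, cout). Stride-1 1x1 ungrouped convolutions collapse to
# a single BLAS matrix product.
conv2d_fw <- function(x, w, stride = 1L, groups = 1L) {
  d <- dim(x)
  k <- dim(w)[1L]
  cout <- dim(w)[4L]
  if (k == 1L && stride == 1L && groups == 1L) {
    y <- cpp_matmul(x, prod(d[1:3]), matrix(w, nrow = d[4L], ncol = cout))
    dim(y) <- c(d[1:3], cout)
    return(y)
  }
  ph <- same_pad(d[2L], k, stride)
  pw <- same_pad(d[3L], k, stride)
  if (groups == 1L) {
    col <- cpp_im2col(x, dim(x), k, stride, ph$beg, pw$beg, ph$out, pw$out)
    y <- col %*% matrix(w, nrow = k * k * d[4L], ncol = cout)
    dim(y) <- c(d[1L], ph$out, pw$out, cout)
    y
  } else {
    cpp_gconv_fw(x, dim(x), w, k, cout, groups, stride, ph$beg, pw$beg,
                 ph$out, pw$out)
  }
}

conv2d_bw <- function(x, w, dy, stride = 1L, groups = 1L) {
  d <- dim(x)
  k <- dim(w)[1L]
  cout <- dim(w)[4L]
  if (k == 1L && stride == 1L && groups == 1L) {
    n <- prod(d[1:3])
    dw <- cpp_crossprod(x, n, d[4L], dy, cout)
    dim(dw) <- dim(w)
    dx <- cpp_matmul_t(dy, n, matrix(w, nrow = d[4L], ncol = cout))
    dim(dx) <- d
    return(list(dx = dx, dw = dw))
  }
  ph <- same_pad(d[2L], k, stride)
  pw <- same_pad(d[3L], k, stride)
  if (groups == 1L) {
    col <- cpp_im2col(x, dim(x), k, stride, ph$beg, pw$beg, ph$out, pw$out)
    n <- nrow(col)
    dw <- cpp_crossprod(col, n, ncol(col), dy, cout)
    dim(dw) <- dim(w)
    dcol <- cpp_matmul_t(dy, n, matrix(w, nrow = k * k * d[4L], ncol = cout))
    dx <- cpp_col2im(dcol, dim(x), k, stride, ph$beg, pw$beg, ph$out, pw$out)
    list(dx = dx, dw = dw)
  } else {
    cpp_gconv_bw(x, dim(x), w, k, cout, groups, dy, stride, ph$beg, pw$beg,
                 ph$out, pw$out)
  }
}

# --- depthwise convolution -------------------------------------------------

# w: (k, k, channels); one spatial filter per channel.
dwconv_fw <- function(x, w, stride = 1L) {
  d <- dim(x)
  k <- dim(w)[1L]
  ph <- same_pad(d[2L], k, stride)
  pw <- same_pad(d[3L], k, stride)
  cpp_dwconv_fw(x, dim(x), w, k, stride, ph$beg, pw$beg, ph$out, pw$out)
}

dwconv_bw <- function(x, w, dy, stride = 1L) {
  d <- dim(x)
  k <- dim(w)[1L]
  ph <- same_pad(d[2L], k, stride)
  pw <- same_pad(d[3L], k, stride)
  cpp_dwconv_bw(x, dim(x), w, k, dy, stride, ph$beg, pw$beg, ph$out, pw$out)
}

# --- bias, batch norm, activations -----------------------------------------

bias_add <- function(y, b) {
  # channels are the outermost dimension, so per-channel bias is a block
  # recycle over contiguous slices
  y + rep(b, each = prod(dim(y)[1:3]))
}

bias_bw <- function(dy) {
  colSums(matrix(dy, nrow = prod(dim(dy)[1:3]), ncol = dim(dy)[4L]))
}

BN_EPS <- 1e-3
BN_MOMENTUM <- 0.9

# Batch norm, optionally fused with ReLU6 (act = TRUE). Training mode uses
# batch statistics and updates the running state with the given momentum
# (the recalibration pass drives the momentum schedule explicitly).
bn_fw <- function(x, p, s, training, act = FALSE, momentum = BN_MOMENTUM) {
  if (training) {
    out <- cpp_bn_fw(x, dim(x), p$gamma, p$beta, BN_EPS, as.integer(act))
    var <- 1 / out$invstd^2 - BN_EPS
    s$rmean <- momentum * s$rmean + (1 - momentum) * out$mean
    s$rvar <- momentum * s$rvar + (1 - momentum) * var
    list(y = out$y, cache = list(mean = out$mean, invstd = out$invstd),
         state = s)
  } else {
    list(y = cpp_bn_fw_eval(x, dim(x), p$gamma, p$beta, s$rmean, s$rvar,
                            BN_EPS, as.integer(act)),
         cache = NULL, state = s)
  }
}

# Backward through (ReLU6 o) batch norm; `yact` is the fused forward output,
# used only when act = TRUE to mask the gradient.
bn_bw <- function(x, dy, p, cache, yact = NULL, act = FALSE) {
  out <- cpp_bn_bw(x, dim(x), dy, if (act) yact else numeric(0), p$gamma,
                   cache$mean, cache$invstd, as.integer(act))
  list(dx = out$dx, grads = list(gamma = out$dgamma, beta = out$dbeta))
}

relu6_fw <- function(x) cpp_relu6_fw(x)
relu6_bw <- function(x, dy) cpp_relu6_bw(x, dy)

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(m) {
  e <- exp(m - apply(m, 1L, max))
  e / rowSums(e)
}

# --- parameter initialization ----------------------------------------------

# He-normal for convolutions feeding ReLU6, Glorot-uniform for the classifier.
init_conv <- function(k, cin_per_group, cout, depthwise = FALSE) {
  fan_in <- k * k * cin_per_group
  sd <- sqrt(2 / fan_in)
  if (depthwise) {
    array(stats::rnorm(k * k * cout, sd = sd), dim = c(k, k, cout))
  } else {
    array(stats::rnorm(k * k * cin_per_group * cout, sd = sd),
          dim = c(k, k, cin_per_group, cout))
  }
}

init_bn <- function(channels) {
  list(gamma = rep(1, channels), beta = rep(0, channels))
}

init_bn_state <- function(channels) {
  list(rmean = rep(0, channels), rvar = rep(1, channels))
}

init_dense <- function(cin, cout) {
  lim <- sqrt(6 / (cin + cout))
  list(W = matrix(stats::runif(cin * cout, -lim, lim), cin, cout),
       b = rep(0, cout))
}

# --- recursive parameter containers ----------------------------------------

# Parameters and their gradients are nested lists of numeric arrays with
# identical shape; these helpers traverse them structurally.

param_count <- function(p) {
  if (is.numeric(p)) return(length(p))
  if (is.list(p)) return(sum(vapply(p, param_count, numeric(1))))
  0
}

param_map2 <- function(f, a, b) {
  if (is.numeric(a)) return(f(a, b))
  out <- vector("list", length(a))
  names(out) <- names(a)
  for (i in seq_along(a)) out[[i]] <- param_map2(f, a[[i]], b[[i]])
  out
}

param_zeros_like <- function(p) {
  if (is.numeric(p)) {
    z <- p
    z[] <- 0
    return(z)
  }
  lapply(p, param_zeros_like)
}
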