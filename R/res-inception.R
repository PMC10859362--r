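# Res-Inception inverted-residual block.
#
# At stride 1 the depthwise stage runs parallel 3x3, 5x5 and 7x7 kernels whose
# outputs are summed (each branch with its own batch norm and ReLU6), with a
# residual connection from input to output when the channel counts match. At
# stride 2 the block falls back to the plain inverted-residual unit with a
# single depthwise 3x3. Convolutions carry no bias (a batch-norm layer always
# follows); the final pointwise projection is linear.

#' Block specification
#'
#' @param in_channels,out_channels channel counts.
#' @param stride 1 or 2.
#' @param expansion channel expansion factor `t` (1 disables the expansion
#'   convolution, as in the first backbone stage).
#' @param kernels odd depthwise kernel sizes; defaults to `c(3, 5, 7)` at
#'   stride 1 and `3` otherwise.
#' @param use_residual add the input to the output; defaults to
#'   `stride == 1 && in_channels == out_channels`, the only admissible case.
#' @return an object of class `block_spec`.
#' @export
block_spec <- function(in_channels, out_channels, stride = 1L,
                       expansion = 6L, kernels = NULL, use_residual = NULL) {
  stride <- as.integer(stride)
  if (!stride %in% c(1L, 2L)) {
    stop("`stride` must be 1 or 2", call. = FALSE)
  }
  if (is.null(kernels)) kernels <- if (stride == 1L) c(3L, 5L, 7L) else 3L
  kernels <- as.integer(kernels)
  if (length(kernels) < 1L || any(kernels %% 2L == 0L)) {
    stop("`kernels` must be a non-empty set of odd integers", call. = FALSE)
  }
  if (is.null(use_residual)) {
    use_residual <- stride == 1L && in_channels == out_channels
  }
  if (use_residual && (stride != 1L || in_channels != out_channels)) {
    stop("residual connection requires stride 1 and matching channel counts",
         call. = FALSE)
  }
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 stride = stride, expansion = as.integer(expansion),
                 kernels = kernels, use_residual = use_residual),
            class = "block_spec")
}

block_expanded <- function(spec) spec$expansion * spec$in_channels

block_init <- function(spec) {
  e <- block_expanded(spec)
  p <- list()
  if (spec$expansion > 1L) {
    p$expand <- c(list(W = init_conv(1L, spec$in_channels, e)), init_bn(e))
  }
  p$branches <- lapply(spec$kernels, function(k) {
    c(list(W = init_conv(k, 1L, e, depthwise = TRUE)), init_bn(e))
  })
  names(p$branches) <- paste0("k", spec$kernels)
  p$proj <- c(list(W = init_conv(1L, e, spec$out_channels)),
              init_bn(spec$out_channels))
  p
}

block_init_state <- function(spec) {
  e <- block_expanded(spec)
  s <- list()
  if (spec$expansion > 1L) s$expand <- init_bn_state(e)
  s$branches <- lapply(spec$kernels, function(k) init_bn_state(e))
  names(s$branches) <- paste0("k", spec$kernels)
  s$proj <- init_bn_state(spec$out_channels)
  s
}

#' Closed-form trainable-parameter count of one block
#'
#' Sums the convolution weights and batch-norm scale/shift parameters implied
#' by the specification: pointwise expansion (absent when `expansion == 1`),
#' one depthwise convolution per kernel with its own batch norm, and the
#' linear pointwise projection.
#'
#' @param spec a [block_spec()].
#' @return integer parameter count.
#' @export
block_param_count <- function(spec) {
  e <- block_expanded(spec)
  n <- 0L
  if (spec$expansion > 1L) n <- n + spec$in_channels * e + 2L * e
  n <- n + sum(vapply(spec$kernels, function(k) k * k * e + 2L * e,
                      integer(1)))
  n + e * spec$out_channels + 2L * spec$out_channels
}

#' Res-Inception block forward pass
#'
#' @param x input feature map (batch, height, width, in_channels).
#' @param params parameters from `block_init()`.
#' @param spec a [block_spec()].
#' @param state batch-norm running statistics (from `block_init_state()`).
#' @param training use batch statistics and update `state`.
#' @param want_cache keep intermediates for the backward pass.
#' @param momentum running-statistics update momentum (training mode).
#' @return the output feature map; with `want_cache = TRUE` a list
#'   `(y, cache, state)`; otherwise a list `(y, state)`.
#' @export
block_forward <- function(x, params, spec, state = NULL, training = FALSE,
                          want_cache = FALSE, momentum = BN_MOMENTUM) {
  d <- check_feature_map(x)
  if (d[4L] != spec$in_channels) {
    stop(sprintf("input has %d channels but the block expects %d",
                 d[4L], spec$in_channels), call. = FALSE)
  }
  if (is.null(state)) state <- block_init_state(spec)
  cache <- list(x = x)

  if (spec$expansion > 1L) {
    ce <- conv2d_fw(x, params$expand$W)
    bn <- bn_fw(ce, params$expand, state$expand, training, act = TRUE,
                momentum = momentum)
    state$expand <- bn$state
    e <- bn$y
    cache$expand <- list(conv_out = ce, bn = bn$cache, act_out = e)
  } else {
    e <- x
  }
  cache$e <- e

  fused <- NULL
  cache$branches <- vector("list", length(spec$kernels))
  for (i in seq_along(spec$kernels)) {
    k <- spec$kernels[i]
    key <- paste0("k", k)
    cv <- dwconv_fw(e, params$branches[[key]]$W, stride = spec$stride)
    bn <- bn_fw(cv, params$branches[[key]], state$branches[[key]], training,
                act = TRUE, momentum = momentum)
    state$branches[[key]] <- bn$state
    fused <- if (is.null(fused)) bn$y else fused + bn$y
    cache$branches[[i]] <- list(conv_out = cv, bn = bn$cache, act_out = bn$y)
  }
  cache$fused <- fused

  cp <- conv2d_fw(fused, params$proj$W)
  bnp <- bn_fw(cp, params$proj, state$proj, training, momentum = momentum)
  state$proj <- bnp$state
  y <- bnp$y
  cache$proj <- list(conv_out = cp, bn = bnp$cache)
  if (spec$use_residual) y <- y + x

  if (want_cache) list(y = y, cache = cache, state = state)
  else list(y = y, state = state)
}

block_backward <- function(dy, cache, params, spec) {
  grads <- list()
  dproj_bn <- bn_bw(cache$proj$conv_out, dy, params$proj, cache$proj$bn)
  cw <- conv2d_bw(cache$fused, params$proj$W, dproj_bn$dx)
  grads$proj <- c(list(W = cw$dw), dproj_bn$grads)
  dfused <- cw$dx

  de <- NULL
  grads$branches <- vector("list", length(spec$kernels))
  names(grads$branches) <- paste0("k", spec$kernels)
  for (i in seq_along(spec$kernels)) {
    key <- paste0("k", spec$kernels[i])
    br <- cache$branches[[i]]
    dbn <- bn_bw(br$conv_out, dfused, params$branches[[key]], br$bn,
                 yact = br$act_out, act = TRUE)
    dcv <- dwconv_bw(cache$e, params$branches[[key]]$W, dbn$dx,
                     stride = spec$stride)
    grads$branches[[key]] <- c(list(W = dcv$dw), dbn$grads)
    de <- if (is.null(de)) dcv$dx else de + dcv$dx
  }

  if (spec$expansion > 1L) {
    ex <- cache$expand
    dbn <- bn_bw(ex$conv_out, de, params$expand, ex$bn,
                 yact = ex$act_out, act = TRUE)
    cwe <- conv2d_bw(cache$x, params$expand$W, dbn$dx)
    grads$expand <- c(list(W = cwe$dw), dbn$grads)
    dx <- cwe$dx
  } else {
    dx <- de
  }
  if (spec$use_residual) dx <- dx + dy
  # order grads to mirror params
  ordered <- list()
  if (spec$expansion > 1L) ordered$expand <- grads$expand
  ordered$branches <- grads$branches
  ordered$proj <- grads$proj
  list(dx = dx, grads = ordered)
}
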