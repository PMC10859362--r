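# Model assembly: parameter initialization, forward/backward over the whole
# network, parameter audits and summaries.

#' Build an improved-MobileNetV2 model
#'
#' Initializes all trainable parameters deterministically under `seed`
#' (He-normal convolutions, unit/zero batch-norm scale/shift, Glorot-uniform
#' classifier) for the given architecture table.
#'
#' @param table an [default_architecture()] table.
#' @param seed integer seed for parameter initialization.
#' @return an object of class `fruitnet_model`.
#' @export
build_model <- function(table, seed = 1L) {
  arch_spatial_trace(table)  # validates input size against stride schedule
  withr::with_seed(as.integer(seed), {
    params <- list()
    state <- list()
    params$stem <- c(list(W = init_conv(table$stem$kernel, 3L,
                                        table$stem$out_channels)),
                     init_bn(table$stem$out_channels))
    state$stem <- init_bn_state(table$stem$out_channels)

    params$blocks <- lapply(table$blocks, block_init)
    state$blocks <- lapply(table$blocks, block_init_state)

    ema_cfgs <- vector("list", length(table$blocks))
    params$emas <- vector("list", length(table$blocks))
    for (i in seq_along(table$blocks)) {
      if (table$ema_after[i]) {
        cfg <- ema_config(table$blocks[[i]]$out_channels, table$groups)
        ema_cfgs[[i]] <- cfg
        params$emas[[i]] <- ema_init(cfg)
      }
    }

    cin_head <- table$blocks[[length(table$blocks)]]$out_channels
    params$head <- c(list(W = init_conv(1L, cin_head, table$head_channels)),
                     init_bn(table$head_channels))
    state$head <- init_bn_state(table$head_channels)
    params$classifier <- init_dense(table$head_channels, table$num_classes)

    structure(list(table = table, params = params, state = state,
                   ema_cfgs = ema_cfgs, seed = as.integer(seed)),
              class = "fruitnet_model")
  })
}

#' Count trainable parameters
#'
#' Counts every trainable scalar (convolution and dense weights, biases,
#' batch-norm scale/shift); running batch-norm statistics are excluded.
#'
#' @param model a [build_model()] result.
#' @return integer count.
#' @export
count_parameters <- function(model) {
  as.integer(param_count(model$params))
}

#' Per-component parameter breakdown
#'
#' Closed-form audit of where the parameters sit: stem, each block, each EMA
#' module, head and classifier. The sum equals [count_parameters()].
#'
#' @param model a [build_model()] result.
#' @return data.frame with columns `component`, `params`.
#' @export
model_param_breakdown <- function(model) {
  t <- model$table
  rows <- list(data.frame(component = "stem",
                          params = as.integer(param_count(model$params$stem))))
  for (i in seq_along(t$blocks)) {
    rows[[length(rows) + 1L]] <-
      data.frame(component = sprintf("block%02d", i),
                 params = as.integer(param_count(model$params$blocks[[i]])))
    if (t$ema_after[i]) {
      rows[[length(rows) + 1L]] <-
        data.frame(component = sprintf("ema%02d", i),
                   params = as.integer(param_count(model$params$emas[[i]])))
    }
  }
  rows[[length(rows) + 1L]] <-
    data.frame(component = "head",
               params = as.integer(param_count(model$params$head)))
  rows[[length(rows) + 1L]] <-
    data.frame(component = "classifier",
               params = as.integer(param_count(model$params$classifier)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Forward to logits. Returns y plus (optionally) caches, and updated state.
model_forward_logits <- function(model, x, training = FALSE,
                                 want_cache = FALSE,
                                 bn_momentum = BN_MOMENTUM) {
  t <- model$table
  p <- model$params
  s <- model$state
  caches <- if (want_cache) list() else NULL

  cs <- conv2d_fw(x, p$stem$W, stride = t$stem$stride)
  bn <- bn_fw(cs, p$stem, s$stem, training, act = TRUE,
              momentum = bn_momentum)
  s$stem <- bn$state
  h <- bn$y
  if (want_cache) caches$stem <- list(x = x, conv_out = cs, bn = bn$cache,
                                      act_out = h)

  caches_blocks <- if (want_cache) vector("list", length(t$blocks))
  caches_emas <- if (want_cache) vector("list", length(t$blocks))
  for (i in seq_along(t$blocks)) {
    bf <- block_forward(h, p$blocks[[i]], t$blocks[[i]], s$blocks[[i]],
                        training, want_cache, momentum = bn_momentum)
    s$blocks[[i]] <- bf$state
    h <- bf$y
    if (want_cache) caches_blocks[[i]] <- bf$cache
    if (t$ema_after[i]) {
      ef <- ema_forward(h, p$emas[[i]], model$ema_cfgs[[i]],
                        want_cache = want_cache)
      if (want_cache) {
        caches_emas[[i]] <- ef$cache
        h <- ef$y
      } else {
        h <- ef
      }
    }
  }
  if (want_cache) {
    caches$blocks <- caches_blocks
    caches$emas <- caches_emas
  }

  ch <- conv2d_fw(h, p$head$W)
  bnh <- bn_fw(ch, p$head, s$head, training, act = TRUE,
               momentum = bn_momentum)
  s$head <- bnh$state
  hh <- bnh$y
  if (want_cache) caches$head <- list(x = h, conv_out = ch, bn = bnh$cache,
                                      act_out = hh)

  # global average pooling + dense classifier
  pooled <- cpp_pool_global(hh, dim(hh))         # (b, head_channels)
  logits <- sweep(pooled %*% p$classifier$W, 2L, p$classifier$b, "+")
  if (want_cache) caches$top <- list(feat = hh, pooled = pooled)

  list(logits = logits, state = s, caches = caches)
}

model_backward <- function(model, caches, dlogits) {
  t <- model$table
  p <- model$params
  grads <- list()

  pooled <- caches$top$pooled
  grads$classifier <- list(W = crossprod(pooled, dlogits),
                           b = colSums(dlogits))
  dpooled <- dlogits %*% t(p$classifier$W)
  fd <- dim(caches$top$feat)
  hw <- fd[2L] * fd[3L]
  # global-average-pool backward: spread each (batch, channel) gradient
  # uniformly over the h*w positions
  dfeat <- dpooled[rep(seq_len(fd[1L]), times = hw), , drop = FALSE] / hw
  dim(dfeat) <- fd

  dbn <- bn_bw(caches$head$conv_out, dfeat, p$head, caches$head$bn,
               yact = caches$head$act_out, act = TRUE)
  cw <- conv2d_bw(caches$head$x, p$head$W, dbn$dx)
  grads$head <- c(list(W = cw$dw), dbn$grads)
  dh <- cw$dx

  grads$blocks <- vector("list", length(t$blocks))
  grads$emas <- vector("list", length(t$blocks))
  for (i in rev(seq_along(t$blocks))) {
    if (t$ema_after[i]) {
      eb <- ema_backward(dh, caches$emas[[i]], p$emas[[i]],
                         model$ema_cfgs[[i]])
      grads$emas[[i]] <- eb$grads
      dh <- eb$dx
    }
    bb <- block_backward(dh, caches$blocks[[i]], p$blocks[[i]], t$blocks[[i]])
    grads$blocks[[i]] <- bb$grads
    dh <- bb$dx
  }

  dbn <- bn_bw(caches$stem$conv_out, dh, p$stem, caches$stem$bn,
               yact = caches$stem$act_out, act = TRUE)
  cw <- conv2d_bw(caches$stem$x, p$stem$W, dbn$dx, stride = t$stem$stride)
  grads$stem <- c(list(W = cw$dw), dbn$grads)

  # mirror params ordering
  grads[c("stem", "blocks", "emas", "head", "classifier")]
}

#' Model forward pass to class probabilities
#'
#' @param model a [build_model()] result.
#' @param x input batch, array (batch, height, width, 3) of preprocessed
#'   pixel values.
#' @param training use batch statistics (and return updated running
#'   statistics); inference mode otherwise.
#' @return matrix (batch, num_classes) of softmax probabilities.
#' @export
model_forward <- function(model, x, training = FALSE) {
  out <- model_forward_logits(model, x, training = training)
  softmax_rows(out$logits)
}

#' @export
predict.fruitnet_model <- function(object, x, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  pr <- model_forward(object, x)
  if (type == "prob") return(pr)
  max.col(pr, ties.method = "first") - 1L    # 0-based class labels
}

#' Per-layer model summary
#'
#' @param model a [build_model()] result.
#' @return data.frame with columns `layer`, `output_shape`, `params`.
#' @export
model_summary <- function(model) {
  t <- model$table
  trace <- arch_spatial_trace(t)
  fmt <- function(hw, c) sprintf("(%d, %d, %d)", hw[1L], hw[2L], c)
  rows <- list(data.frame(layer = "stem",
                          output_shape = fmt(trace$stem, t$stem$out_channels),
                          params = as.integer(param_count(model$params$stem))))
  for (i in seq_along(t$blocks)) {
    b <- t$blocks[[i]]
    nm <- sprintf("block%02d[s%d,k{%s}]", i, b$stride,
                  paste(b$kernels, collapse = ","))
    rows[[length(rows) + 1L]] <-
      data.frame(layer = nm,
                 output_shape = fmt(trace[[paste0("block", i)]],
                                    b$out_channels),
                 params = as.integer(param_count(model$params$blocks[[i]])))
    if (t$ema_after[i]) {
      rows[[length(rows) + 1L]] <-
        data.frame(layer = sprintf("ema%02d[g=%d]", i, t$groups),
                   output_shape = fmt(trace[[paste0("block", i)]],
                                      b$out_channels),
                   params = as.integer(param_count(model$params$emas[[i]])))
    }
  }
  last <- trace[[paste0("block", length(t$blocks))]]
  rows[[length(rows) + 1L]] <-
    data.frame(layer = "head", output_shape = fmt(last, t$head_channels),
               params = as.integer(param_count(model$params$head)))
  rows[[length(rows) + 1L]] <-
    data.frame(layer = "classifier",
               output_shape = sprintf("(%d)", t$num_classes),
               params = as.integer(param_count(model$params$classifier)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
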