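# Training (Adam + categorical cross-entropy) and evaluation.

#' Training configuration
#'
#' @param epochs maximum number of epochs (default 100).
#' @param batch_size minibatch size (default 32).
#' @param learning_rate Adam step size (library default 1e-3; the remaining
#'   Adam moments use their customary defaults beta1 = 0.9, beta2 = 0.999,
#'   epsilon = 1e-8). No schedule, weight decay or early stopping is applied.
#' @param seed integer seed; the epoch-e data order is drawn under the
#'   derived seed `seed + e`.
#' @param target_accuracy optional training-accuracy level at which training
#'   stops before `epochs` (useful for overfitting checks); `NULL` runs all
#'   epochs.
#' @param verbose print one line per epoch to stderr.
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs = 100L, batch_size = 32L,
                         learning_rate = 1e-3, seed = 1L,
                         target_accuracy = NULL, verbose = FALSE) {
  epochs <- as.integer(epochs)
  batch_size <- as.integer(batch_size)
  if (epochs < 1L) stop("`epochs` must be >= 1", call. = FALSE)
  if (batch_size < 1L) stop("`batch_size` must be >= 1", call. = FALSE)
  structure(list(epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, seed = as.integer(seed),
                 target_accuracy = target_accuracy, verbose = verbose),
            class = "train_config")
}

# softmax cross-entropy on logits; returns loss, accuracy and dlogits
softmax_xent <- function(logits, labels0) {
  n <- nrow(logits)
  probs <- softmax_rows(logits)
  idx <- cbind(seq_len(n), labels0 + 1L)
  loss <- -mean(log(pmax(probs[idx], 1e-12)))
  acc <- mean(max.col(probs, ties.method = "first") - 1L == labels0)
  dlogits <- probs
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, acc = acc, dlogits = dlogits / n)
}

adam_update <- function(params, grads, m, v, t, lr, b1 = 0.9, b2 = 0.999,
                        eps = 1e-8) {
  m <- param_map2(function(a, g) b1 * a + (1 - b1) * g, m, grads)
  v <- param_map2(function(a, g) b2 * a + (1 - b2) * g * g, v, grads)
  bc1 <- 1 - b1^t
  bc2 <- 1 - b2^t
  step <- function(p, mm, vv) p - lr * (mm / bc1) / (sqrt(vv / bc2) + eps)
  walk <- function(p, mm, vv) {
    if (is.numeric(p)) return(step(p, mm, vv))
    out <- vector("list", length(p))
    names(out) <- names(p)
    for (i in seq_along(p)) out[[i]] <- walk(p[[i]], mm[[i]], vv[[i]])
    out
  }
  list(params = walk(params, m, v), m = m, v = v)
}

dataset_labels_ok <- function(ds, num_classes) {
  length(ds$images) > 0L && all(ds$labels >= 0L & ds$labels < num_classes)
}

# Precise-BN recalibration: replace the exponentially decayed running
# statistics with the exact (sample-weighted) average of batch statistics
# over the given tensor. Batches are drawn in a seeded shuffled order —
# class-sorted batches would be class-homogeneous, and averaging their
# within-batch variances would drop the between-class variance the network
# was normalized under during (shuffled) training.
recalibrate_bn_stats <- function(model, x, batch_size = 32L, seed = 0L) {
  n <- dim(x)[1L]
  order <- withr::with_seed(as.integer(seed), sample.int(n))
  seen <- 0
  for (start in seq(1L, n, by = batch_size)) {
    idx <- order[start:min(start + batch_size - 1L, n)]
    fw <- model_forward_logits(model, x[idx, , , , drop = FALSE],
                               training = TRUE,
                               bn_momentum = seen / (seen + length(idx)))
    model$state <- fw$state
    seen <- seen + length(idx)
  }
  model
}

#' Train a model
#'
#' Runs minibatch Adam on categorical cross-entropy. Data order is
#' reshuffled each epoch under a per-epoch derived seed; training-mode batch
#' statistics update the running batch-norm state. The parameters achieving
#' the best validation accuracy are retained alongside the final parameters.
#'
#' After the last epoch the running batch-norm statistics are recalibrated
#' over the training set (exact average of batch statistics), so inference
#' normalization matches what the network saw during fitting.
#'
#' @param model a [build_model()] result.
#' @param train_set,val_set `labeled_image_set`s (validation optional).
#' @param config a [train_config()].
#' @return list with elements `model` (final), `history` (one row per epoch:
#'   epoch, train_loss, train_acc, val_loss, val_acc), `best_params`,
#'   `best_epoch`, `epochs_run`.
#' @export
train_model <- function(model, train_set, val_set = NULL,
                        config = train_config()) {
  K <- model$table$num_classes
  if (length(train_set$images) == 0L) stop("empty training set", call. = FALSE)
  if (!dataset_labels_ok(train_set, K)) {
    stop(sprintf("training labels outside [0, %d)", K), call. = FALSE)
  }
  if (!is.null(val_set) && !dataset_labels_ok(val_set, K)) {
    stop(sprintf("validation labels outside [0, %d)", K), call. = FALSE)
  }
  size <- model$table$input_size[1L]
  xtr <- as_batch_tensor(train_set, size = size)
  ytr <- train_set$labels
  xval <- if (!is.null(val_set)) as_batch_tensor(val_set, size = size)
  n <- length(ytr)

  m <- param_zeros_like(model$params)
  v <- param_zeros_like(model$params)
  t_step <- 0L
  hist <- list()
  best_acc <- -Inf
  best_params <- NULL
  best_epoch <- NA_integer_
  epochs_run <- 0L

  for (epoch in seq_len(config$epochs)) {
    order <- withr::with_seed(config$seed + epoch, sample.int(n))
    ep_loss <- 0
    ep_correct <- 0
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- order[start:min(start + config$batch_size - 1L, n)]
      xb <- xtr[idx, , , , drop = FALSE]
      yb <- ytr[idx]
      fw <- model_forward_logits(model, xb, training = TRUE,
                                 want_cache = TRUE)
      model$state <- fw$state
      ls <- softmax_xent(fw$logits, yb)
      grads <- model_backward(model, fw$caches, ls$dlogits)
      t_step <- t_step + 1L
      upd <- adam_update(model$params, grads, m, v, t_step,
                         config$learning_rate)
      model$params <- upd$params
      m <- upd$m
      v <- upd$v
      ep_loss <- ep_loss + ls$loss * length(idx)
      ep_correct <- ep_correct + ls$acc * length(idx)
    }
    train_loss <- ep_loss / n
    train_acc <- ep_correct / n

    val_loss <- NA_real_
    val_acc <- NA_real_
    if (!is.null(val_set)) {
      ev <- eval_on_tensor(model, xval, val_set$labels, config$batch_size)
      val_loss <- ev$loss
      val_acc <- ev$acc
      if (val_acc > best_acc) {
        best_acc <- val_acc
        best_params <- model$params
        best_epoch <- epoch
      }
    }
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = train_loss,
                                train_acc = train_acc, val_loss = val_loss,
                                val_acc = val_acc)
    if (config$verbose) {
      message(sprintf("epoch %3d  loss %.4f  acc %.4f  val_loss %s  val_acc %s",
                      epoch, train_loss, train_acc,
                      ifelse(is.na(val_loss), "-", sprintf("%.4f", val_loss)),
                      ifelse(is.na(val_acc), "-", sprintf("%.4f", val_acc))))
    }
    epochs_run <- epoch
    if (!is.null(config$target_accuracy) &&
        train_acc >= config$target_accuracy) break
  }
  model <- recalibrate_bn_stats(model, xtr, config$batch_size,
                                seed = config$seed)
  if (is.null(best_params)) {
    best_params <- model$params
    best_epoch <- epochs_run
  }
  list(model = model, history = do.call(rbind, hist),
       best_params = best_params, best_epoch = best_epoch,
       epochs_run = epochs_run)
}

eval_on_tensor <- function(model, x, labels0, batch_size = 32L) {
  n <- length(labels0)
  loss <- 0
  correct <- 0
  preds <- integer(n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    fw <- model_forward_logits(model, x[idx, , , , drop = FALSE],
                               training = FALSE)
    ls <- softmax_xent(fw$logits, labels0[idx])
    loss <- loss + ls$loss * length(idx)
    correct <- correct + ls$acc * length(idx)
    preds[idx] <- max.col(softmax_rows(fw$logits), ties.method = "first") - 1L
  }
  list(loss = loss / n, acc = correct / n, preds = preds)
}

#' Evaluate a model on a labeled set
#'
#' Argmax prediction per image, confusion matrix and metric report; artifacts
#' (confusion CSV, per-class CSV, metrics JSON) are written when `out_dir`
#' is given.
#'
#' @param model a [build_model()] result.
#' @param test_set a `labeled_image_set`.
#' @param out_dir optional artifact directory.
#' @param batch_size evaluation batch size.
#' @return list `(report, confusion, predictions)`.
#' @export
evaluate_model <- function(model, test_set, out_dir = NULL,
                           batch_size = 32L) {
  K <- model$table$num_classes
  if (length(test_set$images) == 0L) stop("empty test set", call. = FALSE)
  if (!dataset_labels_ok(test_set, K)) {
    stop(sprintf("test labels outside [0, %d)", K), call. = FALSE)
  }
  size <- model$table$input_size[1L]
  x <- as_batch_tensor(test_set, size = size)
  ev <- eval_on_tensor(model, x, test_set$labels, batch_size)
  cm <- confusion_matrix(test_set$labels, ev$preds, K,
                         class_names = test_set$class_names)
  report <- metric_report(cm)
  if (!is.null(out_dir)) write_metrics(report, cm, out_dir)
  list(report = report, confusion = cm, predictions = ev$preds)
}
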