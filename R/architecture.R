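# Architecture table: the single source of truth for the improved MobileNetV2.
#
# Backbone recipe (width multiplier 1.0): a 3x3/stride-2 stem to 32 channels,
# seven bottleneck stages with (expansion, channels, repeats, first-stride)
# (1,16,1,1) (6,24,2,2) (6,32,3,2) (6,64,4,2) (6,96,3,1) (6,160,3,2)
# (6,320,1,1), a 1x1 head convolution to 1280 channels, global average
# pooling and a dense softmax classifier. Stride-1 blocks are Res-Inception
# blocks (kernels 3/5/7); stride-2 blocks keep the single 3x3 depthwise. One
# EMA module (g = 8) sits between every two consecutive bottleneck blocks.

MOBILENETV2_STAGES <- list(
  list(t = 1L, c = 16L,  n = 1L, s = 1L),
  list(t = 6L, c = 24L,  n = 2L, s = 2L),
  list(t = 6L, c = 32L,  n = 3L, s = 2L),
  list(t = 6L, c = 64L,  n = 4L, s = 2L),
  list(t = 6L, c = 96L,  n = 3L, s = 1L),
  list(t = 6L, c = 160L, n = 3L, s = 2L),
  list(t = 6L, c = 320L, n = 1L, s = 1L)
)

#' Default improved-MobileNetV2 architecture table
#'
#' Builds the standard MobileNetV2 stage table (width 1.0) with stride-1
#' blocks specified as Res-Inception blocks, one EMA attention module between
#' every two consecutive bottleneck blocks, and a classifier head for
#' `num_classes`. The two ablation switches restore the original backbone:
#' `use_res_inception = FALSE` reverts every block to a single depthwise 3x3,
#' `use_ema = FALSE` removes all attention modules.
#'
#' @param num_classes number of output classes (>= 2).
#' @param input_size input image side length (square input) or a length-2
#'   (height, width) vector.
#' @param use_res_inception,use_ema ablation toggles.
#' @param groups EMA channel groups `g`.
#' @return an object of class `architecture_table`.
#' @export
default_architecture <- function(num_classes, input_size = 100L,
                                 use_res_inception = TRUE, use_ema = TRUE,
                                 groups = 8L) {
  num_classes <- as.integer(num_classes)
  if (num_classes < 2L) stop("`num_classes` must be >= 2", call. = FALSE)
  if (length(input_size) == 1L) input_size <- rep(input_size, 2L)
  input_size <- as.integer(input_size)

  blocks <- list()
  cin <- 32L
  for (st in MOBILENETV2_STAGES) {
    for (i in seq_len(st$n)) {
      s <- if (i == 1L) st$s else 1L
      kernels <- if (s == 1L && use_res_inception) c(3L, 5L, 7L) else 3L
      blocks[[length(blocks) + 1L]] <-
        block_spec(cin, st$c, stride = s, expansion = st$t, kernels = kernels)
      cin <- st$c
    }
  }
  nb <- length(blocks)
  ema_after <- rep(use_ema, nb)
  ema_after[nb] <- FALSE          # interior boundaries only

  structure(list(
    stem = list(kernel = 3L, stride = 2L, out_channels = 32L),
    blocks = blocks,
    ema_after = ema_after,
    groups = as.integer(groups),
    head_channels = 1280L,
    num_classes = num_classes,
    input_size = input_size,
    use_res_inception = use_res_inception,
    use_ema = use_ema
  ), class = "architecture_table")
}

# Trace spatial dimensions through the stride schedule; errors with the block
# index at which a dimension would degenerate (downsampling a 1-pixel map).
arch_spatial_trace <- function(table) {
  hw <- table$input_size
  if (any(hw < 2L * table$stem$stride)) {
    stop("input size too small: spatial dimension degenerates at the stem",
         call. = FALSE)
  }
  trace <- list(stem = hw <- ceiling(hw / table$stem$stride))
  for (i in seq_along(table$blocks)) {
    if (table$blocks[[i]]$stride > 1L && any(hw < 2L)) {
      stop(sprintf("input size too small: spatial dimension degenerates at block %d",
                   i), call. = FALSE)
    }
    hw <- ceiling(hw / table$blocks[[i]]$stride)
    trace[[paste0("block", i)]] <- hw
  }
  trace
}

#' Write / read an architecture table as YAML or JSON
#'
#' @param table an [default_architecture()] table.
#' @param path output file; `.yaml`/`.yml` or `.json`.
#' @return `read_architecture()` returns the reconstructed table.
#' @export
write_architecture <- function(table, path) {
  obj <- list(num_classes = table$num_classes,
              input_size = table$input_size,
              use_res_inception = table$use_res_inception,
              use_ema = table$use_ema,
              groups = table$groups)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(obj, path)
  }
  invisible(path)
}

#' @rdname write_architecture
#' @export
read_architecture <- function(path) {
  obj <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  default_architecture(num_classes = obj$num_classes,
                       input_size = unlist(obj$input_size),
                       use_res_inception = isTRUE(obj$use_res_inception),
                       use_ema = isTRUE(obj$use_ema),
                       groups = obj$groups)
}
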