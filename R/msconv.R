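# Multi-scale convolution: Res2Net modules and their cascade.
#
# A Res2Net module applies a leading 1x1 convolution, splits the channels
# into S equal subsets, and processes them hierarchically:
#   Y_1 = X_1 (identity), Y_2 = f3x3(X_2), Y_i = f3x3(X_i + Y_{i-1}) for
#   2 < i <= S,
# then concatenates Y_1..Y_S and mixes them with a trailing 1x1 convolution.
# Each Y_i sees a strictly larger receptive field than the last, so the
# concatenation carries a combinatorial mix of scales. The multi-scale block
# cascades one 3x3 convolution with two Res2Net modules.

#' Res2Net block configuration
#'
#' @param channels_in,channels_out positive channel counts.
#' @param scales integer number of channel subsets S >= 2 (the network uses
#'   4 on shallow levels and 6 on deep ones, see [scale_schedule()]).
#' @param mid_channels width after the leading 1x1 convolution; must be
#'   divisible by `scales`. Defaults to the largest multiple of `scales` not
#'   exceeding `channels_out`, so any output width is usable with any S.
#' @param batchnorm,activation attach batch normalization / ReLU after each
#'   convolution (defaults `TRUE`; turn off for linear-algebra checks).
#' @return a `vb_res2net_config` list.
#' @export
res2net_config <- function(channels_in, channels_out, scales = 4L,
                           mid_channels = NULL, batchnorm = TRUE,
                           activation = TRUE) {
  scales <- as.integer(scales)
  if (scales < 2L) vb_stop("scales must be >= 2")
  if (channels_in < 1L || channels_out < 1L)
    vb_stop("channel counts must be positive")
  if (is.null(mid_channels)) {
    mid_channels <- scales * max(1L, channels_out %/% scales)
  } else if (mid_channels %% scales != 0L) {
    vb_stop("mid_channels (", mid_channels, ") not divisible by scales (",
            scales, ")")
  }
  structure(list(channels_in = as.integer(channels_in),
                 channels_out = as.integer(channels_out),
                 scales = scales, mid_channels = as.integer(mid_channels),
                 batchnorm = isTRUE(batchnorm),
                 activation = isTRUE(activation)),
            class = "vb_res2net_config")
}

vb_res2net <- function(cfg) {
  stopifnot(inherits(cfg, "vb_res2net_config"))
  ws <- cfg$mid_channels %/% cfg$scales
  ch <- list(conv_in = vb_cbr(cfg$channels_in, cfg$mid_channels, k = 1L,
                              cfg$batchnorm, cfg$activation))
  for (i in 2:cfg$scales)
    ch[[paste0("f", i)]] <- vb_cbr(ws, ws, k = 3L, cfg$batchnorm,
                                   cfg$activation)
  ch$conv_out <- vb_cbr(cfg$mid_channels, cfg$channels_out, k = 1L,
                        cfg$batchnorm, cfg$activation)
  m <- new_module("res2net", children = ch)
  m$cfg <- cfg
  m
}

#' @export
vb_forward.vb_res2net <- function(m, x, train = FALSE) {
  cfg <- m$cfg
  s <- cfg$scales
  ws <- cfg$mid_channels %/% s
  u <- vb_forward(m$children$conv_in, x, train)
  d <- dim(u)
  v <- array(0, d)
  sub <- function(a, i) a[, , (i - 1L) * ws + seq_len(ws), , drop = FALSE]
  v[, , seq_len(ws), ] <- sub(u, 1L)                       # identity subset
  yprev <- NULL
  for (i in 2:s) {
    inp <- if (i == 2L) sub(u, i) else sub(u, i) + yprev
    yprev <- vb_forward(m$children[[paste0("f", i)]], inp, train)
    v[, , (i - 1L) * ws + seq_len(ws), ] <- yprev
  }
  vb_forward(m$children$conv_out, v, train)
}

#' @export
vb_backward.vb_res2net <- function(m, gy) {
  cfg <- m$cfg
  s <- cfg$scales
  ws <- cfg$mid_channels %/% s
  gv <- vb_backward(m$children$conv_out, gy)
  d <- dim(gv)
  gu <- array(0, d)
  idx <- function(i) (i - 1L) * ws + seq_len(ws)
  # dL/dY_i starts as the concat gradient; Y_{i-1} also feeds f_i's input
  # (for i >= 3), so the input gradient of f_i is carried down one subset.
  gY <- lapply(seq_len(s), function(i) gv[, , idx(i), , drop = FALSE])
  if (s >= 3L) for (i in s:3) {
    gin <- vb_backward(m$children[[paste0("f", i)]], gY[[i]])
    gu[, , idx(i), ] <- gin
    gY[[i - 1L]] <- gY[[i - 1L]] + gin
  }
  gu[, , idx(2L), ] <- vb_backward(m$children$f2, gY[[2L]])
  gu[, , idx(1L), ] <- gY[[1L]]
  vb_backward(m$children$conv_in, gu)
}

#' Apply a Res2Net block to a feature map
#'
#' Functional form over a single feature map. `block` may be either a
#' [res2net_config()] (a fresh block is initialized; pass `seed` for
#' reproducibility) or a block module created by `vb_res2net()` whose
#' parameters have been set explicitly.
#'
#' @param x feature map, H x W x C array.
#' @param block a `vb_res2net_config` or a `vb_res2net` module.
#' @param seed optional seed used when `block` is a config.
#' @param train logical; use batch (TRUE) or running (FALSE) normalization
#'   statistics.
#' @return H x W x channels_out array.
#' @export
res2net_block <- function(x, block, seed = NULL, train = TRUE) {
  b <- check_feature_map(x)
  if (inherits(block, "vb_res2net_config")) {
    block <- if (is.null(seed)) vb_res2net(block)
             else with_seed(seed, vb_res2net(block))
  }
  stopifnot(inherits(block, "vb_res2net"))
  if (dim(b$x)[3] != block$cfg$channels_in)
    vb_stop("feature map has ", dim(b$x)[3], " channels; block expects ",
            block$cfg$channels_in)
  drop_batch(vb_forward(block, b$x, train), b$ndim)
}

# the multi-scale convolution block: 3x3 conv then two Res2Net modules,
# channel change at the leading convolution
vb_msconv <- function(in_ch, out_ch, scales, batchnorm = TRUE,
                      activation = TRUE) {
  cfg <- res2net_config(out_ch, out_ch, scales, batchnorm = batchnorm,
                        activation = activation)
  vb_seq(list(conv = vb_cbr(in_ch, out_ch, 3L, batchnorm, activation),
              res2a = vb_res2net(cfg), res2b = vb_res2net(cfg)))
}

#' Multi-scale convolution block
#'
#' Cascades a 3x3 convolution (mapping `channels_in` to `channels_out`) with
#' two independent Res2Net modules that preserve the channel count. Spatial
#' size is preserved throughout (same padding).
#'
#' @inheritParams res2net_block
#' @param block a `vb_res2net_config` (its `channels_in`/`channels_out`
#'   describe the whole block) or a prebuilt module from `vb_msconv()`.
#' @return H x W x channels_out array.
#' @export
multiscale_conv <- function(x, block, seed = NULL, train = TRUE) {
  b <- check_feature_map(x)
  if (inherits(block, "vb_res2net_config")) {
    mk <- function() vb_msconv(block$channels_in, block$channels_out,
                               block$scales, block$batchnorm,
                               block$activation)
    block <- if (is.null(seed)) mk() else with_seed(seed, mk())
  }
  drop_batch(vb_forward(block, b$x, train), b$ndim)
}

#' Layer-wise Res2Net scale schedule
#'
#' The split count S per network level: the first three encoder
#' (down-sampling) levels and the last two decoder (up-sampling) levels use
#' S = 4; the deepest two encoder levels and the first two decoder levels,
#' where channel counts are largest, use S = 6.
#'
#' @param stage `"encoder"` or `"decoder"`.
#' @param layer_index 1-based level index (encoder 1..5, decoder 1..4).
#' @return integer S (4 or 6).
#' @examples
#' vapply(1:5, function(i) scale_schedule("encoder", i), 1L)  # 4 4 4 6 6
#' vapply(1:4, function(i) scale_schedule("decoder", i), 1L)  # 6 6 4 4
#' @export
scale_schedule <- function(stage = c("encoder", "decoder"), layer_index) {
  stage <- match.arg(stage)
  layer_index <- as.integer(layer_index)
  n <- if (stage == "encoder") 5L else 4L
  if (length(layer_index) != 1L || is.na(layer_index) || layer_index < 1L ||
      layer_index > n)
    vb_stop(stage, " layer index must be in 1..", n)
  if (stage == "encoder") {
    if (layer_index <= 3L) 4L else 6L
  } else {
    if (layer_index <= 2L) 6L else 4L
  }
}
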