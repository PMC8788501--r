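# The full segmentation network.
#
# Three stages. Feature extraction: five encoder levels of multi-scale
# convolution blocks; level 1 works at full resolution, levels 2-5 each
# follow a 2x2 max pooling, so channel width doubles and spatial size halves
# per level (ladder 256,128,64,32,16 / widths w..16w at input 256). Middle
# processing: channel attention on each of the four skip features, dual
# attention on the bottleneck feature. Prediction: a four-level decoder (the
# "feature box") of transposed-convolution upsampling + skip concatenation +
# multi-scale convolution; every decoder feature emits a coarse class-score
# map through a 1x1 head, bilinearly upsampled to input resolution, and the
# four coarse maps are concatenated and fused by a final 1x1 convolution.

#' Network configuration
#'
#' @param in_channels image channels (1 for CT slices).
#' @param num_classes number of segmentation classes (>= 2; background is
#'   class 0).
#' @param base_width channels at encoder level 1; doubled at each deeper
#'   level. Must be divisible by 4 (channel-attention bottleneck).
#' @param input_size square input size in pixels; must be divisible by 32
#'   (the five pooling stages of the ladder).
#' @param batchnorm use batch normalization inside convolution blocks.
#' @param activation use ReLU activations inside convolution blocks
#'   (default `TRUE`; turning them off yields a piecewise-smooth network
#'   useful for gradient diagnostics).
#' @return a `vertebox_config` list.
#' @export
vertebox_config <- function(in_channels = 1L, num_classes = 2L,
                            base_width = 64L, input_size = 256L,
                            batchnorm = TRUE, activation = TRUE) {
  in_channels <- as.integer(in_channels)
  num_classes <- as.integer(num_classes)
  base_width <- as.integer(base_width)
  input_size <- as.integer(input_size)
  if (num_classes < 2L) vb_stop("num_classes must be >= 2")
  if (base_width %% 4L != 0L)
    vb_stop("base_width must be divisible by 4 (attention bottleneck C/4)")
  if (input_size %% 32L != 0L)
    vb_stop("input_size must be divisible by 2^5")
  structure(list(in_channels = in_channels, num_classes = num_classes,
                 base_width = base_width, input_size = input_size,
                 batchnorm = isTRUE(batchnorm), activation = isTRUE(activation)),
            class = "vertebox_config")
}

#' Build the segmentation network
#'
#' Assembles the encoder, attention units, decoder and prediction heads
#' described in [vertebox_config()]. Parameters are He-initialized from the
#' current RNG unless `seed` is given.
#'
#' @param cfg a [vertebox_config()].
#' @param seed optional integer seed for reproducible initialization.
#' @return a `vb_vertebox` module (an environment with reference semantics).
#' @export
build_vertebox <- function(cfg = vertebox_config(), seed = NULL) {
  stopifnot(inherits(cfg, "vertebox_config"))
  if (!is.null(seed)) return(with_seed(seed, build_vertebox(cfg)))
  w <- cfg$base_width * 2L^(0:4)
  bn <- cfg$batchnorm
  act <- cfg$activation %||% TRUE
  ch <- list()
  for (k in 1:5) {
    s <- scale_schedule("encoder", k)
    in_ch <- if (k == 1L) cfg$in_channels else w[k - 1L]
    ch[[paste0("enc", k)]] <- vb_msconv(in_ch, w[k], s, batchnorm = bn,
                                         activation = act)
    if (k > 1L) ch[[paste0("pool", k)]] <- vb_maxpool()
  }
  for (k in 1:4) ch[[paste0("cam", k)]] <- vb_cam(w[k])
  ch$dam <- vb_dam(w[5])
  for (k in 1:4) {
    wk <- w[5L - k]                 # decoder level k output width
    ch[[paste0("up", k)]] <- vb_upconv(if (k == 1L) w[5] else w[6L - k], wk)
    ch[[paste0("dec", k)]] <- vb_msconv(2L * wk, wk,
                                        scale_schedule("decoder", k),
                                        batchnorm = bn, activation = act)
    ch[[paste0("head", k)]] <- vb_conv(wk, cfg$num_classes, k = 1L)
    ch[[paste0("bil", k)]] <- vb_bilinear(cfg$input_size, cfg$input_size)
  }
  ch$fuse <- vb_conv(4L * cfg$num_classes, cfg$num_classes, k = 1L)
  m <- new_module("vertebox", children = ch)
  m$cfg <- cfg
  m
}

as_image_batch <- function(x, cfg) {
  d <- dim(x)
  if (is.null(d)) vb_stop("images must be a matrix or array")
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == 3L) {
    # (H, W, N) stack of single-channel slices
    if (cfg$in_channels != 1L)
      vb_stop("3-d input assumes single-channel images")
    x <- array(x, c(d[1], d[2], 1L, d[3]))
  }
  d <- dim(x)
  if (d[1] != cfg$input_size || d[2] != cfg$input_size)
    vb_stop("input spatial size ", d[1], "x", d[2],
            " does not match configured input_size ", cfg$input_size)
  if (d[3] != cfg$in_channels) vb_stop("wrong number of image channels")
  if (any(!is.finite(x))) vb_stop("images contain non-finite values")
  x
}

#' Forward pass: coarse and final prediction maps
#'
#' Runs a batch of images through the network and returns the prediction
#' set: four auxiliary coarse class-score maps (one per decoder level, level
#' 1 deepest, all bilinearly upsampled to input resolution) plus the final
#' fused map.
#'
#' @param model a `vb_vertebox` module from [build_vertebox()].
#' @param images H x W matrix, H x W x N stack, or H x W x C x N array with
#'   spatial size equal to the configured `input_size`.
#' @param train logical; `TRUE` uses batch statistics in normalization
#'   layers (training mode), `FALSE` the running statistics (deterministic
#'   evaluation mode).
#' @return a `vb_predictions` list with elements `aux` (list of 4 arrays
#'   H x W x num_classes x N) and `final` (same shape).
#' @export
vertebox_forward <- function(model, images, train = FALSE) {
  stopifnot(inherits(model, "vb_vertebox"))
  cfg <- model$cfg
  x <- as_image_batch(images, cfg)
  ch <- model$children
  e <- vector("list", 5)
  e[[1]] <- vb_forward(ch$enc1, x, train)
  for (k in 2:5)
    e[[k]] <- vb_forward(ch[[paste0("enc", k)]],
                         vb_forward(ch[[paste0("pool", k)]], e[[k - 1]],
                                    train), train)
  a <- vector("list", 5)
  for (k in 1:4) a[[k]] <- vb_forward(ch[[paste0("cam", k)]], e[[k]], train)
  a[[5]] <- vb_forward(ch$dam, e[[5]], train)
  dec <- vector("list", 4)
  model$skip_ch <- integer(4)
  prev <- a[[5]]
  aux <- vector("list", 4)
  for (k in 1:4) {
    up <- vb_forward(ch[[paste0("up", k)]], prev, train)
    skip <- a[[5L - k]]
    model$skip_ch[k] <- dim(up)[3]
    cat_in <- array(0, dim(up) + c(0, 0, dim(skip)[3], 0))
    cat_in[, , seq_len(dim(up)[3]), ] <- up
    cat_in[, , dim(up)[3] + seq_len(dim(skip)[3]), ] <- skip
    dec[[k]] <- vb_forward(ch[[paste0("dec", k)]], cat_in, train)
    h <- vb_forward(ch[[paste0("head", k)]], dec[[k]], train)
    aux[[k]] <- vb_forward(ch[[paste0("bil", k)]], h, train)
    prev <- dec[[k]]
  }
  ccls <- cfg$num_classes
  du <- dim(aux[[1]])
  cat_aux <- array(0, c(du[1], du[2], 4L * ccls, du[4]))
  for (k in 1:4) cat_aux[, , (k - 1L) * ccls + seq_len(ccls), ] <- aux[[k]]
  final <- vb_forward(ch$fuse, cat_aux, train)
  if (any(!is.finite(final))) vb_stop("non-finite values in network output")
  structure(list(aux = aux, final = final), class = "vb_predictions")
}

# Backward pass for the deep-supervision objective. `g_aux` is a list of 4
# gradients w.r.t. the (upsampled) auxiliary maps, `g_final` the gradient
# w.r.t. the final fused map. Populates parameter gradients in place.
vertebox_backward <- function(model, g_aux, g_final) {
  ch <- model$children
  ccls <- model$cfg$num_classes
  g_cat <- vb_backward(ch$fuse, g_final)
  g_dec_next <- NULL                    # gradient flowing into dec[[k]]
  g_skip <- vector("list", 5)           # gradients into attended features
  for (k in 4:1) {
    g_up <- g_aux[[k]] + g_cat[, , (k - 1L) * ccls + seq_len(ccls), ,
                                drop = FALSE]
    g_h <- vb_backward(ch[[paste0("bil", k)]], g_up)
    g_dec <- vb_backward(ch[[paste0("head", k)]], g_h)
    if (!is.null(g_dec_next)) g_dec <- g_dec + g_dec_next
    g_cat_in <- vb_backward(ch[[paste0("dec", k)]], g_dec)
    nup <- model$skip_ch[k]
    g_upout <- g_cat_in[, , seq_len(nup), , drop = FALSE]
    g_skip[[5L - k]] <- g_cat_in[, , nup + seq_len(dim(g_cat_in)[3] - nup), ,
                                 drop = FALSE]
    g_prev <- vb_backward(ch[[paste0("up", k)]], g_upout)
    if (k == 1L) g_skip[[5]] <- g_prev else g_dec_next <- g_prev
  }
  g_e5 <- vb_backward(ch$dam, g_skip[[5]])
  g_e <- g_e5
  for (k in 5:2) {
    if (k < 5L) {
      g_cam <- vb_backward(ch[[paste0("cam", k)]], g_skip[[k]])
      g_e <- g_e + g_cam
    }
    g_pooled <- vb_backward(ch[[paste0("enc", k)]], g_e)
    g_e <- vb_backward(ch[[paste0("pool", k)]], g_pooled)
  }
  g_e <- g_e + vb_backward(ch$cam1, g_skip[[1]])
  vb_backward(ch$enc1, g_e)
}

#' Hard labels from a prediction set
#'
#' Per-pixel argmax over the classes of the final fused map only (the
#' auxiliary maps are training aids). Ties break toward the lower class
#' index, so exactly tied scores yield background.
#'
#' @param pred a `vb_predictions` object from [vertebox_forward()].
#' @return integer array of 0-based class labels, H x W (single image) or
#'   H x W x N.
#' @export
predict_labels <- function(pred) {
  stopifnot(inherits(pred, "vb_predictions"))
  f <- pred$final
  d <- dim(f)
  lab <- array(0L, c(d[1], d[2], d[4]))
  best <- array(f[, , 1L, , drop = FALSE], c(d[1], d[2], d[4]))
  if (d[3] > 1L) for (c in 2:d[3]) {
    sc <- array(f[, , c, , drop = FALSE], c(d[1], d[2], d[4]))
    upd <- sc > best
    best[upd] <- sc[upd]
    lab[upd] <- c - 1L
  }
  if (d[4] == 1L) lab <- matrix(lab, d[1], d[2])
  lab
}

#' Class probabilities of the final prediction map
#'
#' Softmax over the class dimension of the final fused map.
#' @param pred a `vb_predictions` object.
#' @return H x W x num_classes x N probability array.
#' @export
predict_probs <- function(pred) {
  stopifnot(inherits(pred, "vb_predictions"))
  softmax_cls(pred$final)
}

# numerically stable softmax over the class (third) dimension
softmax_cls <- function(x) {
  d <- dim(x)
  mx <- array(x[, , 1L, , drop = FALSE], d[c(1, 2, 4)])
  if (d[3] > 1L) for (c in 2:d[3])
    mx <- pmax(mx, array(x[, , c, , drop = FALSE], d[c(1, 2, 4)]))
  e <- exp(x - as.vector(bcast_hw(array(mx, c(d[1], d[2], 1L, d[4])), d)))
  tot <- array(0, d[c(1, 2, 4)])
  for (c in seq_len(d[3])) tot <- tot + array(e[, , c, , drop = FALSE],
                                              d[c(1, 2, 4)])
  e / bcast_hw(array(tot, c(d[1], d[2], 1L, d[4])), d)
}

## ---- checkpointing --------------------------------------------------------

#' Save a model checkpoint
#'
#' Writes a single version-tagged RDS file holding the network
#' configuration, all parameters and normalization buffers, plus any extra
#' training state supplied by the caller.
#'
#' @param model a `vb_vertebox` module.
#' @param path file path to write.
#' @param extra optional named list (optimizer state, history, ...).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path, extra = list()) {
  obj <- list(format = "vertebox-checkpoint", version = 1L,
              package_version = as.character(utils::packageVersion("vertebox")),
              cfg = model$cfg, params = vb_params(model),
              buffers = vb_buffers(model), extra = extra)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path file written by [save_checkpoint()].
#' @return list with elements `model` (rebuilt `vb_vertebox`) and `extra`.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "vertebox-checkpoint"))
    vb_stop("not a vertebox checkpoint: ", path)
  model <- build_vertebox(obj$cfg, seed = 1L)
  vb_set_params(model, obj$params)
  vb_set_buffers(model, obj$buffers)
  list(model = model, extra = obj$extra)
}
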