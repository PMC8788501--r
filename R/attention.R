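# Channel, position and dual attention.
#
# The channel attention module (CAM) summarizes each channel by its spatial
# mean and maximum (a 2C descriptor), squeezes it through a C/4 bottleneck of
# two fully connected layers, and rescales each channel by the resulting
# sigmoid activation. The position attention module (PAM) builds three H x W
# descriptors (channel-wise max, channel-wise mean, and a learned 1x1
# projection), convolves the stack with a 3x3 kernel, and rescales every
# pixel by the sigmoid gate. The dual attention module (DAM) sums the two
# branch outputs element-wise.

## ---- CAM ------------------------------------------------------------------

vb_cam <- function(ch, init = c("he", "zeros")) {
  init <- match.arg(init)
  if (ch %% 4L != 0L)
    vb_stop("channel attention requires a channel count divisible by 4, got ",
            ch)
  cb <- ch %/% 4L
  par <- if (init == "he")
    list(W1 = he_init(c(cb, 2L * ch), 2L * ch), b1 = numeric(cb),
         W2 = he_init(c(ch, cb), cb), b2 = numeric(ch))
  else
    list(W1 = matrix(0, cb, 2L * ch), b1 = numeric(cb),
         W2 = matrix(0, ch, cb), b2 = numeric(ch))
  new_module("cam", par = par)
}

# spatial mean and max per channel and image; argmax kept for the backward
cam_descriptor <- function(x) {
  d <- dim(x)
  hw <- d[1] * d[2]
  xm <- matrix(x, hw, d[3] * d[4])
  zavg <- matrix(colMeans(xm), d[3], d[4])
  im <- integer(ncol(xm))
  zmax <- numeric(ncol(xm))
  for (k in seq_len(ncol(xm))) {
    im[k] <- which.max(xm[, k])
    zmax[k] <- xm[im[k], k]
  }
  list(z = rbind(zavg, matrix(zmax, d[3], d[4])), im = im)
}

#' @export
vb_forward.vb_cam <- function(m, x, train = FALSE) {
  d <- dim(x)
  de <- cam_descriptor(x)
  a_pre <- m$par$W1 %*% de$z + m$par$b1
  a <- pmax(a_pre, 0)
  s <- sigmoid(m$par$W2 %*% a + m$par$b2)      # C x N channel gates
  m$x <- x
  m$z <- de$z
  m$im <- de$im
  m$a_pre <- a_pre
  m$a <- a
  m$s <- s
  x * bcast_cn(s, d)
}

#' @export
vb_backward.vb_cam <- function(m, gy) {
  d <- dim(m$x)
  hw <- d[1] * d[2]
  ch <- d[3]
  gx <- gy * bcast_cn(m$s, d)
  gs <- csum_cn(gy * m$x)                      # C x N
  gsp <- gs * m$s * (1 - m$s)
  m$grad$W2 <- m$grad$W2 + gsp %*% t(m$a)
  m$grad$b2 <- m$grad$b2 + rowSums(gsp)
  ga <- crossprod(m$par$W2, gsp)
  ga[m$a_pre <= 0] <- 0
  m$grad$W1 <- m$grad$W1 + ga %*% t(m$z)
  m$grad$b1 <- m$grad$b1 + rowSums(ga)
  gz <- crossprod(m$par$W1, ga)                # 2C x N
  gx <- gx + bcast_cn(gz[seq_len(ch), , drop = FALSE], d) / hw
  gmax <- as.vector(gz[ch + seq_len(ch), , drop = FALSE])
  pos <- (seq_along(gmax) - 1) * hw + m$im
  gx[pos] <- gx[pos] + gmax
  gx
}

## ---- PAM ------------------------------------------------------------------

vb_pam <- function(ch, init = c("he", "zeros"), pool = c("mean", "sum")) {
  init <- match.arg(init)
  m <- new_module("pam", children = list(
    proj = vb_conv(ch, 1L, k = 1L, init = init),
    gate = vb_conv(3L, 1L, k = 3L, init = init)
  ))
  m$pool <- match.arg(pool)
  m
}

# the three H x W position descriptors: channel max, channel mean (or literal
# sum), learned 1x1 projection
pam_descriptor <- function(m, x, train = FALSE) {
  d <- dim(x)
  p1 <- x[, , 1L, , drop = FALSE]
  idx <- array(1L, dim(p1))
  if (d[3] > 1L) for (c in 2:d[3]) {
    xc <- x[, , c, , drop = FALSE]
    upd <- xc > p1
    p1[upd] <- xc[upd]
    idx[upd] <- c
  }
  x3 <- array(x, c(d[1] * d[2], d[3], d[4]))
  p2 <- array(0, dim(p1))
  for (n in seq_len(d[4]))
    p2[, , 1L, n] <- rowSums(x3[, , n, drop = FALSE][, , 1L])
  if (m$pool == "mean") p2 <- p2 / d[3]
  p3 <- vb_forward(m$children$proj, x, train)
  z <- array(0, c(d[1], d[2], 3L, d[4]))
  z[, , 1L, ] <- p1
  z[, , 2L, ] <- p2
  z[, , 3L, ] <- p3
  list(z = z, idx = idx)
}

#' @export
vb_forward.vb_pam <- function(m, x, train = FALSE) {
  d <- dim(x)
  de <- pam_descriptor(m, x, train)
  gate <- sigmoid(vb_forward(m$children$gate, de$z, train))  # H,W,1,N
  m$x <- x
  m$idx <- de$idx
  m$gate <- gate
  x * bcast_hw(gate, d)
}

#' @export
vb_backward.vb_pam <- function(m, gy) {
  d <- dim(m$x)
  hw <- d[1] * d[2]
  gx <- gy * bcast_hw(m$gate, d)
  t3 <- array(gy * m$x, c(hw, d[3], d[4]))
  ggate <- array(0, c(d[1], d[2], 1L, d[4]))
  for (n in seq_len(d[4]))
    ggate[, , 1L, n] <- rowSums(t3[, , n, drop = FALSE][, , 1L])
  gpre <- ggate * m$gate * (1 - m$gate)
  gz <- vb_backward(m$children$gate, gpre)
  gx <- gx + vb_backward(m$children$proj, gz[, , 3L, , drop = FALSE])
  g2 <- gz[, , 2L, , drop = FALSE]
  if (m$pool == "mean") g2 <- g2 / d[3]
  gx <- gx + bcast_hw(g2, d)
  # channel-max plane: route gradient to the winning channel at each pixel
  g1 <- as.vector(gz[, , 1L, , drop = FALSE])          # length HW*N
  ci <- as.vector(m$idx)
  n_of <- rep(seq_len(d[4]) - 1L, each = hw)
  hw_of <- rep(seq_len(hw), d[4])
  pos <- (n_of * d[3] + (ci - 1L)) * hw + hw_of
  gx[pos] <- gx[pos] + g1
  gx
}

## ---- DAM ------------------------------------------------------------------

vb_dam <- function(ch, init = c("he", "zeros"), pool = c("mean", "sum")) {
  new_module("dam", children = list(
    cam = vb_cam(ch, init = match.arg(init)),
    pam = vb_pam(ch, init = match.arg(init), pool = match.arg(pool))
  ))
}

#' @export
vb_forward.vb_dam <- function(m, x, train = FALSE) {
  yc <- vb_forward(m$children$cam, x, train)
  yp <- vb_forward(m$children$pam, x, train)
  if (!identical(dim(yc), dim(yp)))
    vb_stop("internal error: attention branch outputs differ in shape")
  yc + yp
}

#' @export
vb_backward.vb_dam <- function(m, gy) {
  vb_backward(m$children$cam, gy) + vb_backward(m$children$pam, gy)
}

## ---- functional interface -------------------------------------------------

#' Gate parameters for the attention modules
#'
#' Creates the learnable parameters shared by the channel and position
#' attention gates: the fully connected bottleneck `W1` (C/4 x 2C) and `W2`
#' (C x C/4) with zero biases, a 1x1 convolution kernel (C -> 1) and a 3x3
#' convolution kernel (3 -> 1). Weights use He-normal initialization unless
#' `init = "zeros"`, which yields the neutral gate (all sigmoid outputs 0.5).
#'
#' @param channels number of feature-map channels C; must be divisible by 4.
#' @param init `"he"` (default) or `"zeros"`.
#' @param seed optional integer seed for reproducible initialization.
#' @return an object of class `vb_gate_params`.
#' @examples
#' p <- gate_params(8, init = "zeros")
#' x <- array(runif(8 * 6 * 6), c(6, 6, 8))
#' max(abs(dual_attention(x, p) - x)) < 1e-12  # neutral identity
#' @export
gate_params <- function(channels, init = c("he", "zeros"), seed = NULL) {
  init <- match.arg(init)
  if (channels %% 4L != 0L)
    vb_stop("channels must be divisible by 4 (bottleneck width C/4)")
  build <- function() {
    cam <- vb_cam(channels, init = init)
    pam <- vb_pam(channels, init = init)
    structure(list(channels = channels,
                   W1 = cam$par$W1, b1 = cam$par$b1,
                   W2 = cam$par$W2, b2 = cam$par$b2,
                   conv1x1 = pam$children$proj$par$W,
                   b1x1 = pam$children$proj$par$b,
                   conv3x3 = pam$children$gate$par$W,
                   b3x3 = pam$children$gate$par$b),
              class = "vb_gate_params")
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

gate_to_dam <- function(params, pool = "mean") {
  stopifnot(inherits(params, "vb_gate_params"))
  m <- vb_dam(params$channels, pool = pool)
  m$children$cam$par <- list(W1 = params$W1, b1 = params$b1,
                             W2 = params$W2, b2 = params$b2)
  m$children$pam$children$proj$par <- list(W = params$conv1x1, b = params$b1x1)
  m$children$pam$children$gate$par <- list(W = params$conv3x3, b = params$b3x3)
  m
}

check_feature_map <- function(x) {
  b <- as_batch(x)
  if (dim(b$x)[1] * dim(b$x)[2] == 0L) vb_stop("empty spatial extent")
  b
}

#' Channel descriptor: spatial mean and max of each channel
#'
#' Summarizes a feature map into a length-2C vector: entries 1..C are the
#' per-channel spatial means (global average pooling) and entries C+1..2C the
#' per-channel spatial maxima (global max pooling), channel order preserved.
#'
#' @param x feature map, an H x W x C array (a matrix is taken as C = 1).
#' @return numeric vector of length 2C.
#' @examples
#' x <- array(5, c(2, 2, 2))
#' channel_descriptor(x)  # c(5, 5, 5, 5)
#' @export
channel_descriptor <- function(x) {
  b <- check_feature_map(x)
  as.vector(cam_descriptor(b$x)$z)
}

#' Position descriptor: three spatial summary planes
#'
#' Returns the H x W x 3 stack of position descriptors: plane 1 the
#' channel-wise maximum, plane 2 the channel-wise mean (or literal sum when
#' `pool = "sum"`), plane 3 the learned 1x1 projection of the channels.
#'
#' @inheritParams channel_attention
#' @param pool `"mean"` (default, matching the average-pooling description)
#'   or `"sum"` for the literal channel sum.
#' @return H x W x 3 array.
#' @export
position_descriptor <- function(x, params, pool = c("mean", "sum")) {
  b <- check_feature_map(x)
  m <- gate_to_dam(params, pool = match.arg(pool))$children$pam
  z <- pam_descriptor(m, b$x)$z
  array(z, dim(z)[1:3])
}

#' Channel attention: rescale channels by a gated global descriptor
#'
#' Each channel of `x` is multiplied by a scalar gate in (0, 1) computed from
#' the 2C channel descriptor through a two-layer bottleneck
#' (`sigmoid(W2 %*% relu(W1 %*% z))`). The output has the input's shape, and
#' within one channel the output/input ratio is constant.
#'
#' @param x feature map, an H x W x C array.
#' @param params a [gate_params()] object whose `channels` equals C.
#' @return array with the same shape as `x`.
#' @export
channel_attention <- function(x, params) {
  b <- check_feature_map(x)
  if (dim(b$x)[3] != params$channels)
    vb_stop("params built for ", params$channels, " channels, feature map has ",
            dim(b$x)[3])
  m <- gate_to_dam(params)$children$cam
  drop_batch(vb_forward(m, b$x), b$ndim)
}

#' Position attention: rescale pixels by a gated spatial descriptor
#'
#' Every pixel of `x` is multiplied (across all channels) by the sigmoid of a
#' 3x3 convolution over the three position descriptor planes.
#'
#' @inheritParams channel_attention
#' @inheritParams position_descriptor
#' @return array with the same shape as `x`.
#' @export
position_attention <- function(x, params, pool = c("mean", "sum")) {
  b <- check_feature_map(x)
  m <- gate_to_dam(params, pool = match.arg(pool))$children$pam
  drop_batch(vb_forward(m, b$x), b$ndim)
}

#' Dual attention: element-wise sum of channel and position attention
#'
#' `dual_attention(x) = channel_attention(x) + position_attention(x)`. With
#' all gate weights and biases zero both gates are 0.5 everywhere, so the
#' module reduces to the identity map.
#'
#' @inheritParams position_attention
#' @return array with the same shape as `x`.
#' @export
dual_attention <- function(x, params, pool = c("mean", "sum")) {
  b <- check_feature_map(x)
  m <- gate_to_dam(params, pool = match.arg(pool))
  drop_batch(vb_forward(m, b$x), b$ndim)
}
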