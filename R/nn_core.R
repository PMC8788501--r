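# Minimal neural-network layer framework.
#
# A module is an environment holding `par` (named list of parameter arrays),
# `grad` (matching gradients, populated by the backward pass), optional
# buffers, and `children` (named list of sub-modules). Forward passes cache
# whatever the analytic backward pass needs inside the module environment.
# Environments give reference semantics, so the optimizer can update
# parameters in place.

new_module <- function(type, par = list(), children = list()) {
  self <- new.env(parent = emptyenv())
  self$par <- par
  self$grad <- lapply(par, function(p) {
    if (is.null(dim(p))) numeric(length(p)) else array(0, dim(p))
  })
  self$children <- children
  class(self) <- c(paste0("vb_", type), "vb_module")
  self
}

vb_forward <- function(m, x, train = FALSE) UseMethod("vb_forward")
vb_backward <- function(m, gy) UseMethod("vb_backward")

#' Collect the parameters of a network module
#'
#' Returns a flat named list of all learnable arrays (names are
#' slash-separated module paths). Used for parameter counting, checkpointing
#' and tests that manipulate weights directly.
#'
#' @param m a network module (e.g. the result of [build_vertebox()]).
#' @param prefix internal; name prefix for recursion.
#' @return named list of numeric arrays.
#' @export
vb_params <- function(m, prefix = "") {
  out <- list()
  for (nm in names(m$par)) out[[paste0(prefix, nm)]] <- m$par[[nm]]
  for (cn in names(m$children))
    out <- c(out, vb_params(m$children[[cn]], paste0(prefix, cn, "/")))
  out
}

#' Overwrite module parameters from a flat named list
#'
#' The inverse of [vb_params()]; unknown names are an error, shapes must
#' match.
#'
#' @param m a network module.
#' @param params flat named list as produced by [vb_params()].
#' @return the module, invisibly (modified in place).
#' @export
vb_set_params <- function(m, params) {
  for (nm in names(params)) {
    parts <- strsplit(nm, "/", fixed = TRUE)[[1]]
    tgt <- m
    if (length(parts) > 1L)
      for (p in parts[-length(parts)]) {
        tgt <- tgt$children[[p]]
        if (is.null(tgt)) vb_stop("unknown module path in parameter name: ", nm)
      }
    leaf <- parts[length(parts)]
    if (is.null(tgt$par[[leaf]])) vb_stop("unknown parameter: ", nm)
    cur <- tgt$par[[leaf]]
    new <- params[[nm]]
    if (!identical(as.integer(dim(cur) %||% length(cur)),
                   as.integer(dim(new) %||% length(new))))
      vb_stop("shape mismatch for parameter: ", nm)
    tgt$par[[leaf]] <- if (is.null(dim(cur))) as.vector(new) else new
  }
  invisible(m)
}

# references to every (module, parameter-name) pair, for the optimizer
vb_param_refs <- function(m) {
  out <- list()
  for (nm in names(m$par)) out[[length(out) + 1L]] <- list(env = m, name = nm)
  for (ch in m$children) out <- c(out, vb_param_refs(ch))
  out
}

#' Collect accumulated parameter gradients
#'
#' Flat named list matching [vb_params()], populated by the most recent
#' backward pass(es) since [vb_zero_grad()].
#' @inheritParams vb_params
#' @return named list of numeric arrays.
#' @export
vb_grads <- function(m, prefix = "") {
  out <- list()
  for (nm in names(m$grad)) out[[paste0(prefix, nm)]] <- m$grad[[nm]]
  for (cn in names(m$children))
    out <- c(out, vb_grads(m$children[[cn]], paste0(prefix, cn, "/")))
  out
}

#' Reset all accumulated gradients to zero
#'
#' @inheritParams vb_params
#' @return the module, invisibly (modified in place).
#' @export
vb_zero_grad <- function(m) {
  for (nm in names(m$grad)) m$grad[[nm]][] <- 0
  for (ch in m$children) vb_zero_grad(ch)
  invisible(m)
}

# buffers (non-learnable state such as batch-norm running moments)
vb_buffers <- function(m, prefix = "") {
  out <- list()
  for (nm in names(m$buf)) out[[paste0(prefix, nm)]] <- m$buf[[nm]]
  for (cn in names(m$children))
    out <- c(out, vb_buffers(m$children[[cn]], paste0(prefix, cn, "/")))
  out
}

vb_set_buffers <- function(m, buffers) {
  for (nm in names(buffers)) {
    parts <- strsplit(nm, "/", fixed = TRUE)[[1]]
    tgt <- m
    if (length(parts) > 1L)
      for (p in parts[-length(parts)]) tgt <- tgt$children[[p]]
    tgt$buf[[parts[length(parts)]]] <- buffers[[nm]]
  }
  invisible(m)
}

#' Count learnable parameters of a module
#' @param m a network module.
#' @return integer, the total number of scalar learnable parameters.
#' @export
vb_n_params <- function(m) sum(vapply(vb_params(m), length, 1L))

he_init <- function(dims, fan_in) {
  array(rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

## ---- convolution ----------------------------------------------------------

vb_conv <- function(in_ch, out_ch, k = 3L, pad = (k - 1L) %/% 2L,
                    init = c("he", "zeros")) {
  init <- match.arg(init)
  w <- if (init == "he") he_init(c(k, k, in_ch, out_ch), k * k * in_ch)
       else array(0, c(k, k, in_ch, out_ch))
  m <- new_module("conv", par = list(W = w, b = numeric(out_ch)))
  m$pad <- as.integer(pad)
  m
}

#' @export
vb_forward.vb_conv <- function(m, x, train = FALSE) {
  m$x <- x
  cpp_conv2d_fw(x, m$par$W, m$par$b, m$pad)
}

#' @export
vb_backward.vb_conv <- function(m, gy) {
  r <- cpp_conv2d_bw(m$x, m$par$W, gy, m$pad)
  m$grad$W <- m$grad$W + r$gw
  m$grad$b <- m$grad$b + r$gb
  r$gx
}

## ---- batch normalization --------------------------------------------------

# Normalizes per channel over (H, W, N) using biased batch variance in
# training mode and running moments in evaluation mode.
vb_bn <- function(ch, eps = 1e-5, momentum = 0.1) {
  m <- new_module("bn", par = list(gamma = rep(1, ch), beta = numeric(ch)))
  m$buf <- list(run_mean = numeric(ch), run_var = rep(1, ch))
  m$eps <- eps
  m$momentum <- momentum
  m
}

#' @export
vb_forward.vb_bn <- function(m, x, train = FALSE) {
  d <- dim(x)
  nM <- d[1] * d[2] * d[4]
  if (train) {
    st <- cpp_chan_stats(x)
    mu <- st$sum / nM
    va <- st$sumsq / nM - mu^2
    m$buf$run_mean <- (1 - m$momentum) * m$buf$run_mean + m$momentum * mu
    m$buf$run_var <- (1 - m$momentum) * m$buf$run_var + m$momentum * va
    m$x <- x
    m$mu <- mu
    m$istd <- 1 / sqrt(va + m$eps)
  } else {
    mu <- m$buf$run_mean
    va <- m$buf$run_var
  }
  cpp_bn_fw(x, m$par$gamma, m$par$beta, mu, 1 / sqrt(va + m$eps))
}

#' @export
vb_backward.vb_bn <- function(m, gy) {
  r <- cpp_bn_bw(m$x, gy, m$par$gamma, m$mu, m$istd)
  m$grad$gamma <- m$grad$gamma + r$dgamma
  m$grad$beta <- m$grad$beta + r$dbeta
  r$gx
}

## ---- elementwise / pooling / resampling -----------------------------------

vb_relu <- function() new_module("relu")

#' @export
vb_forward.vb_relu <- function(m, x, train = FALSE) {
  m$mask <- x > 0
  x * m$mask
}

#' @export
vb_backward.vb_relu <- function(m, gy) gy * m$mask

vb_maxpool <- function() new_module("maxpool")

#' @export
vb_forward.vb_maxpool <- function(m, x, train = FALSE) {
  d <- dim(x)
  m$in_h <- d[1]
  m$in_w <- d[2]
  r <- cpp_maxpool2_fw(x)
  m$idx <- r$idx
  r$y
}

#' @export
vb_backward.vb_maxpool <- function(m, gy) {
  cpp_maxpool2_bw(gy, m$idx, m$in_h, m$in_w)
}

# learnable 2x2 stride-2 transposed convolution (decoder upsampling)
vb_upconv <- function(in_ch, out_ch) {
  w <- he_init(c(2, 2, in_ch, out_ch), in_ch)
  m <- new_module("upconv", par = list(W = w, b = numeric(out_ch)))
  m
}

#' @export
vb_forward.vb_upconv <- function(m, x, train = FALSE) {
  d <- dim(x)
  hw <- d[1] * d[2]
  out_ch <- dim(m$par$W)[4]
  y <- array(0, c(2 * d[1], 2 * d[2], out_ch, d[4]))
  m$x <- x
  for (n in seq_len(d[4])) {
    xm <- matrix(x[, , , n], hw, d[3])
    for (p in 1:2) for (q in 1:2) {
      yb <- xm %*% matrix(m$par$W[p, q, , ], d[3], out_ch)
      y[seq(p, 2 * d[1], 2), seq(q, 2 * d[2], 2), , n] <-
        array(yb, c(d[1], d[2], out_ch))
    }
  }
  sweep(y, 3, m$par$b, `+`)
}

#' @export
vb_backward.vb_upconv <- function(m, gy) {
  d <- dim(m$x)
  hw <- d[1] * d[2]
  out_ch <- dim(m$par$W)[4]
  gx <- array(0, d)
  for (n in seq_len(d[4])) {
    xm <- matrix(m$x[, , , n], hw, d[3])
    gxm <- matrix(0, hw, d[3])
    for (p in 1:2) for (q in 1:2) {
      gb <- matrix(gy[seq(p, 2 * d[1], 2), seq(q, 2 * d[2], 2), , n],
                   hw, out_ch)
      m$grad$W[p, q, , ] <- m$grad$W[p, q, , ] + crossprod(xm, gb)
      gxm <- gxm + gb %*% t(matrix(m$par$W[p, q, , ], d[3], out_ch))
    }
    gx[, , , n] <- array(gxm, c(d[1], d[2], d[3]))
  }
  m$grad$b <- m$grad$b + as.vector(csum_cn(gy) %*% rep(1, d[4]))
  gx
}

# interpolation matrix for 1-D linear resampling with half-pixel alignment
interp_matrix <- function(n_out, n_in) {
  a <- matrix(0, n_out, n_in)
  s <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  s0 <- floor(s)
  w1 <- s - s0
  i0 <- pmin(pmax(s0, 0), n_in - 1) + 1
  i1 <- pmin(pmax(s0 + 1, 0), n_in - 1) + 1
  for (t in seq_len(n_out)) {
    a[t, i0[t]] <- a[t, i0[t]] + (1 - w1[t])
    a[t, i1[t]] <- a[t, i1[t]] + w1[t]
  }
  a
}

# apply separable linear maps A (rows) and B (cols) to a (H,W,C,N) array
apply_sep <- function(x, a, b) {
  d <- dim(x)
  h2 <- nrow(a)
  w2 <- nrow(b)
  y <- array(a %*% matrix(x, d[1], prod(d[-1])), c(h2, d[2], d[3], d[4]))
  y <- aperm(y, c(2, 1, 3, 4))
  y <- array(b %*% matrix(y, d[2], h2 * d[3] * d[4]), c(w2, h2, d[3], d[4]))
  aperm(y, c(2, 1, 3, 4))
}

# fixed (non-learnable) bilinear resize to out_h x out_w
vb_bilinear <- function(out_h, out_w) {
  m <- new_module("bilinear")
  m$out_h <- as.integer(out_h)
  m$out_w <- as.integer(out_w)
  m
}

#' @export
vb_forward.vb_bilinear <- function(m, x, train = FALSE) {
  d <- dim(x)
  if (is.null(m$A) || ncol(m$A) != d[1] || ncol(m$B) != d[2]) {
    m$A <- interp_matrix(m$out_h, d[1])
    m$B <- interp_matrix(m$out_w, d[2])
  }
  apply_sep(x, m$A, m$B)
}

#' @export
vb_backward.vb_bilinear <- function(m, gy) {
  apply_sep(gy, t(m$A), t(m$B))
}

## ---- composition ----------------------------------------------------------

vb_seq <- function(...) {
  ch <- list(...)
  if (length(ch) == 1L && is.list(ch[[1]]) && !inherits(ch[[1]], "vb_module"))
    ch <- ch[[1]]
  if (is.null(names(ch)) || any(names(ch) == ""))
    names(ch) <- paste0("m", seq_along(ch))
  new_module("seq", children = ch)
}

#' @export
vb_forward.vb_seq <- function(m, x, train = FALSE) {
  for (ch in m$children) x <- vb_forward(ch, x, train)
  x
}

#' @export
vb_backward.vb_seq <- function(m, gy) {
  for (ch in rev(m$children)) gy <- vb_backward(ch, gy)
  gy
}

# conv -> batch norm -> ReLU, the standard unit inside multi-scale blocks
vb_cbr <- function(in_ch, out_ch, k = 3L, batchnorm = TRUE, activation = TRUE) {
  ch <- list(conv = vb_conv(in_ch, out_ch, k))
  if (batchnorm) ch$bn <- vb_bn(out_ch)
  if (activation) ch$relu <- vb_relu()
  vb_seq(ch)
}
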