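# Dice loss and the deep-supervision composite objective.
#
# The per-image Dice loss over C classes and N pixels is
#   L(y, P) = 1 - (1/C) * sum_j (2 * sum_i y_ij P_ij + eps) /
#                               (sum_i y_ij + sum_i P_ij + eps)
# with y one-hot ground truth and P per-pixel class probabilities. The
# smoothing constant eps resolves the 0/0 case when a class is absent from
# both y and P (the class term then contributes 1, i.e. no loss). Batches
# are averaged over images. The deep-supervision loss is the
# lambda-weighted sum of the Dice losses of the four auxiliary maps and the
# final map.

#' One-hot encoding of a label image
#'
#' @param labels integer array of 0-based class labels, H x W or H x W x N.
#' @param num_classes number of classes C.
#' @return H x W x C x N array of 0/1 values with per-pixel class sum 1.
#' @export
one_hot <- function(labels, num_classes) {
  d <- dim(labels)
  if (is.null(d)) vb_stop("labels must be a matrix or array")
  if (length(d) == 2L) d <- c(d, 1L)
  labels <- array(as.integer(labels), d)
  if (any(labels < 0L | labels >= num_classes))
    vb_stop("labels out of range 0..", num_classes - 1L)
  y <- array(0, c(d[1], d[2], num_classes, d[3]))
  for (c in seq_len(num_classes))
    y[, , c, ] <- (labels == c - 1L) * 1
  y
}

check_dice_args <- function(y, p) {
  yb <- as_batch(y)$x
  pb <- as_batch(p)$x
  if (!identical(dim(yb), dim(pb)))
    vb_stop("ground truth and prediction shapes differ")
  if (any(p < -1e-9) || any(p > 1 + 1e-9))
    vb_stop("predictions must be probabilities in [0, 1]")
  if (any(y != 0 & y != 1)) vb_stop("ground truth must be one-hot (0/1)")
  cls_sum <- array(0, dim(yb)[c(1, 2, 4)])
  for (c in seq_len(dim(yb)[3]))
    cls_sum <- cls_sum + array(yb[, , c, , drop = FALSE], dim(yb)[c(1, 2, 4)])
  if (max(abs(cls_sum - 1)) > 1e-9)
    vb_stop("ground truth must be exactly one-hot at every pixel")
  list(y = yb, p = pb)
}

#' Dice loss
#'
#' Soft Dice loss between a one-hot label tensor and a probability tensor,
#' averaged over classes (and over images for a batch). 0 for a perfect
#' prediction, approaching 1 for total miss; smoothing `eps` is added to
#' numerator and denominator of each class term.
#'
#' @param y one-hot ground truth, H x W x C (x N) array (see [one_hot()]).
#' @param p predicted per-pixel class probabilities, same shape.
#' @param eps smoothing constant (default 1e-5).
#' @return scalar loss in \[0, 1\].
#' @export
dice_loss <- function(y, p, eps = 1e-5) {
  a <- check_dice_args(y, p)
  inter <- csum_cn(a$y * a$p)           # C x N class overlaps
  denom <- csum_cn(a$y) + csum_cn(a$p)
  mean(1 - colMeans((2 * inter + eps) / (denom + eps)))
}

# gradient of dice_loss w.r.t. p (same shape as p)
dice_loss_grad <- function(y, p, eps = 1e-5) {
  d <- dim(y)
  inter <- csum_cn(y * p)
  denom <- csum_cn(y) + csum_cn(p) + eps
  num <- 2 * inter + eps
  # d term_j / d p_ij = (2 y_ij denom - num) / denom^2
  gterm_y <- bcast_cn(2 / denom, d) * y - bcast_cn(num / denom^2, d)
  -gterm_y / (d[3] * d[4])
}

# Dice loss of softmax(logits) plus its gradient w.r.t. the logits
softmax_dice <- function(y, logits, eps = 1e-5) {
  p <- softmax_cls(logits)
  d <- dim(p)
  gp <- dice_loss_grad(y, p, eps)
  dot <- array(0, d[c(1, 2, 4)])
  for (c in seq_len(d[3]))
    dot <- dot + array((gp * p)[, , c, , drop = FALSE], d[c(1, 2, 4)])
  glog <- p * (gp - bcast_hw(array(dot, c(d[1], d[2], 1L, d[4])), d))
  inter <- csum_cn(y * p)
  denom <- csum_cn(y) + csum_cn(p)
  loss <- mean(1 - colMeans((2 * inter + eps) / (denom + eps)))
  list(loss = loss, grad = glog)
}

#' Deep-supervision loss weights
#'
#' @param lambda_aux nonnegative weights of the four auxiliary terms
#'   (default all 1).
#' @param lambda_final nonnegative weight of the final-map term (default 1).
#' @return a `vb_loss_weights` list.
#' @export
loss_weights <- function(lambda_aux = c(1, 1, 1, 1), lambda_final = 1) {
  if (length(lambda_aux) != 4L)
    vb_stop("lambda_aux must have exactly 4 entries (one per decoder level)")
  if (any(lambda_aux < 0) || lambda_final < 0)
    vb_stop("loss weights must be nonnegative")
  structure(list(lambda_aux = as.numeric(lambda_aux),
                 lambda_final = as.numeric(lambda_final)),
            class = "vb_loss_weights")
}

#' Deep-supervision composite loss
#'
#' Weighted sum of the Dice losses of the four auxiliary coarse maps and the
#' final fused map: `sum_i lambda_i L_i + lambda_P L_P`. Class scores are
#' converted to probabilities by a per-pixel softmax before the Dice term.
#'
#' @param y one-hot ground truth at input resolution, H x W x C (x N).
#' @param preds a `vb_predictions` object from [vertebox_forward()].
#' @param weights a [loss_weights()] object.
#' @param eps Dice smoothing constant.
#' @return scalar loss.
#' @export
deep_supervision_loss <- function(y, preds, weights = loss_weights(),
                                  eps = 1e-5) {
  stopifnot(inherits(preds, "vb_predictions"), inherits(weights,
                                                        "vb_loss_weights"))
  yb <- as_batch(y)$x
  total <- weights$lambda_final * dice_loss(yb, softmax_cls(preds$final), eps)
  for (i in 1:4)
    total <- total + weights$lambda_aux[i] *
      dice_loss(yb, softmax_cls(preds$aux[[i]]), eps)
  total
}

# loss + gradients w.r.t. all five score maps, for the training loop
deep_supervision_grad <- function(y, preds, weights = loss_weights(),
                                  eps = 1e-5) {
  g_aux <- vector("list", 4)
  total <- 0
  for (i in 1:4) {
    r <- softmax_dice(y, preds$aux[[i]], eps)
    total <- total + weights$lambda_aux[i] * r$loss
    g_aux[[i]] <- weights$lambda_aux[i] * r$grad
  }
  r <- softmax_dice(y, preds$final, eps)
  list(loss = total + weights$lambda_final * r$loss, g_aux = g_aux,
       g_final = weights$lambda_final * r$grad)
}
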