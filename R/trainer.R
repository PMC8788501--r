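# Training loop: AdamW, Dice deep supervision, reduce-on-plateau schedule.
#
# Protocol: AdamW with learning rate 0.001 and mini-batches of 16, at most
# 100 epochs; if the validation Dice does not improve for 10 consecutive
# epochs the learning rate is halved ("does not rise" is read as no strict
# improvement over the best value seen so far). Validation Dice is the
# slice-averaged DSC of hard (argmax) predictions of the final head.

#' Training configuration
#'
#' @param lr initial learning rate.
#' @param batch_size mini-batch size.
#' @param max_epochs maximum number of epochs.
#' @param max_steps optional cap on total optimizer steps (Inf = epochs
#'   only); useful for short controlled runs.
#' @param plateau_patience epochs without validation-Dice improvement
#'   before the learning rate is multiplied by `lr_factor`.
#' @param lr_factor multiplicative learning-rate decay (0.5 = halving).
#' @param min_lr lower bound on the learning rate (0 = none).
#' @param weight_decay AdamW decoupled weight decay.
#' @param augment apply training augmentation ([augment_slice()]).
#' @param seed master seed for shuffling, augmentation and initialization.
#' @return a `vb_train_config` list.
#' @export
train_config <- function(lr = 1e-3, batch_size = 16L, max_epochs = 100L,
                         max_steps = Inf, plateau_patience = 10L,
                         lr_factor = 0.5, min_lr = 0, weight_decay = 0.01,
                         augment = TRUE, seed = 1L) {
  if (lr <= 0) vb_stop("lr must be positive")
  if (lr_factor <= 0 || lr_factor >= 1)
    vb_stop("lr_factor must lie strictly between 0 and 1")
  if (plateau_patience < 1L) vb_stop("plateau_patience must be >= 1")
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), max_steps = max_steps,
                 plateau_patience = as.integer(plateau_patience),
                 lr_factor = lr_factor, min_lr = min_lr,
                 weight_decay = weight_decay, augment = isTRUE(augment),
                 seed = as.integer(seed)),
            class = "vb_train_config")
}

#' Initial plateau-scheduler state
#'
#' @param lr initial learning rate.
#' @param patience epochs without improvement before decay.
#' @param factor multiplicative decay.
#' @param min_lr learning-rate floor.
#' @return a `vb_train_state` list.
#' @export
init_train_state <- function(lr = 1e-3, patience = 10L, factor = 0.5,
                             min_lr = 0) {
  structure(list(best_val_dsc = -Inf, epochs_since_improve = 0L,
                 current_lr = lr, patience = as.integer(patience),
                 factor = factor, min_lr = min_lr, n_decays = 0L),
            class = "vb_train_state")
}

#' Reduce-on-plateau learning-rate step
#'
#' Pure state machine applied once per epoch: a validation Dice strictly
#' above the best seen so far resets the counter; otherwise the counter
#' increments, and on reaching `patience` the learning rate is multiplied
#' by `factor` (not below `min_lr`) and the counter resets.
#'
#' @param state a `vb_train_state` from [init_train_state()].
#' @param val_dsc validation Dice of the finished epoch.
#' @return the updated state.
#' @export
lr_step <- function(state, val_dsc) {
  stopifnot(inherits(state, "vb_train_state"))
  if (val_dsc > state$best_val_dsc) {
    state$best_val_dsc <- val_dsc
    state$epochs_since_improve <- 0L
  } else {
    state$epochs_since_improve <- state$epochs_since_improve + 1L
    if (state$epochs_since_improve >= state$patience) {
      state$current_lr <- max(state$min_lr,
                              state$current_lr * state$factor)
      state$n_decays <- state$n_decays + 1L
      state$epochs_since_improve <- 0L
    }
  }
  state
}

pairs_to_batch <- function(pairs, idx) {
  h <- nrow(pairs[[1]]$image)
  x <- array(0, c(h, h, length(idx)))
  y <- array(0L, c(h, h, length(idx)))
  for (j in seq_along(idx)) {
    x[, , j] <- pairs[[idx[j]]]$image
    y[, , j] <- pairs[[idx[j]]]$mask
  }
  list(x = x, y = y)
}

# slice-averaged DSC of hard final-head predictions over a list of pairs
model_dsc <- function(model, pairs, batch_size = 8L, train_mode = FALSE) {
  if (length(pairs) == 0L) return(NA_real_)
  scores <- numeric(length(pairs))
  i <- 1L
  while (i <= length(pairs)) {
    idx <- i:min(i + batch_size - 1L, length(pairs))
    b <- pairs_to_batch(pairs, idx)
    pr <- vertebox_forward(model, b$x, train = train_mode)
    lab <- predict_labels(pr)
    if (is.matrix(lab)) lab <- array(lab, c(dim(lab), 1L))
    for (j in seq_along(idx))
      scores[idx[j]] <- dsc(lab[, , j], b$y[, , j])
    i <- i + length(idx)
  }
  mean(scores)
}

#' Train the network
#'
#' Runs the full protocol on in-memory slice pairs: shuffled mini-batches,
#' forward pass, Dice deep-supervision loss, backward pass, AdamW update;
#' per-epoch validation Dice drives the reduce-on-plateau schedule and
#' best-checkpoint selection.
#'
#' @param net_cfg a [vertebox_config()] (its `input_size` must match the
#'   slice size).
#' @param train_pairs list of `vb_slice_pair` with masks.
#' @param val_pairs optional validation pairs (default: the training pairs,
#'   as in a controlled overfitting run).
#' @param cfg a [train_config()].
#' @param weights [loss_weights()] for the deep-supervision loss.
#' @param checkpoint_path optional path; the best-by-validation-Dice model
#'   is saved there (and training can be resumed from it).
#' @param resume_from optional checkpoint path to resume from.
#' @param verbose print one line per epoch.
#' @return list with `model`, `history` (data frame: epoch, train_loss,
#'   val_dsc, lr, steps), `state` (final scheduler state) and
#'   `best_val_dsc`.
#' @export
train_vertebox <- function(net_cfg, train_pairs, val_pairs = NULL,
                           cfg = train_config(), weights = loss_weights(),
                           checkpoint_path = NULL, resume_from = NULL,
                           verbose = FALSE) {
  stopifnot(inherits(net_cfg, "vertebox_config"),
            inherits(cfg, "vb_train_config"))
  if (length(train_pairs) == 0L) vb_stop("empty training set")
  if (is.null(train_pairs[[1]]$mask)) vb_stop("training pairs lack masks")
  val_pairs <- val_pairs %||% train_pairs

  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_dsc = numeric(), lr = numeric(),
                        steps = integer())
  start_epoch <- 0L
  state <- init_train_state(cfg$lr, cfg$plateau_patience, cfg$lr_factor,
                            cfg$min_lr)
  if (!is.null(resume_from)) {
    ckpt <- load_checkpoint(resume_from)
    model <- ckpt$model
    history <- ckpt$extra$history
    state <- ckpt$extra$state
    start_epoch <- max(history$epoch)
  } else {
    model <- build_vertebox(net_cfg, seed = cfg$seed)
  }
  opt <- adamw_init(model)
  steps <- if (nrow(history)) history$steps[nrow(history)] else 0L
  best <- if (nrow(history)) max(history$val_dsc) else -Inf
  best_params <- vb_params(model)
  best_buffers <- vb_buffers(model)
  seeds <- derive_seeds(cfg$seed + 1L, cfg$max_epochs)

  epoch_seq <- if (start_epoch >= cfg$max_epochs) integer(0)
               else (start_epoch + 1L):cfg$max_epochs
  for (epoch in epoch_seq) {
    if (steps >= cfg$max_steps) break
    ep_losses <- c()
    with_seed(seeds[epoch], {
      order_idx <- sample(length(train_pairs))
      aug_seeds <- sample.int(.Machine$integer.max - 1L,
                              length(train_pairs))
    })
    i <- 1L
    while (i <= length(order_idx) && steps < cfg$max_steps) {
      idx <- order_idx[i:min(i + cfg$batch_size - 1L, length(order_idx))]
      use <- if (cfg$augment)
        lapply(seq_along(idx), function(j)
          augment_slice(train_pairs[[idx[j]]], aug_seeds[idx[j]]))
      else train_pairs[idx]
      b <- pairs_to_batch(use, seq_along(use))
      y1h <- one_hot(b$y, net_cfg$num_classes)
      pr <- vertebox_forward(model, b$x, train = TRUE)
      g <- deep_supervision_grad(y1h, pr, weights)
      if (!is.finite(g$loss))
        vb_stop("non-finite training loss at step ", steps + 1L)
      vb_zero_grad(model)
      vertebox_backward(model, g$g_aux, g$g_final)
      opt <- adamw_step(opt, state$current_lr,
                        weight_decay = cfg$weight_decay)
      ep_losses <- c(ep_losses, g$loss)
      steps <- steps + 1L
      i <- i + length(idx)
    }
    vdsc <- model_dsc(model, val_pairs)
    state <- lr_step(state, vdsc)
    history <- rbind(history,
                     data.frame(epoch = epoch,
                                train_loss = mean(ep_losses),
                                val_dsc = vdsc, lr = state$current_lr,
                                steps = steps))
    if (vdsc > best) {
      best <- vdsc
      best_params <- vb_params(model)
      best_buffers <- vb_buffers(model)
      if (!is.null(checkpoint_path))
        save_checkpoint(model, checkpoint_path,
                        extra = list(history = history, state = state))
    }
    if (verbose)
      cat(sprintf("epoch %3d  loss %.4f  val DSC %.4f  lr %.2e\n", epoch,
                  mean(ep_losses), vdsc, state$current_lr))
    if (steps >= cfg$max_steps) break
  }
  vb_set_params(model, best_params)
  vb_set_buffers(model, best_buffers)
  if (!is.null(checkpoint_path))
    save_checkpoint(model, checkpoint_path,
                    extra = list(history = history, state = state))
  list(model = model, history = history, state = state,
       best_val_dsc = best)
}

#' Segment a CT volume slice by slice
#'
#' Applies the training-time preprocessing (intensity windowing if
#' requested, isotropic resampling, axial slicing, resizing — but no
#' augmentation), predicts each slice with the final network head, and
#' restacks the argmax labels on the resampled grid, resized back to the
#' slice geometry with nearest-neighbor interpolation.
#'
#' @param model a trained `vb_vertebox` (or path to a checkpoint file).
#' @param volume 3-D intensity array, or a path readable by
#'   [load_volume()].
#' @param meta required when `volume` is an array: list with `spacing`.
#' @param window HU window for [normalize_ct()], or NULL if the volume is
#'   already normalized to \[0, 1\].
#' @param batch_size slices per forward pass.
#' @return integer label volume aligned with the resampled (1 mm) grid of
#'   the input, with its `meta` attached as attribute `meta`.
#' @export
predict_volume <- function(model, volume, meta = NULL,
                           window = c(-200, 1200), batch_size = 8L) {
  if (is.character(model)) model <- load_checkpoint(model)$model
  stopifnot(inherits(model, "vb_vertebox"))
  if (is.character(volume)) {
    v <- load_volume(volume)
    volume <- v$image
    meta <- v$meta
  }
  if (is.null(meta$spacing)) vb_stop("volume spacing metadata is missing")
  if (!is.null(window)) volume <- normalize_ct(volume, window)
  rs <- resample_isotropic(volume, meta)
  d <- dim(rs$image)
  size <- model$cfg$input_size
  pairs <- slice_and_resize(rs$image, labels = NULL, size = size)
  out <- array(0L, d)
  i <- 1L
  while (i <= d[3]) {
    idx <- i:min(i + batch_size - 1L, d[3])
    x <- array(0, c(size, size, length(idx)))
    for (j in seq_along(idx)) x[, , j] <- pairs[[idx[j]]]$image
    lab <- predict_labels(vertebox_forward(model, x, train = FALSE))
    if (is.matrix(lab)) lab <- array(lab, c(dim(lab), 1L))
    for (j in seq_along(idx))
      out[, , idx[j]] <- as.integer(resize_2d(lab[, , j], d[1], d[2],
                                              nearest = TRUE))
    i <- i + length(idx)
  }
  attr(out, "meta") <- rs$meta
  out
}
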