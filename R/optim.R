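# AdamW optimizer (decoupled weight decay).
#
# Maintains first/second moment estimates per parameter and applies
#   p <- p - lr * ( m_hat / (sqrt(v_hat) + eps) + weight_decay * p )
# with the usual bias corrections. Operates on module parameter references,
# so updates happen in place.

adamw_init <- function(model) {
  refs <- vb_param_refs(model)
  list(refs = refs, t = 0L,
       m = lapply(refs, function(r) r$env$par[[r$name]] * 0),
       v = lapply(refs, function(r) r$env$par[[r$name]] * 0))
}

adamw_step <- function(opt, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       weight_decay = 0.01) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (i in seq_along(opt$refs)) {
    r <- opt$refs[[i]]
    g <- r$env$grad[[r$name]]
    opt$m[[i]] <- beta1 * opt$m[[i]] + (1 - beta1) * g
    opt$v[[i]] <- beta2 * opt$v[[i]] + (1 - beta2) * g * g
    p <- r$env$par[[r$name]]
    upd <- (opt$m[[i]] / bc1) / (sqrt(opt$v[[i]] / bc2) + eps) +
      weight_decay * p
    r$env$par[[r$name]] <- p - lr * upd
  }
  opt
}
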