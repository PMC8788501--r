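# Network assembly, shape ladder, prediction heads.

mini_cfg <- function(...) vertebox_config(base_width = 8L, input_size = 64L,
                                          ...)

test_that("configuration invariants are enforced", {
  expect_error(vertebox_config(base_width = 10L), "divisible by 4")
  expect_error(vertebox_config(input_size = 100L), "2\\^5")
  expect_error(vertebox_config(num_classes = 1L), ">= 2")
})

test_that("the miniature builds and its encoder ladder halves size and
           doubles width", {
  model <- build_vertebox(mini_cfg(), seed = 1)
  x <- array(runif(64 * 64), c(64, 64, 1, 1))
  e <- x
  sizes <- integer(5)
  widths <- integer(5)
  for (k in 1:5) {
    if (k > 1) e <- vertebox:::vb_forward(
      model$children[[paste0("pool", k)]], e)
    e <- vertebox:::vb_forward(model$children[[paste0("enc", k)]], e, TRUE)
    sizes[k] <- dim(e)[1]
    widths[k] <- dim(e)[3]
  }
  expect_identical(sizes, c(64L, 32L, 16L, 8L, 4L))
  expect_identical(widths, c(8L, 16L, 32L, 64L, 128L))
})

test_that("total parameter count matches an independent per-layer tally", {
  model <- build_vertebox(mini_cfg(), seed = 1)
  conv_p <- function(k, cin, cout) k * k * cin * cout + cout
  bn_p <- function(c) 2 * c
  cbr_p <- function(k, cin, cout) conv_p(k, cin, cout) + bn_p(cout)
  res2_p <- function(c, s) {
    mid <- s * (c %/% s)
    ws <- mid / s
    cbr_p(1, c, mid) + (s - 1) * cbr_p(3, ws, ws) + cbr_p(1, mid, c)
  }
  ms_p <- function(cin, cout, s) cbr_p(3, cin, cout) + 2 * res2_p(cout, s)
  cam_p <- function(c) (c / 4) * 2 * c + c / 4 + c * (c / 4) + c
  pam_p <- function(c) conv_p(1, c, 1) + conv_p(3, 3, 1)
  up_p <- function(cin, cout) 2 * 2 * cin * cout + cout
  w <- 8 * 2^(0:4)
  s_enc <- c(4, 4, 4, 6, 6)
  s_dec <- c(6, 6, 4, 4)
  total <- ms_p(1, w[1], s_enc[1])
  for (k in 2:5) total <- total + ms_p(w[k - 1], w[k], s_enc[k])
  for (k in 1:4) total <- total + cam_p(w[k])
  total <- total + cam_p(w[5]) + pam_p(w[5])              # DAM = CAM + PAM
  for (k in 1:4) {
    wk <- w[5 - k]
    total <- total + up_p(if (k == 1) w[5] else w[6 - k], wk) +
      ms_p(2 * wk, wk, s_dec[k]) + conv_p(1, wk, 2)
  }
  total <- total + conv_p(1, 8, 2)                        # fusion head
  expect_equal(vb_n_params(model), total)
})

test_that("forward returns five full-resolution maps and eval mode is
           deterministic", {
  model <- build_vertebox(mini_cfg(), seed = 2)
  set.seed(3)
  x <- array(runif(64 * 64 * 2), c(64, 64, 2))
  pr <- vertebox_forward(model, x, train = TRUE)   # populate BN buffers
  pr1 <- vertebox_forward(model, x, train = FALSE)
  pr2 <- vertebox_forward(model, x, train = FALSE)
  expect_length(pr1$aux, 4)
  for (m in c(pr1$aux, list(pr1$final)))
    expect_identical(dim(m), c(64L, 64L, 2L, 2L))
  expect_identical(pr1$final, pr2$final)           # bit-identical repeats
  for (k in 1:4) expect_identical(pr1$aux[[k]], pr2$aux[[k]])
  expect_error(vertebox_forward(model, array(0.1, c(32, 32, 1))),
               "input_size")
})

test_that("with zero attention gates the network equals its neutral-gate
           twin (identity bottleneck, half-scaled skips)", {
  cfg <- mini_cfg(batchnorm = FALSE)
  model <- build_vertebox(cfg, seed = 4)
  # zero every attention parameter -> CAM/PAM gates become 0.5, DAM identity
  p <- vb_params(model)
  att <- grep("^(cam[1-4]|dam)/", names(p), value = TRUE)
  for (nm in att) p[[nm]][] <- 0
  vb_set_params(model, p)
  set.seed(5)
  x <- array(runif(64 * 64), c(64, 64, 1))
  pr <- vertebox_forward(model, x, train = TRUE)

  # manual twin pass with the attention children replaced by their neutral
  # gates: the zeroed DAM is exactly the identity (0.5x + 0.5x) on the
  # bottleneck, while each zeroed CAM is the constant 0.5 channel scaling
  ch <- model$children
  xb <- array(x, c(64, 64, 1, 1))
  e <- vertebox:::vb_forward(ch$enc1, xb, TRUE)
  es <- list(e)
  for (k in 2:5) {
    e <- vertebox:::vb_forward(ch[[paste0("enc", k)]],
                               vertebox:::vb_forward(
                                 ch[[paste0("pool", k)]], e, TRUE), TRUE)
    es[[k]] <- e
  }
  prev <- es[[5]]
  aux <- list()
  for (k in 1:4) {
    up <- vertebox:::vb_forward(ch[[paste0("up", k)]], prev, TRUE)
    skip <- 0.5 * es[[5 - k]]
    cat_in <- array(0, dim(up) + c(0, 0, dim(skip)[3], 0))
    cat_in[, , seq_len(dim(up)[3]), ] <- up
    cat_in[, , dim(up)[3] + seq_len(dim(skip)[3]), ] <- skip
    prev <- vertebox:::vb_forward(ch[[paste0("dec", k)]], cat_in, TRUE)
    h <- vertebox:::vb_forward(ch[[paste0("head", k)]], prev, TRUE)
    aux[[k]] <- vertebox:::vb_forward(ch[[paste0("bil", k)]], h, TRUE)
  }
  for (k in 1:4)
    expect_equal(pr$aux[[k]], aux[[k]], tolerance = 1e-10)
})

test_that("predict_labels takes the final-map argmax with ties to
           background", {
  mk_pred <- function(final) structure(
    list(aux = replicate(4, final, simplify = FALSE), final = final),
    class = "vb_predictions")
  f <- array(0, c(3, 3, 2, 1))
  f[, , 2, ] <- 1                        # class 1 wins everywhere
  expect_true(all(predict_labels(mk_pred(f)) == 1L))
  f[, , 2, ] <- 0                        # exact ties -> class 0
  expect_true(all(predict_labels(mk_pred(f)) == 0L))
  # random scores match a brute-force per-pixel argmax
  set.seed(6)
  fr <- array(rnorm(4 * 5 * 3 * 2), c(4, 5, 3, 2))
  lab <- predict_labels(mk_pred(fr))
  for (n in 1:2) for (i in 1:4) for (j in 1:5) {
    sc <- fr[i, j, , n]
    expect_equal(lab[i, j, n], which.max(sc) - 1L)
  }
})

test_that("one deep-supervision backward pass reaches every head", {
  model <- build_vertebox(mini_cfg(), seed = 7)
  set.seed(8)
  x <- array(runif(64 * 64), c(64, 64, 1))
  y <- one_hot(array(rand_mask(64, 64, 0.2), c(64, 64, 1)), 2)
  pr <- vertebox_forward(model, x, train = TRUE)
  g <- vertebox:::deep_supervision_grad(y, pr)
  vb_zero_grad(model)
  vertebox:::vertebox_backward(model, g$g_aux, g$g_final)
  for (k in 1:4) {
    gh <- vertebox:::vb_grads(model$children[[paste0("head", k)]])
    expect_gt(sqrt(sum(gh$W^2)), 0)
    expect_gt(sqrt(sum(gh$b^2)), 0)
  }
  gf <- vertebox:::vb_grads(model$children$fuse)
  expect_gt(sqrt(sum(gf$W^2)), 0)
})

test_that("whole-network analytic gradients match finite differences on a
           smooth configuration", {
  cfg <- vertebox_config(base_width = 4L, input_size = 32L,
                         activation = FALSE)
  model <- build_vertebox(cfg, seed = 9)
  set.seed(10)
  x <- array(rnorm(32 * 32), c(32, 32, 1))
  y <- one_hot(array(rand_mask(32, 32, 0.3), c(32, 32, 1)), 2)
  pr <- vertebox_forward(model, x, train = TRUE)
  g <- vertebox:::deep_supervision_grad(y, pr)
  vb_zero_grad(model)
  vertebox:::vertebox_backward(model, g$g_aux, g$g_final)
  gs <- vertebox:::vb_grads(model)
  ps <- vb_params(model)
  lossfun <- function() deep_supervision_loss(
    y, vertebox_forward(model, x, train = TRUE))
  set.seed(11)
  for (nm in sample(names(ps), 12)) {
    i <- sample(length(ps[[nm]]), 1)
    eps <- 1e-6
    p2 <- ps; p2[[nm]][i] <- p2[[nm]][i] + eps
    vb_set_params(model, p2); lp <- lossfun()
    p2[[nm]][i] <- p2[[nm]][i] - 2 * eps
    vb_set_params(model, p2); lm <- lossfun()
    vb_set_params(model, ps)
    expect_equal(gs[[nm]][i], (lp - lm) / (2 * eps),
                 tolerance = 1e-4)
  }
})

test_that("checkpoints round-trip parameters and buffers", {
  model <- build_vertebox(mini_cfg(), seed = 12)
  set.seed(13)
  x <- array(runif(64 * 64), c(64, 64, 1))
  invisible(vertebox_forward(model, x, train = TRUE))  # move BN buffers
  path <- tempfile(fileext = ".rds")
  save_checkpoint(model, path, extra = list(note = "t"))
  ck <- load_checkpoint(path)
  expect_equal(vb_params(ck$model), vb_params(model))
  p1 <- vertebox_forward(model, x, train = FALSE)
  p2 <- vertebox_forward(ck$model, x, train = FALSE)
  expect_equal(p1$final, p2$final, tolerance = 1e-12)
  expect_equal(ck$extra$note, "t")
  file.remove(path)
})
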