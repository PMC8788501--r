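# Plateau schedule, training mechanics, volume prediction.

test_that("lr_step halves the rate exactly at the stated plateau points", {
  st <- init_train_state(lr = 1e-3, patience = 10L, factor = 0.5)
  # improvement then ten flat epochs: one halving after the 10th
  st <- lr_step(st, 0.5)
  for (i in 1:9) {
    st <- lr_step(st, 0.4)
    expect_equal(st$current_lr, 1e-3)
  }
  st <- lr_step(st, 0.4)
  expect_equal(st$current_lr, 5e-4)
  expect_equal(st$n_decays, 1L)

  # strictly increasing sequence: never changes
  st2 <- init_train_state(1e-3, 10L, 0.5)
  for (v in seq(0.1, 0.9, length.out = 30)) st2 <- lr_step(st2, v)
  expect_equal(st2$current_lr, 1e-3)

  # two consecutive plateaus of length 10 -> quartered
  st3 <- init_train_state(1e-3, 10L, 0.5)
  st3 <- lr_step(st3, 0.5)
  for (i in 1:20) st3 <- lr_step(st3, 0.5)   # equal values never improve
  expect_equal(st3$current_lr, 1e-3 * 0.25)
  expect_equal(st3$n_decays, 2L)
})

test_that("lr_step matches an exhaustive state-machine simulation on random
           validation sequences", {
  simulate <- function(vals, lr0, patience, factor) {
    best <- -Inf; since <- 0L; lr <- lr0; out <- numeric(length(vals))
    for (i in seq_along(vals)) {
      if (vals[i] > best) { best <- vals[i]; since <- 0L }
      else {
        since <- since + 1L
        if (since >= patience) { lr <- lr * factor; since <- 0L }
      }
      out[i] <- lr
    }
    out
  }
  set.seed(1)
  for (rep in 1:20) {
    vals <- round(runif(100, 0, 1), 2)       # repeated values force plateaus
    patience <- sample(2:10, 1)
    st <- init_train_state(1e-3, patience, 0.5)
    got <- numeric(100)
    for (i in 1:100) {
      st <- lr_step(st, vals[i])
      got[i] <- st$current_lr
    }
    expect_equal(got, simulate(vals, 1e-3, patience, 0.5))
  }
})

test_that("the first training step optimizes exactly the deep-supervision
           loss of its forward pass", {
  pairs <- tiny_phantom_set(4)
  net_cfg <- vertebox_config(base_width = 8L, input_size = 64L)
  cfg <- train_config(batch_size = 4L, max_steps = 1L, max_epochs = 1L,
                      augment = FALSE, seed = 31L)
  fit <- train_vertebox(net_cfg, pairs, pairs, cfg)
  # replay: same seed -> same initialization and same (single) batch
  model <- build_vertebox(net_cfg, seed = cfg$seed)
  seeds <- vertebox:::derive_seeds(cfg$seed + 1L, cfg$max_epochs)
  order_idx <- vertebox:::with_seed(seeds[1], sample(length(pairs)))
  b <- vertebox:::pairs_to_batch(pairs, order_idx[1:4])
  pr <- vertebox_forward(model, b$x, train = TRUE)
  want <- deep_supervision_loss(one_hot(b$y, 2), pr)
  expect_equal(fit$history$train_loss[1], want, tolerance = 1e-10)
})

test_that("training runs are reproducible and resume from a checkpoint
           continues the saved history", {
  pairs <- tiny_phantom_set(4)
  net_cfg <- vertebox_config(base_width = 8L, input_size = 64L)
  cfg <- train_config(batch_size = 4L, max_epochs = 2L, augment = TRUE,
                      seed = 41L)
  f1 <- train_vertebox(net_cfg, pairs, pairs, cfg)
  f2 <- train_vertebox(net_cfg, pairs, pairs, cfg)
  expect_equal(f1$history, f2$history, tolerance = 1e-12)

  path <- tempfile(fileext = ".rds")
  f3 <- train_vertebox(net_cfg, pairs, pairs, cfg, checkpoint_path = path)
  cfg4 <- train_config(batch_size = 4L, max_epochs = 3L, augment = TRUE,
                       seed = 41L)
  f4 <- train_vertebox(net_cfg, pairs, pairs, cfg4, resume_from = path)
  expect_equal(f4$history[1:2, ], f3$history, tolerance = 1e-12)
  expect_equal(nrow(f4$history), 3)
  file.remove(path)
})

test_that("empty or unlabeled data is rejected and non-finite losses
           abort", {
  net_cfg <- vertebox_config(base_width = 8L, input_size = 64L)
  expect_error(train_vertebox(net_cfg, list(), cfg = train_config()),
               "empty")
  p <- tiny_phantom_set(1)
  p[[1]]$mask <- NULL
  expect_error(train_vertebox(net_cfg, p, cfg = train_config()), "mask")
})

test_that("predict_volume restacks per-slice predictions on the input
           grid deterministically", {
  pairs <- tiny_phantom_set(3, seed = 23)
  vol <- phantoms_to_volume(pairs)
  net_cfg <- vertebox_config(base_width = 8L, input_size = 64L)
  model <- build_vertebox(net_cfg, seed = 51)
  invisible(vertebox_forward(model, vol$image[, , 1], train = TRUE))
  seg1 <- predict_volume(model, vol$image, meta = vol$meta, window = NULL)
  seg2 <- predict_volume(model, vol$image, meta = vol$meta, window = NULL)
  expect_identical(dim(seg1), dim(vol$image))
  expect_identical(seg1, seg2)
  expect_true(all(seg1 %in% 0:1))
  expect_error(predict_volume(model, vol$image, meta = list(),
                              window = NULL),
               "spacing")
})
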