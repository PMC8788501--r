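# Dice loss and deep supervision.

test_that("dice loss closed forms: perfect, hand example, total miss", {
  # perfect prediction on a mask with both classes present
  y <- one_hot(rand_mask(8, 8, 0.4, seed = 1), 2)
  expect_lt(dice_loss(y, y), 1e-4)

  # 4-pixel hand evaluation: fg term 2/3, bg term 4/5, loss 0.2667
  yfg <- c(1, 1, 0, 0)
  pfg <- c(1, 0, 0, 0)
  y4 <- array(c(1 - yfg, yfg), c(1, 4, 2))
  p4 <- array(c(1 - pfg, pfg), c(1, 4, 2))
  expect_equal(dice_loss(y4, p4, eps = 0), 1 - (2 / 3 + 4 / 5) / 2,
               tolerance = 1e-12)
  expect_equal(dice_loss(y4, p4), 0.2667, tolerance = 1e-3)

  # total miss: loss -> 1 as eps -> 0
  expect_equal(dice_loss(y4, 1 - y4, eps = 1e-12), 1, tolerance = 1e-6)
})

test_that("dice loss stays in [0,1], is permutation invariant, and matches
           an independent implementation on random inputs", {
  set.seed(2)
  for (rep in 1:10) {
    m <- rand_mask(6, 7, runif(1, 0.1, 0.9))
    y <- one_hot(m, 2)[, , , 1]
    praw <- array(runif(6 * 7 * 2), c(6, 7, 2))
    tot <- praw[, , 1] + praw[, , 2]
    p <- array(c(praw[, , 1] / tot, praw[, , 2] / tot), c(6, 7, 2))
    l <- dice_loss(y, p, eps = 0)
    expect_gte(l, 0)
    expect_lte(l, 1)
    expect_equal(l, oracle_dice_loss(y, p), tolerance = 1e-12)
    # permute pixels consistently in y and p
    perm <- sample(42)
    yp <- array(c(y[, , 1][perm], y[, , 2][perm]), c(6, 7, 2))
    pp <- array(c(p[, , 1][perm], p[, , 2][perm]), c(6, 7, 2))
    expect_equal(dice_loss(yp, pp, eps = 0), l, tolerance = 1e-12)
  }
})

test_that("invalid inputs are rejected", {
  y <- one_hot(rand_mask(4, 4, 0.5, seed = 3), 2)
  expect_error(dice_loss(y, array(0.5, c(4, 5, 2))), "shapes differ")
  expect_error(dice_loss(y, array(1.5, c(4, 4, 2))), "probabilities")
  ybad <- y
  ybad[1, 1, , 1] <- c(1, 1)
  expect_error(dice_loss(ybad, y), "one-hot")
  expect_error(loss_weights(lambda_aux = c(1, 1, 1)), "4 entries")
})

fake_predictions <- function(h, w, ccls, n, seed) {
  set.seed(seed)
  mk <- function() array(rnorm(h * w * ccls * n), c(h, w, ccls, n))
  structure(list(aux = list(mk(), mk(), mk(), mk()), final = mk()),
            class = "vb_predictions")
}

test_that("deep supervision is the weighted sum of per-map dice terms", {
  y <- one_hot(array(rand_mask(8, 8, 0.3, seed = 4), c(8, 8, 1)), 2)
  pr <- fake_predictions(8, 8, 2, 1, seed = 5)

  # weight zeroing: only the final map contributes
  wf <- loss_weights(lambda_aux = c(0, 0, 0, 0), lambda_final = 1)
  expect_equal(deep_supervision_loss(y, pr, wf),
               dice_loss(y, vertebox:::softmax_cls(pr$final)),
               tolerance = 1e-12)

  # identical maps with unit weights: five times one term
  pr5 <- structure(list(aux = list(pr$final, pr$final, pr$final, pr$final),
                        final = pr$final), class = "vb_predictions")
  expect_equal(deep_supervision_loss(y, pr5),
               5 * dice_loss(y, vertebox:::softmax_cls(pr$final)),
               tolerance = 1e-12)

  # random weights: explicit term-by-term sum
  set.seed(6)
  lam <- runif(5)
  w <- loss_weights(lam[1:4], lam[5])
  terms <- vapply(pr$aux, function(m)
    dice_loss(y, vertebox:::softmax_cls(m)), 1)
  expect_equal(deep_supervision_loss(y, pr, w),
               sum(lam[1:4] * terms) +
                 lam[5] * dice_loss(y, vertebox:::softmax_cls(pr$final)),
               tolerance = 1e-12)
})

test_that("deep supervision is linear in each lambda", {
  y <- one_hot(array(rand_mask(6, 6, 0.4, seed = 7), c(6, 6, 1)), 2)
  pr <- fake_predictions(6, 6, 2, 1, seed = 8)
  base <- deep_supervision_loss(y, pr, loss_weights(c(0, 0, 0, 0), 0))
  expect_equal(base, 0)
  for (i in 1:4) {
    lam <- rep(0, 4)
    lam[i] <- 1
    l1 <- deep_supervision_loss(y, pr, loss_weights(lam, 0))
    expect_equal(deep_supervision_loss(y, pr, loss_weights(2 * lam, 0)),
                 2 * l1, tolerance = 1e-12)
  }
})

test_that("analytic loss gradients match finite differences through the
           softmax", {
  set.seed(9)
  y <- one_hot(array(rand_mask(5, 5, 0.4), c(5, 5, 1)), 2)
  logits <- array(rnorm(5 * 5 * 2), c(5, 5, 2, 1))
  r <- vertebox:::softmax_dice(y, logits)
  eps <- 1e-6
  for (i in sample(length(logits), 12)) {
    lp <- logits; lp[i] <- lp[i] + eps
    lm <- logits; lm[i] <- lm[i] - eps
    num <- (vertebox:::softmax_dice(y, lp)$loss -
            vertebox:::softmax_dice(y, lm)$loss) / (2 * eps)
    expect_equal(r$grad[i], num, tolerance = 1e-5)
  }
})
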