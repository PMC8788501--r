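# Shared fixtures and small independent oracles used across the suite.

rand_feature_map <- function(h, w, c, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(rnorm(h * w * c), c(h, w, c))
}

# random binary mask with roughly the given foreground fraction
rand_mask <- function(h, w, frac = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(as.integer(runif(h * w) < frac), h, w)
}

# independent straight-line Dice computation on plain vectors (per class)
oracle_dice_loss <- function(y, p, eps = 0) {
  stopifnot(identical(dim(y), dim(p)))
  ccls <- dim(y)[3]
  terms <- vapply(seq_len(ccls), function(j) {
    yy <- y[, , j]
    pp <- p[, , j]
    (2 * sum(yy * pp) + eps) / (sum(yy) + sum(pp) + eps)
  }, 1)
  1 - mean(terms)
}

# brute-force directed+pooled percentile Hausdorff over point matrices
oracle_hd <- function(pa, pb, percentile = 95) {
  da <- apply(pa, 1, function(r)
    min(sqrt(colSums((t(pb) - r)^2))))
  db <- apply(pb, 1, function(r)
    min(sqrt(colSums((t(pa) - r)^2))))
  unname(quantile(c(da, db), percentile / 100, type = 7))
}

# scalar, loop-based boundary extraction (4-neighborhood, edges = boundary)
oracle_boundary <- function(mask) {
  d <- dim(mask)
  pts <- NULL
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    if (mask[i, j] != 1) next
    nb <- c(if (i > 1) mask[i - 1, j] else 0,
            if (i < d[1]) mask[i + 1, j] else 0,
            if (j > 1) mask[i, j - 1] else 0,
            if (j < d[2]) mask[i, j + 1] else 0)
    if (any(nb == 0)) pts <- rbind(pts, c(i, j))
  }
  pts
}

# tiny phantom training set reused by trainer tests
tiny_phantom_set <- function(n = 4, seed = 21) {
  generate_dataset(n, "easy", seed = seed, image_size = 64)$pairs
}
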