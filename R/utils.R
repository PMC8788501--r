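`%||%` <- function(a, b) if (is.null(a)) b else a

vb_stop <- function(...) stop(..., call. = FALSE)

#' Run code with a temporarily seeded RNG
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so seeded generators (phantoms, augmentation) do not
#' disturb the global random stream.
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# derive a stream of per-item seeds from a master seed, kept within 32-bit range
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# coerce (H,W) or (H,W,C) input to the internal (H,W,C,N) batch layout;
# returns list(x = array, ndim_in = original dimensionality)
as_batch <- function(x) {
  d <- dim(x)
  if (is.null(d)) vb_stop("input must be a matrix or array")
  if (length(d) == 2L) d <- c(d, 1L, 1L)
  else if (length(d) == 3L) d <- c(d, 1L)
  else if (length(d) != 4L) vb_stop("input must have 2-4 dimensions")
  if (any(!is.finite(x))) vb_stop("input contains non-finite values")
  list(x = array(as.double(x), d), ndim = length(dim(x) %||% d))
}

drop_batch <- function(x, ndim) {
  if (ndim >= 4L) return(x)
  d <- dim(x)
  array(x, d[seq_len(ndim)])
}

# broadcast a (C x N) matrix over the spatial plane of a (H,W,C,N) array
bcast_cn <- function(s, dims) {
  array(rep(as.vector(s), each = dims[1] * dims[2]), dims)
}

# broadcast a (H,W,1,N) map over the channel dimension
bcast_hw <- function(g, dims) {
  hw <- dims[1] * dims[2]
  gm <- matrix(g, hw, dims[4])
  array(gm[, rep(seq_len(dims[4]), each = dims[3]), drop = FALSE], dims)
}

# per-channel-and-image summaries of a (H,W,C,N) array, as (C x N) matrices
csum_cn <- function(x) {
  d <- dim(x)
  matrix(colSums(matrix(x, d[1] * d[2], d[3] * d[4])), d[3], d[4])
}
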