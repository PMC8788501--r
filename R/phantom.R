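# Parametric vertebra phantoms.
#
# A phantom slice emulates the structures that make axial vertebra
# segmentation hard: a bright elliptical vertebral body with narrow attached
# processes (small objects), soft-tissue distractor blobs whose gray level
# matches the bone (interference), an optional hyper-intense lesion patch
# inside the body, and additive Gaussian noise. Geometry is deliberately
# minimal (ellipse + rectangles); anatomical realism is a non-goal - the
# phantoms exist to exercise the challenge structure, not to imitate CT.

pixel_grid <- function(size) {
  list(y = matrix(rep(seq_len(size), size), size, size),
       x = matrix(rep(seq_len(size), each = size), size, size))
}

ellipse_mask <- function(size, center, axes, angle = 0) {
  g <- pixel_grid(size)
  dy <- g$y - center[1]
  dx <- g$x - center[2]
  u <- dx * cos(angle) + dy * sin(angle)
  v <- -dx * sin(angle) + dy * cos(angle)
  (u / axes[1])^2 + (v / axes[2])^2 <= 1
}

# rectangle attached to the body: starts at radius r0 from `center` along
# direction `phi`, extends `len` outward with half-width `hw`
process_mask <- function(size, center, phi, r0, len, hw) {
  g <- pixel_grid(size)
  dy <- g$y - center[1]
  dx <- g$x - center[2]
  along <- dx * cos(phi) + dy * sin(phi)
  across <- -dx * sin(phi) + dy * cos(phi)
  along >= r0 & along <= r0 + len & abs(across) <= hw
}

#' Specification of a synthetic vertebra slice
#'
#' All geometry is in pixels, intensities on the \[0, 1\] gray scale. The
#' spec fully determines the phantom: stochastic elements (distractor
#' placement, noise) are drawn from `seed`, so [generate_phantom()] is a
#' pure function of its spec.
#'
#' @param image_size square image size in pixels.
#' @param body list with `center` (y, x), `axes` (semi-axes a, b), `angle`
#'   (radians) and `intensity` of the vertebral body ellipse.
#' @param processes list with `count` (1-3), `length`, `width` and optional
#'   `intensity` (defaults to the body intensity) of the attached process
#'   rectangles (first points caudally, further ones laterally).
#' @param distractors list with `count` and `intensity_offset` (distractor
#'   gray level = body intensity + offset) and optional `axes` range.
#' @param lesion list with `present`, `boost` (added intensity) and
#'   `radius`.
#' @param noise_sigma standard deviation of the additive Gaussian noise.
#' @param background background gray level.
#' @param seed integer seed controlling all random draws.
#' @return a `vb_phantom_spec` list.
#' @export
phantom_spec <- function(image_size = 256L,
                         body = list(center = NULL, axes = NULL, angle = 0,
                                     intensity = 0.62),
                         processes = list(count = 3L, length = NULL,
                                          width = NULL, intensity = NULL),
                         distractors = list(count = 0L,
                                            intensity_offset = 0.03,
                                            axes = NULL),
                         lesion = list(present = FALSE, boost = 0.2,
                                       radius = NULL),
                         noise_sigma = 0.01, background = 0.12, seed = 1L) {
  s <- as.integer(image_size)
  if (s < 32L) vb_stop("image_size must be at least 32")
  body$center <- body$center %||% c(s / 2, s / 2)
  body$axes <- body$axes %||% (c(0.13, 0.095) * s)
  body$angle <- body$angle %||% 0
  body$intensity <- body$intensity %||% 0.62
  processes$count <- as.integer(processes$count %||% 3L)
  processes$length <- processes$length %||% (0.11 * s)
  processes$width <- max(2, processes$width %||% (0.028 * s))
  processes$intensity <- processes$intensity %||% body$intensity
  distractors$count <- as.integer(distractors$count %||% 0L)
  distractors$intensity_offset <- distractors$intensity_offset %||% 0.03
  distractors$axes <- distractors$axes %||% (c(0.03, 0.07) * s)
  lesion$present <- isTRUE(lesion$present)
  lesion$boost <- lesion$boost %||% 0.2
  lesion$radius <- lesion$radius %||% (0.03 * s)
  if (processes$count < 1L || processes$count > 3L)
    vb_stop("process count must be 1..3")
  if (noise_sigma < 0) vb_stop("noise_sigma must be >= 0")
  if (body$intensity < 0 || body$intensity > 1 || background < 0 ||
      background > 1)
    vb_stop("intensities must lie in [0, 1]")
  reach <- max(body$axes) + processes$length
  if (body$center[1] - reach < 1 || body$center[1] + reach > s ||
      body$center[2] - reach < 1 || body$center[2] + reach > s)
    vb_stop("body plus processes exceed the image bounds")
  structure(list(image_size = s, body = body, processes = processes,
                 distractors = distractors, lesion = lesion,
                 noise_sigma = noise_sigma, background = background,
                 seed = as.integer(seed)),
            class = "vb_phantom_spec")
}

#' Generate one phantom slice and its ground-truth mask
#'
#' Rasterizes the phantom described by `spec`: the mask is the union of the
#' body ellipse, the attached process rectangles and the lesion disk;
#' distractor blobs are drawn in the image only (never in the mask, and
#' only on background pixels). Gaussian noise is added to the image, which
#' is clipped to \[0, 1\]. Deterministic given the spec (including its
#' seed).
#'
#' @param spec a [phantom_spec()].
#' @return a `vb_slice_pair` list with `image` (H x W in \[0, 1\]), `mask`
#'   (H x W 0/1 integer matrix) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "vb_phantom_spec"))
  with_seed(spec$seed, {
    s <- spec$image_size
    body <- ellipse_mask(s, spec$body$center, spec$body$axes,
                         spec$body$angle)
    ang <- c(pi / 2, pi / 2 + 2.2, pi / 2 - 2.2)[seq_len(spec$processes$count)]
    procs <- matrix(FALSE, s, s)
    for (phi in ang) {
      # start just inside the ellipse edge along this direction
      ca <- cos(phi - spec$body$angle) / spec$body$axes[1]
      sa <- sin(phi - spec$body$angle) / spec$body$axes[2]
      r0 <- 1 / sqrt(ca^2 + sa^2) - 1
      procs <- procs | process_mask(s, spec$body$center, phi, r0,
                                    spec$processes$length,
                                    spec$processes$width / 2)
    }
    mask <- body | procs
    img <- matrix(spec$background, s, s)
    img[procs] <- spec$processes$intensity
    img[body] <- spec$body$intensity
    if (spec$lesion$present) {
      off <- runif(2, -0.3, 0.3) * spec$body$axes
      les <- ellipse_mask(s, spec$body$center + off,
                          rep(spec$lesion$radius, 2))
      les <- les & body                       # lesion stays inside the body
      img[les] <- pmin(1, spec$body$intensity + spec$lesion$boost)
      mask <- mask | les
    }
    if (spec$distractors$count > 0L) {
      for (k in seq_len(spec$distractors$count)) {
        ax <- runif(2, spec$distractors$axes[1], spec$distractors$axes[2])
        ctr <- runif(2, 1 + max(ax), s - max(ax))
        blob <- ellipse_mask(s, ctr, ax, runif(1, 0, pi)) & !mask
        img[blob] <- min(1, max(0, spec$body$intensity +
                                  spec$distractors$intensity_offset))
      }
    }
    if (spec$noise_sigma > 0)
      img <- img + matrix(rnorm(s * s, sd = spec$noise_sigma), s, s)
    img <- pmin(pmax(img, 0), 1)
    structure(list(image = img, mask = matrix(as.integer(mask), s, s),
                   spec = spec),
              class = "vb_slice_pair")
  })
}

profile_proportions <- function(profile) {
  switch(profile,
         easy = c(easy = 1, interference = 0, lesion = 0),
         interference = c(easy = 0, interference = 1, lesion = 0),
         lesion = c(easy = 0, interference = 0, lesion = 1),
         mixed = c(easy = 0.4, interference = 0.3, lesion = 0.3),
         vb_stop("unknown phantom profile: ", profile))
}

# one random spec of a given challenge type (consumes the current RNG)
random_spec <- function(type, image_size, seed) {
  s <- image_size
  body <- list(center = s / 2 + runif(2, -0.05 * s, 0.05 * s),
               axes = c(runif(1, 0.11, 0.15), runif(1, 0.08, 0.11)) * s,
               angle = runif(1, -0.15, 0.15),
               intensity = runif(1, 0.55, 0.7))
  phantom_spec(
    image_size = s, body = body,
    processes = list(count = sample(1:3, 1),
                     length = runif(1, 0.08, 0.13) * s,
                     width = runif(1, 0.022, 0.034) * s),
    distractors = if (type == "interference")
      list(count = sample(1:3, 1),
           intensity_offset = runif(1, -0.05, 0.05))
    else list(count = 0L),
    lesion = list(present = type == "lesion",
                  boost = runif(1, 0.15, 0.25),
                  radius = runif(1, 0.02, 0.04) * s),
    noise_sigma = runif(1, 0.005, 0.02),
    seed = seed)
}

#' Generate a phantom dataset with a replayable manifest
#'
#' Draws `n` phantom slices from a challenge profile: `"easy"` (vertebra
#' only), `"interference"` (each slice has 1-3 gray-matched distractors
#' within 0.05 of the body intensity), `"lesion"` (hyper-intense patch
#' inside the body), or `"mixed"` (40% easy, 30% interference, 30% lesion,
#' allocated deterministically in that order). The manifest records every
#' spec, so any slice can be regenerated exactly.
#'
#' @param n number of slices (>= 1).
#' @param profile challenge profile name.
#' @param seed master seed; per-slice seeds are derived from it.
#' @param image_size pixels per side (default 256).
#' @return list with `pairs` (list of `vb_slice_pair`) and `manifest`
#'   (data frame of index, type, seed, plus a `specs` attribute holding the
#'   full spec list).
#' @export
generate_dataset <- function(n, profile = c("mixed", "easy", "interference",
                                            "lesion"),
                             seed = 1L, image_size = 256L) {
  n <- as.integer(n)
  if (n < 1L) vb_stop("n must be >= 1")
  profile <- match.arg(profile)
  prop <- profile_proportions(profile)
  n_int <- floor(prop["interference"] * n)
  n_les <- floor(prop["lesion"] * n)
  n_easy <- n - n_int - n_les
  types <- c(rep("easy", n_easy), rep("interference", n_int),
             rep("lesion", n_les))
  seeds <- derive_seeds(seed, n)
  specs <- lapply(seq_len(n), function(i)
    with_seed(seeds[i], random_spec(types[i], image_size, seeds[i])))
  pairs <- lapply(specs, generate_phantom)
  manifest <- data.frame(index = seq_len(n), type = types, seed = seeds,
                         stringsAsFactors = FALSE)
  attr(manifest, "specs") <- specs
  attr(manifest, "profile") <- profile
  attr(manifest, "image_size") <- as.integer(image_size)
  list(pairs = pairs, manifest = manifest)
}

#' Stack phantom slices into a volume
#'
#' Concatenates the images and masks of a list of slice pairs along a third
#' axis, producing an isotropic (unit-spacing) volume for the 3-D pipeline.
#'
#' @param pairs list of `vb_slice_pair` objects of equal size.
#' @return list with `image` (H x W x D), `labels` (H x W x D integer) and
#'   `meta` (spacing c(1, 1, 1)).
#' @export
phantoms_to_volume <- function(pairs) {
  if (length(pairs) == 0L) vb_stop("empty slice list")
  d <- dim(pairs[[1]]$image)
  img <- array(0, c(d, length(pairs)))
  lab <- array(0L, c(d, length(pairs)))
  for (i in seq_along(pairs)) {
    img[, , i] <- pairs[[i]]$image
    lab[, , i] <- pairs[[i]]$mask
  }
  list(image = img, labels = lab,
       meta = list(spacing = c(1, 1, 1), origin = c(0, 0, 0)))
}
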