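# Volume I/O, resampling, slicing, augmentation, splitting.

make_volume <- function(d = c(20, 18, 6), seed = 1) {
  set.seed(seed)
  list(image = array(runif(prod(d), -100, 900), d),
       labels = array(as.integer(runif(prod(d)) < 0.3), d))
}

test_that("NIfTI round trip preserves values and spacing", {
  v <- make_volume()
  path <- tempfile(fileext = ".nii.gz")
  write_volume(v$image, path, spacing = c(0.5, 0.5, 1))
  r <- load_volume(path)
  expect_equal(r$image, v$image, tolerance = 1e-6)
  expect_equal(r$meta$spacing[1:3], c(0.5, 0.5, 1), tolerance = 1e-6)
  file.remove(path)
})

test_that("MetaImage round trip preserves values and spacing", {
  v <- make_volume(seed = 2)
  path <- tempfile(fileext = ".mhd")
  write_volume(v$image, path, spacing = c(0.31, 0.45, 1))
  r <- load_volume(path)
  expect_identical(dim(r$image), dim(v$image))
  expect_equal(r$image, v$image, tolerance = 0)
  expect_equal(r$meta$spacing, c(0.31, 0.45, 1))
  file.remove(path, sub("\\.mhd$", ".raw", path))
})

test_that("mismatched label shapes and missing files are errors", {
  v <- make_volume()
  ip <- tempfile(fileext = ".nii"); lp <- tempfile(fileext = ".nii")
  write_volume(v$image, ip)
  write_volume(v$labels[1:10, , ], lp)
  expect_error(load_volume(ip, lp), "differ in shape")
  expect_error(load_volume(tempfile(fileext = ".nii")), "not found")
  file.remove(ip, lp)
})

test_that("isotropic resampling: identity, constants, extent arithmetic", {
  v <- make_volume(c(10, 10, 4))
  # already isotropic 1 mm: exact identity
  r <- resample_isotropic(v$image, list(spacing = c(1, 1, 1)), v$labels)
  expect_identical(r$image, v$image)
  expect_identical(r$labels, v$labels)

  # constant volume stays constant at any spacing
  cst <- array(7, c(8, 8, 8))
  r2 <- resample_isotropic(cst, list(spacing = c(0.4, 0.7, 1.3)))
  expect_true(all(abs(r2$image - 7) < 1e-12))
  expect_equal(r2$meta$spacing, c(1, 1, 1))

  # 0.5 mm in-plane input of size 100 -> output in-plane size 50
  half <- array(rnorm(100 * 100 * 3), c(100, 100, 3))
  r3 <- resample_isotropic(half, list(spacing = c(0.5, 0.5, 1)))
  expect_identical(dim(r3$image)[1:2], c(50L, 50L))
  expect_identical(dim(r3$image)[3], 3L)

  expect_error(resample_isotropic(cst, list(spacing = c(0, 1, 1))),
               "positive")
})

test_that("slicing yields one pair per axial slice with binary masks", {
  v <- make_volume(c(30, 30, 40), seed = 3)
  img <- normalize_ct(v$image)
  pairs <- slice_and_resize(img, v$labels, size = 64, volume_id = "v1")
  expect_length(pairs, 40)
  expect_identical(dim(pairs[[7]]$image), c(64L, 64L))
  expect_true(all(vapply(pairs, function(p) all(p$mask %in% 0:1), TRUE)))
  expect_equal(pairs[[40]]$provenance$slice_index, 40)

  # filtering to vertebra-containing slices drops empty-mask slices only
  lab2 <- v$labels
  lab2[, , c(3, 9)] <- 0L
  kept <- slice_and_resize(img, lab2, size = 64, keep_empty = FALSE)
  expect_length(kept, 38)
  expect_false(any(vapply(kept, function(p)
    p$provenance$slice_index, 1L) %in% c(3L, 9L)))

  # a centered disk mask resized 128 -> 256 scales its area by about 4
  disk <- matrix(0L, 128, 128)
  g <- expand.grid(1:128, 1:128)
  disk[as.matrix(g[(g[, 1] - 64)^2 + (g[, 2] - 64)^2 <= 30^2, ])] <- 1L
  vol <- array(disk, c(128, 128, 1))
  up <- slice_and_resize(array(0.5, c(128, 128, 1)), vol, size = 256)
  ratio <- sum(up[[1]]$mask) / sum(disk)
  expect_lt(abs(ratio - 4), 4 * 0.05)
})

test_that("intensity windowing clips to [0,1]", {
  x <- array(c(-500, -200, 500, 1200, 2000), c(5, 1, 1))
  n <- normalize_ct(x)
  expect_equal(as.vector(n), c(0, 0, 0.5, 1, 1))
  expect_error(normalize_ct(x, c(10, 10)), "upper > lower")
})

test_that("augmentation is seed-deterministic and never alters the mask
           semantics", {
  ds <- generate_dataset(1, "easy", seed = 13, image_size = 64)
  pair <- ds$pairs[[1]]
  a1 <- augment_slice(pair, seed = 77)
  a2 <- augment_slice(pair, seed = 77)
  expect_identical(a1$image, a2$image)
  expect_identical(a1$mask, a2$mask)
  expect_true(all(a1$mask %in% 0:1))
  expect_true(all(a1$image >= 0 & a1$image <= 1))

  # find a seed where only contrast/noise fired: the mask must be untouched
  for (s in 1:50) {
    a <- augment_slice(pair, seed = s)
    ap <- a$provenance$augment
    if (is.null(ap$angle) && is.null(ap$flip)) {
      expect_identical(a$mask, pair$mask)
      break
    }
  }
})

test_that("rotating forward then backward returns close to the original", {
  ds <- generate_dataset(1, "easy", seed = 17, image_size = 128)
  img <- ds$pairs[[1]]$image
  for (ang in c(-0.1, 0.05, 0.1)) {
    back <- vertebox:::rotate_2d(vertebox:::rotate_2d(img, ang), -ang)
    inner <- 20:108    # ignore the border band lost to the rotation fill
    expect_lt(mean(abs(back[inner, inner] - img[inner, inner])), 0.02)
  }
})

test_that("train/validation split is 4:1, stratified by volume, leak-free", {
  pairs <- list()
  for (v in 1:5) {
    vol <- make_volume(c(16, 16, 10), seed = v)
    pairs <- c(pairs, slice_and_resize(normalize_ct(vol$image), vol$labels,
                                       size = 32,
                                       volume_id = paste0("vol", v)))
  }
  sp <- split_train_val(pairs, ratio = 0.8, seed = 5)
  expect_equal(length(sp$train) + length(sp$val), 50)
  expect_lte(abs(length(sp$val) - 10), 1)
  vol_of <- function(ps) unique(vapply(ps, function(p)
    p$provenance$volume_id, ""))
  expect_length(intersect(vol_of(sp$train), vol_of(sp$val)), 0)
  # deterministic given the seed
  sp2 <- split_train_val(pairs, ratio = 0.8, seed = 5)
  expect_identical(vapply(sp$val, function(p) p$provenance$slice_index, 1L),
                   vapply(sp2$val, function(p) p$provenance$slice_index, 1L))
})
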