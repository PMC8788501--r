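# Synthetic vertebra phantom generator.

test_that("phantom mask equals an exhaustive point-in-shape rasterization", {
  spec <- phantom_spec(image_size = 64,
                       body = list(center = c(32, 30), axes = c(9, 6.5),
                                   angle = 0.2, intensity = 0.6),
                       processes = list(count = 3, length = 7, width = 3),
                       noise_sigma = 0, seed = 5)
  ph <- generate_phantom(spec)

  # scalar per-pixel oracle: inside rotated ellipse or inside one of the
  # attached rectangles
  inside_ellipse <- function(y, x, ctr, ax, ang) {
    dy <- y - ctr[1]; dx <- x - ctr[2]
    u <- dx * cos(ang) + dy * sin(ang)
    v <- -dx * sin(ang) + dy * cos(ang)
    (u / ax[1])^2 + (v / ax[2])^2 <= 1
  }
  angles <- c(pi / 2, pi / 2 + 2.2, pi / 2 - 2.2)
  r0 <- vapply(angles, function(phi) {
    ca <- cos(phi - 0.2) / 9; sa <- sin(phi - 0.2) / 6.5
    1 / sqrt(ca^2 + sa^2) - 1
  }, 1)
  want <- matrix(0L, 64, 64)
  for (i in 1:64) for (j in 1:64) {
    inb <- inside_ellipse(i, j, c(32, 30), c(9, 6.5), 0.2)
    inp <- FALSE
    for (k in 1:3) {
      dy <- i - 32; dx <- j - 30
      al <- dx * cos(angles[k]) + dy * sin(angles[k])
      ac <- -dx * sin(angles[k]) + dy * cos(angles[k])
      if (al >= r0[k] && al <= r0[k] + 7 && abs(ac) <= 1.5) inp <- TRUE
    }
    want[i, j] <- as.integer(inb || inp)
  }
  expect_identical(ph$mask, want)
  expect_equal(sum(ph$mask), sum(want))
})

test_that("generation is a pure function of the spec", {
  spec <- phantom_spec(image_size = 96, seed = 9,
                       distractors = list(count = 2, intensity_offset = 0.04),
                       lesion = list(present = TRUE))
  p1 <- generate_phantom(spec)
  p2 <- generate_phantom(spec)
  expect_identical(p1$image, p2$image)
  expect_identical(p1$mask, p2$mask)
})

test_that("distractor pixels never enter the mask and lesions always do", {
  spec <- phantom_spec(image_size = 96, seed = 3, noise_sigma = 0,
                       distractors = list(count = 3,
                                          intensity_offset = 0.02))
  ph <- generate_phantom(spec)
  base <- phantom_spec(image_size = 96, seed = 3, noise_sigma = 0,
                       distractors = list(count = 0))
  ph0 <- generate_phantom(base)
  expect_identical(ph$mask, ph0$mask)       # distractors don't alter truth
  changed <- which(ph$image != ph0$image)
  expect_gt(length(changed), 0)
  expect_true(all(ph$mask[changed] == 0))   # only background pixels changed

  les <- generate_phantom(phantom_spec(image_size = 96, seed = 3,
                                       noise_sigma = 0,
                                       lesion = list(present = TRUE,
                                                     boost = 0.2)))
  bright <- les$image > 0.7
  expect_true(any(bright))
  expect_true(all(les$mask[bright] == 1))   # lesion lives inside the truth
})

test_that("out-of-bounds geometry is rejected", {
  expect_error(phantom_spec(image_size = 64,
                            body = list(center = c(5, 32), axes = c(9, 7))),
               "bounds")
  expect_error(phantom_spec(image_size = 64, noise_sigma = -1), "noise")
  expect_error(phantom_spec(image_size = 64,
                            processes = list(count = 4)), "1..3")
})

test_that("dataset generation is deterministic with a replayable manifest", {
  d1 <- generate_dataset(8, "mixed", seed = 11, image_size = 64)
  d2 <- generate_dataset(8, "mixed", seed = 11, image_size = 64)
  expect_identical(d1$manifest, d2$manifest)
  for (i in 1:8) expect_identical(d1$pairs[[i]]$image, d2$pairs[[i]]$image)
  # replay a single slice from its manifest spec
  sp <- attr(d1$manifest, "specs")[[5]]
  expect_identical(generate_phantom(sp)$image, d1$pairs[[5]]$image)
})

test_that("profiles honor their contracts and mixture proportions", {
  di <- generate_dataset(6, "interference", seed = 2, image_size = 64)
  for (p in di$pairs) {
    expect_gte(p$spec$distractors$count, 1)
    expect_lte(abs(p$spec$distractors$intensity_offset), 0.05)
  }
  dl <- generate_dataset(4, "lesion", seed = 2, image_size = 64)
  for (p in dl$pairs) expect_true(p$spec$lesion$present)

  dm <- generate_dataset(100, "mixed", seed = 2, image_size = 64)
  expect_equal(unname(table(dm$manifest$type)["easy"]), 40)
  expect_equal(unname(table(dm$manifest$type)["interference"]), 30)
  expect_equal(unname(table(dm$manifest$type)["lesion"]), 30)
  expect_error(generate_dataset(4, "bogus"), "profile|arg")
})

test_that("mask foreground fraction stays in the declared 2-15% band", {
  for (profile in c("easy", "interference", "lesion")) {
    ds <- generate_dataset(6, profile, seed = 7, image_size = 128)
    fr <- vapply(ds$pairs, function(p) mean(p$mask), 1)
    expect_true(all(fr >= 0.02 & fr <= 0.15))
  }
})

test_that("phantom slices stack into a unit-spacing volume", {
  ds <- generate_dataset(5, "easy", seed = 1, image_size = 64)
  vol <- phantoms_to_volume(ds$pairs)
  expect_identical(dim(vol$image), c(64L, 64L, 5L))
  expect_identical(dim(vol$labels), dim(vol$image))
  expect_equal(vol$meta$spacing, c(1, 1, 1))
  expect_identical(vol$labels[, , 3], ds$pairs[[3]]$mask)
})
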