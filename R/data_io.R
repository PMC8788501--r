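# CT volume input/output and the slice preprocessing pipeline:
# load -> window/normalize -> resample to 1 mm isotropic -> axial slices
# resized to the network input -> (training only) augmentation.
#
# NIfTI goes through RNifti. MetaImage (.mhd + .raw) is a plain text header
# plus a raw block; a minimal reader/writer for uncompressed files is
# provided here. All interpolation (trilinear/bilinear for intensities,
# nearest for labels) is implemented in-package so that training-time and
# inference-time geometry are bit-identical.

mhd_type_map <- c(MET_UCHAR = "integer", MET_CHAR = "integer",
                  MET_SHORT = "integer", MET_USHORT = "integer",
                  MET_INT = "integer", MET_UINT = "integer",
                  MET_FLOAT = "double", MET_DOUBLE = "double")
mhd_size_map <- c(MET_UCHAR = 1L, MET_CHAR = 1L, MET_SHORT = 2L,
                  MET_USHORT = 2L, MET_INT = 4L, MET_UINT = 4L,
                  MET_FLOAT = 4L, MET_DOUBLE = 8L)

read_mhd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = " "), "")
  get <- function(k, default = NULL) {
    i <- match(k, keys)
    if (is.na(i)) default else vals[i]
  }
  ndim <- as.integer(get("NDims", "3"))
  dims <- as.integer(strsplit(get("DimSize"), "\\s+")[[1]])
  spacing <- as.numeric(strsplit(get("ElementSpacing", get("ElementSize",
                                                           "1 1 1")),
                                 "\\s+")[[1]])
  origin <- as.numeric(strsplit(get("Offset", paste(rep("0", ndim),
                                                    collapse = " ")),
                                "\\s+")[[1]])
  etype <- get("ElementType", "MET_FLOAT")
  if (!etype %in% names(mhd_type_map))
    vb_stop("unsupported MetaImage element type: ", etype)
  if (!identical(tolower(get("CompressedData", "False")), "false"))
    vb_stop("compressed MetaImage data is not supported")
  datafile <- get("ElementDataFile")
  if (is.null(datafile) || identical(datafile, "LOCAL"))
    vb_stop("MetaImage header must name an external data file")
  raw_path <- file.path(dirname(path), datafile)
  if (!file.exists(raw_path)) vb_stop("missing raw data file: ", raw_path)
  n <- prod(dims)
  con <- file(raw_path, "rb")
  on.exit(close(con))
  signed <- !etype %in% c("MET_UCHAR", "MET_USHORT", "MET_UINT")
  v <- readBin(con, what = mhd_type_map[[etype]], n = n,
               size = mhd_size_map[[etype]], signed = if (
                 mhd_size_map[[etype]] < 4L) signed else TRUE,
               endian = "little")
  if (length(v) != n) vb_stop("raw file shorter than DimSize implies")
  list(data = array(as.double(v), dims), spacing = spacing, origin = origin)
}

write_mhd <- function(data, path, spacing = c(1, 1, 1),
                      origin = c(0, 0, 0), element_type = "MET_DOUBLE") {
  dims <- dim(data)
  raw_name <- sub("\\.mhd$", ".raw", basename(path))
  header <- c(
    "ObjectType = Image",
    paste0("NDims = ", length(dims)),
    paste0("DimSize = ", paste(dims, collapse = " ")),
    paste0("ElementSpacing = ", paste(spacing, collapse = " ")),
    paste0("Offset = ", paste(origin, collapse = " ")),
    "CompressedData = False",
    paste0("ElementType = ", element_type),
    "ElementByteOrderMSB = False",
    paste0("ElementDataFile = ", raw_name))
  writeLines(header, path)
  con <- file(file.path(dirname(path), raw_name), "wb")
  on.exit(close(con))
  if (element_type == "MET_DOUBLE")
    writeBin(as.double(data), con, size = 8, endian = "little")
  else if (element_type == "MET_SHORT")
    writeBin(as.integer(data), con, size = 2, endian = "little")
  else if (element_type == "MET_UCHAR")
    writeBin(as.integer(data), con, size = 1, endian = "little")
  else vb_stop("unsupported element type for writing: ", element_type)
  invisible(path)
}

is_nifti_path <- function(path) grepl("\\.nii(\\.gz)?$", path)

#' Load a CT volume and (optionally) its label volume
#'
#' Reads NIfTI (`.nii`, `.nii.gz`) via RNifti or uncompressed MetaImage
#' (`.mhd` + `.raw`). Image and label grids must agree in shape.
#'
#' @param image_path path to the intensity volume.
#' @param label_path optional path to a binary label volume.
#' @return list with `image` (3-D array), `labels` (3-D integer array or
#'   NULL) and `meta` (list with `spacing`, `origin`).
#' @export
load_volume <- function(image_path, label_path = NULL) {
  read_one <- function(p) {
    if (!file.exists(p)) vb_stop("file not found: ", p)
    if (is_nifti_path(p)) {
      img <- RNifti::readNifti(p)
      list(data = array(as.double(img), dim(img)),
           spacing = as.numeric(RNifti::pixdim(img)),
           origin = as.numeric(RNifti::origin(img)))
    } else if (grepl("\\.mhd$", p)) {
      r <- read_mhd(p)
      list(data = r$data, spacing = r$spacing, origin = r$origin)
    } else vb_stop("unsupported volume format: ", p)
  }
  im <- read_one(image_path)
  if (length(dim(im$data)) != 3L) vb_stop("expected a 3-D volume")
  labels <- NULL
  if (!is.null(label_path)) {
    lb <- read_one(label_path)
    if (!identical(dim(lb$data), dim(im$data)))
      vb_stop("image and label volumes differ in shape")
    labels <- array(as.integer(lb$data != 0), dim(lb$data))
  }
  list(image = im$data, labels = labels,
       meta = list(spacing = im$spacing, origin = im$origin))
}

#' Write a volume to NIfTI or MetaImage
#'
#' @param data 3-D array.
#' @param path output path (`.nii`, `.nii.gz` or `.mhd`).
#' @param spacing per-axis voxel spacing in mm.
#' @param origin physical origin.
#' @return `path`, invisibly.
#' @export
write_volume <- function(data, path, spacing = c(1, 1, 1),
                         origin = c(0, 0, 0)) {
  if (is_nifti_path(path)) {
    img <- RNifti::asNifti(array(as.double(data), dim(data)))
    RNifti::pixdim(img) <- spacing
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.mhd$", path)) {
    write_mhd(data, path, spacing, origin)
  } else vb_stop("unsupported volume format: ", path)
  invisible(path)
}

# trilinear (or nearest) sampling of `vol` at fractional 0-based coordinates
sample_volume <- function(vol, cy, cx, cz, nearest = FALSE) {
  d <- dim(vol)
  if (nearest) {
    iy <- pmin(pmax(round(cy), 0), d[1] - 1)
    ix <- pmin(pmax(round(cx), 0), d[2] - 1)
    iz <- pmin(pmax(round(cz), 0), d[3] - 1)
    return(vol[1 + iy + d[1] * (ix + d[2] * iz)])
  }
  y0 <- pmin(pmax(floor(cy), 0), d[1] - 1)
  x0 <- pmin(pmax(floor(cx), 0), d[2] - 1)
  z0 <- pmin(pmax(floor(cz), 0), d[3] - 1)
  y1 <- pmin(y0 + 1, d[1] - 1)
  x1 <- pmin(x0 + 1, d[2] - 1)
  z1 <- pmin(z0 + 1, d[3] - 1)
  fy <- pmin(pmax(cy - y0, 0), 1)
  fx <- pmin(pmax(cx - x0, 0), 1)
  fz <- pmin(pmax(cz - z0, 0), 1)
  at <- function(iy, ix, iz) vol[1 + iy + d[1] * (ix + d[2] * iz)]
  (1 - fz) * ((1 - fx) * ((1 - fy) * at(y0, x0, z0) + fy * at(y1, x0, z0)) +
              fx * ((1 - fy) * at(y0, x1, z0) + fy * at(y1, x1, z0))) +
  fz * ((1 - fx) * ((1 - fy) * at(y0, x0, z1) + fy * at(y1, x0, z1)) +
        fx * ((1 - fy) * at(y0, x1, z1) + fy * at(y1, x1, z1)))
}

#' Resample a volume to isotropic spacing
#'
#' Resamples intensities with trilinear interpolation and labels with
#' nearest-neighbor to a uniform target spacing (default 1 mm). The output
#' extent along each axis is `round(extent * spacing / target)`. A volume
#' already at the target spacing is returned unchanged.
#'
#' @param volume 3-D intensity array.
#' @param meta list with `spacing` (per-axis mm).
#' @param labels optional 3-D label array on the same grid.
#' @param target target isotropic spacing in mm.
#' @return list with `image`, `labels` (or NULL) and updated `meta`.
#' @export
resample_isotropic <- function(volume, meta, labels = NULL, target = 1) {
  sp <- as.numeric(meta$spacing)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    vb_stop("voxel spacing must be positive")
  if (target <= 0) vb_stop("target spacing must be positive")
  if (all(abs(sp - target) < 1e-9)) {
    meta$spacing <- rep(target, 3)
    return(list(image = volume, labels = labels, meta = meta))
  }
  d <- dim(volume)
  nd <- pmax(1L, as.integer(round(d * sp / target)))
  # map output voxel centers onto input voxel indices (0-based, corner
  # aligned so that index i sits at physical i * spacing)
  cy <- (seq_len(nd[1]) - 1) * target / sp[1]
  cx <- (seq_len(nd[2]) - 1) * target / sp[2]
  cz <- (seq_len(nd[3]) - 1) * target / sp[3]
  gy <- rep(cy, times = nd[2] * nd[3])
  gx <- rep(rep(cx, each = nd[1]), times = nd[3])
  gz <- rep(cz, each = nd[1] * nd[2])
  out <- array(sample_volume(volume, gy, gx, gz), nd)
  lab <- NULL
  if (!is.null(labels)) {
    if (!identical(dim(labels), d)) vb_stop("label shape mismatch")
    lab <- array(as.integer(sample_volume(labels, gy, gx, gz,
                                          nearest = TRUE)), nd)
  }
  meta$spacing <- rep(target, 3)
  list(image = out, labels = lab, meta = meta)
}

#' Window and normalize CT intensities
#'
#' Clips Hounsfield intensities to a window enclosing soft tissue and bone
#' and rescales to \[0, 1\].
#'
#' @param volume intensity array (any shape).
#' @param window lower/upper HU clip bounds.
#' @return array of the same shape with values in \[0, 1\].
#' @export
normalize_ct <- function(volume, window = c(-200, 1200)) {
  if (length(window) != 2L || window[2] <= window[1])
    vb_stop("window must be c(lower, upper) with upper > lower")
  v <- pmin(pmax(volume, window[1]), window[2])
  (v - window[1]) / (window[2] - window[1])
}

# separable bilinear resize of a matrix (nearest = index mapping for masks)
resize_2d <- function(img, out_h, out_w, nearest = FALSE) {
  d <- dim(img)
  if (nearest) {
    ri <- pmin(pmax(round((seq_len(out_h) - 0.5) * d[1] / out_h + 0.5), 1),
               d[1])
    ci <- pmin(pmax(round((seq_len(out_w) - 0.5) * d[2] / out_w + 0.5), 1),
               d[2])
    return(img[ri, ci, drop = FALSE])
  }
  interp_matrix(out_h, d[1]) %*% img %*% t(interp_matrix(out_w, d[2]))
}

#' Slice a volume axially and resize to the network input
#'
#' Produces one image/mask pair per axial (third-axis) slice: intensities
#' are resized with bilinear interpolation, masks with nearest-neighbor (so
#' they remain strictly binary).
#'
#' @param volume 3-D intensity array, already normalized to \[0, 1\].
#' @param labels 3-D binary label array on the same grid (or NULL).
#' @param size output side length in pixels (default 256).
#' @param volume_id identifier recorded in each pair's provenance.
#' @param keep_empty keep slices whose mask has no foreground (default
#'   `TRUE`, i.e. unfiltered; `FALSE` restricts to vertebra-containing
#'   slices).
#' @return list of `vb_slice_pair` objects.
#' @export
slice_and_resize <- function(volume, labels = NULL, size = 256L,
                             volume_id = "volume", keep_empty = TRUE) {
  d <- dim(volume)
  if (length(d) != 3L) vb_stop("expected a 3-D volume")
  if (!is.null(labels) && !identical(dim(labels), d))
    vb_stop("label shape mismatch")
  pairs <- lapply(seq_len(d[3]), function(k) {
    img <- resize_2d(volume[, , k], size, size)
    msk <- if (is.null(labels)) NULL else
      matrix(as.integer(resize_2d(labels[, , k], size, size,
                                  nearest = TRUE)), size, size)
    structure(list(image = pmin(pmax(img, 0), 1), mask = msk,
                   provenance = list(volume_id = volume_id,
                                     slice_index = k)),
              class = "vb_slice_pair")
  })
  if (!keep_empty && !is.null(labels))
    pairs <- Filter(function(p) sum(p$mask) > 0, pairs)
  pairs
}

rotate_2d <- function(img, angle, nearest = FALSE, fill = 0) {
  d <- dim(img)
  ctr <- (d + 1) / 2
  g <- pixel_grid(d[1])
  if (d[1] != d[2]) {
    g <- list(y = matrix(rep(seq_len(d[1]), d[2]), d[1], d[2]),
              x = matrix(rep(seq_len(d[2]), each = d[1]), d[1], d[2]))
  }
  dy <- g$y - ctr[1]
  dx <- g$x - ctr[2]
  sy <- ctr[1] + cos(angle) * dy - sin(angle) * dx
  sx <- ctr[2] + sin(angle) * dy + cos(angle) * dx
  inside <- sy >= 1 & sy <= d[1] & sx >= 1 & sx <= d[2]
  out <- matrix(fill, d[1], d[2])
  if (nearest) {
    ry <- pmin(pmax(round(sy), 1), d[1])
    rx <- pmin(pmax(round(sx), 1), d[2])
    out[] <- img[cbind(as.vector(ry), as.vector(rx))]
  } else {
    y0 <- pmin(pmax(floor(sy), 1), d[1])
    x0 <- pmin(pmax(floor(sx), 1), d[2])
    y1 <- pmin(y0 + 1, d[1])
    x1 <- pmin(x0 + 1, d[2])
    fy <- pmin(pmax(sy - y0, 0), 1)
    fx <- pmin(pmax(sx - x0, 0), 1)
    val <- (1 - fx) * ((1 - fy) * img[cbind(c(y0), c(x0))] +
                       fy * img[cbind(c(y1), c(x0))]) +
           fx * ((1 - fy) * img[cbind(c(y0), c(x1))] +
                 fy * img[cbind(c(y1), c(x1))])
    out[] <- val
  }
  out[!inside] <- fill
  out
}

#' Augment a slice pair
#'
#' Training augmentation, each transform applied independently with
#' probability 1/2: rotation by an angle uniform in ±0.1 rad (bilinear for
#' the image, nearest for the mask), horizontal flip, contrast scaling
#' (centered multiplication by a factor uniform in \[0.8, 1.2\]), and
#' additive Gaussian noise with sigma uniform in \[0, 0.02\]. Contrast and
#' noise touch the image only; the mask stays binary; the image is
#' re-clipped to \[0, 1\]. Fully determined by `seed`.
#'
#' @param pair a `vb_slice_pair`.
#' @param seed integer seed.
#' @return the augmented `vb_slice_pair` (an `angle`-bearing `augment`
#'   record is attached to the provenance).
#' @export
augment_slice <- function(pair, seed) {
  stopifnot(inherits(pair, "vb_slice_pair"))
  with_seed(seed, {
    img <- pair$image
    msk <- pair$mask
    applied <- list()
    if (runif(1) < 0.5) {
      ang <- runif(1, -0.1, 0.1)
      img <- rotate_2d(img, ang)
      if (!is.null(msk))
        msk <- matrix(as.integer(rotate_2d(msk, ang, nearest = TRUE)),
                      nrow(msk), ncol(msk))
      applied$angle <- ang
    }
    if (runif(1) < 0.5) {
      img <- img[, rev(seq_len(ncol(img))), drop = FALSE]
      if (!is.null(msk)) msk <- msk[, rev(seq_len(ncol(msk))), drop = FALSE]
      applied$flip <- TRUE
    }
    if (runif(1) < 0.5) {
      f <- runif(1, 0.8, 1.2)
      img <- (img - mean(img)) * f + mean(img)
      applied$contrast <- f
    }
    if (runif(1) < 0.5) {
      sg <- runif(1, 0, 0.02)
      img <- img + matrix(rnorm(length(img), sd = sg), nrow(img))
      applied$noise_sigma <- sg
    }
    img <- pmin(pmax(img, 0), 1)
    out <- pair
    out$image <- img
    out$mask <- msk
    out$provenance$augment <- applied
    out
  })
}

#' Split slice pairs into training and validation sets
#'
#' A 4:1 train/validation split by slice count (within one slice), grouped
#' by volume id where the number of volumes permits: whole volumes are
#' assigned to the validation side until it holds about a fifth of the
#' slices, which prevents near-duplicate neighboring slices from straddling
#' the split. With fewer than 3 distinct volumes the split falls back to
#' the slice level.
#'
#' @param pairs list of `vb_slice_pair` objects.
#' @param ratio training fraction (default 0.8, i.e. 4:1).
#' @param seed integer seed.
#' @return list with `train` and `val` lists of pairs.
#' @export
split_train_val <- function(pairs, ratio = 0.8, seed = 1L) {
  if (length(pairs) < 2L) vb_stop("need at least 2 slices to split")
  vol_of <- vapply(pairs, function(p)
    as.character(p$provenance$volume_id %||% "volume"), "")
  n_val_target <- length(pairs) - round(ratio * length(pairs))
  with_seed(seed, {
    vols <- unique(vol_of)
    if (length(vols) >= 3L) {
      vols <- sample(vols)
      counts <- vapply(vols, function(v) sum(vol_of == v), 1L)
      take <- cumsum(counts) <= n_val_target
      if (!any(take)) take[1] <- TRUE
      val_idx <- which(vol_of %in% vols[take])
    } else {
      val_idx <- sample(length(pairs), n_val_target)
    }
    list(train = pairs[-val_idx], val = pairs[val_idx])
  })
}
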