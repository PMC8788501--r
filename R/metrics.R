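# Segmentation evaluation metrics.
#
# DSC(A,B) = 2|A∩B| / (|A|+|B|), IOU(A,B) = |A∩B| / |A∪B|, and the
# 95th-percentile Hausdorff distance between mask boundaries. Boundary
# pixels are foreground pixels with at least one background 4-neighbor in
# 2-D (6-neighbor in 3-D); pixels touching the image edge count as boundary.
# The directed nearest-point distances of both boundaries are pooled and the
# 95th percentile taken with linear interpolation between order statistics
# (stats::quantile type 7), so results are reproducible bit for bit.

check_mask_pair <- function(a, b) {
  if (is.null(dim(a))) vb_stop("masks must be matrices or arrays")
  if (!identical(dim(a), dim(b))) vb_stop("mask shapes differ")
  if (any(a != 0 & a != 1) || any(b != 0 & b != 1))
    vb_stop("masks must be strictly binary (0/1)")
  invisible(TRUE)
}

#' Dice similarity coefficient
#'
#' Overlap between two binary masks, `2|A∩B| / (|A|+|B|)`; 1 when both
#' masks are empty.
#'
#' @param a,b binary masks (0/1), same shape (2-D or 3-D arrays).
#' @return number in \[0, 1\].
#' @export
dsc <- function(a, b) {
  check_mask_pair(a, b)
  sa <- sum(a)
  sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a * b) / (sa + sb)
}

#' Intersection over union
#'
#' `|A∩B| / |A∪B|` for two binary masks; 1 when both masks are empty.
#' Related to [dsc()] by `dsc = 2 iou / (1 + iou)`.
#'
#' @inheritParams dsc
#' @return number in \[0, 1\].
#' @export
iou <- function(a, b) {
  check_mask_pair(a, b)
  inter <- sum(a * b)
  uni <- sum(a) + sum(b) - inter
  if (uni == 0) return(1)
  inter / uni
}

#' Boundary points of a binary mask
#'
#' Foreground pixels with at least one background neighbor under
#' 4-connectivity (2-D) or 6-connectivity (3-D); the outside of the image
#' counts as background.
#'
#' @param mask binary 2-D or 3-D array.
#' @return integer matrix of 1-based pixel coordinates, one row per
#'   boundary point (columns = array dimensions).
#' @export
boundary_points <- function(mask) {
  d <- dim(mask)
  if (is.null(d) || !(length(d) %in% 2:3)) vb_stop("mask must be 2-D or 3-D")
  if (any(mask != 0 & mask != 1)) vb_stop("mask must be binary")
  m <- array(as.integer(mask), d)
  is_bg_neighbor <- array(FALSE, d)
  shift <- function(a, ax, by) {
    dd <- dim(a)
    out <- array(0L, dd)              # outside the image is background
    src <- lapply(dd, seq_len)
    dst <- src
    n <- dd[ax]
    if (by == 1L) {
      src[[ax]] <- seq_len(n - 1L)
      dst[[ax]] <- 1L + seq_len(n - 1L)
    } else {
      src[[ax]] <- 1L + seq_len(n - 1L)
      dst[[ax]] <- seq_len(n - 1L)
    }
    do.call(`[<-`, c(list(out), dst,
                     list(do.call(`[`, c(list(a), src, drop = FALSE)))))
  }
  for (ax in seq_along(d)) for (by in c(1L, -1L))
    is_bg_neighbor <- is_bg_neighbor | (shift(m, ax, by) == 0L)
  which(m == 1L & is_bg_neighbor, arr.ind = TRUE)
}

#' 95th-percentile Hausdorff distance
#'
#' Robust Hausdorff distance between the boundaries of two binary masks:
#' the directed nearest-point Euclidean distances of both boundary point
#' sets are pooled and the given percentile is taken (linear interpolation
#' between order statistics). `percentile = 100` gives the classical
#' maximum (symmetric) Hausdorff distance. Distances are measured in
#' physical units via `spacing` (mm per pixel along each axis; default 1,
#' i.e. pixel units).
#'
#' @inheritParams dsc
#' @param spacing numeric vector of per-axis physical spacings.
#' @param percentile percentile of the pooled distances (default 95).
#' @return nonnegative distance; error if either mask is empty (the metric
#'   is undefined, not zero).
#' @export
hd95 <- function(a, b, spacing = rep(1, length(dim(a))), percentile = 95) {
  check_mask_pair(a, b)
  if (sum(a) == 0 || sum(b) == 0)
    vb_stop("Hausdorff distance undefined for an empty mask")
  if (length(spacing) != length(dim(a)) || any(spacing <= 0))
    vb_stop("spacing must be positive, one entry per mask dimension")
  pa <- sweep(boundary_points(a), 2, spacing, `*`)
  pb <- sweep(boundary_points(b), 2, spacing, `*`)
  dists <- c(cpp_nn_dist(pa, pb), cpp_nn_dist(pb, pa))
  unname(quantile(dists, percentile / 100, type = 7))
}

#' Per-case metric report
#'
#' Computes DSC, IOU and HD95 for each prediction/truth mask pair and a
#' mean and standard deviation summary. HD95 is reported as `NA` for
#' cases where either mask is empty (the distance is undefined there).
#'
#' @param preds,truths lists of binary masks (same length and shapes).
#' @param spacing physical spacing passed to [hd95()].
#' @param ids optional case identifiers.
#' @return list of class `vb_metric_report` with `per_case` (data frame of
#'   id, dsc, iou, hd95) and `summary` (data frame of metric, mean, sd).
#' @export
evaluate_cases <- function(preds, truths, spacing = NULL, ids = NULL) {
  if (length(preds) != length(truths))
    vb_stop("prediction and truth lists differ in length")
  if (length(preds) == 0L) vb_stop("no cases to evaluate")
  ids <- ids %||% paste0("case", seq_along(preds))
  rows <- lapply(seq_along(preds), function(i) {
    p <- preds[[i]]
    t <- truths[[i]]
    sp <- spacing %||% rep(1, length(dim(p)))
    h <- if (sum(p) == 0 || sum(t) == 0) NA_real_ else hd95(p, t, sp)
    data.frame(id = ids[i], dsc = dsc(p, t), iou = iou(p, t), hd95 = h,
               stringsAsFactors = FALSE)
  })
  per_case <- do.call(rbind, rows)
  summ <- data.frame(
    metric = c("dsc", "iou", "hd95"),
    mean = c(mean(per_case$dsc), mean(per_case$iou),
             mean(per_case$hd95, na.rm = TRUE)),
    sd = c(sd(per_case$dsc), sd(per_case$iou),
           sd(per_case$hd95, na.rm = TRUE)))
  structure(list(per_case = per_case, summary = summ),
            class = "vb_metric_report")
}

#' @export
print.vb_metric_report <- function(x, ...) {
  cat("Segmentation metrics over", nrow(x$per_case), "cases\n")
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %-4s %.4f +/- %.4f\n", x$summary$metric[i],
                x$summary$mean[i], x$summary$sd[i]))
  invisible(x)
}

#' Paired comparison of per-case metrics
#'
#' Two-sided paired t-test on the per-case differences between two methods,
#' as used to compare segmentation models case by case.
#'
#' @param per_case_a,per_case_b numeric vectors of per-case metric values,
#'   same length >= 2, paired by case.
#' @return the two-sided p-value.
#' @export
paired_compare <- function(per_case_a, per_case_b) {
  if (length(per_case_a) != length(per_case_b))
    vb_stop("paired samples must have equal length")
  if (length(per_case_a) < 2L) vb_stop("need at least 2 paired cases")
  diffs <- per_case_a - per_case_b
  if (sd(diffs) == 0)
    vb_stop("degenerate input: all per-case differences are identical")
  unname(t.test(per_case_a, per_case_b, paired = TRUE)$p.value)
}
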