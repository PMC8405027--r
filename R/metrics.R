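#' Pixel confusion counts between two binary masks
#'
#' Tallies true/false positives/negatives between a binarised prediction and
#' a ground-truth mask. Foreground (mass) is the positive class.
#'
#' @param pred_mask Binary prediction map (0/1 matrix).
#' @param gt_mask Binary ground-truth map, identical shape.
#' @return A list of class `confusion_counts` with integer fields
#'   `tp`, `fp`, `tn`, `fn`; their sum is the pixel count.
#' @export
#' @examples
#' confusion(matrix(c(1, 1, 0, 0), 2), matrix(c(1, 0, 1, 0), 2))
confusion <- function(pred_mask, gt_mask) {
  check_same_shape(pred_mask, gt_mask)
  p <- as.numeric(pred_mask)
  g <- as.numeric(gt_mask)
  if (!all(p %in% c(0, 1)) || !all(g %in% c(0, 1))) {
    stop_param("`pred_mask` and `gt_mask` must be binary (0/1)")
  }
  structure(
    list(
      tp = as.integer(sum(p == 1 & g == 1)),
      fp = as.integer(sum(p == 1 & g == 0)),
      tn = as.integer(sum(p == 0 & g == 0)),
      fn = as.integer(sum(p == 0 & g == 1))
    ),
    class = "confusion_counts"
  )
}

#' Segmentation metrics from confusion counts
#'
#' Computes the five pixel metrics used to evaluate mass segmentation:
#' accuracy `AC = (TP+TN)/(TP+FP+TN+FN)`, recall `RE = TP/(TP+FN)`,
#' specificity `SP = TN/(FP+TN)`, `F1 = 2*recall*precision/(recall+precision)`
#' and Jaccard overlap `IoU = TP/(TP+FP+FN)`. A metric whose denominator is
#' zero is defined as 0 and listed in the `flags` column.
#'
#' @param counts A `confusion_counts` object (from [confusion()]) or anything
#'   coercible to a list with fields `tp`, `fp`, `tn`, `fn`.
#' @return A one-row tibble with columns `ac`, `re`, `f1`, `sp`, `iou`,
#'   `n_pixels` and `flags` (comma-separated names of zero-denominator
#'   metrics, `""` if none).
#' @export
#' @examples
#' compute_metrics(list(tp = 3, fp = 1, tn = 5, fn = 1))
compute_metrics <- function(counts) {
  counts <- as.list(counts)
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  if (any(c(tp, fp, tn, fn) < 0)) stop_param("confusion counts must be nonnegative")
  n <- tp + fp + tn + fn
  flags <- character(0)
  safe_div <- function(num, den, name) {
    if (den == 0) {
      flags <<- c(flags, name)
      0
    } else {
      num / den
    }
  }
  ac <- safe_div(tp + tn, n, "ac")
  re <- safe_div(tp, tp + fn, "re")
  sp <- safe_div(tn, fp + tn, "sp")
  pr <- safe_div(tp, tp + fp, "precision")
  f1 <- if (re + pr == 0) {
    flags <- c(flags, "f1")
    0
  } else {
    2 * re * pr / (re + pr)
  }
  iou <- safe_div(tp, tp + fp + fn, "iou")
  tibble(
    ac = ac, re = re, f1 = f1, sp = sp, iou = iou,
    n_pixels = n, flags = paste(flags, collapse = ",")
  )
}

#' Dataset-level metric table for mask pairs
#'
#' Evaluates each prediction/ground-truth pair and aggregates either as the
#' per-image mean of metrics (default, one value per metric) or by pooling
#' the confusion counts over all images before computing metrics once.
#'
#' @param pred_list,gt_list Parallel lists of binary masks.
#' @param aggregation `"per_image_mean"` or `"pooled"`.
#' @return A one-row tibble with columns `ac`, `re`, `f1`, `sp`, `iou`,
#'   `n_images` and `aggregation`.
#' @export
metrics_table <- function(pred_list, gt_list,
                          aggregation = c("per_image_mean", "pooled")) {
  aggregation <- match.arg(aggregation)
  if (length(pred_list) != length(gt_list)) {
    stop_shape("`pred_list` and `gt_list` must have equal length")
  }
  counts <- purrr::map2(pred_list, gt_list, confusion)
  if (aggregation == "per_image_mean") {
    per <- purrr::map(counts, compute_metrics) |> purrr::list_rbind()
    out <- dplyr::summarise(per, dplyr::across(c("ac", "re", "f1", "sp", "iou"), mean))
  } else {
    pooled <- list(
      tp = sum(purrr::map_dbl(counts, "tp")),
      fp = sum(purrr::map_dbl(counts, "fp")),
      tn = sum(purrr::map_dbl(counts, "tn")),
      fn = sum(purrr::map_dbl(counts, "fn"))
    )
    out <- compute_metrics(pooled)[, c("ac", "re", "f1", "sp", "iou")]
  }
  dplyr::mutate(out, n_images = length(counts), aggregation = aggregation)
}

#' TP/TN/FP/FN colour overlay
#'
#' Renders the pixelwise agreement between a prediction and the ground truth
#' as an RGB image: true positives blue, true negatives black, false
#' positives green, false negatives red.
#'
#' @param pred_mask,gt_mask Binary masks of identical shape.
#' @return Numeric array `c(nrow, ncol, 3)` with values in `{0, 1}`.
#' @export
overlay <- function(pred_mask, gt_mask) {
  cc <- confusion(pred_mask, gt_mask) # also validates shape/binariness
  p <- pred_mask == 1
  g <- gt_mask == 1
  out <- array(0, dim = c(nrow(pred_mask), ncol(pred_mask), 3))
  out[, , 3][p & g] <- 1  # TP blue
  out[, , 2][p & !g] <- 1 # FP green
  out[, , 1][!p & g] <- 1 # FN red
  attr(out, "counts") <- cc
  out
}

#' Write an overlay to a PNG file
#'
#' @param pred_mask,gt_mask Binary masks of identical shape.
#' @param path Output PNG path.
#' @return The path, invisibly.
#' @export
write_overlay_png <- function(pred_mask, gt_mask, path) {
  img <- overlay(pred_mask, gt_mask)
  attr(img, "counts") <- NULL
  png::writePNG(img, path)
  invisible(path)
}
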