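#' Distillation hyper-parameters
#'
#' Bundles the three scalars that shape the student objective
#' \eqn{L_S = \alpha L_{KD} + (1-\alpha) L_{GT} + \lambda L_{KL}}:
#' the soft-target temperature `T`, the hard/soft balance `alpha` and the
#' feature-transfer weight `lam`.
#'
#' @param T Temperature of the soft-target softmax; larger values flatten the
#'   teacher's class distribution. Must be positive. Default 2.
#' @param alpha Weight of the knowledge-distillation term, in `[0, 1]`;
#'   `1 - alpha` weights the ground-truth segmentation term. Default 0.5.
#' @param lam Weight of the bottleneck KL transfer term, nonnegative.
#'   Default 0.1.
#' @return A list of class `distill_config`.
#' @export
#' @examples
#' distill_config(T = 4, alpha = 0.3)
distill_config <- function(T = 2, alpha = 0.5, lam = 0.1) {
  if (!is.numeric(T) || length(T) != 1 || T <= 0) {
    stop_param("`T` must be a single positive number")
  }
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0 || alpha > 1) {
    stop_param("`alpha` must be a single number in [0, 1]")
  }
  if (!is.numeric(lam) || length(lam) != 1 || lam < 0) {
    stop_param("`lam` must be a single nonnegative number")
  }
  structure(list(T = T, alpha = alpha, lam = lam), class = "distill_config")
}

#' Temperature-scaled soft targets
#'
#' Converts class logits into the teacher's soft-target distribution
#' \eqn{\rho_i = \exp(\tau_i/T) / \sum_j \exp(\tau_j/T)}. At `T = 1` this is
#' the ordinary softmax; as `T` grows the distribution approaches uniform.
#'
#' @param logits Numeric vector of class logits.
#' @param T Positive temperature.
#' @return Probability vector of the same length (positive, sums to 1).
#' @export
#' @examples
#' soft_targets(c(2, 0), T = 2) # approx c(0.731, 0.269)
soft_targets <- function(logits, T = 1) {
  if (!is.numeric(T) || length(T) != 1 || T <= 0) {
    stop_param("`T` must be a single positive number")
  }
  z <- as.numeric(logits) / T
  z <- z - max(z) # shift invariance makes this exact, not just stabilising
  e <- exp(z)
  e / sum(e)
}

#' Mean absolute reconstruction error
#'
#' The teacher's restoration loss: mean over pixels of `|y - y_hat|`.
#'
#' @param y_hat Reconstructed tile (numeric vector/matrix).
#' @param y Input tile of identical shape.
#' @return Single nonnegative number; 0 iff the tiles are identical.
#' @export
l1_loss <- function(y_hat, y) {
  check_same_shape(y_hat, y)
  mean(abs(as.numeric(y) - as.numeric(y_hat)))
}

#' Binary cross-entropy for a single probability
#'
#' `-z log(z_hat) - (1 - z) log(1 - z_hat)` with probabilities clipped to
#' `[eps, 1 - eps]`. Vectorised elementwise; natural logarithm.
#'
#' @param z_hat Predicted positive-class probability (or vector of them).
#' @param z Binary label(s) in `{0, 1}`, same length as `z_hat`.
#' @param eps Clipping constant, default `1e-7`.
#' @return Elementwise nonnegative loss, same shape as `z_hat`.
#' @export
#' @examples
#' ce_loss(0.5, 1) # log(2)
ce_loss <- function(z_hat, z, eps = 1e-7) {
  if (length(z_hat) != length(z)) {
    stop_shape("`z_hat` and `z` must have equal length")
  }
  if (!all(z %in% c(0, 1))) stop_param("`z` must be binary (0/1)")
  p <- pmin(pmax(as.numeric(z_hat), eps), 1 - eps)
  -z * log(p) - (1 - z) * log(1 - p)
}

#' Teacher objective: reconstruction + classification
#'
#' `L_T = L_L1 + L_CE`, the unweighted sum of the mean absolute
#' reconstruction error and the cross-entropy of the predicted pathology.
#' The positive class is `malignant` (index 2 of the logit vector).
#'
#' @param out Teacher forward output: a list with elements `reconstruction`
#'   and `class_logits` (see [build_teacher()]).
#' @param y Input tile the reconstruction is compared against.
#' @param z Binary pathology label (1 = malignant, 0 = benign).
#' @return Single nonnegative number.
#' @export
teacher_loss <- function(out, y, z) {
  l1 <- l1_loss(out$reconstruction, y)
  z_hat <- soft_targets(out$class_logits, T = 1)[2]
  l1 + ce_loss(z_hat, z)
}

#' Kullback-Leibler bottleneck transfer loss
#'
#' `sum_j q_j log(q_j / p_j)` with the teacher distribution `q` as reference,
#' pulling the student bottleneck distribution `p` toward it. Natural log;
#' nonnegative by Gibbs' inequality, zero iff `p == q`.
#'
#' @param p Student bottleneck probability vector (see
#'   [bottleneck_distribution()]).
#' @param q Teacher bottleneck probability vector, same length.
#' @param eps Clipping constant applied inside the logs, default `1e-7`.
#' @return Single nonnegative number.
#' @export
#' @examples
#' kl_loss(c(0.25, 0.75), c(0.5, 0.5)) # 0.5*log(2) + 0.5*log(2/3)
kl_loss <- function(p, q, eps = 1e-7) {
  if (length(p) != length(q)) {
    stop_shape("`p` and `q` must have equal length")
  }
  if (any(p < 0) || any(q < 0)) stop_param("probabilities must be nonnegative")
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6) {
    stop_param("`p` and `q` must each sum to 1")
  }
  pc <- pmax(as.numeric(p), eps)
  qc <- pmax(as.numeric(q), eps)
  sum(ifelse(q > 0, q * (log(qc) - log(pc)), 0))
}

#' Softmax normalisation of a bottleneck code
#'
#' Flattens the deepest encoder activation and maps it onto the probability
#' simplex with a softmax, the form both [kl_loss()] arguments must take.
#'
#' @param code Numeric vector or array of bottleneck activations.
#' @return Probability vector of length `length(code)`.
#' @export
bottleneck_distribution <- function(code) {
  soft_targets(as.numeric(code), T = 1)
}

#' Smoothed Dice overlap
#'
#' `(2 * sum(a*b) + eps) / (sum(a) + sum(b) + eps)` for probability maps or
#' vectors with entries in `[0, 1]`. Equals 1 for identical binary masks and
#' (up to `eps`) 0 for disjoint ones.
#'
#' @param a,b Probability maps/vectors of identical shape, entries in `[0, 1]`.
#' @param eps Smoothing constant, default `1e-6`.
#' @return Number in `[0, 1]`.
#' @export
soft_dice <- function(a, b, eps = 1e-6) {
  check_same_shape(a, b)
  a <- as.numeric(a); b <- as.numeric(b)
  if (any(a < 0 | a > 1) || any(b < 0 | b > 1)) {
    stop_param("`a` and `b` must have entries in [0, 1]")
  }
  (2 * sum(a * b) + eps) / (sum(a) + sum(b) + eps)
}

#' Knowledge-distillation loss on class vectors
#'
#' `(1 - Dice(rho, c)) + BCE(rho_star, c)` where `rho` is the teacher's
#' soft-target class distribution, `rho_star` its one-hot (argmax)
#' binarisation -- soft labels cannot enter a binary cross-entropy -- and `c`
#' the student's sigmoid class probabilities. The BCE is the elementwise mean.
#'
#' @param rho Teacher soft targets (probability vector, length 2).
#' @param rho_star One-hot binarised teacher prediction, same length.
#' @param student_class_probs Student's sigmoid class probabilities,
#'   same length.
#' @return Single nonnegative number.
#' @export
kd_loss <- function(rho, rho_star, student_class_probs) {
  k <- length(rho)
  if (length(rho_star) != k || length(student_class_probs) != k) {
    stop_shape("`rho`, `rho_star` and `student_class_probs` must have equal length")
  }
  if (!all(rho_star %in% c(0, 1)) || sum(rho_star) != 1) {
    stop_param("`rho_star` must be one-hot")
  }
  (1 - soft_dice(rho, student_class_probs)) +
    mean(ce_loss(student_class_probs, rho_star))
}

#' Ground-truth segmentation loss
#'
#' `(1 - Dice(s, sigma)) + BCE(s, sigma)` between the binary reference mask
#' `s` and the student's per-pixel probabilities `sigma`; the BCE term is the
#' pixel mean. Zero (within the smoothing constants) iff the prediction
#' equals the mask exactly.
#'
#' @param gt_mask Binary ground-truth mask.
#' @param student_seg_probs Probability map of identical shape.
#' @return Single nonnegative number.
#' @export
gt_loss <- function(gt_mask, student_seg_probs) {
  check_same_shape(gt_mask, student_seg_probs)
  if (!all(gt_mask %in% c(0, 1))) stop_param("`gt_mask` must be binary (0/1)")
  (1 - soft_dice(gt_mask, student_seg_probs)) +
    mean(ce_loss(student_seg_probs, as.numeric(gt_mask)))
}

#' Student objective
#'
#' The affine combination `L_S = alpha * L_KD + (1 - alpha) * L_GT +
#' lam * L_KL`. With `alpha = 0, lam = 0` it reduces to the purely
#' supervised segmentation loss.
#'
#' @param kd Knowledge-distillation loss value.
#' @param gt Ground-truth segmentation loss value.
#' @param kl Bottleneck KL transfer loss value.
#' @param cfg A [distill_config()].
#' @return Single number.
#' @export
#' @examples
#' student_loss(2, 4, 1, distill_config(alpha = 0.25, lam = 0.1)) # 3.6
student_loss <- function(kd, gt, kl, cfg = distill_config()) {
  if (!inherits(cfg, "distill_config")) {
    cfg <- do.call(distill_config, as.list(cfg))
  }
  cfg$alpha * kd + (1 - cfg$alpha) * gt + cfg$lam * kl
}

#' Per-sample (unreduced) loss variants
#'
#' Apply a loss over parallel lists of samples, returning one value per
#' sample instead of a batch reduction. Used to serialise loss breakdowns to
#' training logs.
#'
#' @param y_hat_list,y_list,a_list,b_list,mask_list,prob_list Lists of
#'   same-shaped numeric arrays, one element per sample.
#' @param ... Passed on to the underlying loss.
#' @return Numeric vector with one loss value per sample.
#' @name loss_each
NULL

#' @rdname loss_each
#' @export
l1_loss_each <- function(y_hat_list, y_list) {
  purrr::map2_dbl(y_hat_list, y_list, l1_loss)
}

#' @rdname loss_each
#' @export
soft_dice_each <- function(a_list, b_list, ...) {
  purrr::map2_dbl(a_list, b_list, soft_dice, ...)
}

#' @rdname loss_each
#' @export
gt_loss_each <- function(mask_list, prob_list) {
  purrr::map2_dbl(mask_list, prob_list, gt_loss)
}

check_same_shape <- function(a, b) {
  da <- dim(a) %||% length(a)
  db <- dim(b) %||% length(b)
  if (!identical(as.integer(da), as.integer(db))) {
    stop_shape(sprintf(
      "shape mismatch: [%s] vs [%s]",
      paste(da, collapse = "x"), paste(db, collapse = "x")
    ))
  }
  invisible(TRUE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
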