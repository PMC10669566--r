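#' Overlap metrics between predicted and reference masks
#'
#' Computes the voxel confusion counts and the three standard brain
#' extraction scores:
#' Dice `= 2TP / (2TP + FN + FP)`, sensitivity `= TP / (TP + FN)` (ability
#' to recognize brain) and specificity `= TN / (TN + FP)` (ability to
#' recognize non-brain).
#'
#' Conventions for degenerate denominators (these arise on empty phantom
#' corners, not from the definitions): if both masks are empty, Dice and
#' sensitivity are 1; specificity is 1 whenever `FP == 0` and `TN > 0`.
#'
#' @param pred predicted [bx_mask()].
#' @param ref reference (ground truth) [bx_mask()], same shape.
#' @return An object of class `"bx_eval"`: `dice`, `sensitivity`,
#'   `specificity`, `tp`, `fp`, `fn`, `tn`.
#' @examples
#' a <- bx_mask(array(c(1, 1, 1, 0, 0, 0, 0, 0), c(2, 2, 2)))
#' b <- bx_mask(array(c(1, 1, 0, 1, 0, 0, 0, 0), c(2, 2, 2)))
#' evaluate(a, b)$dice # 2*2 / (2*2 + 1 + 1)
#' @export
evaluate <- function(pred, ref) {
  stopifnot(inherits(pred, "bx_mask"), inherits(ref, "bx_mask"))
  check_same_shape(pred$data, ref$data, "masks")
  p <- pred$data == 1L; r <- ref$data == 1L
  tp <- sum(p & r); fp <- sum(p & !r); fn <- sum(!p & r); tn <- sum(!p & !r)
  dice <- if (2 * tp + fn + fp > 0) 2 * tp / (2 * tp + fn + fp) else 1
  sens <- if (tp + fn > 0) tp / (tp + fn) else 1
  spec <- if (tn + fp > 0) tn / (tn + fp) else 1
  structure(list(dice = dice, sensitivity = sens, specificity = spec,
                 tp = tp, fp = fp, fn = fn, tn = tn), class = "bx_eval")
}

#' @export
print.bx_eval <- function(x, ...) {
  cat(sprintf("<bx_eval> Dice %.2f%%  sensitivity %.2f%%  specificity %.2f%%\n",
              100 * x$dice, 100 * x$sensitivity, 100 * x$specificity))
  cat(sprintf("  TP %d  FP %d  FN %d  TN %d\n", x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Per-slice brain fraction vs. segmentation accuracy profile
#'
#' For every slice along `plane`, reports the true brain-pixel proportion
#' and the per-slice F1/Dice of the prediction. Peripheral slices carry
#' little brain tissue and are where 2D segmentation degrades; this profile
#' exposes that relationship. Slices with no true and no predicted brain
#' get F1 = 1 by convention.
#'
#' @param pred predicted [bx_mask()].
#' @param ref reference [bx_mask()], same shape.
#' @param plane plane tag.
#' @return A data.frame with columns `slice_index` (1-based),
#'   `brain_fraction` and `f1`.
#' @export
slice_profile <- function(pred, ref, plane) {
  stopifnot(inherits(pred, "bx_mask"), inherits(ref, "bx_mask"))
  check_same_shape(pred$data, ref$data, "masks")
  ax <- plane_axis(plane)
  p <- pred$data == 1L; r <- ref$data == 1L
  tp <- apply(p & r, ax, sum)
  fp <- apply(p & !r, ax, sum)
  fn <- apply(!p & r, ax, sum)
  denom <- 2 * tp + fp + fn
  f1 <- ifelse(denom > 0, 2 * tp / pmax(denom, 1), 1)
  data.frame(slice_index = seq_along(tp),
             brain_fraction = as.numeric(apply(r, ax, mean)),
             f1 = as.numeric(f1))
}
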