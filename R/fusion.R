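#' Per-slice predicted brain fractions
#'
#' For each slice along `plane`, the fraction of voxels whose probability
#' meets the threshold. These fractions are the raw weights of the
#' multi-plane fusion: a plane viewing a voxel from a brain-rich slice
#' should dominate the fused decision for that voxel.
#'
#' @param p a probability 3D array (values in `[0, 1]`) or [bx_volume()].
#' @param plane plane tag.
#' @param threshold counting threshold (default 0.5; a voxel exactly at the
#'   threshold counts as brain).
#' @return Numeric vector, one fraction in `[0, 1]` per slice.
#' @export
slice_fractions <- function(p, plane, threshold = 0.5) {
  arr <- as_array3d(p)
  ax <- plane_axis(plane)
  apply(arr >= threshold, ax, mean)
}

#' One plane's prediction: probabilities plus slice fractions
#'
#' @param prob probability 3D array in `[0, 1]`.
#' @param plane plane tag.
#' @param threshold threshold used for the slice fractions.
#' @return An object of class `"bx_plane_prediction"`.
#' @export
plane_prediction <- function(prob, plane, threshold = 0.5) {
  prob <- as_array3d(prob)
  if (min(prob) < 0 || max(prob) > 1)
    bx_stop("probabilities must lie in [0, 1]", "value")
  plane_axis(plane)
  structure(list(prob = prob, plane = plane,
                 slice_fractions = slice_fractions(prob, plane, threshold)),
            class = "bx_plane_prediction")
}

#' Fuse orthogonal-plane predictions by brain-fraction weighting
#'
#' Implements the weighted combination `Pc = w1*P1 + w2*P2 + w3*P3` of the
#' per-plane probability volumes. For voxel `(i, j, k)` the raw weights are
#' the sagittal slice-`i`, coronal slice-`j` and transverse slice-`k`
#' predicted brain fractions; they are normalized per voxel to sum to 1
#' (equal weights 1/3 where all three fractions are zero). The fused volume
#' is thresholded at 0.5 (ties count as brain) to give the final mask.
#'
#' Fusion also accepts two planes (or degenerates to the identity for one)
#' through [fuse_planes()].
#'
#' @param p_sag,p_cor,p_tra `"bx_plane_prediction"` objects for the
#'   sagittal, coronal and transverse planes, sharing one volume shape.
#' @param threshold binarization threshold for the fused mask.
#' @return An object of class `"bx_fused"`: `prob` (fused probability
#'   array), `mask` (a [bx_mask()]) and `weights_used` (description of the
#'   weight rule).
#' @examples
#' p <- array(0.6, c(4, 4, 4))
#' f <- fuse(plane_prediction(p, "sagittal"), plane_prediction(p, "coronal"),
#'           plane_prediction(p, "transverse"))
#' unique(as.vector(f$prob))
#' @export
fuse <- function(p_sag, p_cor, p_tra, threshold = 0.5) {
  fuse_planes(list(p_sag, p_cor, p_tra), threshold = threshold)
}

#' @rdname fuse
#' @param preds list of 1-3 `"bx_plane_prediction"` objects with distinct
#'   plane tags.
#' @export
fuse_planes <- function(preds, threshold = 0.5) {
  stopifnot(length(preds) >= 1, all(vapply(preds, inherits, logical(1),
                                           "bx_plane_prediction")))
  planes <- vapply(preds, `[[`, character(1), "plane")
  if (anyDuplicated(planes)) bx_stop("duplicate plane tags", "value")
  shape <- dim(preds[[1]]$prob)
  for (p in preds) check_same_shape(p$prob, preds[[1]]$prob, "probability volumes")
  # per-voxel raw weight arrays: broadcast each plane's fractions along its axis
  wts <- lapply(preds, function(p) broadcast_axis(p$slice_fractions,
                                                  plane_axis(p$plane), shape))
  wsum <- Reduce(`+`, wts)
  zero <- wsum == 0
  wsum[zero] <- 1
  pc <- array(0, shape)
  for (m in seq_along(preds)) {
    w <- wts[[m]] / wsum
    w[zero] <- 1 / length(preds)
    pc <- pc + w * preds[[m]]$prob
  }
  structure(list(prob = pc, mask = binarize(pc, threshold),
                 weights_used = paste0("per-voxel normalized slice brain ",
                                       "fractions (equal-weight fallback); planes: ",
                                       paste(planes, collapse = ", "))),
            class = "bx_fused")
}

# expand a per-slice vector into a 3D array varying along `axis`
broadcast_axis <- function(v, axis, shape) {
  stopifnot(length(v) == shape[axis])
  switch(axis,
         array(v, shape),
         array(rep(rep(v, each = shape[1]), shape[3]), shape),
         array(rep(v, each = shape[1] * shape[2]), shape))
}

#' Threshold a probability volume into a brain mask
#'
#' @param p probability 3D array (values in `[0, 1]`).
#' @param threshold value in the open interval (0, 1); voxels with
#'   probability `>= threshold` become brain (a tie at exactly the
#'   threshold is brain).
#' @return A [bx_mask()].
#' @export
binarize <- function(p, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 1)
    bx_stop("threshold must lie strictly between 0 and 1", "value")
  arr <- as_array3d(p)
  bx_mask(array(as.integer(arr >= threshold), dim(arr)))
}

#' @export
print.bx_fused <- function(x, ...) {
  cat(sprintf("<bx_fused> %s voxels, %d brain (%.1f%%)\n  weights: %s\n",
              paste(dim(x$prob), collapse = "x"), sum(x$mask$data),
              100 * mean(x$mask$data), x$weights_used))
  invisible(x)
}
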