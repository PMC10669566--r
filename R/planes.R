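#' @rdname extract_slices
#' @export
plane_axis <- function(plane) {
  planes <- c(sagittal = 1L, coronal = 2L, transverse = 3L)
  if (!is.character(plane) || length(plane) != 1 || !plane %in% names(planes))
    bx_stop(sprintf("unknown plane '%s'; use sagittal, coronal or transverse",
                    paste(plane, collapse = ",")), "value")
  planes[[plane]]
}

#' Decompose a volume into one plane's 2D slice stack
#'
#' Slicing follows the canonical axis convention: sagittal slices are
#' `v[i, , ]`, coronal `v[, i, ]`, transverse `v[, , i]`. In-plane axes keep
#' their original order (lower remaining axis first), so that
#' [restack()] is an exact inverse. "Transverse" and "axial" refer to the
#' same plane; the tag used throughout is `transverse`.
#'
#' @param x a [bx_volume()], [bx_mask()], probability array or plain 3D array.
#' @param plane `"sagittal"`, `"coronal"` or `"transverse"`.
#' @return An object of class `"bx_slice_stack"`: `slices` (list of 2D
#'   matrices), `plane`, `source_shape`.
#' @examples
#' v <- array(seq_len(4 * 5 * 6), c(4, 5, 6))
#' s <- extract_slices(v, "sagittal")
#' length(s$slices); dim(s$slices[[1]])
#' @export
extract_slices <- function(x, plane) {
  ax <- plane_axis(plane)
  arr <- as_array3d(x)
  n <- dim(arr)[ax]
  slices <- lapply(seq_len(n), function(i)
    switch(ax, arr[i, , , drop = TRUE], arr[, i, , drop = TRUE],
           arr[, , i, drop = TRUE]))
  # drop=TRUE can collapse unit in-plane extents; restore 2D shape
  sh <- dim(arr)[setdiff(1:3, ax)]
  slices <- lapply(slices, function(s) { dim(s) <- sh; s })
  structure(list(slices = slices, plane = plane, source_shape = dim(arr)),
            class = "bx_slice_stack")
}

#' Reassemble a slice stack into a 3D array
#'
#' Exact inverse of [extract_slices()] for the same plane: slice `i` returns
#' to position `i` along the plane axis.
#'
#' @param s a `"bx_slice_stack"`.
#' @return A 3D array of shape `s$source_shape`.
#' @export
restack <- function(s) {
  stopifnot(inherits(s, "bx_slice_stack"))
  ax <- plane_axis(s$plane)
  shape <- s$source_shape
  if (length(s$slices) != shape[ax])
    bx_stop(sprintf("stack has %d slices but source extent is %d",
                    length(s$slices), shape[ax]), "shape")
  sh <- shape[setdiff(1:3, ax)]
  ok <- vapply(s$slices, function(sl) identical(dim(sl), as.integer(sh)) ||
                 identical(dim(sl), sh), logical(1))
  if (!all(ok)) bx_stop("slice shapes inconsistent with source_shape", "shape")
  out <- array(0, shape)
  for (i in seq_along(s$slices)) {
    switch(ax,
           out[i, , ] <- s$slices[[i]],
           out[, i, ] <- s$slices[[i]],
           out[, , i] <- s$slices[[i]])
  }
  out
}

#' @export
print.bx_slice_stack <- function(x, ...) {
  cat(sprintf("<bx_slice_stack> %d %s slices of %s\n", length(x$slices),
              x$plane, paste(dim(x$slices[[1]]), collapse = "x")))
  invisible(x)
}
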