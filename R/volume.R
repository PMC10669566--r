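#' 3D intensity volume
#'
#' Container for a 3D scalar MRI volume. The axis convention is fixed across
#' the package: axis 1 indexes sagittal slices, axis 2 coronal slices and
#' axis 3 transverse (axial) slices. Indexing is 1-based as usual in R;
#' human-facing slice reports are also 1-based.
#'
#' @param data numeric 3D array of intensities; all values must be finite.
#' @param spacing numeric length-3 vector of voxel sizes in mm (all > 0).
#' @return An object of class `"bx_volume"` with fields `data`, `spacing`
#'   and `axis_order`.
#' @examples
#' v <- bx_volume(array(rnorm(27), c(3, 3, 3)))
#' dim(v$data)
#' @export
bx_volume <- function(data, spacing = c(1, 1, 1)) {
  data <- validate_vol_array(data)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    bx_stop("spacing must be 3 strictly positive voxel sizes", "value")
  structure(list(data = data, spacing = spacing,
                 axis_order = c("sagittal", "coronal", "transverse")),
            class = "bx_volume")
}

validate_vol_array <- function(data) {
  if (!is.array(data) || length(dim(data)) != 3)
    bx_stop(sprintf("expected a 3D array, got %d dimension(s)",
                    length(dim(data))), "dimensionality")
  if (any(dim(data) < 1)) bx_stop("every extent must be >= 1", "dimensionality")
  storage.mode(data) <- "double"
  nbad <- sum(!is.finite(data))
  if (nbad > 0)
    bx_stop(sprintf("volume contains %d non-finite voxel(s)", nbad), "data")
  data
}

#' Binary brain mask
#'
#' A mask aligned voxel-for-voxel with a [bx_volume()]; values are exactly
#' 0 (non-brain) or 1 (brain), stored as integers.
#'
#' @param data 3D array whose values are 0/1 (within `tol` of an integer).
#' @param tol tolerance for rounding stored values to {0,1}.
#' @return An object of class `"bx_mask"` with field `data`.
#' @examples
#' m <- bx_mask(array(0L, c(4, 4, 4)))
#' sum(m$data)
#' @export
bx_mask <- function(data, tol = 1e-6) {
  if (!is.array(data) || length(dim(data)) != 3)
    bx_stop("mask must be a 3D array", "dimensionality")
  r <- round(as.numeric(data))
  if (any(!is.finite(r)) || any(abs(as.numeric(data) - r) > tol) ||
      any(!(r %in% c(0, 1))))
    bx_stop("mask values must be exactly 0 or 1", "data")
  data <- array(as.integer(r), dim(data))
  structure(list(data = data), class = "bx_mask")
}

#' @export
print.bx_volume <- function(x, ...) {
  cat(sprintf("<bx_volume> %s voxels, spacing %s mm, range [%.4g, %.4g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing, digits = 3), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.bx_mask <- function(x, ...) {
  cat(sprintf("<bx_mask> %s voxels, %d brain (%.1f%%)\n",
              paste(dim(x$data), collapse = "x"), sum(x$data),
              100 * mean(x$data)))
  invisible(x)
}

# coerce volume/mask/plain array to a bare 3D array
as_array3d <- function(x) {
  if (inherits(x, c("bx_volume", "bx_mask"))) return(x$data)
  if (is.array(x) && length(dim(x)) == 3) return(x)
  bx_stop("expected a bx_volume, bx_mask or 3D array", "value")
}

check_same_shape <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b)))
    bx_stop(sprintf("%s have different shapes (%s vs %s)", what,
                    paste(dim(a), collapse = "x"),
                    paste(dim(b), collapse = "x")), "shape")
  invisible(TRUE)
}
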