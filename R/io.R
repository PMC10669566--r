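#' Read a 3D volume from NIfTI or Analyze
#'
#' Reads a NIfTI-1 file (`.nii`, `.nii.gz`) or an Analyze 7.5 pair
#' (`.hdr`/`.img`). The image must be 3D; voxel values must be finite. When
#' the NIfTI header carries a spatial transform, the volume is reoriented to
#' the package's canonical RAS axis convention (axis 1 sagittal, axis 2
#' coronal, axis 3 transverse); otherwise the stored axis order is taken
#' as already canonical.
#'
#' @param path path to a `.nii`, `.nii.gz`, `.hdr` or `.img` file.
#' @return A [bx_volume()].
#' @seealso [write_volume()], [read_mask()]
#' @export
read_volume <- function(path) {
  arr_sp <- read_any_image(path)
  nbad <- sum(!is.finite(arr_sp$data))
  if (nbad > 0)
    bx_stop(sprintf("image contains %d NaN/Inf voxel(s)", nbad), "data")
  bx_volume(arr_sp$data, arr_sp$spacing)
}

#' Write a volume to NIfTI
#'
#' Volumes are stored at double precision so that write/read round trips are
#' lossless. Output is always NIfTI-1 (use `.nii` or `.nii.gz`).
#'
#' @param v a [bx_volume()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "bx_volume"))
  write_nifti_canonical(v$data, v$spacing, path, datatype = "double")
  invisible(path)
}

#' Read a binary brain mask
#'
#' Stored values must be within `1e-6` of 0 or 1; anything else is a data
#' error (a probability map is not a mask).
#'
#' @param path path to a mask image (NIfTI or Analyze).
#' @return A [bx_mask()].
#' @export
read_mask <- function(path) {
  arr_sp <- read_any_image(path)
  bx_mask(arr_sp$data)
}

#' Write a binary brain mask to NIfTI
#'
#' Masks are stored as unsigned 8-bit integers, so round trips are bit-exact.
#'
#' @param m a [bx_mask()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return Invisibly, `path`.
#' @export
write_mask <- function(m, path) {
  stopifnot(inherits(m, "bx_mask"))
  write_nifti_canonical(m$data, c(1, 1, 1), path, datatype = "uint8")
  invisible(path)
}

# ---- internals ---------------------------------------------------------

read_any_image <- function(path) {
  if (!is.character(path) || length(path) != 1)
    bx_stop("path must be a single file path", "value")
  if (!file.exists(path))
    bx_stop(sprintf("file not found: %s", path), "io")
  lower <- tolower(path)
  if (grepl("\\.(hdr|img)(\\.gz)?$", lower)) {
    img <- oro.nifti::readANALYZE(path)
    data <- drop_trailing_units(img@.Data)
    spacing <- as.numeric(img@pixdim[2:4])
  } else {
    img <- RNifti::readNifti(path)
    img <- reorient_canonical(img)
    data <- drop_trailing_units(unclass(as.array(img)))
    spacing <- as.numeric(RNifti::pixdim(img))[seq_len(min(3, length(dim(data))))]
  }
  if (length(dim(data)) != 3)
    bx_stop(sprintf("expected a 3D image, got %dD", length(dim(data))),
            "dimensionality")
  if (any(!is.finite(spacing)) || any(spacing <= 0)) spacing <- c(1, 1, 1)
  list(data = data, spacing = spacing[1:3])
}

# NIfTI images are frequently stored with singleton trailing dims; a
# 64x64x64x1 image is still a 3D volume. A genuine 4D time series is not.
drop_trailing_units <- function(data) {
  d <- dim(data)
  if (is.null(d)) d <- length(data)
  while (length(d) > 3 && d[length(d)] == 1) d <- d[-length(d)]
  if (length(d) == 1) d <- c(d, 1L, 1L) # degenerate but caught later
  array(as.numeric(data), d) # drop image-class attributes
}

reorient_canonical <- function(img) {
  orn <- tryCatch(RNifti::orientation(img), error = function(e) NULL)
  if (is.null(orn) || !is.character(orn) || nchar(orn) != 3) return(img)
  # only trust (and act on) an explicit qform/sform
  code_q <- tryCatch(attr(RNifti::xform(img, useQuaternionFirst = TRUE), "code"),
                     error = function(e) 0L)
  if (is.null(code_q) || length(code_q) != 1 || is.na(code_q) || code_q <= 0)
    return(img)
  if (orn != "RAS") RNifti::orientation(img) <- "RAS"
  img
}

write_nifti_canonical <- function(data, spacing, path, datatype) {
  if (!grepl("\\.nii(\\.gz)?$", tolower(path)))
    bx_stop("output must be NIfTI (.nii or .nii.gz)", "value")
  dir <- dirname(path)
  if (!dir.exists(dir)) bx_stop(sprintf("directory not found: %s", dir), "io")
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}
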