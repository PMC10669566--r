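#' Synthetic head-phantom specification
#'
#' The phantom emulates the six-class intensity structure of a T1-weighted
#' head image as nested ellipsoids: a white-matter core, a gray-matter
#' shell and a thin CSF rim (their union is the brain mask), wrapped in
#' skull and scalp shells over background. The brain ellipsoid is slightly
#' off-center so slice brain-fraction curves are asymmetric, as in real
#' heads. Default tissue means are spaced 20 units apart with noise sigma 2
#' (minimum contrast-to-noise ratio 10), which keeps the six-cluster
#' intensity decomposition well-posed despite the dominant background
#' class; raise `noise_sigma` (e.g. to 10, gap = 2 sigma) for stress tests.
#'
#' @param shape integer 3-vector of volume extents (default 64x64x64).
#' @param tissue_means named 6-vector of intensities for background, scalp,
#'   skull, CSF, gray matter, white matter (pairwise distinct).
#' @param noise_sigma additive Gaussian noise standard deviation (>= 0).
#' @param brain_axes ellipsoid semi-axes of the brain, in voxels.
#' @param center_offset brain-center offset from the volume center, voxels.
#' @param seed integer seed; generation is bit-reproducible per seed.
#' @return An object of class `"bx_phantom_spec"`.
#' @export
phantom_spec <- function(shape = c(64, 64, 64),
                         tissue_means = c(background = 0, scalp = 80,
                                          skull = 20, csf = 40, gm = 60,
                                          wm = 100),
                         noise_sigma = 2, brain_axes = c(22, 18, 20),
                         center_offset = c(2.5, 1.5, -2), seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 8))
    bx_stop("shape must be 3 extents, each >= 8", "spec")
  if (length(tissue_means) != 6 || anyDuplicated(tissue_means))
    bx_stop("tissue_means must be 6 pairwise-distinct intensities", "spec")
  if (noise_sigma < 0) bx_stop("noise_sigma must be >= 0", "spec")
  centre <- (shape + 1) / 2 + center_offset
  outer <- brain_axes + 4 # scalp outer surface
  if (any(centre + outer + 2 > shape) || any(centre - outer - 2 < 1))
    bx_stop("brain ellipsoid too large: scalp shell needs a 2-voxel margin",
            "spec")
  structure(list(shape = shape, tissue_means = tissue_means,
                 noise_sigma = noise_sigma, brain_axes = as.numeric(brain_axes),
                 center_offset = as.numeric(center_offset),
                 seed = as.integer(seed)),
            class = "bx_phantom_spec")
}

# tissue label codes
PHANTOM_LABELS <- c(background = 0L, scalp = 1L, skull = 2L, csf = 3L,
                    gm = 4L, wm = 5L)

#' Generate a head phantom
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `"bx_phantom"`: `volume` (a [bx_volume()]),
#'   `brain_mask` (a [bx_mask()], exactly the CSF+GM+WM voxels),
#'   `tissue_labels` (3D integer array over 0..5) and `spec`.
#' @examples
#' ph <- generate_phantom(phantom_spec(shape = c(24, 24, 24),
#'                                     brain_axes = c(6, 5, 5.5),
#'                                     center_offset = c(0.5, 0, -0.5)))
#' mean(ph$brain_mask$data)
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "bx_phantom_spec"))
  sh <- spec$shape
  centre <- (sh + 1) / 2 + spec$center_offset
  ax <- spec$brain_axes
  # squared normalized radius for an ellipsoid with semi-axes a
  r2 <- function(a) {
    g1 <- ((seq_len(sh[1]) - centre[1]) / a[1])^2
    g2 <- ((seq_len(sh[2]) - centre[2]) / a[2])^2
    g3 <- ((seq_len(sh[3]) - centre[3]) / a[3])^2
    array(outer(outer(g1, g2, `+`), g3, `+`), sh)
  }
  lab <- array(PHANTOM_LABELS[["background"]], sh)
  lab[r2(ax + 4) <= 1] <- PHANTOM_LABELS[["scalp"]]
  lab[r2(ax + 2) <= 1] <- PHANTOM_LABELS[["skull"]]
  lab[r2(ax) <= 1] <- PHANTOM_LABELS[["csf"]]
  lab[r2(0.92 * ax) <= 1] <- PHANTOM_LABELS[["gm"]]
  lab[r2(0.70 * ax) <= 1] <- PHANTOM_LABELS[["wm"]]
  means <- as.numeric(spec$tissue_means)
  data <- array(means[lab + 1L], sh)
  if (spec$noise_sigma > 0)
    data <- data + with_seed(spec$seed,
                             array(rnorm(prod(sh), 0, spec$noise_sigma), sh))
  mask <- array(as.integer(lab >= PHANTOM_LABELS[["csf"]]), sh)
  structure(list(volume = bx_volume(data), brain_mask = bx_mask(mask),
                 tissue_labels = lab, spec = spec), class = "bx_phantom")
}

#' @export
print.bx_phantom <- function(x, ...) {
  cat(sprintf("<bx_phantom> %s voxels, brain fraction %.3f, noise sigma %.3g\n",
              paste(x$spec$shape, collapse = "x"), mean(x$brain_mask$data),
              x$spec$noise_sigma))
  invisible(x)
}

#' Generate a cohort of jittered phantoms
#'
#' Stands in for a multi-subject dataset: each phantom draws its ellipsoid
#' axes, tissue means, noise level and center offset from jittered ranges
#' around `base_spec`. Reproducible per `seed`.
#'
#' @param n number of phantoms (>= 1).
#' @param base_spec a [phantom_spec()] giving central parameter values.
#' @param jitter list with elements `axes` (relative, default 0.08),
#'   `means` (absolute intensity, default 2), `sigma` (relative, default
#'   0.2) and `offset` (absolute voxels, default 1).
#' @param seed integer cohort seed.
#' @return List of `n` `"bx_phantom"` objects.
#' @export
generate_cohort <- function(n, base_spec = phantom_spec(),
                            jitter = list(axes = 0.08, means = 2,
                                          sigma = 0.2, offset = 1),
                            seed = 1L) {
  n <- as.integer(n)
  if (n < 1) bx_stop("n must be >= 1", "value")
  jd <- modifyList(list(axes = 0.08, means = 2, sigma = 0.2, offset = 1),
                   as.list(jitter))
  specs <- with_seed(seed, lapply(seq_len(n), function(i) {
    phantom_spec(
      shape = base_spec$shape,
      tissue_means = base_spec$tissue_means +
        runif(6, -jd$means, jd$means),
      noise_sigma = base_spec$noise_sigma * runif(1, 1 - jd$sigma, 1 + jd$sigma),
      brain_axes = base_spec$brain_axes * runif(3, 1 - jd$axes, 1 + jd$axes),
      center_offset = base_spec$center_offset + runif(3, -jd$offset, jd$offset),
      seed = sample.int(2^30, 1))
  }))
  lapply(specs, generate_phantom)
}

#' Subject-level cross-validation folds
#'
#' Splits `n` subjects into `k` disjoint folds covering all subjects, with
#' sizes differing by at most one. Folds are drawn by subject, never by
#' slice, so no slice of a held-out subject leaks into training.
#'
#' @param n number of subjects.
#' @param k number of folds (default 5).
#' @param seed integer seed for the shuffle.
#' @return List of `k` integer vectors of subject indices.
#' @export
crossval_folds <- function(n, k = 5L, seed = 1L) {
  n <- as.integer(n); k <- as.integer(k)
  if (k < 2 || k > n) bx_stop("need 2 <= k <= n", "value")
  idx <- with_seed(seed, sample.int(n))
  unname(split(idx, rep(seq_len(k), length.out = n)))
}
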