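#' Fit a per-volume K-means intensity model
#'
#' Clusters the voxel amplitudes of one volume into `k` groups (default 6,
#' matching the conventional six-tissue decomposition of a head image:
#' background, scalp/fat, skull, CSF, gray matter, white matter). Clustering
#' is performed on raw amplitudes, background included, with k-means++
#' seeding followed by Lloyd iterations, and is exactly reproducible for a
#' fixed seed. The fitted centroids define the amplitude remapping applied
#' by [apply_cluster_remap()].
#'
#' @param v a [bx_volume()].
#' @param k number of intensity clusters (>= 2); default 6.
#' @param seed integer seed for k-means++ initialization.
#' @param max_iter maximum Lloyd iterations (default 300; Lloyd stops earlier
#'   once assignments are stable).
#' @param n_init number of k-means++ restarts (best inertia wins); all
#'   restarts are derived from `seed`, so the fit stays deterministic.
#' @return An object of class `"bx_cluster_model"`: `centroids` (sorted
#'   increasing), `k`, `seed`, `inertia` (within-cluster sum of squares)
#'   and `sizes` (voxels per cluster, aligned with `centroids`).
#' @examples
#' v <- bx_volume(array(rep(c(1, 9), each = 14), c(4, 7, 1)))
#' fit_kmeans(v, k = 2, seed = 1)$centroids
#' @export
fit_kmeans <- function(v, k = 6L, seed = 1L, max_iter = 300L, n_init = 4L) {
  stopifnot(inherits(v, "bx_volume"))
  k <- as.integer(k)
  if (k < 2) bx_stop("k must be >= 2", "value")
  x <- as.numeric(v$data)
  ux <- unique(x)
  if (length(ux) < k)
    bx_stop(sprintf("volume has only %d distinct intensities; k = %d needs at least k",
                    length(ux), k), "degenerate")
  fit <- with_seed(seed, {
    # candidate initializations: an (essentially exact) binned 1D dynamic
    # program — amplitude histograms are heavily imbalanced, and k-means++
    # alone occasionally locks onto a background-splitting local optimum —
    # plus k-means++ restarts; Lloyd polishes each and the best inertia wins
    inits <- c(list(kmeans_dp_init(x, k)),
               lapply(seq_len(max(1L, n_init)), function(i) kmeanspp_init(x, k)))
    best <- NULL
    for (centers in inits) {
      f <- suppressWarnings(stats::kmeans(x, centers = matrix(centers, ncol = 1),
                                          iter.max = max_iter,
                                          algorithm = "Lloyd"))
      if (is.null(best) || f$tot.withinss < best$tot.withinss) best <- f
    }
    best
  })
  ord <- order(fit$centers[, 1])
  structure(list(centroids = as.numeric(fit$centers[ord, 1]), k = k,
                 seed = as.integer(seed), inertia = fit$tot.withinss,
                 sizes = as.integer(fit$size[ord])),
            class = "bx_cluster_model")
}

# near-exact 1D k-means by dynamic programming on a weighted amplitude
# histogram (optimal 1D clusters are contiguous in sorted order); returns
# k centers to seed Lloyd on the full data
kmeans_dp_init <- function(x, k, bins = 256L) {
  ux <- sort(unique(x))
  if (length(ux) <= bins) {
    centers <- ux
    w <- as.numeric(table(factor(x, levels = ux)))
  } else {
    cut <- findInterval(x, seq(min(x), max(x), length.out = bins + 1L),
                        all.inside = TRUE)
    w <- tabulate(cut, bins)
    centers <- vapply(seq_len(bins), function(b)
      if (w[b] > 0) sum(x[cut == b]) / w[b] else 0, numeric(1))
    keep <- w > 0
    centers <- centers[keep]; w <- w[keep]
  }
  B <- length(centers)
  if (B <= k) return(c(centers, rep(centers[B], k - B))[seq_len(k)])
  # prefix sums for weighted SSE of contiguous bin ranges
  cw <- cumsum(w); cwx <- cumsum(w * centers); cwx2 <- cumsum(w * centers^2)
  seg_cost <- function(a, b) { # vectorized over a
    W <- cw[b] - ifelse(a > 1, cw[a - 1], 0)
    S <- cwx[b] - ifelse(a > 1, cwx[a - 1], 0)
    S2 <- cwx2[b] - ifelse(a > 1, cwx2[a - 1], 0)
    S2 - S^2 / pmax(W, 1e-300)
  }
  D <- matrix(Inf, k, B)
  back <- matrix(1L, k, B)
  D[1, ] <- vapply(seq_len(B), function(b) seg_cost(1L, b), numeric(1))
  for (j in 2:k) {
    for (b in j:B) {
      a <- j:b # first index of cluster j
      tot <- D[j - 1, a - 1] + seg_cost(a, b)
      i <- which.min(tot)
      D[j, b] <- tot[i]
      back[j, b] <- a[i]
    }
  }
  bounds <- integer(k + 1); bounds[k + 1] <- B
  for (j in k:1) {
    bounds[j] <- back[j, bounds[j + 1]] - 1L
  }
  vapply(seq_len(k), function(j) {
    idx <- (bounds[j] + 1):bounds[j + 1]
    sum(w[idx] * centers[idx]) / sum(w[idx])
  }, numeric(1))
}

# k-means++ seeding on a numeric vector: first center uniform, then each
# subsequent center drawn with probability proportional to squared distance
# to the nearest chosen center.
kmeanspp_init <- function(x, k) {
  centers <- numeric(k)
  centers[1] <- x[sample.int(length(x), 1L)]
  d2 <- (x - centers[1])^2
  for (j in seq_len(k - 1L) + 1L) {
    if (all(d2 == 0)) { # degenerate guard: pick any unused distinct value
      centers[j] <- setdiff(unique(x), centers[seq_len(j - 1L)])[1]
    } else {
      centers[j] <- x[sample.int(length(x), 1L, prob = d2)]
    }
    d2 <- pmin(d2, (x - centers[j])^2)
  }
  centers
}

#' @export
print.bx_cluster_model <- function(x, ...) {
  cat(sprintf("<bx_cluster_model> k = %d, inertia = %.4g\ncentroids: %s\n",
              x$k, x$inertia, paste(format(x$centroids, digits = 4),
                                    collapse = ", ")))
  invisible(x)
}

#' Remap voxel amplitudes to their nearest cluster centroid
#'
#' Replaces every voxel by the centroid nearest in intensity (ties go to the
#' lower centroid), compressing the gray-level range of each tissue to a
#' single plateau. The output volume has at most `k` distinct values; shape
#' and spacing are unchanged, and the mapping is monotone in intensity.
#'
#' @param v a [bx_volume()].
#' @param m a `"bx_cluster_model"` from [fit_kmeans()].
#' @param output `"centroid"` (default) replaces voxels by centroid
#'   intensities; `"label"` replaces them by the 1-based cluster index in
#'   increasing-centroid order.
#' @return A [bx_volume()] with remapped data.
#' @export
apply_cluster_remap <- function(v, m, output = c("centroid", "label")) {
  stopifnot(inherits(v, "bx_volume"), inherits(m, "bx_cluster_model"))
  output <- match.arg(output)
  cen <- m$centroids
  mid <- (cen[-length(cen)] + cen[-1]) / 2
  # left.open: a value equal to a midpoint falls to the lower centroid
  idx <- findInterval(v$data, mid, left.open = TRUE) + 1L
  out <- if (output == "centroid") cen[idx] else as.numeric(idx)
  bx_volume(array(out, dim(v$data)), v$spacing)
}

#' Per-slice 2D gradient-magnitude map
#'
#' Computes, slice by slice along the requested plane, the 2D Sobel gradient
#' magnitude `sqrt(Gx^2 + Gy^2)` (replicate-padded at slice borders), then
#' min-max scales the result to `[0, 1]` over the whole volume. This is the
#' second input image of the hybrid networks: it carries the gray-level
#' trend of each pixel's neighbourhood. A constant volume yields all zeros.
#'
#' @param v a [bx_volume()].
#' @param plane `"sagittal"`, `"coronal"` or `"transverse"`.
#' @param operator `"sobel"` (default) or `"central"` (plain central
#'   differences, no smoothing).
#' @return An object of class `"bx_gradient"`: `data` (3D array in `[0,1]`,
#'   same shape as `v`) and `plane`.
#' @export
gradient_map <- function(v, plane, operator = c("sobel", "central")) {
  stopifnot(inherits(v, "bx_volume"))
  operator <- match.arg(operator)
  ax <- plane_axis(plane)
  inplane <- setdiff(1:3, ax)
  d <- dim(v$data)
  if (any(d[inplane] < 3))
    bx_stop(sprintf("slices along %s are %dx%d; need at least 3x3", plane,
                    d[inplane[1]], d[inplane[2]]), "size")
  x <- v$data
  if (operator == "sobel") {
    # smooth along one in-plane axis, difference along the other
    sm1 <- shift3(x, inplane[2], -1) + 2 * x + shift3(x, inplane[2], 1)
    gx <- shift3(sm1, inplane[1], 1) - shift3(sm1, inplane[1], -1)
    sm2 <- shift3(x, inplane[1], -1) + 2 * x + shift3(x, inplane[1], 1)
    gy <- shift3(sm2, inplane[2], 1) - shift3(sm2, inplane[2], -1)
  } else {
    gx <- (shift3(x, inplane[1], 1) - shift3(x, inplane[1], -1)) / 2
    gy <- (shift3(x, inplane[2], 1) - shift3(x, inplane[2], -1)) / 2
  }
  g <- sqrt(gx^2 + gy^2)
  rng <- range(g)
  g <- if (rng[2] > rng[1]) (g - rng[1]) / (rng[2] - rng[1]) else array(0, d)
  structure(list(data = g, plane = plane), class = "bx_gradient")
}

# shift a 3D array by one voxel along `axis` with replicated edges;
# d = +1 brings the next element into each position (forward neighbour)
shift3 <- function(x, axis, d) {
  n <- dim(x)[axis]
  idx <- if (d > 0) c(2:n, n) else c(1, seq_len(n - 1))
  switch(axis, x[idx, , , drop = FALSE], x[, idx, , drop = FALSE],
         x[, , idx, drop = FALSE])
}
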