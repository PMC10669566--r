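# brute-force reference for the weighted plane combination: per voxel,
# weights = (f_sag[i], f_cor[j], f_tra[k]) normalized (1/3 each if all 0)
oracle_fuse <- function(ps, pc, pt, fs, fc, ft) {
  d <- dim(ps)
  out <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    w <- c(fs[i], fc[j], ft[k])
    w <- if (sum(w) > 0) w / sum(w) else rep(1 / 3, 3)
    out[i, j, k] <- w[1] * ps[i, j, k] + w[2] * pc[i, j, k] + w[3] * pt[i, j, k]
  }
  out
}

test_that("slice_fractions counts thresholded voxels per slice", {
  p <- array(0.1, c(10, 10, 3))
  p[1:5, 1:5, 2] <- 0.9
  f <- slice_fractions(p, "transverse")
  expect_equal(f, c(0, 0.25, 0))
  expect_equal(slice_fractions(array(0, c(4, 4, 4)), "sagittal"), rep(0, 4))
  expect_equal(slice_fractions(array(1, c(4, 4, 4)), "coronal"), rep(1, 4))
  # a voxel exactly at the threshold counts
  q <- array(0, c(2, 2, 1)); q[1, 1, 1] <- 0.5
  expect_equal(slice_fractions(q, "transverse"), 0.25)
})

test_that("fuse matches hand calculations", {
  # equal probabilities everywhere: weights cancel
  p <- array(0.6, c(4, 4, 4))
  f <- fuse(plane_prediction(p, "sagittal"), plane_prediction(p, "coronal"),
            plane_prediction(p, "transverse"))
  expect_equal(unique(as.vector(f$prob)), 0.6)
  expect_true(all(f$mask$data == 1)) # 0.6 >= 0.5

  # single voxel with fractions (0.2, 0.3, 0.5) and probs (1, 0, 1) -> 0.7
  mkpp <- function(prob, plane, fr) {
    structure(list(prob = prob, plane = plane, slice_fractions = fr),
              class = "bx_plane_prediction")
  }
  one <- array(1, c(1, 1, 1)); zero <- array(0, c(1, 1, 1))
  f2 <- fuse(mkpp(one, "sagittal", 0.2), mkpp(zero, "coronal", 0.3),
             mkpp(one, "transverse", 0.5))
  expect_equal(as.vector(f2$prob), 0.7)

  # all-zero fractions -> equal weights
  f3 <- fuse(mkpp(array(0.3, c(1, 1, 1)), "sagittal", 0),
             mkpp(array(0.6, c(1, 1, 1)), "coronal", 0),
             mkpp(array(0.9, c(1, 1, 1)), "transverse", 0))
  expect_equal(as.vector(f3$prob), 0.6)
})

test_that("fuse equals the brute-force per-voxel reference on random inputs", {
  set.seed(31)
  for (i in 1:5) {
    d <- sample(3:6, 3, replace = TRUE)
    ps <- array(runif(prod(d)), d); pc <- array(runif(prod(d)), d)
    pt <- array(runif(prod(d)), d)
    # random fractions, including some zeros to hit the fallback
    fs <- runif(d[1]); fs[sample(d[1], 1)] <- 0
    fc <- runif(d[2]); fc[sample(d[2], 1)] <- 0
    ft <- runif(d[3]); ft[sample(d[3], 1)] <- 0
    mkpp <- function(prob, plane, fr)
      structure(list(prob = prob, plane = plane, slice_fractions = fr),
                class = "bx_plane_prediction")
    f <- fuse(mkpp(ps, "sagittal", fs), mkpp(pc, "coronal", fc),
              mkpp(pt, "transverse", ft))
    ref <- oracle_fuse(ps, pc, pt, fs, fc, ft)
    expect_lt(max(abs(f$prob - ref)), 1e-12)
    # convex combination bound at every voxel
    lo <- pmin(ps, pc, pt); hi <- pmax(ps, pc, pt)
    expect_true(all(f$prob >= lo - 1e-12 & f$prob <= hi + 1e-12))
    # permutation consistency: feeding the same predictions in a different
    # argument-plane pairing is a different problem, but relabeling all
    # three together must not change the result
    f_perm <- fuse_planes(list(mkpp(pt, "transverse", ft),
                               mkpp(ps, "sagittal", fs),
                               mkpp(pc, "coronal", fc)))
    expect_equal(f_perm$prob, f$prob)
  }
})

test_that("identical plane volumes fuse to themselves", {
  set.seed(8)
  p <- array(runif(4 * 5 * 6), c(4, 5, 6))
  f <- fuse(plane_prediction(p, "sagittal"), plane_prediction(p, "coronal"),
            plane_prediction(p, "transverse"))
  expect_equal(f$prob, p, tolerance = 1e-12)
})

test_that("binarize applies the >= threshold tie rule", {
  p <- array(c(0.49, 0.5, 0.51, 0), c(4, 1, 1))
  m <- binarize(p)
  expect_equal(as.vector(m$data), c(0L, 1L, 1L, 0L))
  expect_true(all(binarize(array(0.49, c(3, 3, 3)))$data == 0))
  set.seed(4)
  q <- array(runif(5 * 5 * 5), c(5, 5, 5))
  expect_equal(sum(binarize(q)$data), sum(q >= 0.5))
  expect_error(binarize(p, threshold = 1.2), class = "brainext_value")
  expect_error(binarize(p, threshold = 0), class = "brainext_value")
})

test_that("two-plane and one-plane fusion use the same rule", {
  set.seed(9)
  d <- c(4, 4, 4)
  pa <- array(runif(prod(d)), d); pb <- array(runif(prod(d)), d)
  f2 <- fuse_planes(list(plane_prediction(pa, "sagittal"),
                         plane_prediction(pb, "coronal")))
  expect_true(all(f2$prob >= pmin(pa, pb) - 1e-12 &
                  f2$prob <= pmax(pa, pb) + 1e-12))
  f1 <- fuse_planes(list(plane_prediction(pa, "sagittal")))
  expect_equal(f1$prob, pa, tolerance = 1e-12)
})
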