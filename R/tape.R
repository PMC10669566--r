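# Minimal reverse-mode tape for the U-Net engine.
#
# A tape is an environment holding a list of nodes in topological (creation)
# order. Each node stores its value, its parents' ids and a backward closure
# mapping the node's output gradient to a list of parent gradients. Backward
# sweeps the list in reverse, accumulating gradients by node id. This is all
# the autodiff the segmentation networks need: the graph is rebuilt every
# batch, so no retain/free bookkeeping is required.

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

tape_node <- function(tp, value, parents = integer(0), backward = NULL) {
  tp$n <- tp$n + 1L
  if (tp$n > length(tp$nodes)) tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  tp$nodes[[tp$n]] <- list(value = value, parents = as.integer(parents),
                           backward = backward)
  tp$n
}

tape_value <- function(tp, id) {
  # force `id` before touching tp$nodes: evaluating an op-call promise can
  # append nodes, and the list must be re-read afterwards
  id <- as.integer(id)
  tp$nodes[[id]]$value
}

# gradient of node `loss_id` (a scalar) w.r.t. every node; returns the list
# of gradients indexed by node id (NULL where the node is unreachable)
tape_backward <- function(tp, loss_id) {
  grads <- vector("list", tp$n)
  grads[[loss_id]] <- 1
  for (id in seq(loss_id, 1L)) {
    g <- grads[[id]]
    node <- tp$nodes[[id]]
    if (is.null(g) || is.null(node$backward) || length(node$parents) == 0) next
    pg <- node$backward(g)
    for (j in seq_along(node$parents)) {
      p <- node$parents[j]
      if (is.null(pg[[j]])) next
      grads[[p]] <- if (is.null(grads[[p]])) pg[[j]] else grads[[p]] + pg[[j]]
    }
  }
  grads
}

# ---- ops ---------------------------------------------------------------
# activations are (H, W, C, N) arrays throughout

op_input <- function(tp, x) tape_node(tp, x)

op_conv3 <- function(tp, x_id, w_id, b_id) {
  x <- tape_value(tp, x_id); w <- tape_value(tp, w_id); b <- tape_value(tp, b_id)
  dims <- dim(x)
  y <- cpp_conv2d_fw(x, as.integer(dims), w, b)
  tape_node(tp, y, c(x_id, w_id, b_id), function(dy) {
    g <- cpp_conv2d_bw(x, as.integer(dims), w, dy)
    list(g$dx, g$dw, g$db)
  })
}

op_relu <- function(tp, x_id) {
  x <- tape_value(tp, x_id)
  pos <- x > 0
  y <- x * pos
  tape_node(tp, y, x_id, function(dy) list(dy * pos))
}

# 2x2 max pooling, stride 2; H and W must be even (guaranteed by padding)
op_pool <- function(tp, x_id) {
  x <- tape_value(tp, x_id)
  d <- dim(x)
  ro <- seq(1, d[1], 2); re <- ro + 1
  co <- seq(1, d[2], 2); ce <- co + 1
  a11 <- x[ro, co, , , drop = FALSE]; a21 <- x[re, co, , , drop = FALSE]
  a12 <- x[ro, ce, , , drop = FALSE]; a22 <- x[re, ce, , , drop = FALSE]
  y <- pmax(a11, a21, a12, a22)
  m11 <- a11 == y; m21 <- a21 == y & !m11
  m12 <- a12 == y & !(m11 | m21); m22 <- !(m11 | m21 | m12)
  tape_node(tp, y, x_id, function(dy) {
    dx <- array(0, d)
    dx[ro, co, , ] <- dy * m11; dx[re, co, , ] <- dy * m21
    dx[ro, ce, , ] <- dy * m12; dx[re, ce, , ] <- dy * m22
    list(dx)
  })
}

# 2x2 stride-2 transposed convolution; weight w is (Cin, 4*Cout), offset
# block o in 0..3 maps input (i,j) to output (2i + o%%2, 2j + o%/%2)
op_upconv <- function(tp, x_id, w_id, b_id) {
  x <- tape_value(tp, x_id); w <- tape_value(tp, w_id); b <- tape_value(tp, b_id)
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  Cout <- ncol(w) %/% 4L
  y <- array(0, c(2 * H, 2 * W, Cout, N))
  for (n in seq_len(N)) {
    xm <- matrix(x[, , , n], H * W, C)
    for (o in 0:3) {
      yo <- xm %*% w[, o * Cout + seq_len(Cout), drop = FALSE]
      y[seq(1 + o %% 2, 2 * H, 2), seq(1 + o %/% 2, 2 * W, 2), , n] <-
        array(yo, c(H, W, Cout))
    }
  }
  y <- y + rep(rep(b, each = 4 * H * W), N)
  tape_node(tp, y, c(x_id, w_id, b_id), function(dy) {
    dx <- array(0, d); dw <- matrix(0, C, 4 * Cout)
    for (n in seq_len(N)) {
      xm <- matrix(x[, , , n], H * W, C)
      dxm <- matrix(0, H * W, C)
      for (o in 0:3) {
        dyo <- matrix(dy[seq(1 + o %% 2, 2 * H, 2),
                         seq(1 + o %/% 2, 2 * W, 2), , n], H * W, Cout)
        cols <- o * Cout + seq_len(Cout)
        dxm <- dxm + dyo %*% t(w[, cols, drop = FALSE])
        dw[, cols] <- dw[, cols] + t(xm) %*% dyo
      }
      dx[, , , n] <- array(dxm, c(H, W, C))
    }
    db <- apply(dy, 3, sum)
    list(dx, dw, db)
  })
}

# concatenate along the channel axis
op_concat <- function(tp, ids) {
  vals <- lapply(ids, tape_value, tp = tp)
  d1 <- dim(vals[[1]])
  chans <- vapply(vals, function(v) dim(v)[3], numeric(1))
  y <- array(0, c(d1[1], d1[2], sum(chans), d1[4]))
  at <- 0L
  for (v in vals) {
    y[, , at + seq_len(dim(v)[3]), ] <- v
    at <- at + dim(v)[3]
  }
  tape_node(tp, y, ids, function(dy) {
    out <- vector("list", length(ids)); at <- 0L
    for (j in seq_along(ids)) {
      out[[j]] <- dy[, , at + seq_len(chans[j]), , drop = FALSE]
      at <- at + chans[j]
    }
    out
  })
}

# 1x1 convolution (per-pixel linear map across channels)
op_conv1 <- function(tp, x_id, w_id, b_id) {
  x <- tape_value(tp, x_id); w <- tape_value(tp, w_id); b <- tape_value(tp, b_id)
  d <- dim(x); HW <- d[1] * d[2]; C <- d[3]; N <- d[4]; Cout <- ncol(w)
  y <- array(0, c(d[1], d[2], Cout, N))
  for (n in seq_len(N))
    y[, , , n] <- array(matrix(x[, , , n], HW, C) %*% w, c(d[1], d[2], Cout))
  y <- y + rep(rep(b, each = HW), N)
  tape_node(tp, y, c(x_id, w_id, b_id), function(dy) {
    dx <- array(0, d); dw <- matrix(0, C, Cout)
    for (n in seq_len(N)) {
      dyn <- matrix(dy[, , , n], HW, Cout)
      dx[, , , n] <- array(dyn %*% t(w), c(d[1], d[2], C))
      dw <- dw + t(matrix(x[, , , n], HW, C)) %*% dyn
    }
    list(dx, dw, apply(dy, 3, sum))
  })
}

# 2-class softmax + mean pixelwise cross-entropy against a 0/1 label array
# labels: (H, W, N) with 1 = brain (channel 2). Returns the loss node id.
op_softmax_ce <- function(tp, logits_id, labels) {
  z <- tape_value(tp, logits_id)
  d <- dim(z)
  hwn <- c(d[1], d[2], d[4])
  z1 <- array(z[, , 1, ], hwn); z2 <- array(z[, , 2, ], hwn)
  m <- pmax(z1, z2)
  e1 <- exp(z1 - m); e2 <- exp(z2 - m)
  p_brain <- e2 / (e1 + e2)
  npix <- length(labels)
  eps <- 1e-12
  loss <- -sum(labels * log(p_brain + eps) +
               (1 - labels) * log(1 - p_brain + eps)) / npix
  tape_node(tp, loss, logits_id, function(dy) {
    dz <- array(0, d)
    db <- (p_brain - labels) / npix * dy
    dz[, , 2, ] <- db
    dz[, , 1, ] <- -db
    list(dz)
  })
}

# forward-only softmax brain probability from logits; returns (H, W, N)
softmax_prob <- function(z) {
  d <- dim(z)
  hwn <- c(d[1], d[2], d[4])
  z1 <- array(z[, , 1, ], hwn); z2 <- array(z[, , 2, ], hwn)
  m <- pmax(z1, z2)
  e2 <- exp(z2 - m)
  e2 / (exp(z1 - m) + e2)
}
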