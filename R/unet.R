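#' Network architecture specification
#'
#' Describes one of the four 2D segmentation backbones:
#' \describe{
#'   \item{`single`}{a plain U-Net on one input image.}
#'   \item{`hybrid1`}{the two input images (clustered intensity and gradient
#'     map) are concatenated channel-wise at the input layer only; a single
#'     standard U-Net follows.}
#'   \item{`hybrid2`}{two independent encoders, one per input; their deepest
#'     features are concatenated and a single decoder upsamples, each skip
#'     connection taking both encoders' same-level features.}
#'   \item{`hybrid3`}{two complete encoder-decoder U-Nets, one per input,
#'     cross-connected: at every encoder and decoder level the two networks'
#'     same-level feature maps are concatenated (four maps meet at each
#'     decoder merge), and the two decoder outputs are concatenated before
#'     the final classification layer.}
#' }
#' Every variant ends in a 2-class softmax over brain / non-brain. The
#' backbone is the classic recipe: two 3x3 convolutions + ReLU per level,
#' 2x2 max pooling, transposed-convolution upsampling, channel width
#' doubling with depth.
#'
#' @param variant `"single"`, `"hybrid1"`, `"hybrid2"` or `"hybrid3"`.
#' @param depth number of encoder levels (>= 2), default 4.
#' @param base_channels channels at the first level (>= 4), default 16.
#' @return An object of class `"bx_network_spec"`.
#' @examples
#' network_spec("hybrid2")
#' @export
network_spec <- function(variant = c("single", "hybrid1", "hybrid2", "hybrid3"),
                         depth = 4L, base_channels = 16L) {
  variant <- match.arg(variant)
  depth <- as.integer(depth); base_channels <- as.integer(base_channels)
  if (depth < 2) bx_stop("depth must be >= 2", "value")
  if (base_channels < 4) bx_stop("base_channels must be >= 4", "value")
  structure(list(variant = variant, depth = depth,
                 base_channels = base_channels,
                 in_channels = if (variant == "single") 1L else 2L,
                 n_inputs = if (variant %in% c("single")) 1L else 2L),
            class = "bx_network_spec")
}

#' @export
print.bx_network_spec <- function(x, ...) {
  cat(sprintf("<bx_network_spec> %s, depth %d, base %d channels\n",
              x$variant, x$depth, x$base_channels))
  invisible(x)
}

# parameter shape table; names encode the op: *.w/*.b with prefixes
# e<l> encoder blocks, bott bottleneck, u<l> upconvs, d<l> decoder blocks,
# fin final 1x1; hybrid3 prefixes its two nets A./B.
# types: conv3 w = (9*Cin, Cout); upconv w = (Cin, 4*Cout); conv1 w = (Cin, Cout)
unet_param_shapes <- function(spec) {
  d <- spec$depth; b <- spec$base_channels
  cl <- b * 2^(seq_len(d) - 1)
  cb <- b * 2^d
  sh <- list()
  dbl <- function(prefix, cin, cout) {
    sh[[paste0(prefix, ".c1.w")]] <<- c(9 * cin, cout, 3)
    sh[[paste0(prefix, ".c1.b")]] <<- c(cout, 0, 0)
    sh[[paste0(prefix, ".c2.w")]] <<- c(9 * cout, cout, 3)
    sh[[paste0(prefix, ".c2.b")]] <<- c(cout, 0, 0)
  }
  upc <- function(prefix, cin, cout) {
    sh[[paste0(prefix, ".w")]] <<- c(cin, 4 * cout, 2)
    sh[[paste0(prefix, ".b")]] <<- c(cout, 0, 0)
  }
  fin <- function(prefix, cin, cout) {
    sh[[paste0(prefix, ".w")]] <<- c(cin, cout, 1)
    sh[[paste0(prefix, ".b")]] <<- c(cout, 0, 0)
  }
  v <- spec$variant
  if (v %in% c("single", "hybrid1")) {
    in1 <- if (v == "single") 1 else 2
    for (l in seq_len(d)) dbl(paste0("e", l), if (l == 1) in1 else cl[l - 1], cl[l])
    dbl("bott", cl[d], cb)
    for (l in d:1) {
      upc(paste0("u", l), if (l == d) cb else cl[l + 1], cl[l])
      dbl(paste0("d", l), 2 * cl[l], cl[l])
    }
    fin("fin", cl[1], 2)
  } else if (v == "hybrid2") {
    for (m in c("A", "B"))
      for (l in seq_len(d))
        dbl(paste0(m, ".e", l), if (l == 1) 1 else cl[l - 1], cl[l])
    dbl("bott", 2 * cl[d], cb)
    for (l in d:1) {
      upc(paste0("u", l), if (l == d) cb else cl[l + 1], cl[l])
      dbl(paste0("d", l), 3 * cl[l], cl[l])
    }
    fin("fin", cl[1], 2)
  } else { # hybrid3
    for (m in c("A", "B")) {
      for (l in seq_len(d))
        dbl(paste0(m, ".e", l), if (l == 1) 1 else 2 * cl[l - 1], cl[l])
      dbl(paste0(m, ".bott"), 2 * cl[d], cb)
      for (l in d:1) {
        upc(paste0(m, ".u", l), if (l == d) cb else cl[l + 1], cl[l])
        dbl(paste0(m, ".d", l), 4 * cl[l], cl[l])
      }
    }
    fin("fin", 2 * cl[1], 2)
  }
  sh
}

#' Build an untrained network
#'
#' Initializes all weights (He initialization, deterministic per seed) for
#' the requested architecture.
#'
#' @param spec a [network_spec()].
#' @param seed integer seed for weight initialization.
#' @return An object of class `"bx_unet"` holding `spec`, `params` and
#'   `seed`; train it with [unet_train()].
#' @export
build_network <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "bx_network_spec"))
  shapes <- unet_param_shapes(spec)
  params <- with_seed(seed, lapply(shapes, function(s) {
    if (s[2] == 0) return(numeric(s[1]))               # bias
    fan_in <- if (s[3] == 2) s[1] else s[1]            # rows = fan-in terms
    matrix(rnorm(s[1] * s[2], sd = sqrt(2 / fan_in)), s[1], s[2])
  }))
  structure(list(spec = spec, params = params, seed = as.integer(seed),
                 trained = FALSE, history = NULL), class = "bx_unet")
}

#' Number of trainable parameters
#'
#' @param net a `"bx_unet"` or a [network_spec()].
#' @return Integer count of trainable scalars.
#' @export
count_params <- function(net) {
  shapes <- if (inherits(net, "bx_unet")) unet_param_shapes(net$spec)
            else unet_param_shapes(net)
  sum(vapply(shapes, function(s) if (s[2] == 0) s[1] else s[1] * s[2], numeric(1)))
}

#' @export
print.bx_unet <- function(x, ...) {
  cat(sprintf("<bx_unet> %s (depth %d, base %d), %d parameters, %s\n",
              x$spec$variant, x$spec$depth, x$spec$base_channels,
              count_params(x),
              if (x$trained) sprintf("trained (%d epochs, final loss %.4g)",
                                     nrow(x$history), x$history$loss[nrow(x$history)])
              else "untrained"))
  invisible(x)
}

# ---- forward graph -----------------------------------------------------

# builds the variant's graph on tape `tp`; `P(name)` yields a parameter
# node id; `xs` is the list of input arrays (H, W, C, N); returns logits id
unet_forward <- function(tp, P, spec, xs) {
  conv <- function(x, nm) op_relu(tp, op_conv3(tp, x, P(paste0(nm, ".w")),
                                               P(paste0(nm, ".b"))))
  dblk <- function(x, nm) conv(conv(x, paste0(nm, ".c1")), paste0(nm, ".c2"))
  up <- function(x, nm) op_upconv(tp, x, P(paste0(nm, ".w")), P(paste0(nm, ".b")))
  fin <- function(x, nm) op_conv1(tp, x, P(paste0(nm, ".w")), P(paste0(nm, ".b")))
  d <- spec$depth
  v <- spec$variant
  if (v %in% c("single", "hybrid1")) {
    h <- op_input(tp, xs[[1]])
    skips <- vector("list", d)
    for (l in seq_len(d)) {
      s <- dblk(h, paste0("e", l)); skips[[l]] <- s; h <- op_pool(tp, s)
    }
    h <- dblk(h, "bott")
    for (l in d:1) {
      u <- up(h, paste0("u", l))
      h <- dblk(op_concat(tp, c(u, skips[[l]])), paste0("d", l))
    }
    fin(h, "fin")
  } else if (v == "hybrid2") {
    hs <- list(op_input(tp, xs[[1]]), op_input(tp, xs[[2]]))
    skips <- list(vector("list", d), vector("list", d))
    for (m in 1:2) {
      nm <- c("A", "B")[m]
      for (l in seq_len(d)) {
        s <- dblk(hs[[m]], paste0(nm, ".e", l))
        skips[[m]][[l]] <- s; hs[[m]] <- op_pool(tp, s)
      }
    }
    h <- dblk(op_concat(tp, c(hs[[1]], hs[[2]])), "bott")
    for (l in d:1) {
      u <- up(h, paste0("u", l))
      h <- dblk(op_concat(tp, c(u, skips[[1]][[l]], skips[[2]][[l]])),
                paste0("d", l))
    }
    fin(h, "fin")
  } else { # hybrid3: two cross-connected U-Nets
    hA <- op_input(tp, xs[[1]]); hB <- op_input(tp, xs[[2]])
    sA <- sB <- vector("list", d)
    pA <- pB <- NULL
    for (l in seq_len(d)) {
      inA <- if (l == 1) hA else op_concat(tp, c(pA, pB))
      inB <- if (l == 1) hB else op_concat(tp, c(pB, pA))
      a <- dblk(inA, paste0("A.e", l)); b2 <- dblk(inB, paste0("B.e", l))
      sA[[l]] <- a; sB[[l]] <- b2
      pA <- op_pool(tp, a); pB <- op_pool(tp, b2)
    }
    hA <- dblk(op_concat(tp, c(pA, pB)), "A.bott")
    hB <- dblk(op_concat(tp, c(pB, pA)), "B.bott")
    for (l in d:1) {
      uA <- up(hA, paste0("A.u", l)); uB <- up(hB, paste0("B.u", l))
      hA <- dblk(op_concat(tp, c(uA, uB, sA[[l]], sB[[l]])), paste0("A.d", l))
      hB <- dblk(op_concat(tp, c(uB, uA, sB[[l]], sA[[l]])), paste0("B.d", l))
    }
    fin(op_concat(tp, c(hA, hB)), "fin")
  }
}

# ---- batching and padding ----------------------------------------------

# reflecting index vector mapping 1..np onto 1..n (mirror boundary)
reflect_idx <- function(np, n) {
  if (n == 1) return(rep(1L, np))
  j <- (seq_len(np) - 1L) %% (2L * n - 2L)
  ifelse(j < n, j + 1L, 2L * n - 1L - j)
}

# stack a list of equally-shaped matrices into (Hp, Wp, 1, N), reflect-padded
# on the bottom/right up to a multiple of 2^depth
assemble_batch <- function(slices, depth) {
  h <- nrow(slices[[1]]); w <- ncol(slices[[1]])
  mult <- 2^depth
  hp <- mult * ceiling(h / mult); wp <- mult * ceiling(w / mult)
  ri <- reflect_idx(hp, h); ci <- reflect_idx(wp, w)
  arr <- array(0, c(hp, wp, 1, length(slices)))
  for (n in seq_along(slices)) arr[, , 1, n] <- slices[[n]][ri, ci]
  arr
}

# memoized parameter-leaf factory; also records name -> node id for
# gradient collection after a backward sweep
param_loader <- function(tp, params) {
  ids <- new.env(parent = emptyenv())
  f <- function(nm) {
    if (!exists(nm, envir = ids, inherits = FALSE)) {
      if (is.null(params[[nm]])) bx_stop(paste("unknown parameter", nm), "value")
      assign(nm, op_input(tp, params[[nm]]), envir = ids)
    }
    get(nm, envir = ids)
  }
  attr(f, "ids") <- ids
  f
}

# run one batched forward pass (no gradient use) and return probability
# maps cropped back to the original slice shape
forward_prob_batch <- function(net, slice_lists) {
  depth <- net$spec$depth
  xs <- lapply(slice_lists, assemble_batch, depth = depth)
  if (net$spec$variant == "hybrid1") {
    x <- array(0, c(dim(xs[[1]])[1:2], 2, dim(xs[[1]])[4]))
    x[, , 1, ] <- xs[[1]]; x[, , 2, ] <- xs[[2]]
    xs <- list(x)
  }
  tp <- tape_new()
  P <- param_loader(tp, net$params)
  logits <- unet_forward(tp, P, net$spec, xs)
  prob <- softmax_prob(tape_value(tp, logits))
  h <- nrow(slice_lists[[1]][[1]]); w <- ncol(slice_lists[[1]][[1]])
  lapply(seq_len(dim(prob)[3]), function(n) prob[seq_len(h), seq_len(w), n])
}

#' Predict brain-probability maps for a slice stack
#'
#' Runs the trained network over every slice and returns per-pixel brain
#' probabilities (the softmax output for the brain class). Slices whose
#' shape is not a multiple of `2^depth` are reflect-padded internally and
#' the output cropped back, so output shapes always equal input shapes.
#'
#' @param net a trained `"bx_unet"`.
#' @param inputs a single `"bx_slice_stack"` (variant `single`) or a list of
#'   two aligned stacks (hybrid variants): clustered intensity first,
#'   gradient map second.
#' @param batch_size slices per forward batch.
#' @return A `"bx_slice_stack"` of probability matrices in `[0, 1]`.
#' @export
predict_stack <- function(net, inputs, batch_size = 16L) {
  stopifnot(inherits(net, "bx_unet"))
  if (inherits(inputs, "bx_slice_stack")) inputs <- list(inputs)
  n_in <- if (net$spec$variant == "single") 1L else 2L
  if (length(inputs) != n_in)
    bx_stop(sprintf("variant %s needs %d input stack(s), got %d",
                    net$spec$variant, n_in, length(inputs)), "value")
  ns <- length(inputs[[1]]$slices)
  if (n_in == 2 && length(inputs[[2]]$slices) != ns)
    bx_stop("input stacks are not aligned slice-for-slice", "shape")
  out <- vector("list", ns)
  for (start in seq(1, ns, by = batch_size)) {
    idx <- start:min(ns, start + batch_size - 1)
    sl <- lapply(inputs, function(s) s$slices[idx])
    out[idx] <- forward_prob_batch(net, sl)
  }
  structure(list(slices = out, plane = inputs[[1]]$plane,
                 source_shape = inputs[[1]]$source_shape),
            class = "bx_slice_stack")
}
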