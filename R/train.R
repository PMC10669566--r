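#' Training configuration
#'
#' The optimizer is Adam with a learning rate of 1e-3 and the loss is
#' pixelwise cross-entropy; both are the package defaults for every
#' variant. Epochs and batch size are problem-scale choices logged with
#' every run.
#'
#' @param learning_rate Adam step size (> 0), default `1e-3`.
#' @param epochs number of passes over the training slices (>= 1).
#' @param batch_size slices per gradient step.
#' @param seed integer seed controlling weight initialization order-of-use,
#'   shuffling, and hence the entire run.
#' @return An object of class `"bx_train_config"`.
#' @export
train_config <- function(learning_rate = 1e-3, epochs = 50L, batch_size = 16L,
                         seed = 1L) {
  if (!is.numeric(learning_rate) || learning_rate <= 0)
    bx_stop("learning_rate must be > 0", "value")
  epochs <- as.integer(epochs)
  if (epochs < 1) bx_stop("epochs must be >= 1", "value")
  structure(list(optimizer = "adam", loss = "cross-entropy",
                 learning_rate = learning_rate, epochs = epochs,
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "bx_train_config")
}

#' Concatenate slice stacks from several subjects
#'
#' @param ... `"bx_slice_stack"` objects sharing one plane tag.
#' @return A single `"bx_slice_stack"` (source_shape taken from the first).
#' @export
c_stacks <- function(...) {
  stacks <- list(...)
  if (length(stacks) == 1 && !inherits(stacks[[1]], "bx_slice_stack"))
    stacks <- stacks[[1]]
  planes <- unique(vapply(stacks, `[[`, character(1), "plane"))
  if (length(planes) != 1) bx_stop("stacks mix planes", "value")
  structure(list(slices = do.call(c, lapply(stacks, `[[`, "slices")),
                 plane = planes, source_shape = stacks[[1]]$source_shape),
            class = "bx_slice_stack")
}

# labels to padded (Hp, Wp, N) array matching assemble_batch's padding
assemble_labels <- function(slices, depth) {
  h <- nrow(slices[[1]]); w <- ncol(slices[[1]])
  mult <- 2^depth
  hp <- mult * ceiling(h / mult); wp <- mult * ceiling(w / mult)
  ri <- reflect_idx(hp, h); ci <- reflect_idx(wp, w)
  arr <- array(0, c(hp, wp, length(slices)))
  for (n in seq_along(slices)) arr[, , n] <- slices[[n]][ri, ci]
  arr
}

#' Train a segmentation network
#'
#' Minimizes mean pixelwise cross-entropy with Adam over shuffled
#' mini-batches of slices. Training is deterministic for a fixed
#' `config$seed` (on one machine/BLAS configuration): the seed fixes
#' shuffling, and the network's own seed fixed its initialization. The
#' returned network carries the weights of the epoch with the lowest
#' training loss and a per-epoch loss history.
#'
#' @param net an untrained (or previously trained) `"bx_unet"`.
#' @param inputs a `"bx_slice_stack"`, or a list of two aligned stacks for
#'   hybrid variants (clustered intensity first, gradient second).
#' @param labels a `"bx_slice_stack"` of 0/1 mask slices aligned with
#'   `inputs`.
#' @param config a [train_config()].
#' @return The trained `"bx_unet"`, with `history` (data.frame of epoch,
#'   loss) and `best_epoch`.
#' @export
unet_train <- function(net, inputs, labels, config = train_config()) {
  stopifnot(inherits(net, "bx_unet"), inherits(config, "bx_train_config"))
  if (inherits(inputs, "bx_slice_stack")) inputs <- list(inputs)
  n_in <- if (net$spec$variant == "single") 1L else 2L
  if (length(inputs) != n_in)
    bx_stop(sprintf("variant %s needs %d input stack(s), got %d",
                    net$spec$variant, n_in, length(inputs)), "value")
  xsl <- lapply(inputs, `[[`, "slices")
  ysl <- labels$slices
  ns <- length(ysl)
  if (any(vapply(xsl, length, integer(1)) != ns))
    bx_stop("input and label stacks have different slice counts", "shape")

  depth <- net$spec$depth
  # deep copies: the Adam step updates these buffers in place
  params <- lapply(net$params, function(p) p + 0)
  adam_m <- lapply(params, function(p) p * 0)
  adam_v <- lapply(params, function(p) p * 0)
  tstep <- 0L
  lr <- config$learning_rate; b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  history <- data.frame(epoch = integer(0), loss = numeric(0))
  best <- list(loss = Inf, params = params, epoch = 0L)

  with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(ns)
      ep_loss <- 0
      for (start in seq(1, ns, by = config$batch_size)) {
        idx <- ord[start:min(ns, start + config$batch_size - 1)]
        xs <- lapply(xsl, function(sl) assemble_batch(sl[idx], depth))
        if (net$spec$variant == "hybrid1") {
          x <- array(0, c(dim(xs[[1]])[1:2], 2, length(idx)))
          x[, , 1, ] <- xs[[1]]; x[, , 2, ] <- xs[[2]]
          xs <- list(x)
        }
        y <- assemble_labels(ysl[idx], depth)
        tp <- tape_new()
        P <- param_loader(tp, params)
        loss_id <- op_softmax_ce(tp, unet_forward(tp, P, net$spec, xs), y)
        grads <- tape_backward(tp, loss_id)
        ids <- attr(P, "ids")
        tstep <- tstep + 1L
        corr <- sqrt(1 - b2^tstep) / (1 - b1^tstep)
        for (nm in ls(ids)) {
          g <- grads[[get(nm, envir = ids)]]
          if (is.null(g)) next
          cpp_adam_step(params[[nm]], adam_m[[nm]], adam_v[[nm]], g,
                        lr, b1, b2, eps, corr)
        }
        ep_loss <- ep_loss + tape_value(tp, loss_id) * length(idx)
      }
      ep_loss <- ep_loss / ns
      history <- rbind(history, data.frame(epoch = ep, loss = ep_loss))
      if (ep_loss < best$loss)
        best <- list(loss = ep_loss,
                     params = lapply(params, function(p) p + 0), epoch = ep)
    }
  })
  net$params <- best$params
  net$trained <- TRUE
  net$history <- history
  net$best_epoch <- best$epoch
  net$config <- config
  net
}
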