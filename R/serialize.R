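#' Save / load a fitted brain-extraction model
#'
#' The model (all network weights, configuration and manifest) is written
#' as an RDS file, with a JSON sidecar (`<path>.json`) recording the
#' architecture, training configuration, seeds and per-plane loss history
#' so a run can be audited without deserializing the weights.
#'
#' @param model a `"bx_brain_unet"` from [brain_unet()].
#' @param path output path for the RDS file (sidecar gets `.json` added).
#' @return Invisibly, `path`.
#' @export
save_brain_unet <- function(model, path) {
  stopifnot(inherits(model, "bx_brain_unet"))
  saveRDS(model, path)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    side <- list(
      variant = model$config$variant,
      depth = model$config$network$depth,
      base_channels = model$config$network$base_channels,
      planes = model$config$planes,
      preprocess = model$config$preprocess,
      train = model$config$train[c("optimizer", "loss", "learning_rate",
                                   "epochs", "batch_size", "seed")],
      manifest = model$manifest,
      history = lapply(model$nets, function(n) n$history))
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' @rdname save_brain_unet
#' @export
load_brain_unet <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "bx_brain_unet"))
    bx_stop("file does not contain a brain extraction model", "value")
  model
}
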