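#' End-to-end pipeline configuration
#'
#' Bundles every choice of the brain-extraction pipeline: whether K-means
#' preprocessing is applied, which network variant consumes which inputs,
#' which planes are segmented and fused, the network size and the training
#' protocol. Disabling preprocessing and choosing variant `"single"`
#' reduces the pipeline exactly to a plain per-plane U-Net plus fusion.
#'
#' @param preprocess apply per-volume K-means amplitude compression
#'   (default TRUE).
#' @param variant network wiring; see [network_spec()].
#' @param planes character subset of sagittal/coronal/transverse (>= 1).
#' @param depth,base_channels network size; see [network_spec()].
#' @param train a [train_config()].
#' @param kmeans_k clusters for preprocessing (default 6).
#' @param kmeans_seed seed for each per-volume K-means fit.
#' @param gradient_source `"preprocessed"` (default: gradients of the
#'   cluster-remapped image) or `"raw"`.
#' @param gradient_operator `"sobel"` or `"central"`.
#' @param threshold fusion/binarization threshold.
#' @param slice_stride train on every `slice_stride`-th slice (default 1 =
#'   all slices); prediction always uses every slice.
#' @return An object of class `"bx_pipeline_config"`.
#' @export
pipeline_config <- function(preprocess = TRUE,
                            variant = c("hybrid2", "single", "hybrid1", "hybrid3"),
                            planes = c("sagittal", "coronal", "transverse"),
                            depth = 4L, base_channels = 16L,
                            train = train_config(),
                            kmeans_k = 6L, kmeans_seed = 1L,
                            gradient_source = c("preprocessed", "raw"),
                            gradient_operator = c("sobel", "central"),
                            threshold = 0.5, slice_stride = 1L) {
  variant <- match.arg(variant)
  gradient_source <- match.arg(gradient_source)
  gradient_operator <- match.arg(gradient_operator)
  planes <- unique(planes)
  vapply(planes, plane_axis, integer(1))
  if (length(planes) < 1) bx_stop("select at least one plane", "config")
  stopifnot(inherits(train, "bx_train_config"))
  structure(list(preprocess = preprocess, variant = variant, planes = planes,
                 network = network_spec(variant, depth, base_channels),
                 train = train, kmeans_k = as.integer(kmeans_k),
                 kmeans_seed = as.integer(kmeans_seed),
                 gradient_source = gradient_source,
                 gradient_operator = gradient_operator,
                 threshold = threshold, slice_stride = as.integer(slice_stride)),
            class = "bx_pipeline_config")
}

# accept a bx_phantom or list(volume=, mask=) and normalize to the latter
as_subject <- function(s) {
  if (inherits(s, "bx_phantom")) return(list(volume = s$volume, mask = s$brain_mask))
  if (is.list(s) && inherits(s$volume, "bx_volume")) return(s)
  bx_stop("subjects must be bx_phantom or list(volume=, mask=)", "config")
}

# preprocessing + input-channel construction for one volume.
# Returns the intensity channel (scaled to [0,1]) and a closure giving the
# per-plane gradient channel.
prepare_inputs <- function(v, config) {
  vsrc <- v
  if (config$preprocess) {
    cm <- fit_kmeans(v, k = config$kmeans_k, seed = config$kmeans_seed)
    vsrc <- apply_cluster_remap(v, cm)
  }
  gsrc <- if (config$gradient_source == "preprocessed") vsrc else v
  int <- vsrc$data
  rng <- range(int)
  int <- if (rng[2] > rng[1]) (int - rng[1]) / (rng[2] - rng[1]) else int * 0
  list(intensity = int,
       gradient = function(plane)
         gradient_map(gsrc, plane, config$gradient_operator)$data)
}

#' Fit the multi-view brain-extraction model
#'
#' Trains one 2D network per selected plane. For every subject the volume
#' is (optionally) K-means-compressed and min-max scaled; hybrid variants
#' additionally receive the per-slice gradient-magnitude map. Each plane's
#' slice stacks from all subjects are concatenated and a network of the
#' configured variant is trained on them. Seeds are derived from
#' `config$train$seed` per plane, and everything needed to reproduce the
#' run is kept in the returned manifest.
#'
#' @param subjects list of training subjects: `"bx_phantom"` objects or
#'   `list(volume = bx_volume, mask = bx_mask)` pairs.
#' @param config a [pipeline_config()].
#' @return An object of class `"bx_brain_unet"` with elements `nets` (one
#'   trained [build_network()] per plane), `config` and `manifest`. Use
#'   [predict.bx_brain_unet()] on new volumes.
#' @export
brain_unet <- function(subjects, config = pipeline_config()) {
  stopifnot(inherits(config, "bx_pipeline_config"))
  if (length(subjects) < 1) bx_stop("need at least one subject", "config")
  subjects <- lapply(subjects, as_subject)
  for (s in subjects) check_same_shape(s$volume$data, s$mask$data,
                                       "volume and mask")
  prepped <- lapply(subjects, function(s) prepare_inputs(s$volume, config))
  hybrid <- config$variant != "single"
  nets <- list()
  for (pi in seq_along(config$planes)) {
    plane <- config$planes[pi]
    x1 <- list(); x2 <- list(); yl <- list()
    for (si in seq_along(subjects)) {
      st1 <- extract_slices(prepped[[si]]$intensity, plane)
      sty <- extract_slices(subjects[[si]]$mask, plane)
      keep <- seq(1, length(st1$slices), by = config$slice_stride)
      x1 <- c(x1, st1$slices[keep])
      yl <- c(yl, sty$slices[keep])
      if (hybrid) {
        st2 <- extract_slices(prepped[[si]]$gradient(plane), plane)
        x2 <- c(x2, st2$slices[keep])
      }
    }
    mk <- function(sl) structure(list(slices = sl, plane = plane,
                                      source_shape = dim(subjects[[1]]$mask$data)),
                                 class = "bx_slice_stack")
    net <- build_network(config$network, seed = config$train$seed + 101L * pi)
    cfg <- config$train
    cfg$seed <- cfg$seed + 17L * pi
    inputs <- if (hybrid) list(mk(x1), mk(x2)) else mk(x1)
    nets[[plane]] <- unet_train(net, inputs, mk(yl), cfg)
  }
  structure(list(nets = nets, config = config,
                 manifest = list(
                   n_subjects = length(subjects),
                   planes = config$planes, variant = config$variant,
                   base_seed = config$train$seed,
                   plane_seeds = stats::setNames(
                     config$train$seed + 17L * seq_along(config$planes),
                     config$planes),
                   init_seeds = stats::setNames(
                     config$train$seed + 101L * seq_along(config$planes),
                     config$planes),
                   package_version = as.character(utils::packageVersion("brainext")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))),
            class = "bx_brain_unet")
}

#' Predict a brain mask for a new volume
#'
#' Applies the fitted per-plane networks to a new volume: preprocessing is
#' re-fitted per volume (fresh K-means, as at training time), each plane's
#' slices are segmented, the per-plane probability stacks are reassembled
#' into 3D, and the planes are fused with brain-fraction weights
#' ([fuse_planes()]; with one plane, fusion is the identity). If a
#' reference mask is supplied the result carries an [evaluate()] report.
#'
#' @param object a `"bx_brain_unet"` model.
#' @param newdata a [bx_volume()] or `"bx_phantom"`.
#' @param reference optional reference [bx_mask()] (taken from the phantom
#'   automatically if `newdata` is one and `reference` is missing).
#' @param ... unused.
#' @return An object of class `"bx_prediction"`: `fused` (a
#'   `"bx_fused"`), `planes` (per-plane `"bx_plane_prediction"`s) and
#'   `report` (a `"bx_eval"` or NULL).
#' @export
predict.bx_brain_unet <- function(object, newdata, reference = NULL, ...) {
  if (inherits(newdata, "bx_phantom")) {
    if (is.null(reference)) reference <- newdata$brain_mask
    newdata <- newdata$volume
  }
  stopifnot(inherits(newdata, "bx_volume"))
  config <- object$config
  prep <- prepare_inputs(newdata, config)
  hybrid <- config$variant != "single"
  preds <- list()
  for (plane in config$planes) {
    if (is.null(object$nets[[plane]]))
      bx_stop(sprintf("no trained network for plane %s", plane), "config")
    st1 <- extract_slices(prep$intensity, plane)
    inputs <- if (hybrid)
      list(st1, extract_slices(prep$gradient(plane), plane)) else st1
    pstack <- predict_stack(object$nets[[plane]], inputs)
    preds[[plane]] <- plane_prediction(pmin(pmax(restack(pstack), 0), 1),
                                       plane, config$threshold)
  }
  fused <- fuse_planes(unname(preds), threshold = config$threshold)
  report <- if (!is.null(reference)) evaluate(fused$mask, reference) else NULL
  structure(list(fused = fused, planes = preds, report = report),
            class = "bx_prediction")
}

#' @export
print.bx_prediction <- function(x, ...) {
  print(x$fused)
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}

#' @export
print.bx_brain_unet <- function(x, ...) {
  cat(sprintf("<bx_brain_unet> %s, %s preprocessing, planes: %s\n",
              x$config$variant, if (x$config$preprocess) "K-means" else "no",
              paste(x$config$planes, collapse = ", ")))
  cat(sprintf("  trained on %d subject(s); seeds %s\n", x$manifest$n_subjects,
              paste(x$manifest$plane_seeds, collapse = "/")))
  invisible(x)
}

#' @export
summary.bx_brain_unet <- function(object, ...) {
  cat(sprintf("Multi-view brain extraction model (%s)\n", object$config$variant))
  print(object$config$network)
  for (plane in names(object$nets)) {
    h <- object$nets[[plane]]$history
    cat(sprintf("  %-10s final loss %.5f (best epoch %d of %d)\n", plane,
                h$loss[nrow(h)], object$nets[[plane]]$best_epoch, nrow(h)))
  }
  invisible(object)
}

#' @export
plot.bx_brain_unet <- function(x, ...) {
  hs <- lapply(x$nets, function(n) n$history$loss)
  ep <- seq_len(max(lengths(hs)))
  graphics::matplot(ep, do.call(cbind, hs), type = "l", lty = 1,
                    xlab = "epoch", ylab = "training loss", ...)
  graphics::legend("topright", legend = names(hs), lty = 1,
                   col = seq_along(hs), bty = "n")
  invisible(x)
}

#' Subject-level k-fold cross-validation of the pipeline
#'
#' Splits subjects into folds with [crossval_folds()], trains on the
#' training portion and evaluates each held-out subject. By default each
#' iteration trains on k-1 folds and tests on the remaining one;
#' `invert = TRUE` trains on a single fold and tests on the rest.
#'
#' @param subjects list of subjects as in [brain_unet()].
#' @param config a [pipeline_config()].
#' @param k number of folds.
#' @param seed seed for the fold shuffle.
#' @param invert train on one fold instead of k-1.
#' @return List with `results` (data.frame: subject, fold, dice,
#'   sensitivity, specificity) and `folds`.
#' @export
run_crossval <- function(subjects, config = pipeline_config(), k = 5L,
                         seed = 1L, invert = FALSE) {
  folds <- crossval_folds(length(subjects), k, seed)
  rows <- list()
  for (fi in seq_along(folds)) {
    test_idx <- if (invert) setdiff(seq_along(subjects), folds[[fi]]) else folds[[fi]]
    train_idx <- setdiff(seq_along(subjects), test_idx)
    model <- brain_unet(subjects[train_idx], config)
    for (ti in test_idx) {
      s <- as_subject(subjects[[ti]])
      pr <- predict(model, s$volume, reference = s$mask)
      rows[[length(rows) + 1L]] <-
        data.frame(subject = ti, fold = fi, dice = pr$report$dice,
                   sensitivity = pr$report$sensitivity,
                   specificity = pr$report$specificity)
    }
  }
  list(results = do.call(rbind, rows), folds = folds)
}
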