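#' Configuration of a segmentation model
#'
#' @param scheme Target [class_scheme] (tissue or artifact).
#' @param mpp Resolution the model is trained/run at (microns per pixel).
#' @param patch_size Input side length in pixels; must be a multiple of 32.
#' @param encoder_width `"compact"` (width 8; trains on a CPU in minutes) or
#'   `"paper"` (width 32; for users with real data and time).
#' @param epochs Training epochs (>= 0).
#' @param learning_rate Adam learning rate.
#' @param batch_size Patches per optimizer step.
#' @param seed Integer seed controlling init, shuffling and augmentation.
#' @param loss_weights Optional per-class weights for the cross-entropy term.
#' @param dice_weight Weight of the soft-Dice term added to cross-entropy.
#' @param augment Random flips/rotations during training.
#' @return An object of class `qc_model_config`.
#' @export
model_config <- function(scheme, mpp, patch_size = 64,
                         encoder_width = c("compact", "paper"),
                         epochs = 20, learning_rate = 2e-3, batch_size = 8,
                         seed = 1L, loss_weights = NULL, dice_weight = 1,
                         augment = TRUE) {
  encoder_width <- match.arg(encoder_width)
  stop_if_not(inherits(scheme, "qc_scheme"), "scheme must be a qc_scheme")
  stop_if_not(is_count(patch_size) && patch_size %% 32 == 0,
              "patch_size must be a positive multiple of 32",
              class = "slideqc_config_error")
  stop_if_not(is.numeric(epochs) && epochs >= 0, "epochs must be >= 0")
  if (is.null(loss_weights)) loss_weights <- rep(1, n_classes(scheme))
  stop_if_not(length(loss_weights) == n_classes(scheme),
              "need one loss weight per class")
  structure(list(scheme = scheme, mpp = as.numeric(mpp),
                 patch_size = as.integer(patch_size),
                 encoder_width = encoder_width, epochs = as.integer(epochs),
                 learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 seed = as.integer(seed), loss_weights = as.numeric(loss_weights),
                 dice_weight = as.numeric(dice_weight), augment = isTRUE(augment)),
            class = "qc_model_config")
}

width_of <- function(config) switch(config$encoder_width, compact = 8L, paper = 32L)

#' Build an untrained segmentation model bundle
#'
#' Initialises the encoder-decoder weights (He-normal, seeded) for the
#' configured scheme and width. The forward pass yields per-pixel class
#' probabilities that sum to one.
#'
#' @param config A [model_config].
#' @return An object of class `qc_model_bundle` with fields `weights`,
#'   `config`, `normalization` (filled in at training time) and `history`.
#' @export
build_model <- function(config) {
  stop_if_not(inherits(config, "qc_model_config"), "config must be a model_config")
  wb <- cpp_unet_init(width_of(config), n_classes(config$scheme), config$seed)
  structure(list(weights = list(W = wb$W, b = wb$b), config = config,
                 normalization = NULL, history = NULL),
            class = "qc_model_bundle")
}

#' @export
print.qc_model_bundle <- function(x, ...) {
  cat(sprintf("<qc_model_bundle> %s scheme (%d classes), MPP %.4g, patch %d px, %s width\n",
              x$config$scheme$kind, n_classes(x$config$scheme), x$config$mpp,
              x$config$patch_size, x$config$encoder_width))
  if (is.null(x$history)) cat("  untrained\n")
  else cat(sprintf("  trained %d epoch(s); final train loss %.4f, val Dice %.4f\n",
                   nrow(x$history), utils::tail(x$history[, "train_loss"], 1),
                   utils::tail(x$history[, "val_dice"], 1)))
  invisible(x)
}

# dataset (list of qc_labeled_slide) -> list(X = normalized arrays, Y = labels)
.prep_dataset <- function(dataset, config, normalization) {
  stop_if_not(length(dataset) >= 1, "empty dataset", class = "slideqc_data_error")
  for (d in dataset) {
    stop_if_not(inherits(d, "qc_labeled_slide"), "dataset entries must be qc_labeled_slide")
    stop_if_not(same_scheme(d$gt$scheme, config$scheme),
                "dataset scheme does not match the model's scheme",
                class = "slideqc_scheme_error")
    stop_if_not(all(dim(d$gt$labels) == config$patch_size),
                "dataset patch size does not match the model's patch size",
                class = "slideqc_shape_error")
  }
  X <- lapply(dataset, function(d) {
    px <- d$image$pixels
    for (ch in 1:3) px[, , ch] <- (px[, , ch] - normalization$mean[ch]) / normalization$sd[ch]
    px
  })
  Y <- lapply(dataset, function(d) d$gt$labels)
  list(X = X, Y = Y)
}

#' Train a segmentation model
#'
#' Optimises class-weighted cross-entropy plus soft Dice with Adam. The
#' per-channel normalization (mean/sd of the training images) is computed
#' here and stored in the bundle. Single-threaded runs with the same seeds
#' and data are exactly reproducible. `epochs = 0` returns the input bundle
#' unchanged.
#'
#' @param bundle A `qc_model_bundle` from [build_model].
#' @param train_set,val_set Lists of `qc_labeled_slide` whose ground truth
#'   uses the bundle's scheme and patch size (see [as_labeled_scheme]).
#' @param config Optional [model_config] overriding the bundle's.
#' @return The trained `qc_model_bundle` with per-epoch `history`
#'   (`train_loss`, `val_dice`).
#' @export
train_model <- function(bundle, train_set, val_set = list(), config = bundle$config) {
  stop_if_not(inherits(bundle, "qc_model_bundle"), "bundle must be a qc_model_bundle")
  if (config$epochs == 0L) return(bundle)
  norm <- bundle$normalization
  if (is.null(norm)) {
    stop_if_not(length(train_set) >= 1, "empty training set", class = "slideqc_data_error")
    px_means <- vapply(train_set, function(d) apply(d$image$pixels, 3, mean), numeric(3))
    px_sqm <- vapply(train_set, function(d) apply(d$image$pixels^2, 3, mean), numeric(3))
    m <- rowMeans(px_means)
    s <- sqrt(pmax(rowMeans(px_sqm) - m^2, 1e-8))
    norm <- list(mean = m, sd = s)
  }
  tr <- .prep_dataset(train_set, config, norm)
  va <- if (length(val_set)) .prep_dataset(val_set, config, norm) else list(X = list(), Y = list())
  fit <- cpp_unet_train(bundle$weights$W, bundle$weights$b, tr$X, tr$Y, va$X, va$Y,
                        config$epochs, config$learning_rate, config$batch_size,
                        config$seed, config$loss_weights, config$dice_weight,
                        config$augment)
  bundle$weights <- list(W = fit$W, b = fit$b)
  bundle$normalization <- norm
  bundle$history <- rbind(bundle$history, fit$history)
  bundle$config <- config
  bundle
}

#' Predict label masks for image patches
#'
#' Deterministic inference: per-pixel class probabilities plus their argmax
#' (ties resolved to the lower class index). Batched and single-patch calls
#' agree exactly.
#'
#' @param object A trained `qc_model_bundle`.
#' @param patches A [qc_raster] or list of them, each of the configured patch
#'   size and within 10\% of the configured MPP.
#' @param ... Unused.
#' @return A list per patch: `mask` (a `qc_mask`) and `prob`
#'   (`h x w x K` probability array). A single raster input returns the
#'   single result unwrapped.
#' @export
predict.qc_model_bundle <- function(object, patches, ...) {
  single <- inherits(patches, "qc_raster")
  if (single) patches <- list(patches)
  norm <- object$normalization %||% list(mean = c(0, 0, 0), sd = c(1, 1, 1))
  cfg <- object$config
  out <- lapply(patches, function(p) {
    stop_if_not(inherits(p, "qc_raster"), "patches must be qc_raster")
    stop_if_not(all(dim(p$pixels)[1:2] == cfg$patch_size),
                "patch dims do not match the model's patch size",
                class = "slideqc_shape_error")
    stop_if_not(abs(p$mpp - cfg$mpp) <= 0.1 * cfg$mpp + 1e-9,
                "patch MPP differs from the model's by more than 10%")
    px <- p$pixels
    for (ch in 1:3) px[, , ch] <- (px[, , ch] - norm$mean[ch]) / norm$sd[ch]
    prob <- cpp_unet_forward(object$weights$W, object$weights$b, px)
    k <- dim(prob)[3]
    lab <- max.col(matrix(prob, ncol = k), ties.method = "first") - 1L
    list(mask = label_mask(matrix(as.integer(lab), nrow(p$pixels)), p$mpp, cfg$scheme),
         prob = prob)
  })
  if (single) out[[1]] else out
}

#' Re-express labeled slides in another scheme
#'
#' Converts the ground truth of a labeled slide (or list of them) to the
#' tissue scheme; used to derive tissue-model training data from
#' artifact-scheme synthetic slides.
#'
#' @param dataset A `qc_labeled_slide` or list of them.
#' @return Same shape as the input, ground truth in the tissue scheme.
#' @export
as_labeled_scheme <- function(dataset) {
  conv <- function(d) { d$gt <- as_tissue_mask(d$gt); d }
  if (inherits(dataset, "qc_labeled_slide")) conv(dataset) else lapply(dataset, conv)
}

#' Save / load a model bundle
#'
#' Weights go to an RDS blob; the configuration and normalization are
#' mirrored in a human-readable JSON sidecar `<path>.json`.
#'
#' @param bundle A `qc_model_bundle`.
#' @param path Destination file.
#' @return `path` (save) or the restored bundle (load).
#' @export
save_model_bundle <- function(bundle, path) {
  stop_if_not(inherits(bundle, "qc_model_bundle"), "bundle must be a qc_model_bundle")
  saveRDS(bundle, path)
  cfg <- bundle$config
  jsonlite::write_json(list(
    scheme = cfg$scheme$names, kind = cfg$scheme$kind, mpp = cfg$mpp,
    patch_size = cfg$patch_size, encoder_width = cfg$encoder_width,
    normalization = bundle$normalization), paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model_bundle
#' @export
load_model_bundle <- function(path) {
  b <- readRDS(path)
  stop_if_not(inherits(b, "qc_model_bundle"), "file does not contain a model bundle")
  b
}
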