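# Shared fixtures: small random masks/rasters and lazily trained models.
# Training happens at most once per test run; the trained bundles and their
# datasets are reused by the segmentation, pipeline and acceptance tests.

.fixtures <- new.env(parent = emptyenv())

random_mask <- function(h, w, k = 7, mpp = 1, seed = 1,
                        scheme = artifact_scheme()) {
  set.seed(seed)
  label_mask(matrix(sample.int(k, h * w, replace = TRUE) - 1L, h, w), mpp, scheme)
}

flat_raster <- function(h, w, rgb = c(1, 1, 1), mpp = 1) {
  qc_raster(array(rep(rgb, each = h * w), c(h, w, 3)), mpp)
}

# four flat-colour classes; linearly separable per pixel
toy_scheme <- function() {
  class_scheme(c("background", "a", "b", "c"),
               c("#FFFFFF", "#CC6699", "#1A8033", "#3333BB"), "artifact")
}

toy_patch <- function(seed) {
  set.seed(seed)
  lab <- matrix(sample(0:3, 4, TRUE), 2, 2)[rep(1:2, each = 16), rep(1:2, each = 16)]
  cols <- rbind(c(1, 1, 1), c(0.8, 0.4, 0.6), c(0.1, 0.5, 0.2), c(0.2, 0.2, 0.7))
  px <- array(0, c(32, 32, 3))
  for (ch in 1:3) px[, , ch] <- matrix(cols[lab + 1, ch], 32, 32) +
      stats::rnorm(1024, sd = 0.02)
  structure(list(image = qc_raster(pmin(pmax(px, 0), 1), 1),
                 gt = label_mask(lab, 1, toy_scheme())),
            class = "qc_labeled_slide")
}

toy_model <- function() {
  if (is.null(.fixtures$toy)) {
    ds <- lapply(1:24, toy_patch)
    cfg <- model_config(toy_scheme(), mpp = 1, patch_size = 32, epochs = 5,
                        learning_rate = 0.01, batch_size = 2, seed = 1)
    .fixtures$toy <- list(bundle = train_model(build_model(cfg), ds[1:20], ds[21:24]),
                          train = ds[1:20], val = ds[21:24])
  }
  .fixtures$toy
}

# desk-scale study fixtures: ~300 synthetic patches, compact models
tissue_fixture <- function() {
  if (is.null(.fixtures$tissue)) {
    ds <- as_labeled_scheme(gen_dataset(110, patch_size = 64, mpp = 10, seed = 11,
                                        with_artifacts = FALSE))
    cfg <- model_config(tissue_scheme(), mpp = 10, patch_size = 64, epochs = 6,
                        learning_rate = 0.01, batch_size = 2, seed = 1)
    .fixtures$tissue <- list(bundle = train_model(build_model(cfg), ds[1:90], ds[91:110]),
                             train = ds[1:90], val = ds[91:110])
  }
  .fixtures$tissue
}

artifact_fixture <- function() {
  if (is.null(.fixtures$artifact)) {
    ds <- gen_dataset(190, patch_size = 64, mpp = 2.0, seed = 7)
    cfg <- model_config(artifact_scheme(), mpp = 2.0, patch_size = 64,
                        epochs = 10, learning_rate = 0.01, batch_size = 2,
                        seed = 1, loss_weights = c(1, 1, 3, 3, 2, 2, 1))
    .fixtures$artifact <- list(bundle = train_model(build_model(cfg), ds[1:150], ds[151:190]),
                               train = ds[1:150], val = ds[151:190])
  }
  .fixtures$artifact
}

# one synthetic demo slide with known artifacts, used by pipeline tests
demo_slide <- function() {
  if (is.null(.fixtures$slide)) {
    spec <- slide_spec(
      size = c(512, 512), mpp = 2.0, tissue_frac = 0.65,
      artifacts = list(
        artifact_spec("fold", c(150, 150), 60, angle = 0.6, seed = 5),
        artifact_spec("pen_marking", c(380, 120), 80, angle = 2.1, seed = 6)),
      oof = oof_spec(seed = 9), seed = 42)
    labeled <- compose_synthetic_slide(spec)
    .fixtures$slide <- list(labeled = labeled,
                            pyramid = build_pyramid(labeled$image, c(1, 2, 4)))
  }
  .fixtures$slide
}
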