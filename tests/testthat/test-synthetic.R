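# Synthetic slide simulator: texture, artifact injection, synthetic OOF.

test_that("tissue texture is seed-reproducible with calibrated coverage", {
  a <- gen_tissue_texture(c(96, 96), mpp = 1, tissue_frac = 0.6, seed = 3)
  b <- gen_tissue_texture(c(96, 96), mpp = 1, tissue_frac = 0.6, seed = 3)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$gt$labels, b$gt$labels)
  # coverage within 0.6 +/- 0.1 and labels limited to background/tissue
  expect_equal(mean(a$gt$labels == 1), 0.6, tolerance = 0.1 / 0.6)
  expect_setequal(unique(as.vector(a$gt$labels)), c(0L, 1L))
  # background is near-white glass
  bg <- a$gt$labels == 0
  for (ch in 1:3)
    expect_true(all(a$image$pixels[, , ch][bg] >= 200 / 255))
  mean_chan <- (a$image$pixels[, , 1] + a$image$pixels[, , 2] + a$image$pixels[, , 3]) / 3
  expect_true(all(mean_chan[bg] >= 220 / 255))
  expect_error(gen_tissue_texture(c(96, 96), 1, tissue_frac = 1.2), "tissue_frac")
})

test_that("artifact injection labels exactly the altered region", {
  base <- gen_tissue_texture(c(96, 96), 1, 0.7, seed = 8)
  fold <- inject_artifact(base, artifact_spec("fold", c(48, 48), 30, angle = 0.3, seed = 1))
  band <- fold$gt$labels == 2L
  expect_true(any(band))
  # no gt change outside the fold band
  expect_true(all(fold$gt$labels[!band] == base$gt$labels[!band]))
  # the band was tissue before (folds are bound to tissue)
  expect_true(all(base$gt$labels[band] == 1L))
})

test_that("pigment is a confounder: image changes, ground truth does not", {
  base <- gen_tissue_texture(c(96, 96), 1, 0.7, seed = 9)
  pig <- inject_artifact(base, artifact_spec("pigment", c(48, 48), 30, seed = 2))
  expect_false(identical(pig$image$pixels, base$image$pixels))
  expect_identical(pig$gt$labels, base$gt$labels)
})

test_that("overlapping artifacts resolve by the fixed precedence order", {
  base <- gen_tissue_texture(c(96, 96), 1, 0.95, seed = 10)
  sc <- artifact_scheme()
  # fold then pen over the same centre: pen (opaque) wins on the overlap
  fold_first <- inject_artifact(base, artifact_spec("fold", c(48, 48), 30, angle = 0, seed = 1))
  both <- inject_artifact(fold_first, artifact_spec("pen_marking", c(48, 48), 30,
                                                    angle = 0, seed = 1))
  pen_only <- inject_artifact(base, artifact_spec("pen_marking", c(48, 48), 30,
                                                  angle = 0, seed = 1))
  overlap <- fold_first$gt$labels == class_index(sc, "fold") &
    pen_only$gt$labels == class_index(sc, "pen_marking")
  expect_true(any(overlap))
  expect_true(all(both$gt$labels[overlap] == class_index(sc, "pen_marking")))
  # and injecting the fold after the pen must not overwrite it
  rev_order <- inject_artifact(pen_only, artifact_spec("fold", c(48, 48), 30,
                                                       angle = 0, seed = 1))
  expect_true(all(rev_order$gt$labels[overlap] == class_index(sc, "pen_marking")))
})

test_that("synthetic OOF reaches the minimum fraction with kernels from the set", {
  base <- gen_tissue_texture(c(128, 128), 1, 0.65, seed = 12)
  out <- inject_oof(base, oof_spec(min_frac = 0.30, seed = 1))
  expect_gte(mean(out$gt$labels == 6L), 0.30)
  expect_true(attr(out, "oof_kernel") %in% seq(3, 17, 2))
  # OOF only relabels artifact-free tissue
  relabeled <- out$gt$labels == 6L
  expect_true(all(base$gt$labels[relabeled] == 1L))
  # image alterations are confined to the binary map support
  diff <- apply(out$image$pixels != base$image$pixels, c(1, 2), any)
  expect_true(all(!diff | attr(out, "oof_map")))
})

test_that("identity kernel leaves the image untouched; blur reduces local variance", {
  base <- gen_tissue_texture(c(96, 96), 1, 0.65, seed = 13)
  same <- inject_oof(base, oof_spec(min_frac = 0.3, kernel_sizes = 1L, seed = 2))
  expect_identical(same$image$pixels, base$image$pixels)
  expect_gte(mean(same$gt$labels == 6L), 0.30)

  blur <- inject_oof(base, oof_spec(min_frac = 0.3, kernel_sizes = 9L, seed = 2))
  lv <- function(px) {
    m <- px[, , 1]
    k <- matrix(1 / 25, 5, 5)
    mu <- EBImage::filter2(m, k, boundary = "replicate")
    EBImage::filter2(m^2, k, boundary = "replicate") - mu^2
  }
  core <- attr(blur, "oof_map")
  # erode the map so the comparison avoids boundary support of the 5x5 window
  core[c(1:8, 89:96), ] <- FALSE; core[, c(1:8, 89:96)] <- FALSE
  core <- core & EBImage::erode(attr(blur, "oof_map"), EBImage::makeBrush(9, "box")) > 0
  expect_gt(sum(core), 50)
  expect_lt(mean(lv(blur$image$pixels)[core]), mean(lv(base$image$pixels)[core]))
})

test_that("OOF generation fails cleanly when tissue cannot satisfy min_frac", {
  base <- gen_tissue_texture(c(96, 96), 1, 0.2, seed = 14)
  expect_error(inject_oof(base, oof_spec(min_frac = 0.5, seed = 1)),
               class = "slideqc_generation_error")
})

test_that("composed slides contain every requested class and reproduce exactly", {
  spec <- slide_spec(
    size = c(160, 160), mpp = 1, tissue_frac = 0.7,
    artifacts = list(
      artifact_spec("fold", c(40, 40), 22, angle = 0.4, seed = 1),
      artifact_spec("dark_spot_foreign", c(120, 40), 18, seed = 2),
      artifact_spec("pen_marking", c(40, 120), 30, angle = 1.2, seed = 3),
      artifact_spec("air_bubble_edge", c(120, 120), 24, seed = 4),
      artifact_spec("pigment", c(80, 80), 20, seed = 5)),
    oof = oof_spec(seed = 6), seed = 15)
  a <- compose_synthetic_slide(spec)
  b <- compose_synthetic_slide(spec)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$gt$labels, b$gt$labels)
  expect_setequal(unique(as.vector(a$gt$labels)), 0:6)
  # without artifacts or OOF only background/tissue appear
  clean <- compose_synthetic_slide(slide_spec(c(96, 96), 1, 0.6, seed = 16))
  expect_true(all(clean$gt$labels %in% c(0L, 1L)))
})

test_that("generated datasets are reproducible, sized and class-balanced", {
  d1 <- gen_dataset(10, patch_size = 64, mpp = 2, seed = 21)
  d2 <- gen_dataset(10, patch_size = 64, mpp = 2, seed = 21)
  expect_length(d1, 10)
  expect_identical(lapply(d1, function(x) x$image$pixels),
                   lapply(d2, function(x) x$image$pixels))
  expect_true(all(vapply(d1, function(x) all(dim(x$gt$labels) == 64), TRUE)))
  expect_error(gen_dataset(0), "positive")

  big <- gen_dataset(50, patch_size = 64, mpp = 2, seed = 22, balanced = TRUE)
  labs <- sort(unique(unlist(lapply(big, function(x) unique(as.vector(x$gt$labels))))))
  expect_equal(labs, 0:6)
  # balancing: each artifact class present in at least 5% of patches
  for (ci in 2:6) {
    frac <- mean(vapply(big, function(x) any(x$gt$labels == ci), TRUE))
    expect_gte(frac, 0.05)
  }
})

test_that("datasets round-trip through the PNG pair writer", {
  ds <- gen_dataset(3, patch_size = 64, mpp = 2, seed = 23)
  dir <- tempfile()
  manifest <- write_dataset(ds, dir)
  expect_equal(nrow(manifest), 3)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_mask_png(file.path(dir, manifest$mask[2]))
  expect_identical(back$labels, ds[[2]]$gt$labels)
  expect_equal(back$mpp, 2)
  img <- read_slide(file.path(dir, manifest$image[2]))
  expect_equal(img$levels[[1]]$pixels, ds[[2]]$image$pixels, tolerance = 1 / 254)
})
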