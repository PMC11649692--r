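# Tile planning, tissue filtering, stitching and mask resampling.

test_that("non-overlapping plans produce the expected box counts", {
  expect_equal(nrow(plan_tiles(2048, 2048, 512, 512)$boxes), 16)
  p1 <- plan_tiles(512, 512, 512, 512)
  expect_equal(unname(p1$boxes), matrix(c(0, 0, 512, 512), 1))
  # shifted edge tile ends flush with the extent
  p2 <- plan_tiles(700, 512, 512, 512, "shift_to_fit")
  expect_equal(unname(p2$boxes[, "x"]), c(0, 188))
  expect_equal(unname(p2$boxes[, "y"]), c(0, 0))
  # pad policy keeps the grid-aligned start instead
  p3 <- plan_tiles(700, 512, 512, 512, "pad")
  expect_equal(unname(p3$boxes[, "x"]), c(0, 512))
  # extent smaller than the patch: one tile per policy
  expect_equal(nrow(plan_tiles(100, 100, 512, 512, "shift_to_fit")$boxes), 1)
  expect_equal(nrow(plan_tiles(100, 100, 512, 512, "pad")$boxes), 1)
})

test_that("plan size matches the ceiling formula for arbitrary extents", {
  set.seed(31)
  for (i in 1:20) {
    w <- sample(40:400, 1); h <- sample(40:400, 1); p <- sample(c(32, 64, 96), 1)
    plan <- plan_tiles(w, h, p, p)
    expect_equal(nrow(plan$boxes), ceiling(w / p) * ceiling(h / p))
    expect_false(anyDuplicated(plan$boxes[, 1:2, drop = FALSE]) > 0)
    # all boxes inside the extent under shift_to_fit (when extent >= patch)
    if (w >= p && h >= p) {
      expect_true(all(plan$boxes[, "x"] + p <= w))
      expect_true(all(plan$boxes[, "y"] + p <= h))
    }
  }
})

test_that("tissue filtering keeps exactly the boxes a per-box count keeps", {
  plan <- plan_tiles(64, 64, 16, 16, mpp = 1)
  # checkerboard at tile granularity: half the tiles all-tissue
  tis <- matrix(0L, 64, 64)
  for (bx in 0:3) for (by in 0:3)
    if ((bx + by) %% 2 == 0) tis[by * 16 + 1:16, bx * 16 + 1:16] <- 1L
  tmask <- label_mask(tis, 1, tissue_scheme())
  kept <- filter_tiles_by_tissue(plan, tmask, min_tissue_frac = 0.4)
  oracle <- vapply(seq_len(nrow(plan$boxes)), function(i) {
    b <- plan$boxes[i, ]
    frac <- mean(tis[(b[2] + 1):(b[2] + b[4]), (b[1] + 1):(b[1] + b[3])] > 0)
    frac >= 0.4 && frac > 0
  }, TRUE)
  expect_equal(nrow(kept$boxes), sum(oracle))
  expect_equal(kept$boxes, plan$boxes[oracle, , drop = FALSE])

  expect_equal(nrow(filter_tiles_by_tissue(
    plan, label_mask(matrix(0L, 64, 64), 1, tissue_scheme()))$boxes), 0)
  expect_equal(filter_tiles_by_tissue(
    plan, label_mask(matrix(1L, 64, 64), 1, tissue_scheme()))$boxes, plan$boxes)
  expect_error(filter_tiles_by_tissue(plan, random_mask(64, 64)),
               class = "slideqc_scheme_error")
})

test_that("lowering the tissue threshold never drops a retained box", {
  set.seed(32)
  tis <- matrix(as.integer(runif(64 * 64) < 0.4), 64, 64)
  tmask <- label_mask(tis, 1, tissue_scheme())
  plan <- plan_tiles(64, 64, 16, 16)
  prev <- NULL
  for (f in c(0.8, 0.5, 0.2, 0)) {
    kept <- filter_tiles_by_tissue(plan, tmask, f)
    key <- paste(kept$boxes[, 1], kept$boxes[, 2])
    if (!is.null(prev)) expect_true(all(prev %in% key))
    prev <- key
  }
})

test_that("extract-then-stitch with stride = patch is the identity", {
  m <- random_mask(96, 128, seed = 33)
  plan <- plan_tiles(128, 96, 32, 32, mpp = 1)
  tiles <- extract_tiles(m, plan)
  back <- stitch_masks(tiles, plan)
  expect_identical(back$labels, m$labels)
  # non-multiple extent still round-trips (edge tiles shifted)
  m2 <- random_mask(70, 90, seed = 34)
  plan2 <- plan_tiles(90, 70, 32, 32, mpp = 1)
  back2 <- stitch_masks(extract_tiles(m2, plan2), plan2)
  expect_identical(back2$labels, m2$labels)
})

test_that("overlapping tiles resolve to the later-written value; empty plans fill", {
  plan <- plan_tiles(48, 32, 32, 16, mpp = 1)   # stride < patch: overlaps
  tiles <- lapply(seq_len(nrow(plan$boxes)), function(i)
    label_mask(matrix(i, 32, 32), 1, artifact_scheme()))
  out <- stitch_masks(tiles, plan)
  # at each pixel the value is from the last box covering it (row-major order)
  for (px in list(c(1, 1), c(20, 1), c(40, 1), c(20, 30))) {
    covering <- which(vapply(seq_len(nrow(plan$boxes)), function(i) {
      b <- plan$boxes[i, ]
      px[1] > b[1] && px[1] <= b[1] + b[3] && px[2] > b[2] && px[2] <= b[2] + b[4]
    }, TRUE))
    expect_equal(out$labels[px[2], px[1]], max(covering))
  }
  empty <- plan_tiles(48, 32, 32, 32)
  empty$boxes <- empty$boxes[0, , drop = FALSE]
  filled <- stitch_masks(list(), empty, fill = 5L)
  expect_true(all(filled$labels == 5L))
  expect_error(stitch_masks(tiles[1], plan), class = "slideqc_shape_error")
})

test_that("mask resampling is nearest-neighbour and never invents labels", {
  m <- random_mask(20, 20, seed = 35, mpp = 2)
  expect_identical(resample_mask(m, 2), m)
  up <- resample_mask(m, 1)
  expect_equal(dim(up$labels), c(40, 40))
  expect_identical(up$labels, m$labels[rep(1:20, each = 2), rep(1:20, each = 2)])
  for (seed in 36:40) {
    r <- random_mask(17, 23, seed = seed, mpp = 1)
    for (target in c(0.7, 1.9, 3.1)) {
      rs <- resample_mask(r, target)
      expect_true(all(unique(as.vector(rs$labels)) %in% unique(as.vector(r$labels))))
    }
  }
})

test_that("tile plans survive the JSON round trip", {
  plan <- plan_tiles(700, 512, 512, 512, "shift_to_fit", mpp = 2)
  path <- tempfile(fileext = ".json")
  write_tile_plan(plan, path)
  back <- read_tile_plan(path)
  expect_equal(unname(back$boxes), unname(plan$boxes))
  expect_equal(back$mpp, plan$mpp)
  expect_equal(back$edge_policy, plan$edge_policy)
})
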