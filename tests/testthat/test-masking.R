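# Downstream masking: scoring exclusion, OOF corruption, detection filtering.

test_that("QC masking alters exactly the artifact pixels", {
  fx <- demo_slide()
  patch <- fx$labeled$image
  mask <- fx$labeled$gt
  res <- apply_qc_mask(patch, mask, "white")
  art <- mask$labels > 1L
  expect_identical(res$ignore, art)
  for (ch in 1:3) {
    expect_identical(res$patch$pixels[, , ch][!art], patch$pixels[, , ch][!art])
    expect_true(all(res$patch$pixels[, , ch][art] == 1))
  }
  # ignore_label policy leaves the image untouched entirely
  res2 <- apply_qc_mask(patch, mask, "ignore_label")
  expect_identical(res2$patch$pixels, patch$pixels)
  expect_identical(res2$ignore, art)
  # an all-clear mask is a no-op
  clear <- label_mask(matrix(1L, 512, 512), 2, artifact_scheme())
  res3 <- apply_qc_mask(patch, clear, "white")
  expect_identical(res3$patch$pixels, patch$pixels)
  expect_false(any(res3$ignore))
})

test_that("ROI corruption reaches the OOF minimum and stays inside the map", {
  roi <- gen_tissue_texture(c(128, 128), 1, 0.7, seed = 91)
  cor <- corrupt_roi_with_oof(roi, seed = 2)
  expect_gte(mean(cor$gt$labels == 6L), 0.30)
  diff <- apply(cor$image$pixels != roi$image$pixels, c(1, 2), any)
  expect_true(all(!diff | attr(cor, "oof_map")))
  expect_identical(corrupt_roi_with_oof(roi, kernel_sizes = 1L, seed = 3)$image$pixels,
                   roi$image$pixels)
})

test_that("sensitivity and specificity follow their closed forms", {
  sc <- tissue_scheme()
  # tissue one-vs-rest with TP = 3, FN = 1, TN = 5, FP = 1 on 10 pixels
  gt <- label_mask(matrix(c(rep(1L, 4), rep(0L, 6)), 2), 1, sc)
  pr <- label_mask(matrix(c(rep(1L, 3), 0L, 1L, rep(0L, 5)), 2), 1, sc)
  tab <- slideqc:::class_sens_spec(pr, gt)
  expect_equal(tab$sensitivity[tab$class == "tissue"], 0.75)
  expect_equal(tab$specificity[tab$class == "tissue"], 5 / 6, tolerance = 1e-4)
})

test_that("corrected scores exclude ignored pixels", {
  set.seed(92)
  sc <- tissue_scheme()
  gt <- random_mask(20, 20, k = 2, seed = 93, scheme = sc)
  base_pred <- random_mask(20, 20, k = 2, seed = 94, scheme = sc)
  ignore <- matrix(FALSE, 20, 20); ignore[1:8, ] <- TRUE
  # corrected prediction: equals baseline outside the ignore region but is
  # filled with sentinel nonsense inside it
  corr <- base_pred$labels
  corr[ignore] <- 1L - corr[ignore]
  corr_pred <- label_mask(corr, 1, sc)
  tab <- accuracy_delta(gt, base_pred, base_pred, corr_pred, ignore)
  base_rows <- tab[tab$condition == "baseline", c("dice", "sensitivity", "specificity")]
  corr_rows <- tab[tab$condition == "corrected", c("dice", "sensitivity", "specificity")]
  # corrected must be scored only on the clean region: it cannot see the
  # sentinel labels, but is evaluated on fewer pixels than baseline
  keep_gt <- label_mask(gt$labels[9:20, , drop = FALSE], 1, sc)
  keep_pr <- label_mask(base_pred$labels[9:20, , drop = FALSE], 1, sc)
  oracle <- slideqc:::class_sens_spec(keep_pr, keep_gt)
  expect_equal(corr_rows$sensitivity, oracle$sensitivity)
  expect_equal(corr_rows$specificity, oracle$specificity)
  expect_equal(corr_rows$dice, oracle$dice)
  # identical inputs across conditions give identical rows
  same <- accuracy_delta(gt, base_pred, base_pred, base_pred,
                         matrix(FALSE, 20, 20))
  expect_equal(same[same$condition == "baseline", -1],
               same[same$condition == "corrected", -1],
               ignore_attr = TRUE)
})

test_that("detections on artifact pixels are removed by centre-point lookup", {
  sc <- artifact_scheme()
  lab <- matrix(1L, 32, 32)
  lab[10:20, 10:20] <- 2L   # fold block
  mask <- label_mask(lab, 1, sc)
  dets <- detection_set(x = c(5, 15, 25, 12), y = c(5, 15, 25, 30),
                        class = c("t", "t", "t", "t"), mpp = 1)
  kept <- filter_detections(dets, mask)
  expect_equal(kept$x, c(5, 25, 12))
  # brute force per-point oracle on random detections
  set.seed(95)
  many <- detection_set(x = runif(200, 0, 32), y = runif(200, 0, 32),
                        class = rep("c", 200), mpp = 1)
  kept2 <- filter_detections(many, mask)
  oracle <- vapply(seq_len(200), function(i) {
    lab[floor(many$y[i]) + 1, floor(many$x[i]) + 1] <= 1L
  }, TRUE)
  expect_equal(nrow(kept2), sum(oracle))
  # idempotent
  expect_equal(nrow(filter_detections(kept2, mask)), nrow(kept2))
  # monotone: a superset artifact mask removes a superset of detections
  lab2 <- lab; lab2[5:25, 5:25] <- 2L
  kept3 <- filter_detections(many, label_mask(lab2, 1, sc))
  expect_true(all(paste(kept3$x, kept3$y) %in% paste(kept2$x, kept2$y)))
  # empty set stays empty; out-of-extent points are dropped with a message
  expect_equal(nrow(filter_detections(detection_set(mpp = 1), mask)), 0)
  oob <- detection_set(x = c(5, 100), y = c(5, 5), class = c("a", "b"), mpp = 1)
  expect_message(kept4 <- filter_detections(oob, mask), "outside")
  expect_equal(nrow(kept4), 1)
})

test_that("detections round-trip through CSV", {
  dets <- detection_set(x = c(1.5, 7), y = c(2, 3.25), class = c("tumor", "immune"),
                        mpp = 0.5)
  path <- tempfile(fileext = ".csv")
  write_detections(dets, path)
  back <- read_detections(path)
  expect_equal(back$x, dets$x)
  expect_equal(back$class, dets$class)
  expect_equal(attr(back, "mpp"), 0.5)
})
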