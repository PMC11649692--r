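# Two-module QC pipeline: low-magnification tissue detection gating
# multi-class artifact segmentation at 5x/7x/10x, plus per-slide summaries,
# overlays and mask export.

# MPP of each artifact-model variant (objective magnification -> 10/power)
variant_mpp <- function(variant) {
  switch(variant, "10x" = 1.0, "7x" = 10 / 7, "5x" = 2.0,
         stop_if_not(FALSE, "unknown variant: ", variant,
                     class = "slideqc_config_error"))
}

# read a tile, padding by edge replication where the box overruns the extent
read_region_pad <- function(slide, target_mpp, box) {
  ext <- slide_dims_at(slide, target_mpp)
  x <- box[1]; y <- box[2]; w <- box[3]; h <- box[4]
  cw <- min(w, ext[1] - x); ch <- min(h, ext[2] - y)
  r <- read_region(slide, target_mpp, c(x, y, cw, ch))
  if (cw == w && ch == h) return(r)
  px <- r$pixels[c(seq_len(ch), rep(ch, h - ch)),
                 c(seq_len(cw), rep(cw, w - cw)), , drop = FALSE]
  qc_raster(px, target_mpp)
}

#' Run the tissue-detection module over a slide
#'
#' Tiles the slide at MPP 10 (1x objective magnification), predicts each tile
#' with the tissue model and stitches the per-tile masks into a slide-level
#' tissue mask.
#'
#' @param slide A [slide_pyramid].
#' @param bundle A trained tissue-scheme `qc_model_bundle` (MPP 10).
#' @return A `qc_mask` in the tissue scheme at MPP 10 whose dims equal the
#'   slide extent at MPP 10.
#' @export
run_tissue_module <- function(slide, bundle) {
  stop_if_not(inherits(bundle, "qc_model_bundle"), "bundle must be a qc_model_bundle")
  stop_if_not(bundle$config$scheme$kind == "tissue",
              "tissue module needs a tissue-scheme bundle",
              class = "slideqc_scheme_error")
  mpp <- bundle$config$mpp
  dims <- slide_dims_at(slide, mpp)
  plan <- plan_tiles(dims[1], dims[2], bundle$config$patch_size, mpp = mpp)
  tiles <- lapply(seq_len(nrow(plan$boxes)), function(i)
    read_region_pad(slide, mpp, plan$boxes[i, ]))
  preds <- predict(bundle, tiles)
  stitch_masks(lapply(preds, `[[`, "mask"), plan, fill = 0L)
}

#' Run the artifact-detection module inside the tissue mask
#'
#' Tiles the slide at the variant's MPP (10x -> 1.0, 7x -> 1.4286, 5x -> 2.0),
#' skips tiles containing no tissue, predicts the rest with the artifact
#' model, stitches, and forces every pixel outside the (resampled) tissue
#' mask to background: the artifact module inherits background from the
#' tissue module.
#'
#' @param slide A [slide_pyramid].
#' @param tissue_mask Tissue-scheme `qc_mask` from [run_tissue_module].
#' @param bundle A trained artifact-scheme `qc_model_bundle` whose configured
#'   MPP matches the variant.
#' @param variant `"5x"`, `"7x"` or `"10x"`.
#' @param min_tissue_frac Minimum tissue fraction for a tile to be processed.
#' @return A `qc_mask` in the artifact scheme at the variant's MPP.
#' @export
run_artifact_module <- function(slide, tissue_mask, bundle,
                                variant = c("10x", "7x", "5x"),
                                min_tissue_frac = 0) {
  variant <- match.arg(variant)
  stop_if_not(inherits(bundle, "qc_model_bundle"), "bundle must be a qc_model_bundle")
  stop_if_not(bundle$config$scheme$kind == "artifact",
              "artifact module needs an artifact-scheme bundle",
              class = "slideqc_scheme_error")
  mpp <- variant_mpp(variant)
  stop_if_not(abs(bundle$config$mpp - mpp) < 1e-3,
              "bundle MPP ", bundle$config$mpp, " does not match variant ", variant,
              class = "slideqc_config_error")
  stop_if_not(inherits(tissue_mask, "qc_mask") && tissue_mask$scheme$kind == "tissue",
              "tissue_mask must be a tissue-scheme qc_mask",
              class = "slideqc_scheme_error")
  dims <- slide_dims_at(slide, mpp)
  plan <- plan_tiles(dims[1], dims[2], bundle$config$patch_size, mpp = mpp)
  plan <- filter_tiles_by_tissue(plan, tissue_mask, min_tissue_frac)
  preds <- if (nrow(plan$boxes)) {
    tiles <- lapply(seq_len(nrow(plan$boxes)), function(i)
      read_region_pad(slide, mpp, plan$boxes[i, ]))
    predict(bundle, tiles)
  } else list()
  out <- stitch_masks(lapply(preds, `[[`, "mask"), plan, fill = 0L)
  out$scheme <- bundle$config$scheme
  # gate on the tissue module: outside tissue is background, always
  gate <- resize_nearest(tissue_mask$labels, dims[2], dims[1])
  labels <- out$labels
  labels[gate == 0L] <- 0L
  label_mask(labels, mpp, bundle$config$scheme)
}

#' Per-slide QC summary from an artifact mask
#'
#' Tissue area is every non-background pixel; each artifact class is reported
#' as a percentage of the tissue area, together with the artifact-free
#' percentage (they sum to 100).
#'
#' @param mask Artifact-scheme `qc_mask`.
#' @param slide_id Identifier recorded in the summary.
#' @param variant Optional variant tag (`"5x"`, `"7x"`, `"10x"`).
#' @return An object of class `qc_slide_summary`: `slide_id`,
#'   `tissue_area_mm2`, `class_pct` (named percentages over artifact classes),
#'   `artifact_free_pct`, `any_artifact_pct`, `variant`, `no_tissue` flag.
#' @export
slide_summary <- function(mask, slide_id = "slide", variant = NA_character_) {
  stop_if_not(inherits(mask, "qc_mask") && mask$scheme$kind == "artifact",
              "mask must be an artifact-scheme qc_mask",
              class = "slideqc_scheme_error")
  sc <- mask$scheme
  counts <- tabulate(mask$labels + 1L, nbins = n_classes(sc))
  names(counts) <- sc$names
  tissue_px <- sum(counts[-1])
  art_classes <- setdiff(sc$names, c("background", "tissue_no_artifact"))
  if (tissue_px == 0) {
    class_pct <- stats::setNames(rep(NaN, length(art_classes)), art_classes)
    free <- NaN; any_art <- NaN
  } else {
    class_pct <- 100 * counts[art_classes] / tissue_px
    free <- 100 * counts["tissue_no_artifact"] / tissue_px
    any_art <- 100 - free
  }
  structure(list(slide_id = slide_id,
                 tissue_area_mm2 = tissue_px * (mask$mpp / 1000)^2,
                 class_pct = class_pct,
                 artifact_free_pct = unname(free),
                 any_artifact_pct = unname(any_art),
                 variant = variant, no_tissue = tissue_px == 0),
            class = "qc_slide_summary")
}

#' @export
print.qc_slide_summary <- function(x, ...) {
  cat(sprintf("<qc_slide_summary> %s: %.3f mm2 tissue, %.1f%% artifact-free\n",
              x$slide_id, x$tissue_area_mm2, x$artifact_free_pct))
  for (nm in names(x$class_pct))
    cat(sprintf("  %-18s %6.2f%%\n", nm, x$class_pct[nm]))
  invisible(x)
}

#' Blend a class palette over a slide image
#'
#' The mask is nearest-neighbour resampled to the image dims; labeled
#' (non-background) pixels are alpha-blended with their class colour,
#' background pixels are untouched.
#'
#' @param image A [qc_raster].
#' @param mask A `qc_mask`.
#' @param alpha Blend weight in `[0, 1]`.
#' @return A [qc_raster] of the image's dims.
#' @export
make_overlay <- function(image, mask, alpha = 0.5) {
  stop_if_not(inherits(image, "qc_raster") && inherits(mask, "qc_mask"),
              "need a qc_raster and a qc_mask")
  stop_if_not(is.numeric(alpha) && alpha >= 0 && alpha <= 1,
              "alpha must be in [0, 1]")
  h <- raster_h(image); w <- raster_w(image)
  lab <- resize_nearest(mask$labels, h, w)
  pal <- t(grDevices::col2rgb(mask$scheme$palette)) / 255
  px <- image$pixels
  on <- lab > 0L
  for (ch in 1:3) {
    v <- px[, , ch]
    v[on] <- v[on] * (1 - alpha) + pal[lab[on] + 1L, ch] * alpha
    px[, , ch] <- v
  }
  qc_raster(px, image$mpp)
}

#' Write a label mask as an indexed PNG (+ JSON sidecar)
#'
#' Pixel value = class index; the MPP, scheme names and palette go to
#' `<path>.json`. The round trip through [read_mask_png] is bit-exact.
#'
#' @param mask A `qc_mask`.
#' @param path Output `.png` path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  stop_if_not(inherits(mask, "qc_mask"), "mask must be a qc_mask")
  png::writePNG(mask$labels / 255, path)
  jsonlite::write_json(list(mpp = mask$mpp, kind = mask$scheme$kind,
                            classes = mask$scheme$names,
                            palette = mask$scheme$palette),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  labels <- round(png::readPNG(path) * 255)
  if (length(dim(labels)) == 3) labels <- labels[, , 1]
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  scheme <- class_scheme(meta$classes, meta$palette, meta$kind)
  label_mask(matrix(as.integer(labels), nrow(labels)), meta$mpp, scheme)
}

#' Export the QC outputs for one slide
#'
#' Writes the artifact mask as indexed PNG, its per-class polygons as
#' GeoJSON, and the slide summary as JSON.
#'
#' @param mask Artifact-scheme `qc_mask`.
#' @param summary A `qc_slide_summary`.
#' @param out_dir Output directory (created if needed).
#' @param prefix File-name prefix; defaults to the summary's slide id.
#' @return Named character vector of the written paths, invisibly.
#' @export
export_outputs <- function(mask, summary, out_dir, prefix = summary$slide_id) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(mask_png = file.path(out_dir, paste0(prefix, "_mask.png")),
             geojson = file.path(out_dir, paste0(prefix, "_mask.geojson")),
             summary_json = file.path(out_dir, paste0(prefix, "_summary.json")))
  write_mask_png(mask, paths[["mask_png"]])
  write_mask_geojson(mask, paths[["geojson"]])
  jsonlite::write_json(list(
    slide_id = summary$slide_id, tissue_area_mm2 = summary$tissue_area_mm2,
    class_pct = as.list(summary$class_pct),
    artifact_free_pct = summary$artifact_free_pct,
    any_artifact_pct = summary$any_artifact_pct, variant = summary$variant,
    no_tissue = summary$no_tissue), paths[["summary_json"]],
    auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Run the full QC pipeline on one slide
#'
#' Convenience wrapper: tissue module, artifact module at the chosen variant,
#' summary, and optional export.
#'
#' @param slide A [slide_pyramid].
#' @param tissue_bundle,artifact_bundle Trained model bundles.
#' @param variant `"5x"`, `"7x"` or `"10x"`.
#' @param slide_id Identifier for the summary.
#' @param out_dir Optional output directory for [export_outputs].
#' @param overlay_alpha If non-`NULL` and `out_dir` given, also writes an
#'   overlay PNG at the artifact MPP with this alpha.
#' @return List: `tissue_mask`, `artifact_mask`, `summary`.
#' @export
run_qc <- function(slide, tissue_bundle, artifact_bundle,
                   variant = c("10x", "7x", "5x"), slide_id = "slide",
                   out_dir = NULL, overlay_alpha = NULL) {
  variant <- match.arg(variant)
  tm <- run_tissue_module(slide, tissue_bundle)
  am <- run_artifact_module(slide, tm, artifact_bundle, variant)
  sm <- slide_summary(am, slide_id, variant)
  if (!is.null(out_dir)) {
    export_outputs(am, sm, out_dir)
    if (!is.null(overlay_alpha)) {
      dims <- slide_dims_at(slide, am$mpp)
      img <- read_region_pad(slide, am$mpp, c(0, 0, dims[1], dims[2]))
      write_raster(make_overlay(img, am, overlay_alpha),
                   file.path(out_dir, paste0(slide_id, "_overlay.png")))
    }
  }
  list(tissue_mask = tm, artifact_mask = am, summary = sm)
}
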