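# MPP-aware tile planning, tissue-based tile filtering and mask stitching.
# Boxes are c(x, y, w, h), 0-based, half-open, expressed at the plan's MPP.

#' Plan a patch grid over a slide extent
#'
#' Lays out `patch_size` square boxes row-major at `stride` spacing. Boxes
#' overrunning the right/bottom edge are shifted back to end flush
#' (`shift_to_fit`) or kept in place with the slide conceptually padded
#' (`pad`). If the extent is smaller than the patch in some direction,
#' a single flush/padded tile is planned for that direction.
#'
#' @param w,h Slide extent in pixels at `mpp`.
#' @param patch_size Tile side length in pixels.
#' @param stride Tile spacing in pixels; `stride = patch_size` (default) gives
#'   non-overlapping cover.
#' @param edge_policy `"shift_to_fit"` (default) or `"pad"`.
#' @param mpp MPP the plan's coordinates refer to (metadata; default 1).
#' @return An object of class `qc_tile_plan` with fields `boxes` (n x 4
#'   matrix), `slide_dims`, `patch_size`, `stride`, `edge_policy`, `mpp`.
#' @export
plan_tiles <- function(w, h, patch_size, stride = patch_size,
                       edge_policy = c("shift_to_fit", "pad"), mpp = 1.0) {
  edge_policy <- match.arg(edge_policy)
  stop_if_not(is_count(patch_size) && is_count(stride), "patch_size and stride must be positive integers")
  stop_if_not(is_count(w) && is_count(h), "slide extent must be positive")
  starts <- function(n) {
    n <- as.integer(n)
    if (n <= patch_size) return(0L)     # single (possibly clipped/padded) tile
    if (edge_policy == "shift_to_fit") {
      s <- seq.int(0L, n - patch_size, by = stride)
      if (s[length(s)] + patch_size < n) s <- c(s, n - patch_size)
      s
    } else {
      s <- seq.int(0L, n - 1L, by = stride)
      s[seq_len(min(which(s + patch_size >= n)))]   # first cover of the extent
    }
  }
  xs <- starts(w); ys <- starts(h)
  boxes <- cbind(x = rep(xs, times = length(ys)),
                 y = rep(ys, each = length(xs)),
                 w = patch_size, h = patch_size)
  boxes <- boxes[!duplicated(boxes[, 1:2, drop = FALSE]), , drop = FALSE]
  structure(list(boxes = boxes, slide_dims = c(as.integer(w), as.integer(h)),
                 patch_size = as.integer(patch_size), stride = as.integer(stride),
                 edge_policy = edge_policy, mpp = as.numeric(mpp)),
            class = "qc_tile_plan")
}

#' @export
print.qc_tile_plan <- function(x, ...) {
  cat(sprintf("<qc_tile_plan> %d box(es) of %d px, stride %d, %s, extent %d x %d @ MPP %.4g\n",
              nrow(x$boxes), x$patch_size, x$stride, x$edge_policy,
              x$slide_dims[1], x$slide_dims[2], x$mpp))
  invisible(x)
}

#' @export
length.qc_tile_plan <- function(x) nrow(x$boxes)

#' Keep only tiles with enough tissue
#'
#' The tissue mask (any MPP) is nearest-neighbour resampled to the plan's
#' extent; a tile is retained when the fraction of tissue pixels inside its
#' box is at least `min_tissue_frac`. With the default `min_tissue_frac = 0`,
#' tiles touching no tissue at all are still dropped (a fraction of exactly
#' zero never exceeds the threshold meaningfully), matching the convention
#' that tiles with zero tissue are skipped.
#'
#' @param plan A `qc_tile_plan`.
#' @param tissue_mask A `qc_mask` in the tissue scheme.
#' @param min_tissue_frac Minimum tissue fraction per tile, in `[0, 1]`.
#' @return The filtered `qc_tile_plan` (box order preserved).
#' @export
filter_tiles_by_tissue <- function(plan, tissue_mask, min_tissue_frac = 0) {
  stop_if_not(inherits(plan, "qc_tile_plan"), "plan must be a qc_tile_plan")
  stop_if_not(inherits(tissue_mask, "qc_mask"), "tissue_mask must be a qc_mask")
  stop_if_not(tissue_mask$scheme$kind == "tissue",
              "tissue_mask must use the tissue scheme", class = "slideqc_scheme_error")
  m <- resize_nearest(tissue_mask$labels, plan$slide_dims[2], plan$slide_dims[1])
  keep <- vapply(seq_len(nrow(plan$boxes)), function(i) {
    b <- plan$boxes[i, ]
    ys <- (b[2] + 1):min(b[2] + b[4], nrow(m))
    xs <- (b[1] + 1):min(b[1] + b[3], ncol(m))
    frac <- mean(m[ys, xs] > 0)
    frac >= min_tissue_frac && frac > 0
  }, logical(1))
  plan$boxes <- plan$boxes[keep, , drop = FALSE]
  plan
}

#' Stitch per-tile label masks into a slide-level mask
#'
#' Tiles are written onto a canvas of the plan's extent in box order; where
#' tiles overlap, the later-written tile wins (with the default
#' `stride = patch_size` no overlaps occur). Uncovered pixels take `fill`.
#'
#' @param patch_masks List of `qc_mask`, one per box in `plan`, each of the
#'   plan's patch size.
#' @param plan A `qc_tile_plan`.
#' @param fill Class index for uncovered pixels (default 0, background).
#' @return A slide-level `qc_mask` at the plan's MPP.
#' @export
stitch_masks <- function(patch_masks, plan, fill = 0L) {
  stop_if_not(inherits(plan, "qc_tile_plan"), "plan must be a qc_tile_plan")
  stop_if_not(length(patch_masks) == nrow(plan$boxes),
              "need exactly one mask per planned box", class = "slideqc_shape_error")
  w <- plan$slide_dims[1]; h <- plan$slide_dims[2]
  canvas <- matrix(as.integer(fill), h, w)
  scheme <- if (length(patch_masks)) patch_masks[[1]]$scheme else artifact_scheme()
  for (i in seq_along(patch_masks)) {
    pm <- patch_masks[[i]]
    stop_if_not(all(dim(pm$labels) == plan$patch_size),
                "patch mask ", i, " does not match the plan's patch size",
                class = "slideqc_shape_error")
    b <- plan$boxes[i, ]
    ys <- (b[2] + 1):min(b[2] + b[4], h)
    xs <- (b[1] + 1):min(b[1] + b[3], w)
    canvas[ys, xs] <- pm$labels[seq_along(ys), seq_along(xs)]
  }
  label_mask(canvas, plan$mpp, scheme)
}

#' Extract per-tile masks from a slide-level mask
#'
#' Inverse companion of [stitch_masks] for testing and training-data
#' extraction; boxes beyond the mask edge are filled with `fill`.
#'
#' @param mask A `qc_mask` at the plan's MPP.
#' @param plan A `qc_tile_plan`.
#' @param fill Class index for out-of-extent pixels.
#' @return List of `qc_mask`, one per box.
#' @export
extract_tiles <- function(mask, plan, fill = 0L) {
  stop_if_not(inherits(mask, "qc_mask"), "mask must be a qc_mask")
  lapply(seq_len(nrow(plan$boxes)), function(i) {
    b <- plan$boxes[i, ]
    tile <- matrix(as.integer(fill), b[4], b[3])
    ys <- (b[2] + 1):min(b[2] + b[4], nrow(mask$labels))
    xs <- (b[1] + 1):min(b[1] + b[3], ncol(mask$labels))
    tile[seq_along(ys), seq_along(xs)] <- mask$labels[ys, xs]
    label_mask(tile, mask$mpp, mask$scheme)
  })
}

#' Resample a label mask to a target MPP
#'
#' Nearest-neighbour only: a resampled mask can never contain labels absent
#' from the input. Output dims are `round(dims * mpp / target_mpp)` (at least
#' 1 x 1).
#'
#' @param mask A `qc_mask`.
#' @param target_mpp Target microns per pixel (> 0).
#' @param dims Optional explicit output dims `c(w, h)` (e.g. to match a
#'   pyramid extent, which is rounded up rather than to nearest).
#' @return The resampled `qc_mask` at `target_mpp`.
#' @export
resample_mask <- function(mask, target_mpp, dims = NULL) {
  stop_if_not(inherits(mask, "qc_mask"), "mask must be a qc_mask")
  stop_if_not(is.numeric(target_mpp) && target_mpp > 0, "target_mpp must be positive")
  if (is.null(dims)) {
    if (abs(target_mpp - mask$mpp) < 1e-12) return(mask)
    dims <- c(max(1L, round(ncol(mask$labels) * mask$mpp / target_mpp)),
              max(1L, round(nrow(mask$labels) * mask$mpp / target_mpp)))
  }
  label_mask(resize_nearest(mask$labels, dims[2], dims[1]), target_mpp, mask$scheme)
}

#' Serialize / restore a tile plan as JSON
#' @param plan A `qc_tile_plan`.
#' @param path JSON file path.
#' @return `path` (write) or the restored `qc_tile_plan` (read).
#' @export
write_tile_plan <- function(plan, path) {
  jsonlite::write_json(list(
    boxes = unname(apply(plan$boxes, 1, as.list)), slide_dims = plan$slide_dims,
    patch_size = plan$patch_size, stride = plan$stride,
    edge_policy = plan$edge_policy, mpp = plan$mpp), path,
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tile_plan
#' @export
read_tile_plan <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  boxes <- as.matrix(as.data.frame(j$boxes))
  storage.mode(boxes) <- "integer"
  colnames(boxes) <- c("x", "y", "w", "h")
  structure(list(boxes = boxes, slide_dims = as.integer(j$slide_dims),
                 patch_size = as.integer(j$patch_size), stride = as.integer(j$stride),
                 edge_policy = j$edge_policy, mpp = as.numeric(j$mpp)),
            class = "qc_tile_plan")
}
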