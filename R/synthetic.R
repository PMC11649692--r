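# Synthetic H&E-like slides with pixel-exact ground truth.
#
# The simulator emulates the appearance QC models are trained on: tissue with
# pink/purple stain texture on a near-white glass background, plus injected
# artifacts (folds, dark spots / foreign objects, pen markings, air bubble /
# slide edge rims, melanin-like pigment as an unlabeled confounder) and
# synthetic out-of-focus regions produced by Gaussian-blurring the image under
# a random smooth binary map.

# bilinear upsample of a matrix (used to turn coarse noise into smooth fields)
bilinear_resize <- function(m, new_h, new_w) {
  h <- nrow(m); w <- ncol(m)
  ys <- clamp((seq_len(new_h) - 0.5) * h / new_h - 0.5, 0, h - 1)
  xs <- clamp((seq_len(new_w) - 0.5) * w / new_w - 0.5, 0, w - 1)
  y0 <- pmin(floor(ys), h - 1); ty <- ys - y0
  x0 <- pmin(floor(xs), w - 1); tx <- xs - x0
  y1 <- pmin(y0 + 1, h - 1); x1 <- pmin(x0 + 1, w - 1)
  a <- m[y0 + 1, x0 + 1, drop = FALSE]; b <- m[y0 + 1, x1 + 1, drop = FALSE]
  c_ <- m[y1 + 1, x0 + 1, drop = FALSE]; d <- m[y1 + 1, x1 + 1, drop = FALSE]
  top <- a * (1 - tx)[col(a)] + b * tx[col(b)]
  bot <- c_ * (1 - tx)[col(c_)] + d * tx[col(d)]
  top * (1 - ty)[row(top)] + bot * ty[row(bot)]
}

# smooth standard-normal-ish random field, coarse cell size `cell` pixels
smooth_noise_field <- function(h, w, cell = 32) {
  ch <- max(2L, ceiling(h / cell)); cw <- max(2L, ceiling(w / cell))
  bilinear_resize(matrix(stats::rnorm(ch * cw), ch, cw), h, w)
}

# k x k Gaussian kernel; k = 1 is the identity. Sigma follows the standard
# kernel-size rule sigma = 0.3*((k-1)/2 - 1) + 0.8 so that "kernel size"
# fully determines blur strength.
gaussian_kernel <- function(k) {
  stop_if_not(is_count(k) && k %% 2 == 1, "kernel size must be a positive odd integer")
  if (k == 1) return(matrix(1, 1, 1))
  sigma <- 0.3 * ((k - 1) / 2 - 1) + 0.8
  EBImage::makeBrush(as.integer(k), shape = "gaussian", sigma = sigma)
}

blur_rgb <- function(px, k) {
  if (k == 1) return(px)
  kern <- gaussian_kernel(k)
  out <- px
  for (ch in 1:3) out[, , ch] <- EBImage::filter2(px[, , ch], kern, boundary = "replicate")
  clamp(out)
}

#' Specification of one injected artifact
#'
#' @param kind One of `"fold"`, `"dark_spot_foreign"`, `"pen_marking"`,
#'   `"air_bubble_edge"`, `"pigment"`. `pigment` is a labeled confounder: it
#'   alters the image (melanin-like speckling that mimics air-bubble texture)
#'   but leaves the ground truth unchanged.
#' @param center Pixel coordinates `c(x, y)` (0-based) of the artifact centre.
#' @param extent Characteristic size in pixels (band half-length, bubble
#'   radius, stroke half-length, blob cluster radius).
#' @param angle Orientation in radians for elongated artifacts.
#' @param severity In `[0, 1]`; scales opacity/darkening.
#' @param seed Integer seed for the artifact's internal randomness.
#' @return An object of class `qc_artifact_spec`.
#' @export
artifact_spec <- function(kind, center, extent, angle = 0, severity = 0.7,
                          seed = 1L) {
  kinds <- c("fold", "dark_spot_foreign", "pen_marking", "air_bubble_edge", "pigment")
  stop_if_not(kind %in% kinds, "unknown artifact kind: ", kind)
  stop_if_not(severity >= 0 && severity <= 1, "severity must be in [0, 1]")
  stop_if_not(extent > 0, "extent must be positive")
  structure(list(kind = kind, center = as.numeric(center),
                 extent = as.numeric(extent), angle = as.numeric(angle),
                 severity = as.numeric(severity), seed = as.integer(seed)),
            class = "qc_artifact_spec")
}

#' Specification of the synthetic out-of-focus procedure
#'
#' A random smooth binary map selects the out-of-focus region; the image under
#' the map is blurred with a Gaussian kernel whose size is drawn from
#' `kernel_sizes`. The map threshold is chosen so that at least `min_frac` of
#' the region's pixels end up labeled out-of-focus.
#'
#' @param min_frac Minimum out-of-focus fraction of the region, in `(0, 1]`.
#'   Default 0.30.
#' @param kernel_sizes Odd kernel sizes the blur is drawn from; default
#'   `{3, 5, ..., 17}`.
#' @param seed Integer seed.
#' @return An object of class `qc_oof_spec`.
#' @export
oof_spec <- function(min_frac = 0.30, kernel_sizes = seq(3L, 17L, 2L), seed = 1L) {
  stop_if_not(min_frac > 0 && min_frac <= 1, "min_frac must be in (0, 1]")
  stop_if_not(all(kernel_sizes >= 1) && all(kernel_sizes %% 2 == 1),
              "kernel sizes must be odd and >= 1")
  structure(list(min_frac = min_frac, kernel_sizes = as.integer(kernel_sizes),
                 seed = as.integer(seed)), class = "qc_oof_spec")
}

#' Specification of a whole synthetic slide
#'
#' @param size Pixel dimensions `c(w, h)`, at least 64 x 64.
#' @param mpp Microns per pixel of the slide; default 1.0 (10x).
#' @param tissue_frac Target tissue coverage in `(0, 1)`; default 0.65.
#' @param artifacts List of [artifact_spec] applied in order.
#' @param oof Optional [oof_spec] applied last.
#' @param seed Integer seed.
#' @return An object of class `qc_slide_spec`.
#' @export
slide_spec <- function(size = c(512, 512), mpp = 1.0, tissue_frac = 0.65,
                       artifacts = list(), oof = NULL, seed = 1L) {
  stop_if_not(length(size) == 2 && all(size >= 64), "size must be at least 64 x 64")
  stop_if_not(tissue_frac > 0 && tissue_frac < 1, "tissue_frac must be in (0, 1)")
  stop_if_not(is.null(oof) || inherits(oof, "qc_oof_spec"), "oof must be an oof_spec")
  structure(list(size = as.integer(size), mpp = as.numeric(mpp),
                 tissue_frac = tissue_frac, artifacts = artifacts, oof = oof,
                 seed = as.integer(seed)), class = "qc_slide_spec")
}

labeled_slide <- function(image, gt, provenance = NULL) {
  stop_if_not(identical(dim(image$pixels)[1:2], dim(gt$labels)),
              "image and ground truth dims differ")
  stop_if_not(abs(image$mpp - gt$mpp) < 1e-9, "image and ground truth MPP differ")
  structure(list(image = image, gt = gt, provenance = provenance),
            class = "qc_labeled_slide")
}

#' @export
print.qc_labeled_slide <- function(x, ...) {
  cat("<qc_labeled_slide>\n  "); print(x$image); cat("  "); print(x$gt)
  invisible(x)
}

# stain colours (RGB in [0,1])
.eosin <- c(0.86, 0.58, 0.70)      # pink cytoplasm/stroma
.hematox <- c(0.42, 0.28, 0.58)    # purple nuclei-dense areas
.nucleus <- c(0.24, 0.13, 0.38)

#' Generate H&E-like tissue texture with ground truth
#'
#' Produces a near-white background with a contiguous tissue region drawn from
#' a pink/purple stain palette, coarse stain mottling, fine per-pixel grain
#' and scattered nucleus-like dark speckles (the high-frequency content that
#' distinguishes in-focus from out-of-focus tissue).
#'
#' @param size Pixel dims `c(w, h)`.
#' @param mpp Microns per pixel.
#' @param tissue_frac Target tissue coverage in `(0, 1)`; achieved coverage is
#'   exact up to ties in the underlying random field.
#' @param seed Integer seed; the generator is a pure function of it.
#' @return A `qc_labeled_slide` whose ground truth uses the artifact scheme
#'   and contains only `background` and `tissue_no_artifact`.
#' @export
gen_tissue_texture <- function(size = c(512, 512), mpp = 1.0, tissue_frac = 0.65,
                               seed = 1L) {
  stop_if_not(tissue_frac > 0 && tissue_frac < 1, "tissue_frac must be in (0, 1)")
  stop_if_not(length(size) == 2 && all(size >= 64), "size must be at least 64 x 64")
  w <- as.integer(size[1]); h <- as.integer(size[2])
  with_seed(seed, {
    shape <- smooth_noise_field(h, w, cell = max(24, round(min(h, w) / 6)))
    thr <- stats::quantile(shape, 1 - tissue_frac, names = FALSE)
    tissue <- shape > thr

    mix <- stats::pnorm(smooth_noise_field(h, w, cell = max(8, round(min(h, w) / 16))))
    px <- array(0, c(h, w, 3L))
    for (ch in 1:3)
      px[, , ch] <- .eosin[ch] * (1 - mix) + .hematox[ch] * mix
    # fine grain + nucleus speckles inside tissue
    grain <- matrix(stats::rnorm(h * w, sd = 0.045), h, w)
    spk <- matrix(stats::runif(h * w) < 0.06, h, w) & tissue
    for (ch in 1:3) {
      v <- px[, , ch] + grain
      v[spk] <- v[spk] * 0.35 + .nucleus[ch] * 0.65
      px[, , ch] <- v
    }
    # glass background: bright, slightly uneven, low-noise
    bgfield <- 0.965 + 0.015 * smooth_noise_field(h, w, cell = max(32, round(min(h, w) / 4))) +
      matrix(stats::rnorm(h * w, sd = 0.006), h, w)
    bg <- clamp(bgfield, 0.9, 1)
    for (ch in 1:3) {
      v <- px[, , ch]
      v[!tissue] <- bg[!tissue]
      px[, , ch] <- v
    }
    px <- clamp(px)
    gt <- matrix(0L, h, w)
    gt[tissue] <- class_index(artifact_scheme(), "tissue_no_artifact")
    labeled_slide(qc_raster(px, mpp), label_mask(gt, mpp, artifact_scheme()),
                  provenance = slide_spec(c(w, h), mpp, tissue_frac, seed = seed))
  })
}

# squared distance from every pixel (grid) to a segment p1-p2 (0-based coords)
.dist2_segment <- function(h, w, p1, p2) {
  X <- matrix(rep(seq_len(w) - 1, each = h), h, w)
  Y <- matrix(rep(seq_len(h) - 1, times = w), h, w)
  dx <- p2[1] - p1[1]; dy <- p2[2] - p1[2]
  len2 <- dx * dx + dy * dy
  if (len2 < 1e-12) return((X - p1[1])^2 + (Y - p1[2])^2)
  t <- clamp(((X - p1[1]) * dx + (Y - p1[2]) * dy) / len2, 0, 1)
  (X - (p1[1] + t * dx))^2 + (Y - (p1[2] + t * dy))^2
}

# distance mask to a polyline (list of points), vectorised per segment
.polyline_mask <- function(h, w, pts, width) {
  d2 <- NULL
  for (i in seq_len(nrow(pts) - 1)) {
    s <- .dist2_segment(h, w, pts[i, ], pts[i + 1, ])
    d2 <- if (is.null(d2)) s else pmin(d2, s)
  }
  d2 <= (width / 2)^2
}

.ellipse_mask <- function(h, w, center, rx, ry) {
  X <- matrix(rep(seq_len(w) - 1, each = h), h, w)
  Y <- matrix(rep(seq_len(h) - 1, times = w), h, w)
  ((X - center[1]) / rx)^2 + ((Y - center[2]) / ry)^2 <= 1
}

# overlay a flat colour with per-pixel alpha on the image
.blend <- function(px, mask, col, alpha) {
  for (ch in 1:3) {
    v <- px[, , ch]
    v[mask] <- v[mask] * (1 - alpha) + col[ch] * alpha
    px[, , ch] <- v
  }
  px
}

# write class `idx` into gt where `mask`, respecting precedence; classes that
# are physically bound to tissue (`tissue_only = TRUE`) never label background
.write_label <- function(gt, mask, idx, tissue_only = FALSE) {
  rank <- precedence_rank()
  writable <- mask & (rank[gt + 1L] < rank[idx + 1L])
  if (tissue_only) writable <- writable & (gt != 0L)
  gt[writable] <- idx
  gt
}

#' Inject one artifact into a labeled slide
#'
#' The image is altered according to the artifact kind and the ground truth is
#' updated under a fixed precedence order (pen marking > air bubble/edge >
#' fold > dark spot/foreign > out-of-focus > tissue > background): opaque
#' artifacts occlude translucent ones. Folds and dark spots are bound to
#' tissue; pen markings and air-bubble rims may extend over background and
#' are labeled there too. `pigment` alters the image only.
#'
#' @param labeled A `qc_labeled_slide`.
#' @param spec An [artifact_spec].
#' @return The modified `qc_labeled_slide`.
#' @export
inject_artifact <- function(labeled, spec) {
  stop_if_not(inherits(labeled, "qc_labeled_slide"), "labeled must be a qc_labeled_slide")
  stop_if_not(inherits(spec, "qc_artifact_spec"), "spec must be an artifact_spec")
  px <- labeled$image$pixels
  gt <- labeled$gt$labels
  h <- nrow(gt); w <- ncol(gt)
  cx <- spec$center[1]; cy <- spec$center[2]
  stop_if_not(cx >= 0 && cy >= 0 && cx < w && cy < h, "artifact centre outside slide")
  sc <- artifact_scheme()
  with_seed(spec$seed, switch(
    spec$kind,
    fold = {
      dx <- cos(spec$angle); dy <- sin(spec$angle)
      p1 <- c(cx - dx * spec$extent, cy - dy * spec$extent)
      p2 <- c(cx + dx * spec$extent, cy + dy * spec$extent)
      width <- max(4, spec$extent * 0.22)
      band <- .polyline_mask(h, w, rbind(p1, p2), width)
      # a fold doubles the section: sample the texture shifted across the band
      # and take the darker of the two layers, then darken further
      sh <- max(1L, round(width / 3))
      shifted <- px[c(rep(1L, sh), seq_len(h - sh)), , , drop = FALSE]
      dark <- 1 - (0.25 + 0.35 * spec$severity)
      for (ch in 1:3) {
        v <- px[, , ch]
        v[band] <- pmin(v[band], shifted[, , ch][band]) * dark
        px[, , ch] <- v
      }
      gt <- .write_label(gt, band, class_index(sc, "fold"), tissue_only = TRUE)
    },
    air_bubble_edge = {
      rx <- spec$extent; ry <- spec$extent * 0.75
      outer <- .ellipse_mask(h, w, c(cx, cy), rx, ry)
      inner <- .ellipse_mask(h, w, c(cx, cy), max(1, rx - 3), max(1, ry - 3))
      rim <- outer & !inner
      px <- .blend(px, inner, c(0.93, 0.90, 0.92), 0.35 + 0.45 * spec$severity)
      px <- .blend(px, rim, c(0.22, 0.20, 0.22), 0.75 + 0.25 * spec$severity)
      gt <- .write_label(gt, outer, class_index(sc, "air_bubble_edge"))
    },
    dark_spot_foreign = {
      n_blob <- sample(3:7, 1)
      mask <- matrix(FALSE, h, w)
      for (i in seq_len(n_blob)) {
        bc <- c(cx, cy) + stats::runif(2, -spec$extent, spec$extent)
        r <- stats::runif(1, 1.5, max(2.5, spec$extent * 0.18))
        mask <- mask | .ellipse_mask(h, w, bc, r, r)
      }
      if (stats::runif(1) < 0.5) {  # thread-like foreign object
        pts <- cbind(cx + cumsum(stats::runif(5, -1, 1)) * spec$extent * 0.5,
                     cy + cumsum(stats::runif(5, -1, 1)) * spec$extent * 0.5)
        mask <- mask | .polyline_mask(h, w, pts, 2.5)
      }
      px <- .blend(px, mask, c(0.10, 0.08, 0.07), 0.6 + 0.4 * spec$severity)
      gt <- .write_label(gt, mask, class_index(sc, "dark_spot_foreign"),
                         tissue_only = TRUE)
    },
    pen_marking = {
      dx <- cos(spec$angle); dy <- sin(spec$angle)
      ctrl <- c(cx - dy * spec$extent * 0.5, cy + dx * spec$extent * 0.5)
      t <- seq(0, 1, length.out = 12)
      p1 <- c(cx - dx * spec$extent, cy - dy * spec$extent)
      p2 <- c(cx + dx * spec$extent, cy + dy * spec$extent)
      pts <- cbind((1 - t)^2 * p1[1] + 2 * t * (1 - t) * ctrl[1] + t^2 * p2[1],
                   (1 - t)^2 * p1[2] + 2 * t * (1 - t) * ctrl[2] + t^2 * p2[2])
      width <- max(5, spec$extent * 0.14)
      stroke <- .polyline_mask(h, w, pts, width)
      col <- switch(sample(3, 1), c(0.02, 0.35, 0.12), c(0.05, 0.10, 0.55),
                    c(0.05, 0.05, 0.05))
      px <- .blend(px, stroke, col, 0.55 + 0.45 * spec$severity)
      gt <- .write_label(gt, stroke, class_index(sc, "pen_marking"))
    },
    pigment = {
      # melanin-like dark-brown speckling confined to tissue; mimics the
      # texture of air-bubble rims but is biology, so gt stays unchanged
      field <- smooth_noise_field(h, w, cell = max(6, round(spec$extent / 3)))
      blob <- .ellipse_mask(h, w, c(cx, cy), spec$extent, spec$extent * 0.8)
      mask <- blob & (field > 0.3) & (gt == class_index(sc, "tissue_no_artifact"))
      px <- .blend(px, mask, c(0.22, 0.13, 0.06), 0.35 + 0.5 * spec$severity)
    },
    stop_if_not(FALSE, "unknown artifact kind: ", spec$kind)
  ))
  labeled_slide(qc_raster(clamp(px), labeled$image$mpp),
                label_mask(gt, labeled$gt$mpp, labeled$gt$scheme),
                provenance = labeled$provenance)
}

#' Inject a synthetic out-of-focus region
#'
#' A smooth random field is thresholded to a binary map covering enough
#' artifact-free tissue that at least `min_frac` of all pixels can be labeled
#' `out_of_focus`; the image under the map is blurred with a Gaussian kernel
#' drawn from `kernel_sizes`. Only pixels whose current label is
#' `tissue_no_artifact` are relabeled (out-of-focus has the lowest precedence
#' among artifacts).
#'
#' @param labeled A `qc_labeled_slide`.
#' @param oof An [oof_spec].
#' @return The modified `qc_labeled_slide`; its achieved out-of-focus fraction
#'   (labeled pixels / all pixels) is at least `oof$min_frac`.
#' @export
inject_oof <- function(labeled, oof = oof_spec()) {
  stop_if_not(inherits(labeled, "qc_labeled_slide"), "labeled must be a qc_labeled_slide")
  stop_if_not(inherits(oof, "qc_oof_spec"), "oof must be an oof_spec")
  gt <- labeled$gt$labels
  h <- nrow(gt); w <- ncol(gt)
  sc <- labeled$gt$scheme
  eligible <- gt == class_index(sc, "tissue_no_artifact")
  need <- ceiling(oof$min_frac * length(gt))
  stop_if_not(sum(eligible) >= need,
              "not enough artifact-free tissue to reach min_frac ", oof$min_frac,
              class = "slideqc_generation_error")
  with_seed(oof$seed, {
    k <- oof$kernel_sizes[sample.int(length(oof$kernel_sizes), 1)]
    field <- smooth_noise_field(h, w, cell = max(24, round(min(h, w) / 6)))
    # threshold on the field restricted to eligible pixels; exact coverage
    vals <- sort(field[eligible], decreasing = TRUE)
    thr <- vals[need]
    map <- field >= thr
    blurred <- blur_rgb(labeled$image$pixels, k)
    px <- labeled$image$pixels
    for (ch in 1:3) {
      v <- px[, , ch]
      v[map] <- blurred[, , ch][map]
      px[, , ch] <- v
    }
    gt <- .write_label(gt, map & eligible, class_index(sc, "out_of_focus"))
    out <- labeled_slide(qc_raster(px, labeled$image$mpp),
                         label_mask(gt, labeled$gt$mpp, sc),
                         provenance = labeled$provenance)
    attr(out, "oof_kernel") <- k
    attr(out, "oof_map") <- map
    out
  })
}

#' Compose a full synthetic slide from a specification
#'
#' Order of operations: tissue texture, then artifacts in list order, then the
#' optional out-of-focus pass last. Ground truth respects the global artifact
#' precedence and the result is a pure function of the spec (and its seeds).
#'
#' @param spec A [slide_spec].
#' @return A `qc_labeled_slide`.
#' @export
compose_synthetic_slide <- function(spec) {
  stop_if_not(inherits(spec, "qc_slide_spec"), "spec must be a slide_spec")
  out <- gen_tissue_texture(spec$size, spec$mpp, spec$tissue_frac, seed = spec$seed)
  for (a in spec$artifacts) out <- inject_artifact(out, a)
  if (!is.null(spec$oof)) out <- inject_oof(out, spec$oof)
  out$provenance <- spec
  out
}

# random artifact spec of a given kind, geometry drawn inside (w, h)
.random_artifact <- function(kind, w, h, seed) {
  with_seed(seed, {
    margin <- 0.2
    center <- c(stats::runif(1, w * margin, w * (1 - margin)),
                stats::runif(1, h * margin, h * (1 - margin)))
    artifact_spec(kind, center = center,
                  extent = stats::runif(1, 0.14, 0.30) * min(w, h),
                  angle = stats::runif(1, 0, pi),
                  severity = stats::runif(1, 0.5, 1),
                  seed = sample.int(.Machine$integer.max, 1))
  })
}

#' Generate a dataset of labeled synthetic patches
#'
#' Each patch is an independently composed synthetic slide of size
#' `patch_size` square. With `balanced = TRUE` the artifact kinds (and the
#' out-of-focus pass) are assigned round-robin so that every artifact class
#' appears in well over 5\% of patches; otherwise kinds are drawn at random.
#'
#' @param n Number of patches (>= 1).
#' @param patch_size Patch side length in pixels.
#' @param mpp Microns per pixel of the patches.
#' @param seed Integer seed; the dataset is a pure function of `(n, seed, ...)`.
#' @param balanced Balance artifact classes across patches (default `TRUE`).
#' @param tissue_frac Tissue coverage passed to the texture generator.
#' @param with_artifacts Set `FALSE` for clean tissue/background patches
#'   (tissue-detection training data).
#' @return List of `n` `qc_labeled_slide` patches.
#' @export
gen_dataset <- function(n, patch_size = 128, mpp = 1.0, seed = 1L,
                        balanced = TRUE, tissue_frac = 0.65,
                        with_artifacts = TRUE) {
  stop_if_not(is_count(n), "n must be a positive integer")
  kinds <- c("fold", "dark_spot_foreign", "pen_marking", "air_bubble_edge")
  seeds <- with_seed(seed, matrix(sample.int(.Machine$integer.max, 5 * n), ncol = 5))
  lapply(seq_len(n), function(i) {
    s <- seeds[i, ]
    if (!with_artifacts) {
      arts <- list(); use_oof <- FALSE
    } else if (balanced) {
      slot <- (i - 1L) %% 5L                      # 5th slot: clean patch
      arts <- if (slot < 4L)
        list(.random_artifact(kinds[slot + 1L], patch_size, patch_size, s[1]))
      else list()
      if (with_seed(s[2], stats::runif(1)) < 0.3)  # occasional second artifact
        arts <- c(arts, list(.random_artifact(
          with_seed(s[2], sample(kinds, 1)), patch_size, patch_size, s[3])))
      use_oof <- (i %% 5L) %in% c(0L, 2L)          # 40% of patches
    } else {
      pick <- with_seed(s[1], stats::runif(4)) < 0.35
      arts <- lapply(which(pick), function(j)
        .random_artifact(kinds[j], patch_size, patch_size, s[3] + j))
      use_oof <- with_seed(s[2], stats::runif(1)) < 0.4
    }
    oof <- if (use_oof) oof_spec(min_frac = 0.30, seed = s[4]) else NULL
    # unlucky artifact placements can leave too little clear tissue for the
    # OOF minimum; retry deterministically with a fresh texture seed
    for (attempt in 0:4) {
      out <- tryCatch(
        compose_synthetic_slide(slide_spec(
          size = c(patch_size, patch_size), mpp = mpp, tissue_frac = tissue_frac,
          artifacts = arts, oof = oof, seed = (s[5] + attempt) %% .Machine$integer.max)),
        slideqc_generation_error = function(e) NULL)
      if (!is.null(out)) break
      if (attempt == 4) stop("could not compose patch ", i, " within retry budget")
      arts <- lapply(arts, function(a) { a$extent <- a$extent * 0.7; a })
    }
    out
  })
}

#' Write a labeled dataset to disk
#'
#' Writes paired image and label PNGs (`patch_<i>.png`,
#' `patch_<i>_mask.png`, label value = class index) plus a `manifest.csv`
#' listing the classes present in each patch.
#'
#' @param dataset List of `qc_labeled_slide` (from [gen_dataset]).
#' @param dir Output directory (created if needed).
#' @return The manifest as a data frame, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(dataset), function(i) {
    ls <- dataset[[i]]
    img_path <- file.path(dir, sprintf("patch_%04d.png", i))
    mask_path <- file.path(dir, sprintf("patch_%04d_mask.png", i))
    write_raster(ls$image, img_path)
    write_mask_png(ls$gt, mask_path)
    present <- sort(unique(as.vector(ls$gt$labels)))
    data.frame(patch = i, image = basename(img_path), mask = basename(mask_path),
               mpp = ls$image$mpp,
               classes = paste(ls$gt$scheme$names[present + 1L], collapse = ";"))
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Reduce an artifact-scheme mask to the 2-class tissue scheme
#'
#' Any non-background label becomes `tissue`; used to derive tissue-detection
#' ground truth from artifact-scheme ground truth.
#'
#' @param mask A `qc_mask` in the artifact scheme.
#' @return A `qc_mask` in the tissue scheme.
#' @export
as_tissue_mask <- function(mask) {
  stop_if_not(inherits(mask, "qc_mask"), "mask must be a qc_mask")
  label_mask((mask$labels > 0L) + 0L, mask$mpp, tissue_scheme())
}
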