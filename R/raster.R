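#' RGB raster bound to a physical resolution
#'
#' The basic image container used throughout the package: an 8-bit-per-channel
#' RGB raster stored as a numeric array in `[0, 1]` together with its physical
#' resolution in microns per pixel (MPP).
#'
#' @param pixels Numeric array `h x w x 3` with values in `[0, 1]`, or an
#'   `h x w` matrix which is expanded to three identical channels.
#' @param mpp Microns per pixel (single positive number).
#' @return An object of class `qc_raster` with fields `pixels` and `mpp`.
#' @export
qc_raster <- function(pixels, mpp) {
  if (is.matrix(pixels)) pixels <- array(rep(pixels, 3L), c(dim(pixels), 3L))
  stop_if_not(is.array(pixels) && length(dim(pixels)) == 3L && dim(pixels)[3] == 3L,
              "pixels must be an h x w x 3 array")
  stop_if_not(dim(pixels)[1] >= 1 && dim(pixels)[2] >= 1, "raster must be at least 1 x 1")
  stop_if_not(is.numeric(mpp) && length(mpp) == 1L && is.finite(mpp) && mpp > 0,
              "mpp must be a single positive number")
  structure(list(pixels = pixels, mpp = as.numeric(mpp)), class = "qc_raster")
}

#' @export
print.qc_raster <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<qc_raster> %d x %d px (w x h), MPP %.4g um/px\n", d[2], d[1], x$mpp))
  invisible(x)
}

#' @export
dim.qc_raster <- function(x) dim(x$pixels)[1:2]

raster_w <- function(x) dim(x$pixels)[2]
raster_h <- function(x) dim(x$pixels)[1]

#' Convert objective magnification to microns per pixel
#'
#' Uses the linear scanner convention `mpp = 10 / power`, anchored by the two
#' standard pairs 40x ~ 0.25 MPP and 10x ~ 1.0 MPP.
#'
#' @param power Objective magnification (e.g. 40, 10, 7, 5, 1). Vectorised.
#' @return Microns per pixel for each power.
#' @examples
#' mpp_for_power(40)  # 0.25
#' mpp_for_power(10)  # 1.0
#' @export
mpp_for_power <- function(power) {
  stop_if_not(is.numeric(power) && all(is.finite(power)) && all(power > 0),
              "power must be positive")
  10.0 / power
}

#' Multi-resolution slide pyramid
#'
#' Wraps an ordered list of progressively downsampled RGB rasters as a slide
#' pyramid. Level 0 is full resolution; each further level's downsample factor
#' relative to level 0 must be strictly increasing and its dimensions must
#' equal `ceiling(base_dims / downsample)`.
#'
#' @param levels List of [qc_raster] (or bare `h x w x 3` arrays), largest first.
#' @param base_mpp MPP of level 0. Defaults to the MPP of the first raster.
#' @return An object of class `qc_pyramid` with fields `levels`, `base_mpp`,
#'   `downsamples`.
#' @export
slide_pyramid <- function(levels, base_mpp = NULL) {
  stop_if_not(is.list(levels) && length(levels) >= 1L, "need at least one level")
  levels <- lapply(levels, function(l) {
    if (inherits(l, "qc_raster")) l else qc_raster(l, mpp = base_mpp %||% 1)
  })
  if (is.null(base_mpp)) base_mpp <- levels[[1]]$mpp
  w0 <- raster_w(levels[[1]]); h0 <- raster_h(levels[[1]])
  ds <- vapply(levels, function(l) w0 / raster_w(l), numeric(1))
  ds <- round(ds * 1e6) / 1e6
  stop_if_not(abs(ds[1] - 1) < 1e-9, "level 0 must be full resolution")
  stop_if_not(all(diff(ds) > 0), "downsamples must be strictly increasing")
  for (i in seq_along(levels)) {
    stop_if_not(raster_w(levels[[i]]) == ceiling(w0 / ds[i]) &&
                raster_h(levels[[i]]) == ceiling(h0 / ds[i]),
                "level ", i - 1, " dims inconsistent with its downsample")
    levels[[i]]$mpp <- base_mpp * ds[i]
  }
  structure(list(levels = levels, base_mpp = as.numeric(base_mpp),
                 downsamples = ds), class = "qc_pyramid")
}

#' @export
print.qc_pyramid <- function(x, ...) {
  cat(sprintf("<qc_pyramid> %d level(s), base MPP %.4g um/px\n",
              length(x$levels), x$base_mpp))
  for (i in seq_along(x$levels))
    cat(sprintf("  level %d: %d x %d px, downsample %.4g\n", i - 1,
                raster_w(x$levels[[i]]), raster_h(x$levels[[i]]), x$downsamples[i]))
  invisible(x)
}

#' Build a pyramid from a single full-resolution raster
#'
#' Plain (non-pyramidal) images are wrapped as single-level pyramids; extra
#' levels can be materialised by area-average downsampling.
#'
#' @param raster A [qc_raster].
#' @param downsamples Increasing downsample factors, starting at 1.
#' @return A [slide_pyramid].
#' @export
build_pyramid <- function(raster, downsamples = 1) {
  stop_if_not(inherits(raster, "qc_raster"), "raster must be a qc_raster")
  stop_if_not(downsamples[1] == 1 && all(diff(downsamples) > 0),
              "downsamples must start at 1 and increase")
  w0 <- raster_w(raster); h0 <- raster_h(raster)
  levels <- lapply(downsamples, function(d) {
    if (d == 1) return(raster)
    qc_raster(resize_area(raster$pixels, ceiling(h0 / d), ceiling(w0 / d)),
              mpp = raster$mpp * d)
  })
  slide_pyramid(levels, base_mpp = raster$mpp)
}

#' Slide extent (width, height) at a target MPP
#' @param slide A [slide_pyramid].
#' @param target_mpp Target resolution in microns per pixel.
#' @return Integer vector `c(w, h)`.
#' @export
slide_dims_at <- function(slide, target_mpp) {
  stop_if_not(inherits(slide, "qc_pyramid"), "slide must be a qc_pyramid")
  c(ceiling(raster_w(slide$levels[[1]]) * slide$base_mpp / target_mpp),
    ceiling(raster_h(slide$levels[[1]]) * slide$base_mpp / target_mpp))
}

# Sparse row-weight matrix for 1-D area-average resampling: output cell j
# covers the source interval [offset + (j-1)*scale, offset + j*scale).
area_weights <- function(n_out, offset, scale, n_src) {
  ii <- integer(0); jj <- integer(0); ww <- numeric(0)
  for (j in seq_len(n_out)) {
    a <- offset + (j - 1) * scale
    b <- offset + j * scale
    a <- max(a, 0); b <- min(b, n_src)
    lo <- max(1L, floor(a) + 1L)
    hi <- min(n_src, ceiling(b))
    if (hi < lo) { lo <- min(n_src, lo); hi <- lo }
    idx <- lo:hi
    w <- pmin(b, idx) - pmax(a, idx - 1)
    w[w < 0] <- 0
    if (sum(w) <= 0) { w <- rep(0, length(idx)); w[1] <- 1 }
    ii <- c(ii, rep.int(j, length(idx))); jj <- c(jj, idx); ww <- c(ww, w / sum(w))
  }
  m <- matrix(0, n_out, n_src)
  m[cbind(ii, jj)] <- ww
  m
}

# Area-average resample of an h x w x 3 array to (new_h, new_w), optionally of
# a sub-window starting at fractional source offset (off_y, off_x) with the
# given per-axis scale (source pixels per output pixel).
resize_area <- function(px, new_h, new_w, off_y = 0, off_x = 0,
                        scale_y = dim(px)[1] / new_h, scale_x = dim(px)[2] / new_w) {
  wr <- area_weights(new_h, off_y, scale_y, dim(px)[1])
  wc <- area_weights(new_w, off_x, scale_x, dim(px)[2])
  out <- array(0, c(new_h, new_w, 3L))
  for (ch in 1:3) out[, , ch] <- wr %*% px[, , ch] %*% t(wc)
  out
}

# Nearest-neighbour resample of a matrix to (new_h, new_w).
resize_nearest <- function(m, new_h, new_w) {
  ri <- pmin(nrow(m), pmax(1L, floor((seq_len(new_h) - 0.5) * nrow(m) / new_h) + 1L))
  ci <- pmin(ncol(m), pmax(1L, floor((seq_len(new_w) - 0.5) * ncol(m) / new_w) + 1L))
  m[ri, ci, drop = FALSE]
}

#' Read a region of a slide pyramid at a target resolution
#'
#' Picks the finest pyramid level whose MPP does not exceed `target_mpp` and
#' area-average resamples the requested window to exactly `w x h` output
#' pixels. The box is expressed in pixels at `target_mpp`, 0-based, half-open.
#'
#' @param slide A [slide_pyramid].
#' @param target_mpp Requested output resolution (microns per pixel); must be
#'   at least the base MPP of the pyramid.
#' @param box Numeric `c(x, y, w, h)` at `target_mpp`.
#' @return A [qc_raster] of dimensions `w x h` at `target_mpp`.
#' @export
read_region <- function(slide, target_mpp, box) {
  stop_if_not(inherits(slide, "qc_pyramid"), "slide must be a qc_pyramid")
  stop_if_not(length(box) == 4 && all(is.finite(box)), "box must be c(x, y, w, h)")
  x <- box[1]; y <- box[2]; w <- box[3]; h <- box[4]
  stop_if_not(w >= 1 && h >= 1, "box must have positive size")
  stop_if_not(target_mpp >= slide$base_mpp * (1 - 1e-9),
              "target_mpp below base resolution of the pyramid",
              class = "slideqc_resolution_error")
  ext <- slide_dims_at(slide, target_mpp)
  stop_if_not(x >= 0 && y >= 0 && x + w <= ext[1] && y + h <= ext[2],
              "box out of bounds at target MPP", class = "slideqc_bounds_error")
  level_mpps <- slide$base_mpp * slide$downsamples
  li <- max(which(level_mpps <= target_mpp * (1 + 1e-9)))
  lev <- slide$levels[[li]]
  scale <- target_mpp / level_mpps[li]
  if (abs(scale - 1) < 1e-9 && x == floor(x) && y == floor(y)) {
    px <- lev$pixels[(y + 1):(y + h), (x + 1):(x + w), , drop = FALSE]
  } else {
    px <- resize_area(lev$pixels, h, w, off_y = y * scale, off_x = x * scale,
                      scale_y = scale, scale_x = scale)
  }
  qc_raster(px, mpp = target_mpp)
}

#' Read a slide image from disk
#'
#' Multi-page TIFFs are read as pyramids (pages ordered by size); single-page
#' TIFF and PNG images are wrapped as single-level pyramids. The MPP is taken
#' from the `mpp` argument or from a JSON sidecar `<path>.json` containing
#' `{"mpp": <value>}`.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @param mpp Base MPP; overrides any sidecar value.
#' @return A [slide_pyramid].
#' @export
read_slide <- function(path, mpp = NULL) {
  stop_if_not(file.exists(path), "no such file: ", path)
  if (is.null(mpp)) {
    sidecar <- paste0(path, ".json")
    stop_if_not(file.exists(sidecar),
                "MPP not given and no sidecar JSON found at ", sidecar)
    mpp <- jsonlite::read_json(sidecar)$mpp
    stop_if_not(!is.null(mpp), "sidecar JSON has no 'mpp' field: ", sidecar)
  }
  ext <- tolower(tools::file_ext(path))
  to_rgb <- function(a) {
    if (is.matrix(a)) a <- array(rep(a, 3L), c(dim(a), 3L))
    if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
    a
  }
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, to_rgb)
    ord <- order(vapply(pages, function(p) -prod(dim(p)[1:2]), numeric(1)))
    pages <- pages[ord]
    levels <- lapply(seq_along(pages), function(i) {
      d <- dim(pages[[1]])[2] / dim(pages[[i]])[2]
      qc_raster(pages[[i]], mpp = mpp * d)
    })
    slide_pyramid(levels, base_mpp = mpp)
  } else if (ext == "png") {
    build_pyramid(qc_raster(to_rgb(png::readPNG(path)), mpp = mpp))
  } else {
    stop_if_not(FALSE, "unsupported slide format: .", ext)
  }
}

#' Write a raster to a PNG file with a JSON MPP sidecar
#' @param raster A [qc_raster].
#' @param path Output `.png` path; the MPP is recorded in `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_raster <- function(raster, path) {
  stop_if_not(inherits(raster, "qc_raster"), "raster must be a qc_raster")
  png::writePNG(clamp(raster$pixels), path)
  jsonlite::write_json(list(mpp = raster$mpp), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
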