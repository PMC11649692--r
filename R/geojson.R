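# Exact pixel-boundary polygonisation of label masks and GeoJSON export.
#
# Every labeled pixel (r, c) (1-based) occupies the unit square
# x in [c-1, c], y in [r-1, r] (y down). For each class, the directed
# boundary edges of its pixel set are chained into closed rings on the
# integer lattice, so rasterising the rings back (even-odd rule at pixel
# centres) reproduces the mask exactly. Rings are emitted individually
# (holes are rings too) and are meant to be filled with the even-odd rule.

# rings (list of n x 2 coordinate matrices) for a binary matrix
trace_rings <- function(bin) {
  h <- nrow(bin); w <- ncol(bin)
  idx <- which(bin, arr.ind = TRUE)
  if (nrow(idx) == 0) return(list())
  r <- idx[, 1]; c <- idx[, 2]
  inside <- function(rr, cc) {
    ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
    res <- logical(length(rr)); res[ok] <- bin[cbind(rr[ok], cc[ok])]
    res
  }
  vkey <- function(x, y) x * (h + 1) + y
  # directed edges with the region kept on a consistent side
  from <- integer(0); to <- integer(0)
  top <- !inside(r - 1, c)
  from <- c(from, vkey(c[top] - 1, r[top] - 1)); to <- c(to, vkey(c[top], r[top] - 1))
  bot <- !inside(r + 1, c)
  from <- c(from, vkey(c[bot], r[bot])); to <- c(to, vkey(c[bot] - 1, r[bot]))
  lef <- !inside(r, c - 1)
  from <- c(from, vkey(c[lef] - 1, r[lef])); to <- c(to, vkey(c[lef] - 1, r[lef] - 1))
  rig <- !inside(r, c + 1)
  from <- c(from, vkey(c[rig], r[rig] - 1)); to <- c(to, vkey(c[rig], r[rig]))
  # chain edges into closed loops: out-degree equals in-degree at every vertex
  ord <- order(from)
  from_s <- from[ord]; to_s <- to[ord]
  starts <- match(unique(from_s), from_s)
  first_edge <- stats::setNames(starts, unique(from_s))
  n_at <- stats::setNames(tabulate(match(from_s, unique(from_s))), unique(from_s))
  used <- logical(length(from_s))
  next_unused <- function(v) {
    key <- as.character(v)
    i0 <- first_edge[[key]]
    if (is.null(i0)) return(NA_integer_)
    for (i in i0:(i0 + n_at[[key]] - 1L)) if (!used[i]) return(i)
    NA_integer_
  }
  rings <- list()
  for (e0 in seq_along(from_s)) {
    if (used[e0]) next
    path <- integer(0)
    e <- e0
    repeat {
      used[e] <- TRUE
      path <- c(path, from_s[e])
      v <- to_s[e]
      if (v == from_s[e0]) break
      e <- next_unused(v)
      if (is.na(e)) break   # should not happen on valid masks
    }
    path <- c(path, from_s[e0])  # close
    xs <- path %/% (h + 1); ys <- path %% (h + 1)
    # drop collinear intermediate vertices
    keep <- rep(TRUE, length(xs))
    if (length(xs) > 3) {
      for (i in 2:(length(xs) - 1)) {
        if ((xs[i - 1] == xs[i] && xs[i] == xs[i + 1]) ||
            (ys[i - 1] == ys[i] && ys[i] == ys[i + 1])) keep[i] <- FALSE
      }
    }
    rings[[length(rings) + 1]] <- cbind(x = xs[keep], y = ys[keep])
  }
  rings
}

#' Polygonise a label mask
#'
#' Traces, for every non-background class present, the exact pixel-boundary
#' rings of its region. Ring coordinates are on the integer pixel lattice at
#' the mask's MPP; filling all of a class's rings with the even-odd rule
#' reproduces the class region pixel-exactly.
#'
#' @param mask A `qc_mask`.
#' @return Named list (by class name) of lists of `n x 2` ring coordinate
#'   matrices.
#' @export
mask_to_polygons <- function(mask) {
  stop_if_not(inherits(mask, "qc_mask"), "mask must be a qc_mask")
  present <- sort(unique(as.vector(mask$labels)))
  present <- present[present > 0]
  out <- lapply(present, function(ci) trace_rings(mask$labels == ci))
  names(out) <- mask$scheme$names[present + 1L]
  out
}

#' Write a label mask as a GeoJSON FeatureCollection
#'
#' One feature per class with a MultiPolygon geometry (each boundary ring as
#' its own polygon; fill with the even-odd rule). Class name, class index and
#' the mask MPP are stored in the feature properties.
#'
#' @param mask A `qc_mask`.
#' @param path Output `.geojson` path.
#' @return `path`, invisibly.
#' @export
write_mask_geojson <- function(mask, path) {
  polys <- mask_to_polygons(mask)
  features <- lapply(names(polys), function(nm) {
    coords <- lapply(polys[[nm]], function(ring)
      list(lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1], ring[i, 2]))))
    list(type = "Feature",
         properties = list(class = nm,
                           class_index = class_index(mask$scheme, nm),
                           mpp = mask$mpp, fill_rule = "evenodd"),
         geometry = list(type = "MultiPolygon", coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Rasterise class rings back to a binary matrix
#'
#' Even-odd scanline fill at pixel centres; exact inverse of [mask_to_polygons]
#' for the same dims.
#'
#' @param rings List of `n x 2` ring coordinate matrices (one class).
#' @param h,w Output dims in pixels.
#' @return Logical `h x w` matrix.
#' @export
rasterize_rings <- function(rings, h, w) {
  cross <- matrix(0L, h, w)
  for (ring in rings) {
    for (i in seq_len(nrow(ring) - 1)) {
      x0 <- ring[i, 1]; y0 <- ring[i, 2]; x1 <- ring[i + 1, 1]; y1 <- ring[i + 1, 2]
      if (x0 == x1 && y0 != y1 && x0 >= 1 && x0 <= w) {
        ys <- (min(y0, y1) + 1):max(y0, y1)   # rows whose centre the edge spans
        cross[ys, x0] <- cross[ys, x0] + 1L
      }
    }
  }
  # pixel centre of column c lies inside when an odd number of vertical edges
  # sit strictly to its right (lattice x >= c)
  parity <- if (w == 1) cross else
    t(apply(cross[, w:1, drop = FALSE], 1, cumsum))[, w:1, drop = FALSE]
  (parity %% 2L) == 1L
}

#' Read back a GeoJSON mask written by [write_mask_geojson]
#'
#' @param path GeoJSON path.
#' @param scheme The [class_scheme] the file was written with.
#' @param h,w Mask dims in pixels.
#' @return A `qc_mask` (classes painted in scheme order).
#' @export
read_mask_geojson <- function(path, scheme, h, w) {
  gj <- jsonlite::read_json(path)
  labels <- matrix(0L, h, w)
  mpp <- 1
  for (f in gj$features) {
    ci <- f$properties$class_index
    mpp <- f$properties$mpp %||% mpp
    rings <- lapply(f$geometry$coordinates, function(poly) {
      do.call(rbind, lapply(poly[[1]], function(pt) c(pt[[1]], pt[[2]])))
    })
    labels[rasterize_rings(rings, h, w)] <- as.integer(ci)
  }
  label_mask(labels, mpp, scheme)
}
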