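#' Segmentation class schemes
#'
#' A class scheme is an ordered list of class names with one display colour
#' per class. Index 0 is always `background`. Two schemes are used: the
#' 2-class tissue scheme and the 7-class artifact scheme in which air bubbles
#' are merged with slide edges and dark spots with foreign objects (the pairs
#' are visually near-identical at QC magnifications).
#'
#' @param names Character vector of unique class names; first must be
#'   `"background"`.
#' @param palette One colour per class (any form `grDevices::col2rgb` accepts).
#' @param kind `"tissue"` or `"artifact"`.
#' @return An object of class `qc_scheme` with fields `names`, `palette`
#'   (hex), `kind`.
#' @export
class_scheme <- function(names, palette, kind = c("tissue", "artifact")) {
  kind <- match.arg(kind)
  stop_if_not(is.character(names) && length(names) >= 1 && !anyDuplicated(names),
              "class names must be unique")
  stop_if_not(names[1] == "background", "class index 0 must be background")
  stop_if_not(length(palette) == length(names), "one palette colour per class")
  palette <- grDevices::rgb(t(grDevices::col2rgb(palette)), maxColorValue = 255)
  structure(list(names = names, palette = palette, kind = kind),
            class = "qc_scheme")
}

#' @export
print.qc_scheme <- function(x, ...) {
  cat(sprintf("<qc_scheme> %s (%d classes): %s\n", x$kind, length(x$names),
              paste(x$names, collapse = ", ")))
  invisible(x)
}

#' @rdname class_scheme
#' @export
tissue_scheme <- function() {
  class_scheme(c("background", "tissue"), c("#FFFFFF", "#2CA02C"), "tissue")
}

#' @rdname class_scheme
#' @export
artifact_scheme <- function() {
  class_scheme(
    c("background", "tissue_no_artifact", "fold", "dark_spot_foreign",
      "pen_marking", "air_bubble_edge", "out_of_focus"),
    c("#FFFFFF", "#C8C8C8", "#D62728", "#2CA02C", "#1F77B4", "#FF7F0E",
      "#9467BD"),
    "artifact")
}

n_classes <- function(scheme) length(scheme$names)

class_index <- function(scheme, name) {
  i <- match(name, scheme$names)
  stop_if_not(!anyNA(i), "unknown class name: ", paste(name[is.na(i)], collapse = ", "))
  i - 1L
}

same_scheme <- function(a, b) identical(a$names, b$names) && identical(a$kind, b$kind)

#' Integer label mask bound to a scheme and an MPP
#'
#' @param labels Integer matrix of 0-based class indices into `scheme`.
#' @param mpp Microns per pixel of the mask raster.
#' @param scheme A [class_scheme].
#' @return An object of class `qc_mask`.
#' @export
label_mask <- function(labels, mpp, scheme) {
  stop_if_not(is.matrix(labels) && nrow(labels) >= 1 && ncol(labels) >= 1,
              "labels must be a matrix")
  stop_if_not(inherits(scheme, "qc_scheme"), "scheme must be a qc_scheme")
  storage.mode(labels) <- "integer"
  rng <- range(labels)
  stop_if_not(rng[1] >= 0 && rng[2] < n_classes(scheme),
              "labels outside the scheme's class indices")
  stop_if_not(is.numeric(mpp) && length(mpp) == 1 && mpp > 0, "mpp must be positive")
  structure(list(labels = labels, mpp = as.numeric(mpp), scheme = scheme),
            class = "qc_mask")
}

#' @export
print.qc_mask <- function(x, ...) {
  tab <- tabulate(x$labels + 1L, nbins = n_classes(x$scheme))
  cat(sprintf("<qc_mask> %d x %d px (w x h), MPP %.4g, scheme %s\n",
              ncol(x$labels), nrow(x$labels), x$mpp, x$scheme$kind))
  present <- tab > 0
  cat("  ", paste(sprintf("%s: %.1f%%", x$scheme$names[present],
                          100 * tab[present] / sum(tab)), collapse = "; "), "\n")
  invisible(x)
}

#' @export
dim.qc_mask <- function(x) dim(x$labels)

#' Map the nine raw annotation classes onto the 7-class artifact scheme
#'
#' Annotation protocols distinguish air bubbles from slide edges and dark
#' spots from foreign objects; for segmentation the members of each pair are
#' merged into a single class (`air_bubble_edge`, `dark_spot_foreign`) because
#' they are visually near-identical. All other raw labels map to the
#' identically named artifact-scheme class (`tissue` to `tissue_no_artifact`).
#'
#' @param raw_label Character vector of raw annotation class names.
#' @return Integer 0-based indices into [artifact_scheme()].
#' @examples
#' merge_annotation_classes(c("slide_edge", "foreign_object", "fold"))
#' @export
merge_annotation_classes <- function(raw_label) {
  map <- c(background = "background", tissue = "tissue_no_artifact",
           fold = "fold", dark_spot = "dark_spot_foreign",
           foreign_object = "dark_spot_foreign", pen_marking = "pen_marking",
           air_bubble = "air_bubble_edge", slide_edge = "air_bubble_edge",
           out_of_focus = "out_of_focus")
  stop_if_not(all(raw_label %in% names(map)),
              "unknown raw annotation label: ",
              paste(setdiff(raw_label, names(map)), collapse = ", "))
  class_index(artifact_scheme(), unname(map[raw_label]))
}

# Precedence rank used when artifacts overlap in synthetic ground truth:
# opaque artifacts occlude translucent ones. Higher rank wins.
artifact_precedence <- function() {
  c(background = 0, tissue_no_artifact = 1, out_of_focus = 2,
    dark_spot_foreign = 3, fold = 4, air_bubble_edge = 5, pen_marking = 6)
}

# rank lookup vector indexed by artifact-scheme index + 1
precedence_rank <- function(scheme = artifact_scheme()) {
  unname(artifact_precedence()[scheme$names])
}
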