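---
title: "Whole-slide image QC: models, simulator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-slide image QC: models, simulator and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Histological slides accumulate physical and optical artifacts — tissue folds,
air bubbles and slide-edge rims, dark spots and foreign objects (dust, fibres,
fingerprints), pen markings, and out-of-focus (OOF) regions. These corrupt
downstream image-analysis algorithms: tumour segmenters produce false
positives in folded or blurred tissue, and cell detectors hallucinate cells on
dirt. `slideqc` implements a two-module QC pipeline for H&E whole-slide
images:

1. a **tissue-detection** model run at low magnification (1x objective,
   MPP 10) separating tissue from glass background, and
2. a **multi-class artifact-segmentation** model run only inside the detected
   tissue, in three variants (10x/7x/5x objective, i.e. MPP 1.0 / 1.43 / 2.0)
   trading precision against speed.

The artifact model distinguishes seven classes: background, artifact-free
tissue, fold, dark spot/foreign object, pen marking, air bubble/slide edge,
and out-of-focus. Air bubbles are merged with slide edges and dark spots with
foreign objects because the members of each pair are visually near-identical
at QC magnifications; `merge_annotation_classes()` maps the nine-class
annotation vocabulary onto this seven-class scheme.

Per-slide artifact percentages feed three benchmarks: ranking institutes by
mean artifact burden, paired comparison of two scanners, and temporal
monitoring of slide quality.

# Magnification and geometry conventions

* MPP (microns per pixel) anchors everything; magnification converts as
  `mpp = 10 / power` (40x ~ 0.25, 10x ~ 1.0). Scanners with odd base MPPs are
  handled by resampling, never by re-anchoring.
* Coordinates are 0-based with half-open `(x, y, w, h)` boxes, x rightwards,
  y downwards, always expressed at the MPP of the raster they index. This
  makes crop/stitch round trips exact and testable.
* Images are downsampled by exact area averaging (interval-overlap weights),
  label masks only by nearest neighbour — a resampled mask can never contain
  a label absent from its input.
* `read_region()` picks the finest pyramid level at or below the requested
  resolution and resamples from there, like any pyramidal slide reader.

# The segmentation core

Both modules share one trainable pixel-wise segmentation network: a
U-Net-style convolutional encoder-decoder written for this package (im2col
convolutions, average pooling, nearest-neighbour upsampling with skip
concatenations, softmax head), trained with class-weighted cross-entropy plus
soft Dice under Adam. Two width presets exist: `compact` (width 8, ~15k
parameters) trains on a few hundred 64-px patches in minutes on one CPU core;
`paper` (width 32) is the same topology scaled up for users with real
annotated slides and more time. The design premise is that QC segmentation is
a shallow problem — artifact classes are separable from colour plus local
texture statistics — so a small fully-convolutional net with a ~30 px
receptive field suffices; the package deliberately does not depend on a deep
learning framework or pretrained encoders.

Training choices (made here because no single canonical choice exists for
this problem):

* **Loss** — cross-entropy + soft Dice (equal weight by default), the
  standard pairing for imbalanced multi-class segmentation; per-class CE
  weights are exposed for the rare classes (folds, dark spots).
* **Normalization** — per-channel mean/sd computed over the training images
  and frozen into the bundle.
* **Augmentation** — the eight dihedral flips/rotations only.
* **Determinism** — all randomness (init, shuffling, augmentation) flows from
  one integer seed through a dedicated RNG; single-threaded runs reproduce
  exactly, and inference is deterministic with argmax ties resolved to the
  lower class index.

The backward pass is verified against finite differences in the test suite,
which is the strongest correctness oracle available for a hand-written
network.

# The synthetic-slide simulator

All training and testing runs on simulated slides with pixel-exact ground
truth, so the package needs no external data. `gen_tissue_texture()` draws a
smooth random field, thresholds it at the requested tissue fraction (default
0.65 — a typical biopsy/resection coverage), and renders tissue from an
eosin-pink/hematoxylin-purple palette with coarse stain mottling, fine grain
and nucleus-like speckles on a near-white glass background. The speckle layer
matters: it is the high-frequency content whose disappearance defines an
out-of-focus region.

`inject_artifact()` adds, per kind: folds (a darkened band that samples the
texture shifted across the band — a doubled section), air bubble/edge (washed
interior with a dark rim), dark spot/foreign (dark blobs and thread-like
polylines), pen markings (opaque saturated bezier strokes), and `pigment`, a
melanin-like confounder that alters the image but leaves the ground truth
unchanged — pigmented melanoma is the classic false positive for
bubble-texture detectors, and the simulator reproduces that trap on purpose.

When artifacts overlap, ground truth follows a fixed precedence
(pen > bubble/edge > fold > dark spot/foreign > OOF > tissue > background):
opaque artifacts occlude translucent ones. Pen and bubble rims may extend
over glass and are labeled there; folds and dark spots are physically bound
to tissue. OOF is labeled only where the prior label was artifact-free
tissue.

`inject_oof()` follows the synthetic-OOF recipe: a smooth random field is
thresholded into a binary map and the image under the map is blurred with a
k x k Gaussian kernel, k drawn uniformly from {3, 5, ..., 17} (sigma from the
standard `0.3*((k-1)/2 - 1) + 0.8` rule, so the kernel size alone sets blur
strength; k = 1 is the identity). The threshold is chosen by exact quantile
selection on the field restricted to eligible tissue — the limiting case of
bisection — so that at least 30% of the region's pixels are labeled
out-of-focus; if clear tissue cannot support that, generation fails loudly
rather than silently under-delivering. The kernel-size distribution is a
deliberate default: any distribution over the odd sizes 3–17 is consistent
with the procedure, and uniform is the neutral choice.

# What the simulator does and does not show

Synthetic slides are colour- and texture-faithful caricatures: stain palette,
glass background, artifact morphology and OOF blur are realistic in kind, but
there is no scanner noise model, no stain variation between labs, no organ
morphology, and artifact geometry is simpler than reality. Passing the
recovery tests therefore demonstrates that the pipeline machinery — tiling,
training, stitching, gating, metrics — is correct and that the models can
learn the intended cues; it does not certify accuracy on real slides. Real
deployments should train the `paper`-width models on annotated data. The
desk-scale bars (held-out tissue Dice at least 0.90, artifact-free-tissue
Dice at least 0.75, trained from ~300 synthetic 64-px patches) play the role
of the real-data accuracies (tissue 0.957, artifact-free 0.919–0.938) that
require released weights and a deposited test set.

# Pipeline and numerical details

* Tiles default to non-overlapping 512-px grids (the downstream-model patch
  convention); edge tiles are shifted back flush (`shift_to_fit`) rather
  than padded, so segmentation inputs contain no synthetic borders. With
  stride = patch no overlaps occur; if a user configures overlaps, the
  later-written tile wins, deterministically.
* Tiles without tissue are skipped; any tile touching tissue is processed
  (`min_tissue_frac = 0`), since out-of-tissue pixels are overwritten to
  background afterwards anyway. The artifact mask inherits background from
  the tissue module — gating is exact by construction and tested.
* No morphological post-processing is applied: the masks are raw pixel-wise
  argmax output.
* Summaries report each artifact class as % of tissue area (non-background
  pixels); the percentages plus artifact-free % conserve to 100 by
  construction, and area converts as `pixels * (mpp/1000)^2` mm².
* Dice tables pool pixels over all patches (micro average), so a dataset
  score equals the score of the concatenated masks; per-patch macro
  averaging is available as an option. Classes absent from both prediction
  and truth are excluded from means rather than scored 1, avoiding inflated
  scores on clean slides.
* Quartiles use type-7 linear interpolation (fixed because whisker and
  outlier sets depend on the convention); whiskers reach the furthest datum
  within 1.5 IQR of the quartiles. The scanner comparison uses a paired
  Student-t 95% interval on within-slide differences (a bootstrap percentile
  interval is available); swapping scanners negates the estimate and mirrors
  the interval.
* Mask PNGs store the class index as the pixel value (bit-exact round trip);
  GeoJSON export traces exact pixel-boundary rings, so rasterising them back
  reproduces the mask pixel-for-pixel under the even-odd fill rule.
* QC "masking" for downstream models is realised as scoring exclusion plus
  optional white fill: masking prevents misclassification in corrupted areas
  but cannot recover structures there, so corrected-condition scores are
  computed only on non-ignored pixels (enforced with sentinel-label tests).
  Detection filtering uses the cell's centre point.

# Problem sizes

The bundled tests and the acceptance script run entirely at desk scale on one
CPU core: ~300 simulated 64-px training patches, 512-px demonstration slides,
and 100 simulated 512-px ROIs for the OOF-contract check. These sizes were
chosen so a full run completes in minutes while every contract (including
training-based recovery) is exercised end to end.

# Known limitations

* The `paper` width preset scales the same compact topology; it does not
  replicate a pretrained EfficientNetB0 encoder or a UNet++ dense decoder.
* The simulator does not model scanner-specific noise, stain variability or
  organ morphology (see above).
* Overlapping-window probability blending is not implemented (last-write-wins
  is); it is a possible extension, not needed for non-overlapping strides.
* Institute ranking is descriptive — no significance testing between
  institutes is attempted.
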