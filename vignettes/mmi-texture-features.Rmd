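---
title: "Mask Matching Image texture features: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mask Matching Image texture features: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmitex)
```

## The model

Higher-order local autocorrelation (HLAC) features summarize a binary
image by a bank of *masks*: each mask is a set of pixel offsets inside a
small displacement window (here 3×3), always including the origin. A mask
of order *N* has *N* + 1 reference points. Scanning a mask over the image
and counting the positions where **every** reference point lands on a
foreground pixel yields one number per mask — the classical HLAC feature
vector. Because the count is a sum over all image positions, it is
shift-invariant, and additive over image regions that do not interact
through the window.

Two masks that are translates of one another always produce the same
count, so the bank enumerates translation-equivalence classes:

```{r masks}
length(enumerate_masks(2))   # orders 0-2: the classical 25 masks
length(enumerate_masks(8))   # all origin-containing 3x3 subsets: 223
```

The *Mask Matching Image* (MMI) keeps, for each mask, the full binary map
of matching positions instead of only its sum. The pixel sum of the MMI is
exactly the HLAC count, but the MMI's spatial structure supports richer
per-mask features:

* **SSMMI** — five statistics of the connected components of the MMI:
  total area S (= the HLAC count), component count L, and the maximum,
  minimum and mean component area.
* **Length histogram (LH)** — the counts of *maximal* horizontal runs of
  foreground pixels by length (width histogram, bins 1..W), concatenated
  with the counts of maximal vertical runs (height histogram, bins 1..H).

Why this helps: very different images can share every HLAC count. The
canonical demonstration places 16 foreground pixels as 16 singletons, four
2×2 blocks, two 2×4 blocks, or one 4×4 block — all have S = 16 under the
single-point mask, yet L distinguishes all four (16, 4, 2, 1), as do the
maximal areas (1, 4, 8, 16) and the run-length histograms:

```{r configs}
sapply(c("singletons16", "blocks2x2", "blocks2x4", "block4x4"),
       function(nm) ssmmi_stats(component_areas(make_configuration(nm))))
```

## Conventions and numerical choices

Choices the feature definitions leave open, fixed here once:

* **Border handling.** A mask matches only where all its offsets land
  inside the image; the MMI keeps the input's dimensions with unmatched
  border positions at 0. No padding, so the MMI sum always equals the
  match count with no phantom border matches.
* **Representative masks.** Masks are stored as point *sets* (no
  multiplicities: on binary images repeated reference points are
  idempotent), rooted at the origin, ordered by (order, canonical key) so
  the feature layout is reproducible. The class representative is the
  first origin-containing member encountered in a fixed generation order;
  any representative of a class yields the same counts, differing only by
  a translation of the MMI.
* **Connectivity.** Components use 4-connectivity by default — horizontal
  and vertical adjacency are the only adjacencies the run-length
  definitions use — with 8-connectivity as an option.
* **Fifth SSMMI statistic.** The mean component area S/L, the natural
  companion of sum/count/max/min. All five statistics are 0 for an empty
  MMI, keeping vectors total and finite.
* **Binarization.** Otsu's global threshold over the 256 gray levels is
  the default (deterministic and parameter-free), with a fixed threshold
  as an option. Foreground is the bright phase (intensity at or above the
  threshold); `invert = TRUE` serves images where the structures of
  interest are dark. Edge-based binarization is out of scope.
* **LH layout.** Bins are dense, 1..W then 1..H per mask, so feature
  vectors align across a dataset; images of differing sizes are rejected
  rather than silently resized. The histograms are typically very sparse —
  sparsity is an internal storage opportunity, but the dense layout is the
  external contract.
* **1-NN ties.** Equal L1 distances resolve to the lowest training-row
  index, making predictions deterministic.
* **SVM parameters.** Linear-kernel C-SVC with C = 100 via LIBSVM
  (e1071). Degree and coef0 are inert under a linear kernel and are not
  exposed. Features enter raw (counts); an optional per-split min–max
  scaling flag exists but is off by default.
* **Seed policy.** A master seed deterministically spawns per-repeat (and
  per-image) sub-seeds via `sample.int` under the master seed; identical
  seeds reproduce splits and datasets bit-for-bit, and split generation
  depends only on the labels and split specification, so different feature
  kinds are compared on identical training/test samples.

## The evaluation protocol

`run_experiment()` implements repeated stratified holdout: per class, 15
images train and the rest test (5 with the reference 20-per-class layout),
repeated 30 times, scored as accuracy in percent and summarized as
mean ± standard deviation. Classifiers: 1-NN with L1 distance, and linear
C-SVC. The protocol mirrors how HLAC-family features are benchmarked on
wood stereogram collections (24 species × 20 images, 100×100 pixels,
256 gray levels); with such a collection on disk in class-per-directory
layout, `load_image_dataset()` + `extract_feature_table()` +
`run_experiment()` reproduce the full workflow.

## The synthetic generator

`generate_wood_texture()` emulates the cross-section anatomy that texture
features respond to: bright elliptical pore-like blobs (count Poisson with
mean `pore_density`, semi-axes uniform in `pore_radius`), periodic bright
vertical streaks standing in for rays (`ray_period`, `ray_width`), Gaussian
background granularity, and sparse salt noise. The four preset classes
differ along the axes that differentiate species — pore density (25 vs 6
per image), pore size (2–3 vs 5–7 px), ray spacing/width (7/1 vs 15/3 px) —
on 100×100 canvases, values fixed once as a plausible stylization of
coarse- versus fine-pored woods.

What the generator does *not* emulate: growth-ring curvature and gradients,
parenchyma patterning, imaging artifacts (uneven illumination, blur,
surface scratches), and within-species biological variability beyond seed
noise. Passing the end-to-end benchmark therefore shows the pipeline is
correct and that the features separate textures that differ in pore/ray
geometry; it does not certify any particular accuracy on real stereograms.

## Problem sizes used in the shipped checks

The test suite validates the implementations against independent
brute-force oracles (naive triple-loop match counting, explicit-adjacency
run enumeration, stack-based flood fill) exhaustively on all 512 binary
3×3 images and on 1000 random images of side 8–16, and runs the end-to-end
benchmark at the reference scale: 4 classes × 20 images of 100×100, 15/5
split, 30 repeats, LH and HLAC features on shared splits. A reduced
24-class run (6 images of 40×40 per class) exercises the
collection-scale protocol. These sizes keep the full suite comfortably
reproducible on a laptop while covering every code path at the reference
image size.

## Known limitations

* Only PNG and TIFF rasters are read natively.
* LH vectors scale as (W + H) × masks; at 100×100 with 223 masks that is
  44 600 mostly-zero columns — workable, but the 25-mask bank is the
  practical default, and is also where the length histogram is reported to
  shine.
* Binarization quality drives everything downstream; Otsu is a reasonable
  global default but no substitute for inspecting the binarized output on
  a new imaging setup (`binarize()` exposes the threshold it chose).
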