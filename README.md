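# mmitex

Texture features for grayscale images built on higher-order local
autocorrelation (HLAC) and its Mask Matching Image (MMI) extension, with
the classification protocol used to benchmark them on wood cross-section
(stereogram) textures. The intended users are people building image-based
wood species identification — or any texture classification where local
binary structure carries the signal.

## The method

A HLAC **mask** is a set of pixel offsets `{a₀ = 0, a₁, …, a_N}` inside a
3×3 window. For a binary image `f`, the order-N autocorrelation feature is

    x(M) = Σ_r  f(r) · f(r + a₁) · … · f(r + a_N)

— the number of positions where every reference point of the mask lands on
a foreground pixel. Enumerating all origin-containing subsets of the 3×3
window and merging translates gives 25 masks up to order 2 and 223 up to
order 8.

The **Mask Matching Image** keeps the full match map instead of its sum:

    MMI_i(x, y) = Π_{a ∈ M_i} f((x, y) + a)

Its pixel sum is the HLAC count, but its spatial structure supports richer
per-mask features:

* **SSMMI** — for the connected subgraphs `D_k` of each MMI: total area
  `S = Σ|D_k|`, count `L`, `max|D_k|`, `min|D_k|`, and mean area `S/L`
  (5 numbers per mask).
* **Length histogram (LH)** — counts of *maximal* horizontal runs of
  foreground pixels by length (bins 1..W) concatenated with maximal
  vertical runs (bins 1..H), per mask.

Evaluation follows repeated stratified holdout (15 train / 5 test per
class, 30 repeats) scored with 1-NN under the L1 norm and a linear C-SVC
(C = 100), reported as mean ± standard deviation of accuracy in percent.

## Worked example

The classical demonstration of why MMI features out-discriminate bare
HLAC counts: configurations with identical match counts but different
component structure.

```r
library(mmitex)

bank <- enumerate_masks(2)
bank
#> HLAC mask bank: 25 masks, max order 2
#> masks per order: 0:1 1:4 2:20

f <- make_configuration("blocks2x4")   # two separated 2x4 blocks, 16 pixels
ssmmi_stats(component_areas(f))
#>    S    L  max  min mean
#>   16    2    8    8    8
which(width_histogram(f) > 0)          # all maximal horizontal runs have length 4
#> [1] 4
```

`S = 16` is what every 16-pixel configuration reports under the
single-point mask; `L = 2` and the run lengths are what tell the 2×4
blocks apart from, say, one 4×4 block.

End to end on the built-in synthetic wood textures (4 classes × 20 images
of 100×100, differing in pore density/size and ray spacing), with both
feature kinds scored on the *same* random splits:

```r
ds <- generate_dataset(texture_presets(4), n_per_class = 20, seed = 2024)
lh <- extract_feature_table(ds, bank, "lh")
hl <- extract_feature_table(ds, bank, "hlac")
sp <- make_splits(ds$labels, train_per_class = 15, n_repeats = 30, seed = 2024)

run_experiment(lh, classifier = "knn", splits = sp)
#> KNN: 100.0000±0.0000  (accuracy %, 30 repeats, 15 train/class)
run_experiment(hl, classifier = "knn", splits = sp)
#> KNN: 88.6667±4.7222  (accuracy %, 30 repeats, 15 train/class)
run_experiment(lh, classifier = "svm", splits = sp)
#> SVM: 100.0000±0.0000  (accuracy %, 30 repeats, 15 train/class)
```

The length-histogram features separate the four texture classes perfectly
here, while the 25 bare HLAC counts leave ~11% of test images mislabeled —
the gap the MMI features exist to close.

A real collection laid out one-directory-per-species is processed the same
way via `load_image_dataset("path/to/collection")`, or from a shell:

```sh
Rscript inst/scripts/mmi-cli.R synth --classes 4 --per-class 20 --out imgs
Rscript inst/scripts/mmi-cli.R extract --input imgs --kind lh --out features.tsv
Rscript inst/scripts/mmi-cli.R evaluate --features features.tsv --classifier knn
```

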