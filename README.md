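# hyperseed

Classify crop seed varieties from benchtop hyperspectral images.

A line-scan hyperspectral imager records a reflectance cube — two
spatial dimensions by 462 narrow bands across 400–1000 nm — of seeds
laid out on a dark stage. Varieties that look identical to the eye can
differ in a handful of bands. **hyperseed** implements the full
workflow around that observation:

* **ENVI cube I/O** (BIL/BIP/BSQ + text header) and a band↔wavelength
  calibration fitted to the imager's published window endpoints,
  λ(b) = 390.100 + 1.33253·b nm;
* **RGB pseudo-colour reconstruction**: pick bands (r, g, b) from the
  red (173–292), green (76–127) and blue (23–44) windows and compose a
  display image; **band-triple search** ranks candidate triples by the
  downstream classification accuracy of a pluggable evaluator (default:
  cross-validated LDA on per-seed colour statistics);
* **seed segmentation**: Otsu thresholding (foreground > t, t the
  256-level between-class-variance maximizer), border-flood hole
  filling, disk opening, 8-connected component labelling, per-seed
  crops;
* **sevenfold augmentation**: 45° and 90° rotations, colour/brightness/
  contrast enhancement, horizontal mirror;
* **7:2:1 stratified splits** with the rounding rule
  train = ⌊0.7n⌋, val = ⌊0.2n + 0.5⌋, test = n − train − val, and an
  optional leakage guard that keeps augmented variants of one seed in
  one split;
* **residual classifiers written from scratch** (depths 18/34/50/101)
  plus attention-modified variants: CBAM-ResNet34, SE-ResNet34, and
  SE-ResNet34-DCN, whose first Conv2 convolution is deformable — each
  kernel tap samples at a learned fractional offset via bilinear
  interpolation, and zero offsets reduce it exactly to a standard
  convolution;
* **training and evaluation**: SGD (lr 0.001, momentum 0.9, weight
  decay 0.01, batch 8, 50 epochs by default), confusion matrices, and
  macro precision/recall/specificity/F1.

A synthetic scene generator with known per-class Gaussian-bump spectra
and ground-truth instance masks makes every stage testable without
instrument data.

## Worked example

```r
library(hyperseed)

## 7:2:1 split counts for seven varieties
split_counts(c(1085, 1085, 1099, 1085, 1064, 1120, 1078))
#>      n train val test
#> 1 1085   759 217  109
#> 2 1085   759 217  109
#> 3 1099   769 220  110
#> 4 1085   759 217  109
#> 5 1064   744 213  107
#> 6 1120   784 224  112
#> 7 1078   754 216  108

## band-triple search on a synthetic corpus with signal planted at 188-83-41
corpus <- planted_corpus(rng_seed = 101)
res <- search_band_triples(corpus, planted_grid(), rng_seed = 101)
head(as.data.frame(res), 3)
#>     r  g  b accuracy rank
#> 1 188 83 41     1.00    1
#> 2 188 83 23     0.75    2
#> 3 240 83 41     0.75    3

## full pipeline on the packaged three-class synthetic study
res <- run_pipeline(default_pipeline_config(workspace = "ws", rng_seed = 1))
print(res$metrics)
#> accuracy 100.00%  macro precision 100.00%  recall 100.00%  specificity 100.00%  F1 100.00%
print(res$confusion)
#>     predicted
#> true C1 C2 C3
#>   C1 21  0  0
#>   C2  0 21  0
#>   C3  0  0 21
```

The search table reads: the planted triple 188-83-41 is ranked first
with cross-validated accuracy 1.0, while triples that replace any one
channel with a signal-free band drop to ~0.75 because one class pair
becomes indistinguishable. The pipeline result is the confusion matrix
and macro metrics of the small SE-residual classifier on the held-out
test split of the synthetic study (63 crops here).

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/hyperseed.R run-all --workspace ws --seed 1
Rscript inst/cli/hyperseed.R band-search --seed 3 --out ranking.csv
Rscript inst/cli/hyperseed.R segment --image scene.png --min-area 20 --out-dir crops
```

## Documentation

`vignettes/hyperseed-methods.Rmd` describes the models and the design
decisions in detail: the calibration fit, the synthetic reflectance
model and what it does not emulate, the segmentation conventions, the
attention-module placements, the deformable-convolution initialization,
and the problem sizes used in the packaged experiments.
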