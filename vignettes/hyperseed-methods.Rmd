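---
title: "Methods: band reconstruction, seed segmentation and attention-based classification"
author: "hyperseed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: band reconstruction, seed segmentation and attention-based classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Seed varieties of the same crop can be visually indistinguishable, yet
differ in yield, hardiness and nutritional value. A benchtop line-scan
hyperspectral imager records, for every pixel of a scene of seeds on a
dark stage, a full reflectance spectrum: a cube of `lines x samples x
462` bands spanning roughly 400–1000 nm. hyperseed implements the
workflow that turns such cubes into variety predictions:

1. choose one band for each display channel (R, G, B) and compose a
   pseudo-colour image;
2. segment individual seeds by thresholding and component labelling;
3. expand each seed crop with a fixed six-transform augmentation family;
4. split the crops 7:2:1 into train/validation/test, stratified by
   variety;
5. train a residual convolutional classifier — optionally extended with
   squeeze-and-excitation (SE) channel attention, convolutional block
   attention (CBAM) or deformable convolution (DCN) — and evaluate it
   with confusion-matrix statistics.

Because no public imaging data accompanies this workflow, the package
carries a synthetic scene generator with known per-class spectral
signatures and ground-truth instance masks. Every stage is tested
against it.

## Wavelength calibration

The imager's documentation pins six (band index, wavelength) pairs: the
red window is bands 173–292 = 620.05–779.75 nm, green 76–127 =
491.19–558.79 nm, blue 23–44 = 421.29–448.94 nm. A quoted sampling
interval of 0.67 nm is inconsistent with 462 bands over 400–1000 nm
(which implies roughly 1.3 nm per band) and with those six pairs, so the
default calibration is the least-squares line through the six endpoint
pairs,

$$\lambda(b) = 390.100 + 1.33253\,b \ \text{nm},$$

which reproduces every endpoint with a residual below 0.6 nm — less than
half a band step. Band indices are 1-based everywhere. Cubes whose
headers carry an explicit wavelength list use that list instead.

## ENVI I/O

Cubes are read and written as a minimal ENVI dialect: a `key = value`
text header (`samples`, `lines`, `bands`, `data type`, `interleave`,
`byte order`, optional `wavelength` list; unknown keys preserved
verbatim) plus a raw little-endian payload in BIL, BIP or BSQ
interleave. The default storage type is float64, which makes the
write–read round trip bit-exact; uint8/int16/uint16/float32 are also
supported. Header/payload mismatches (truncated payloads, missing keys,
unknown type codes) are hard errors rather than warnings, since silent
reinterpretation of a binary cube is never recoverable downstream.

## The synthetic scene generator

Each scene plants `n_classes * seeds_per_class` ellipses (random
semi-axes, orientation and position; bounding-circle rejection sampling
enforces a minimum gap, so instances never touch) on a dark stage
(reflectance 0.05). In-seed spectra follow a Gaussian-bump model: a
common baseline (0.35) plus, per class, bumps
`amplitude * exp(-(lambda - center)^2 / (2 width^2))`, with i.i.d.
Gaussian pixel noise (s.d. 0.02 by default) and clipping to [0, 1]. The
default class signatures place single bumps at 640.6, 500.7 and
444.7 nm — the calibrated wavelengths of bands 188, 83 and 41 — and
classes beyond three use combinations of those centres, giving up to
seven separable varieties. All randomness flows from one integer seed
(scene *i* of a corpus uses `seed + i`); generation is bit-reproducible
and never disturbs the caller's RNG.

What the generator deliberately does **not** emulate: seed texture and
glossiness, specular highlights, shadows, touching or overlapping seeds,
dark-current/white-reference artefacts, and spatially correlated noise.
Tests passing on this model therefore demonstrate the correctness of
the pipeline's machinery — band arithmetic, segmentation geometry,
training mechanics — not field performance on real seed images.

## RGB reconstruction and the band-triple search

A band image is the cube slice at one band, rescaled to 0–255. The
default scaling is per-band min–max (the instrument does not prescribe
one); a constant band maps to 0, and a fixed global reflectance range is
available as an alternative. `compose_rgb()` stacks three band images as
the R, G and B display channels and records provenance (source scene and
triple). Window enforcement is on by default — each channel's band must
come from its physiological window — with an explicit override flag.

The band-triple search scores every triple of a candidate grid by
composing the corpus, segmenting the seeds, and handing the result to a
pluggable evaluator; triples are ranked by accuracy (ties broken by
lexicographic (r, g, b) order, evaluator failures recorded as missing
scores that rank last). Training a deep network per triple is faithful
to the original protocol but far beyond a desk budget, so the default
evaluator is a structural proxy: per segmented seed, the channel means
and standard deviations inside the mask (6 features) feed a stratified
5-fold cross-validated linear discriminant analysis, and the triple's
score is the CV accuracy. The proxy preserves exactly what the search
varies — which bands carry between-class contrast — while replacing the
expensive scorer.

The packaged recovery experiment (`planted_corpus()` / `planted_grid()`)
uses four classes: one bump per channel plus a baseline-only class, so
that each channel of the planted triple 188-83-41 is necessary to
separate some class pair; dropping any one of them merges a pair and
caps the proxy accuracy near 0.75. Bumps are narrow here (3 nm s.d.) and
grid alternatives sit several bump widths from the planted centres,
because per-seed features average pixel noise over a few hundred pixels:
any band with even a few-percent leak of class signal would separate the
classes perfectly and tie with the planted triple. Narrow bumps make the
planted triple the unique Bayes-optimal grid point rather than merely
one of several.

## Segmentation

The chain is: luminance grayscale (0.299 R + 0.587 G + 0.114 B) → Otsu
binarization → hole filling → morphological opening → 8-connected
component labelling → area filter → per-seed crops.

Numerical and design choices:

* **Otsu** scans all 256 levels for the threshold maximizing
  between-class variance; ties break toward the lower threshold, and
  foreground is *strictly above* the threshold. A constant image yields
  all-background. The test suite pins this against an exhaustive
  two-class-variance scan.
* **Polarity** assumes bright seeds on a dark stage; an `invert` flag
  covers the opposite arrangement.
* **Hole filling** floods the border-connected background of the
  complement (4-connected, on a padded frame) and promotes everything
  else to foreground; it is idempotent by construction.
* **Opening** uses a disk structuring element (default radius 2 px in
  the generic API; the packaged pipeline uses 1 px to match its small
  synthetic seeds). Opening is applied before labelling to clean
  contours and detach specks.
* **Labelling** is 8-connected: 4-connected labels are merged by
  union–find wherever they touch diagonally. Minimum component area
  defaults to 0.1% of the frame.
* **Touching seeds are not split.** The workflow assumes scenes without
  sticky seeds (they were removed manually in the original protocol);
  a component whose solidity (area / bounding-box area) falls below 0.4
  is flagged as a probable merge instead of being watershed.
* **Crops** expand the tight bounding box by a configurable pad, zero
  out-of-mask pixels (black fill), and resize bilinearly to a square
  (224 px by default, matching the classifier's canonical input).

## Augmentation

Exactly six deterministic transforms per crop, in fixed order: 45°
rotation, 90° rotation, colour enhancement, brightness enhancement,
horizontal mirroring, contrast enhancement — a sevenfold family with the
original. The 90° rotation and the mirror are exact index permutations
(lossless pixel multisets); the 45° rotation keeps the canvas size and
fills the exposed corners with black, consistent with the crop fill
policy. Enhancements are multiplicative with factor 1.3 by default
(the protocol does not state magnitudes; 1.3 is a visible but
non-destructive strengthening): brightness scales all channels, colour
interpolates away from the grayscale image, contrast pivots around the
mean luminance. Normalization is *not* baked into stored files; channel
mean/s.d. are computed on the training split at training time and
persisted with the checkpoint, so stored crops remain inspectable.

## Dataset splitting

The 7:2:1 split uses the rounding convention `train = floor(0.7 n)`,
`val = round-half-up(0.2 n)`, `test = n - train - val` — the unique
simple rule that reproduces the published per-variety table from its row
totals (all 21 cells, and the 5328/1524/764 split totals). Assignment is
stratified by class with a seeded shuffle. Two modes exist because
augment-before-split risks leakage: the default groups all variants of
one original seed so they travel together (per-class sizes then match
the targets to within one group of seven), while the ungrouped mode
reproduces the published protocol and hits the per-class counts exactly.
Neither is asserted to be what the original authors did; the choice is a
flag.

## Classifier families

`build_resnet()` assembles the standard residual topologies from scratch
— 7×7/2 stem convolution, batch norm, ReLU, 3×3/2 max pool, four stages
of basic blocks (depths 18/34) or bottlenecks (50/101), global average
pooling, and a fully connected head. Softmax lives in inference;
training operates on logits with cross-entropy. Convolutions carry
biases (harmless under batch norm; counted in the parameter totals).
Weights use seeded He initialization — no pretrained imports, so every
run is reproducible from its seed.

The modified families interpret the stated insertion points as:

* **"at the max-pool output"** — immediately after the stem pooling
  layer (64 channels);
* **"after Conv2"** — after the last block of the first residual stage
  (64 channels).

`cbam_resnet34` places CBAM at both points; `se_resnet34` places SE at
the same two points (two SE modules total); `se_resnet34_dcn`
additionally replaces the *first 3×3 convolution of the first Conv2
block* with a deformable convolution. The alternative reading
(attention inside every Conv2 block) is structurally possible but would
multiply the module count stated for the composed model, so the
two-point placement is the default and only wiring.

SE uses reduction ratio 16 and CBAM a 7×7 spatial kernel (standard
defaults; neither is prescribed). CBAM's channel attention is the
standard design — a bottleneck MLP over the channel-descriptor vector,
shared between the average- and max-pooled branches — so identical input
channels do *not* receive identical weights; the sharing is across
branches, not across channels.

The deformable convolution predicts a (dy, dx) offset pair per kernel
tap with an internal convolution whose weights are zero-initialized:
training therefore starts at exact equivalence with a standard
convolution (the key invariant, tested to 1e-5 on random inputs), and
offsets grow only as the loss demands. Sampling is bilinear with zero
padding beyond borders.

`se_resnet_small` is a deliberately scaled-down SE variant (3×3 stem,
three stages of one basic block, widths 8/16/32, SE at the two canonical
points, ~20k parameters) for experiments at desk scale.

## Training and evaluation

The engine is a reverse-mode CNN implementation in vectorized base R:
convolution as a sum of strided-slice GEMMs over kernel taps, batch
norm (momentum 0.1, eps 1e-5), max pooling with argmax routing, SE/CBAM
and deformable-conv backward passes derived analytically (all verified
against central-difference numerical gradients to ~1e-10). SGD follows
the study regimen by default: learning rate 0.001, momentum 0.9, weight
decay 0.01, batch size 8, 50 epochs, constant learning rate (a step
schedule is available but off, since only an *initial* rate is
specified). The best-validation-accuracy epoch is checkpointed — weights
*and* batch-norm running statistics, which must travel together — and
restored at the end; per-epoch history records losses and accuracies for
both splits.

Evaluation takes one argmax prediction per item (ties to the lowest
class index) and accumulates a k×k confusion matrix (rows = truth).
Per class, TP is the diagonal entry, FP the rest of its column, FN the
rest of its row, TN the remainder; precision, recall, specificity and
F1 derive in the usual way, and the summary report uses **macro**
(unweighted) averaging across classes, matching the per-variety emphasis
of the original tables; per-variety accuracy is the class recall. A 0/0
ratio (a class never predicted, or absent from the test set) is reported
as 0 with a warning flag rather than NaN.

## The packaged pipeline and its problem sizes

`run_pipeline()` chains generate → reconstruct → segment → augment →
split → train → evaluate through CSV manifests in a workspace; each
stage records a content hash of its configuration and inputs, so
re-running an unchanged configuration skips completed stages without
changing results. The packaged default is a three-class synthetic study
chosen to exercise every stage in a few minutes of CPU: six scenes of
150×200×462, five seeds per class per scene, 188-83-41 reconstruction,
32×32 crops, sevenfold augmentation, grouped 7:2:1 split, and the small
SE variant trained for 10 epochs at learning rate 0.01 (appropriate for
a 20k-parameter model on 32×32 inputs; the full-scale default of 0.001
remains the `train_config()` default). On this study the validation
accuracy passes 90% within the first few epochs and the test split is
classified essentially perfectly — a statement about the machinery on
separable synthetic data, not about real seeds.

The band-search experiment runs ten seeded corpora of three 100×140
scenes (36 seeds each) over the 4×4×4 companion grid; each run scores
64 triples in a few seconds via the LDA proxy.

## Known limitations

* The engine is CPU-bound R: full-depth training at 224×224 is possible
  but slow; the full families are exercised with forward/backward smoke
  batches, and end-to-end *training* demonstrations use the small
  variant. The published absolute accuracies for the seven-variety crop
  study are not reproducible here in any case, since those images were
  never deposited.
* Touching seeds are flagged, not split.
* The proxy evaluator ranks triples by linear separability of low-order
  colour statistics; a triple whose advantage only a deep texture model
  could see would not be preferred by it.
* The synthetic reflectance model is smooth and per-pixel i.i.d.; it
  cannot stand in for instrument-specific noise or scattering effects.
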