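---
title: "Multimodal glioma subtyping from hyperspectral pathology and MRI radiomics"
author: "hafnet package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal glioma subtyping from hyperspectral pathology and MRI radiomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hafnet)
```

## The problem

Adult diffuse gliomas are classified under the WHO-2021 scheme into six
type/grade classes: astrocytoma IDH-mutant grades 2-4 (A2, A3, A4),
oligodendroglioma IDH-mutant 1p/19q-codeleted grades 2-3 (O2, O3) and
glioblastoma IDH-wildtype grade 4 (G4). Hyperspectral microscopy of stained
pathology sections records, for every pixel, a full transmission spectrum
(here: 300 bands on a uniform 2 nm grid from 400 to 998 nm), so a section
becomes a 3D reflectance cube carrying biochemical contrast that ordinary
RGB imaging integrates away. Spectral information alone, however, misses the
macroscopic anatomy that preoperative MRI captures. This package implements
an attention-fusion network that classifies 100x100-pixel hyperspectral
patches into the six classes by fusing selected spectral channels with a
per-patient radiomic feature vector derived from MRI, together with every
step around it: calibration, patch extraction, wavelength selection, the
radiomic vector contract, training, and evaluation.

A note on the wavelength grid: the acquisition platform is described by a
400-1000 nm range with 300 bands and a 2.5 nm optical resolution. A uniform
grid cannot satisfy all three simultaneously; the package fixes the grid at
400, 402, ..., 998 nm (300 bands of 2 nm) and regards 2.5 nm as the optical
(not sampling) resolution.

## Reflectance calibration and patching

Raw sensor counts are converted to reflectance with the standard push-broom
convention
$$R = \frac{I - D}{W - D},$$
where $I$, $W$ and $D$ are the sample, white-reference and dark-reference
cubes on one grid. The quotient is clipped to $[0, 1.5]$: values slightly
above 1 are legitimate where the sample transmits more than the reference,
and 1.5 bounds the influence of dead-pixel artifacts. Calibration demands
$W > D$ elementwise and reports the first offending band/pixel otherwise.
References may be spatially averaged per band first (`averageReferences`),
the usual choice for noisy references under flat illumination.

Cubes are tiled into non-overlapping square patches on a grid anchored at
the top-left corner; partial edge tiles are discarded. A patch is kept only
when its tumor-pixel fraction reaches `minTumorFrac` (default 0.8), i.e.
patches with substantial background are excluded. The tumor mask is an
explicit input (drawn by a pathologist in practice); a luminance-threshold
heuristic (`luminanceTissueMask`) is provided for convenience and labelled
as such — transmitted-light background is near-white, tissue is darker.

## Mutual-information wavelength selection

Not all 300 bands are informative. Each band $b$ is scored by the mutual
information
$$I(X_b; Y) = H(X_b) - H(X_b \mid Y) = \sum_{x,y} p(x,y)\,
\log\frac{p(x,y)}{p(x)\,p(y)}$$
between the per-patch mean intensity at that band ($X_b$) and the class
label ($Y$). The estimator discretizes $X_b$ into `bins` equal-width bins
(default 32) over its observed range and evaluates the sum exactly on the
joint histogram, with $0 \log 0 = 0$; scores are in nats (bits on request).
The histogram form was chosen as the primary estimator because it is
directly oracle-testable against the defining sum on any discrete joint
table; the tests exploit exactly that. The top-$k$ bands (default
$k = 20$, a 93.3% reduction from 300) are retained, ties broken toward the
lower band index so selection is deterministic.

Two hygiene rules apply. First, ranking is computed from training-split
patches only; `rankBands()` takes the held-out patch ids and *fails* if the
band summary contains any of them, rather than silently leaking. (Whether
the original analysis pooled all patches before selection is not stated;
train-only is the conservative reading, and the package makes the other
choice impossible to reach by accident.) Second, the often-quoted selected
window (639-681 nm) is a property of one data set, not of the method; on
synthetic data the selected bands are wherever the class signal was
planted.

## The radiomic feature contract

MRI enters as one 5650-dimensional feature vector per patient, extracted
(by an external radiomics engine) from five sequences — T1WI, T1CE, T2
FLAIR, T2WI, ADC — over twelve image types: the original image, three
Laplacian-of-Gaussian scales ($\sigma = 1, 2, 3$) and the eight first-level
wavelet sub-bands. Shape features are computed on the original image only.
The per-family feature counts are not spelled out in the source
description; the package adopts the de-facto standard cardinalities
(shape 14, first-order 18, GLCM 24, GLDM 14, GLRLM 16, NGTDM 5, GLSZM 16),
which uniquely reproduce the printed total:
$$5 \times \bigl(14 + (18+24+14+16+5+16) \times 12\bigr) = 5 \times 1130 =
5650 .$$
`enumerateSchema()` emits the deterministic sequence-major ordering;
`loadRadiomics()` validates a CSV against it (order-insensitive, itemized
errors, non-finite entries rejected). Feature mathematics are deliberately
out of scope — vectors are consumed as a table.

Because the network's fully-connected layers assume commensurate input
scales, features are z-scored with means/SDs fitted on training-fold
patients only (zero-variance features map to 0); this normalization is a
package addition, as the source is silent on scaling. Every patch of a
patient receives that patient's single radiomic vector — there is no
per-patch MRI.

## The network

The HSI branch consumes a patch as a (1 channel, $k$ bands, $H$, $W$)
tensor:

* stem: 3D convolution, kernel (5,3,3), stride (2,1,1), padding (2,1,1),
  32 channels, then batch norm, ReLU, and (2,2,2) max pooling;
* residual block 1 to 64 channels, then (2,2,2) pooling;
* residual block 2 to 128 channels, then (1,2,2) pooling;
* channel attention; flatten; FC to 512 with batch norm and ReLU.

Each residual block is conv-BN-ReLU-conv-BN plus a shortcut added before a
final ReLU; the shortcut is the identity when shapes match and a 1x1x1
convolution with BN when the channel count changes (as it does in both
blocks here). The channel-attention module pools the feature block globally
by average and by maximum per channel, passes both descriptors through a
shared two-layer bottleneck MLP (reduction ratio 16), sums the two outputs
and applies a sigmoid; the resulting per-channel weights in (0,1) rescale
the features. It is applied once, after the second residual block — the
source is ambiguous between "after the residual blocks" and "after the
second residual block", and the single placement is implemented.

The MRI branch is two FC layers (1024 then 256, each with BN and ReLU); the
source fixes only the 256-d output, and 1024 is the package's choice for
the hidden width. The two feature sets are concatenated (512 + 256 = 768),
passed through a fusion FC layer to 512 with BN, ReLU and dropout 0.3, and
a final FC layer emits the class logits; softmax yields probabilities at
evaluation time, while training consumes logits through the loss's internal
log-softmax (mathematically identical, numerically stable). The `hsi_only`
ablation classifies the 512-d HSI projection directly; `mri_only` the 256-d
radiomic embedding.

One printed figure cannot be honored: a flattened backbone width of "~8192"
is inconsistent with the stated kernels, strides and pools (for a 20-band,
100x100 input the true width is 36864). The layer hyperparameters are
treated as normative and the flatten width is always *computed* by
`shapeTrace()`, a pure floor-division shape propagation that the tests hold
equal to the instantiated tensor shapes, and that `hafnet describe` prints.

No deep-learning framework is involved: the 3D convolution and pooling
kernels are compiled C++ (im2col plus GEMM), and batch norm, attention,
dropout, the weighted loss and Adam are plain R matrix code. Every layer
has an explicit backward pass, and the whole graph is verified against
central finite differences in the test suite — this is the package's
substitute for autograd, and the reason the engine can stay small.
Weights initialize Kaiming-uniform (BN at gamma 1, beta 0) under a seed.

## Training

Optimization follows the reference recipe: weighted cross-entropy with
balanced class weights $w_c = N/(K n_c)$ (so equal counts give unit
weights and the weighted count totals $N$), Adam at learning rate $10^{-4}$
with weight decay $10^{-4}$, learning-rate halving when validation loss
plateaus (factor 0.5, patience 5), early stopping after 5 stagnant epochs,
at most 100 epochs. Validation loss is the monitored quantity and 16 the
batch size — both unstated in the source and fixed here. Training batches
are augmented on the fly: independent horizontal/vertical flips, rotations
by multiples of 90° applied identically to every band (independent
per-band rotation would destroy spatial registration), and a global
brightness factor drawn from [0.8, 1.2]. The best-validation checkpoint is
returned together with the per-epoch history, and the checkpoint carries
the band ranking and feature scaler so inference is self-contained.

Data are split at patch level, stratified 80:20 into a fixed test set plus
five stratified cross-validation folds of the training pool — faithful to
the source, which partitions patches, so one patient's patches may straddle
splits. A grouped variant (`groupOn = "patient"`) that allocates whole
patients is provided for leakage-averse analyses. Per fold, the band
ranking, the feature scaler and the class weights are all recomputed from
that fold's training data; the ranking and scaler fitters accept the
held-out ids and raise an error on contamination. With patch-level splits a
patient may legitimately appear on both sides, so the scaler assertion
targets patients that have *no* training patches. "Class-balance
processing" of the test pool is implemented as seeded resampling to a
per-class target (`balanceClasses`), used for confusion-matrix reporting
parity and never baked into metric definitions.

## Evaluation

Per-class one-vs-rest ROC-AUC is computed by the midrank (Mann-Whitney)
formula — tied pairs count 1/2, identical to the trapezoidal ROC area — and
the macro AUC is the unweighted mean over classes; a class absent from the
evaluated labels yields `NA` and is excluded from the mean with a warning.
Accuracy is the confusion-matrix diagonal fraction; per-class F1 is
$2PR/(P+R)$ with 0 when $P+R=0$; macro F1 the unweighted mean. Model
variants are compared by two-sided paired t-tests on fold-wise metrics
(5 pairs, df 4), with explicit degenerate handling: all-zero differences
give $t=0, p=1$; constant nonzero differences are flagged and reported at
$p=0$ rather than dividing by a zero standard error.

## The synthetic-data generator

The study's clinical data are private, so the generator emulates the
*statistical structure* the pipeline consumes, not histology: patches are a
flat 0.8 reflectance baseline minus per-class Gaussian absorption dips
(centre, depth and width configurable), plus a mild smooth spatial texture
and i.i.d. pixel noise, clipped to [0, 1.5]; radiomic vectors are unit-noise
Gaussians whose class means are raised by `radiomicsEffectSize` on a
class-specific block of informative coordinates. A `complementarity`
parameter in [0,1] makes that fraction of class pairs spectrally identical
— those classes are then separable only through radiomics, which is what
gives the fusion-versus-HSI-only comparison its teeth. Reference-cube
generation inverts the calibration formula, so calibrate-after-generate
recovers the planted reflectance exactly at zero noise. Everything is
bit-reproducible under the spec's seed.

Within-class spectral variance of real stained tissue is not characterized
in the source, so synthetic difficulty (depth vs noise) is a free parameter
chosen once for clear separability, not a calibration to real data. Passing
the synthetic experiments therefore demonstrates that the implementation
learns and fuses as designed — not that it would reach any particular
accuracy on clinical material.

## Reduced experiment scale and numerical choices

The clinical-scale problem (1931 patches of 300x100x100) is far beyond a
single CPU, and the package's reference experiments instead run at reduced
scales chosen once:

* **Learnability** (`learnabilityExperiment`): 6 classes x 30 patches,
  64 bands, 50x50 pixels, 16 selected bands, one CV fold, at most 30
  epochs; the run stops once validation accuracy reaches 95%.
* **Fusion benefit** (`fusionBenefitExperiment`): complementarity 0.5,
  6 classes x 20 patches, 48 bands, 32x32 pixels, 12 selected bands,
  5-fold CV of multimodal vs `hsi_only` on identical splits (ten
  trainings), up to 10 epochs per fold. With half the class pairs
  spectrally collapsed, HSI-only accuracy is capped near 2/3 while the
  fused model can separate all six classes; accuracies are paired per fold
  for the t-test.

Both experiments use Adam at $10^{-3}$ — the package's scaled-down setting,
since the reference $10^{-4}$ is matched to hundreds of epochs over
thousands of patches; the package default remains $10^{-4}$.

Other numerical choices: equal-width MI histograms return exactly 0 for a
constant band (one occupied bin) rather than erroring; MI selection ties
break toward lower band indices; max-pool argmax ties break toward the
first window element; batch norm uses biased batch variance with momentum
0.1 and $\epsilon = 10^{-5}$; dropout is inverted (scaled at train time);
Adam follows the usual bias-corrected moments with weight decay added to
the gradient. Degenerate architecture requests (a pooling chain that
empties a dimension) fail at `shapeTrace()` with the layer named.

## Known limitations

* The synthetic generator does not model stain chemistry, nuclear
  morphology, spatial class structure within a section, or MRI physics.
* Training is CPU-only and single-threaded beyond BLAS; clinical-scale
  inputs would require days, not minutes.
* The kNN-based continuous MI estimator used by some toolchains is not
  implemented; the histogram estimator is the package's normative choice.
* Patch-level splitting, though faithful to the source, lets patients span
  train and test; the grouped splitter exists precisely because this
  inflates patch-level estimates on real data.
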