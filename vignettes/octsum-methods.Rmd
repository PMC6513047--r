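---
title: "Summarising SDOCT volumes: models, phantoms and design choices"
author: "octsum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Summarising SDOCT volumes: models, phantoms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octsum)
```

## The problem

A macular SDOCT acquisition is a stack of 100 or more cross-sectional
B-scans; in an AMD clinic most of them are unremarkable, and the few that
show drusen, pigment epithelial detachments (PED), geographic atrophy (GA)
or epiretinal membranes (ERM) are scattered through the volume. `octsum`
condenses a volume into a small set of key B-scans in three steps:

1. **Localise and standardise.** Each B-scan is reduced to its retinal
   region and resampled to a fixed size.
2. **Detect.** A compact convolutional network scores each B-scan for
   "relevance" (visible structural abnormality), trained under a
   class-balanced cross-entropy loss.
3. **Summarise.** Flagged slices are grouped into contiguous regions and
   each region is reported by its first, median and last flagged scan.

Clinical SDOCT data of the kind the method targets is not redistributable,
so the package ships a synthetic phantom generator that reproduces the
geometry and artifact taxonomy of such acquisitions; every stage of the
pipeline is developed and tested against it.

## Retina localisation

Retinal interfaces are horizontal intensity steps, so the axial first-order
Gaussian-derivative response (sigma = 6 px, edge replication) is large at
the internal limiting membrane (ILM) and at the ellipsoid-zone/RPE complex.
The absolute response is thresholded by Otsu's method over a 256-bin
histogram, the two largest 8-connected components are taken as the two
interface bands, and their joint row span defines the crop. Spans shorter
than 300 px (at the full 512-row scale) are expanded symmetrically about
the span centre and shifted back inside the image, so the crop height
contract holds even at image borders. The crop is resized bilinearly to
300 x 512 and halved again to 150 x 256 for the network input, with
intensities rescaled to [0, 1].

Design points the published recipe leaves open, fixed here once:

* the derivative is taken along the axial (row) axis only and its absolute
  value used — lateral gradients carry no layer information;
* Otsu uses the standard exclusive-cut, cumulative-moment formulation over
  256 bins spanning the data range (the threshold is the boundary between
  the optimal cut's bins);
* components use 8-connectivity; equal-sized components rank by topmost
  row;
* resizing is bilinear;
* for phantoms smaller than full scale the 300 px minimum scales
  proportionally (`round(300 * nRows / 512)`);
* augmentation order is rotate, translate, contrast-scale about the image
  mean, horizontal flip, with ranges ±5°, ±10 px, [0.3, 1.7] and flip
  probability 0.5.

## The classifier

```{r architecture}
net <- buildDenovoNet(networkConfig(), seed = 1)
net
```

Seven 3x3 convolutional layers (ReLU) are wired with concatenating skip
connections: layer *i* computes `c_i = relu(conv(x_i))`, and
`pool(concat(x_i, c_i))` feeds layer *i+1* (2x2 max pooling). After layer 7
a global average pooling (GAP) layer reduces the concatenation — 609
channels with the default filter widths [32, 64, 64, 64, 128, 128, 128] —
to one value per channel, and a fully connected 2-way softmax provides the
class probability. Filter widths are not published; these were chosen so
the trainable-parameter count reproduces the printed "1.4 million"
exactly: 1,388,480 convolutional + 1,220 fully connected = 1,389,700.

Pooling after *every* layer leaves a 1 x 2 final feature map, which makes
class activation maps (CAM) nearly structureless. `poolingMode =
"cam_friendly"` therefore pools after layers 1–5 only (4 x 8 final map);
the parameter count is unchanged, and the faithful `"literal"` schedule
remains the default.

The loss is the class-balanced cross-entropy
$$ L = \sum_i \big[ -C_2\, y_i \log \hat y_i \;-\; C_1\, (1-y_i) \log(1-\hat y_i) \big], $$
with $C_1$ the number of relevant and $C_2$ the number of normal samples
in the batch: each class's term is weighted by the *other* class's count,
the only reading under which the loss counteracts imbalance (each class
then contributes total weight $C_1 C_2$). Probabilities are clipped at
$10^{-7}$ before the logarithm. The decision threshold on the softmax
output is 0.5.

The network, its gradients and Adam optimisation are implemented in the
package itself (single-precision im2col + GEMM convolutions in
C++/Armadillo); gradients are verified against directional finite
differences in the test suite.

## Training protocol

Volumes — never individual B-scans — are allocated to training, validation
and test sets at 75/10/15, so slices from one volume cannot leak across
sets. Cross-validation runs `nFolds` independent seeded re-splits at those
fractions: a strict 10-fold partition is impossible at a 15% test
fraction, and independent re-splits preserve the property that each fold's
test volumes are unseen in that fold. Adam uses the published
hyperparameters (lr 1e-6, beta1 0.9, beta2 0.999, eps 1e-8) by default.
Two published stopping rules are both implemented and selectable:
`loss_delta` (stop when validation loss has not improved by more than 0.1
— read as an absolute delta — for `patience` epochs) and
`val_auc_plateau` (validation AUC unchanged within 1e-4 for `patience`
epochs); the hard cap is 150 epochs. Batches are shuffled without class
stratification — the loss handles imbalance — and a single-class batch
degenerates gracefully (the absent class's weight is zero; a warning is
logged when the whole training set is single-class).

At the phantom scales used for testing, the default 1e-6 learning rate
converges impractically slowly; the synthetic experiments in the test
suite therefore document lr 1e-4 with batch size 16, and cap the
detection experiment at 8 epochs with AUC-plateau early stopping — well
under the protocol's 30-epoch ceiling and enough for the phantom task to
saturate (validation AUC exceeds 0.95 within 5 epochs).

## Summarisation rules

Flagged slice indices are grouped greedily left to right: a gap of at most
`T` slices (default 3) merges, a larger gap opens a new region. Each
region reports (first, median, last); the median is the *lower* median of
the flagged list, so the reported scan is always one the classifier
actually flagged. `M` regions yield exactly `3M` keyframes (duplicates
retained in the count, deduplicated in the rendered montage). When nothing
is flagged the summary falls back to three default slices — two
peripheral, one central. The peripheral slices sit at fractions 0.1 and
0.9 of the depth rather than at the volume ends, which are routinely low
quality; the central slice is `ceiling(n/2)`. `T` is measured in slice
indices (the protocol does not state units; at 100 slices over 6.7 mm one
slice is 67 µm). All slice indices in the package are 1-based, R's native
convention.

```{r summary}
summarizeVolume(c(10, 11, 12, 40, 42, 80), nSlices = 100)
```

## The phantom generator

The generator emulates the study data's geometry, not OCT physics: a
five-level layered retina (vitreous, inner retina, ellipsoid band, RPE
band, choroid), a Gaussian foveal dip pulling the ILM toward the RPE at
the volume centre, smooth low-frequency surface undulation across columns
and slices, and multiplicative Gamma speckle (mean 1, sd = `speckle`,
default 0.2) — speckle 0 reproduces the noiseless rendering exactly.
Full-scale geometry is 100 B-scans of 512 x 1000; tests use a half-scale
"desk" geometry of 24 B-scans of 256 x 512. (Published descriptions of
such acquisitions disagree on the lateral size — 1000 A-scans per the
protocol, 1024 px per the processing text — so the generator leaves
`nCols` configurable and defaults to 1000.)

Lesions are rendered to be visually and statistically separable, scaled to
plausible physical sizes (axially ~3.3 µm per pixel at full scale):

* **drusen** — narrow Gaussian upward bumps of the RPE/EZ (support < 60 px
  full scale, amplitude ~3.5–7% of the axial extent, i.e. ~60–120 µm);
* **PED** — the same profile with broad support and larger amplitude;
* **GA** — RPE band intensity replaced by vitreous level with the
  underlying choroid brightened (light penetration);
* **ERM** — a thin bright line a few pixels above the ILM.

Bump amplitude is modulated by a half-sine across the lesion's slice
range, so lesions form contiguous dome-shaped regions across adjacent
slices, as disease regions do. Slices covered by an artifact — lateral
shadows (columns attenuated), global contrast loss, or a mirror artifact
(the top 40% of the vertically flipped scan composited over the image) —
carry the ground-truth label `poor_quality`; slices covered by a lesion of
positive amplitude are `relevant`; the rest are `normal`. Label assignment
is purely rule-based, so every downstream stage can be property-tested
against it.

`generateCohort()` emulates a mixed study population: 30% lesion-free
volumes (the healthy proportion of a typical AMD cohort), 1–3 random
lesions otherwise, and an acquisition artifact in half the volumes
covering 10–40% of their slices — about 12% of all B-scans, close to the
~15% poor-quality rate such studies report. All randomness flows through
explicitly derived seeds; identical configuration and seed give
bit-identical volumes.

What the phantom deliberately does *not* model: realistic speckle
statistics and shadow texture, vessel shadows, vendor-specific intensity
response, curvature from off-axis scanning, or segmentation-grade layer
anatomy (no ONL/OPL separation, no choroidal vasculature). Passing the
synthetic detection experiment therefore shows the pipeline is wired
correctly and that the detector can learn structural abnormality from
realistic geometry under speckle — it does not certify clinical
performance, which the original study established on ~32,000 annotated
B-scans.

## Evaluation

AUC uses the rank (Mann-Whitney) formulation with midranks, equal to the
trapezoidal ROC area; sensitivity, specificity, FPR and FNR come from the
2x2 table at threshold 0.5. The Wilcoxon rank-sum test reports the
midrank statistic with an exact two-sided p by enumeration of all
$\binom{n_a+n_b}{n_a}$ assignments when $n_a+n_b \le 12$, and a
tie-corrected normal approximation with continuity correction otherwise;
per-fold AUCs of two models are compared unpaired, as the protocol names
the test. Cross-validation dispersion uses the sample (n-1) standard
deviation.

## Numerical and degenerate-input choices

* Otsu on a constant image raises an error (degenerate histogram); a
  localisation failure falls back to the full-image crop with a warning.
* Max pooling uses floor semantics; a dimension of size 1 passes through
  unchanged, so arbitrarily small inputs remain well-defined.
* The network runs in single precision; loss values agree with the
  double-precision reference implementation of the loss to ~1e-6 and
  gradients with finite differences to ~1e-3 (relative, directional).
* TIFF volumes are stored as 32-bit samples: round trips are exact for
  labels and metadata and within 2^-32 per pixel.
* Ties in component ranking (equal pixel counts) break toward the
  component nearer the image top, keeping localisation deterministic.

## Problem sizes in the shipped experiments

The test suite and the acceptance script run entirely on phantoms:
20 full-scale (512 x 1000) B-scans for the localisation contract, a
30-volume desk-scale cohort (24 x 256 x 512; ~720 B-scans, ~490 usable
training slices) for the detection experiment, and micro-scale phantoms
(128 x 256) for property tests. These sizes were chosen so the whole suite
reproduces on a single CPU in well under half an hour while still
exercising the full-scale geometry where the contracts refer to it.
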