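---
title: "Methods: pixel-wise stain classification and radial ring profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pixel-wise stain classification and radial ring profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stainring)
```

## Scope and model

stainring quantifies patterned differentiation of stem-cell colonies in
circular micro-confinements from dual-chromogen-stained RGB micrographs.
Two chromogens mark the lineages — Oil Red O (red, lipid droplets,
adipogenic) and Fast Blue (blue, alkaline phosphatase, osteogenic) — and
area negative for both is read as undifferentiated cells inside the
confinement and as background outside. The analysis is deliberately
pixel-wise: each pixel is assigned one of the three classes using only
its own $(R, G, B)$ triple, with no spatial context, so the classifier is
a partition of the $[0,255]^3$ color cube.

### The classifier

Pixels of single-class reference crops form three clusters in RGB space,
spread roughly along the gray diagonal from black to white and displaced
toward red (adipogenic), blue (osteogenic) and white (negative). A
support vector machine separates them:

* **Features.** Channels divided by 255, so features lie in $[0,1]^3$.
  Kernel-width heuristics behave poorly on 0–255 ranges, and the scaling
  convention travels inside the serialized model.
* **Kernel and hyperparameters.** Radial-basis kernel
  $K(x, x') = \exp(-\gamma\|x-x'\|^2)$ with cost $C = 1$ and
  $\gamma = 1/(3\,\mathrm{Var}(x))$, the inverse-feature-count-times-variance
  heuristic computed on the scaled training features. All three are
  arguments of `train_stain_classifier()`. These are the standard
  defaults of widely used SVM libraries; with the cluster separations
  typical of chromogen staining the fit is insensitive to them.
* **Multi-class rule.** One-vs-one voting over the three pairwise
  decision functions. A vote tie is resolved by the accumulated
  decision-function margin, then by the lowest class code — a fully
  deterministic rule, implemented in the package directly on the fitted
  support vectors and dual coefficients. The quadratic program itself is
  solved by libsvm (via e1071); the package's own decision-surface code
  is what both the in-memory and the deserialized model use, which is
  why predictions are bit-identical across a JSON round-trip.
* **Training order.** Feature rows follow crop-list order then row-major
  pixel order, so order-sensitive trainers see identical input on every
  run; training is reproducible.
* **No spatial post-filtering.** Isolated misclassified speckles (e.g.
  stray "adipogenic" pixels in an osteogenic field) are left as they
  are; pixel-level accuracy makes them a small, quantified error and
  filtering would entangle classification with morphology.

Degenerate inputs: a class with zero training pixels is a configuration
error; two classes with identical feature sets train with a warning (the
boundary between them is arbitrary); colors outside $[0,255]$ are
rejected; alpha channels and grayscale images are flattened to 8-bit RGB
with a warning.

Training accuracy is reported as $1 - \text{errors}/\text{total}$ on the
training pixels themselves, with the full 3×3 confusion table
(`evaluate_training_accuracy()`), matching the way pixel classifiers of
stained micrographs are conventionally summarized. Overlap between the
red/blue/white clusters — dark pixels, mixed stains — bounds this
accuracy below 1 on real data.

### Radial profiling

Given a label map and a confinement geometry (center in px, radius, µm
per px), `build_ring_index()` partitions the in-circle pixels into
coaxial rings of thickness $\Delta r$ (default 25 µm):

* Distances are measured from **pixel centers**; ring $k$ is the
  half-open interval $[k\Delta r, (k{+}1)\Delta r)$; the outermost ring
  is truncated at the confinement radius, and
  $\text{ring count} = \lceil R/\Delta r\rceil$. These conventions make
  the partition exact: every in-circle pixel lies in exactly one ring,
  which the tests check against exhaustive per-pixel enumeration.
* Per ring, the class fraction is a plain pixel tally divided by the
  ring's pixel count. Pixels outside the circle are excluded entirely
  (outside-confinement area is acellular agarose). Empty rings are
  flagged `NA`, never silently 0/0.
* Replicates aggregate per ring as the arithmetic mean and sample SD
  ($N-1$ denominator) of the fractions; a ring empty in some replicate
  is excluded from that ring's aggregation rather than imputed as zero,
  and SD is `NA` below two contributing replicates. Fractions are
  aggregated directly (not re-weighted by per-replicate ring areas):
  replicates of one nominal geometry have near-identical ring areas, so
  the two conventions coincide to rounding.
* Because the field describes radial position both as distance from the
  center and as distance from the confining wall, every profile table
  carries both columns (`r_mid_um` and `dist_wall_um`); neither is
  privileged.

Confinement geometry is a user input whenever it is known.
`detect_confinement()` offers a fallback: the center is the centroid of
the foreground (non-negative labels, or color-thresholded foreground for
raw images, default: more than 40 channel units from white), and the
radius comes from the
expected diameter when given — with a warning if the equivalent-area
estimate deviates by more than 20% — else from the circle of equivalent
foreground area. Centroid detection assumes a roughly complete, roughly
centered colony; strongly asymmetric colonization biases it.

## The synthetic colony simulator

`simulate_colony()` generates study-condition fixtures with exact ground
truth. Defaults are chosen once to mimic the observed structure:

* **Color model.** Isotropic Gaussian per class, means (180, 60, 60) /
  (60, 60, 180) / (225, 225, 225), channel SD 10, clipped to $[0,255]$
  and quantized — three clusters along the gray diagonal displaced
  toward red, blue and white. No numeric color statistics are published
  for the stains, so these are package defaults (all configurable), set
  to reproduce the qualitative cluster geometry rather than any
  instrument.
* **Radial layout.** Three-zone step: adipogenic core to
  $r_\text{adipo}$, osteogenic annulus to $r_\text{osteo}$,
  undifferentiated rim to the wall (default core = 25% of the diameter,
  annulus to 85% of the radius), with optional per-zone class-probability
  mixtures and a logistic-blend variant for smooth transitions. The
  geometries of interest are 200, 400 and 800 µm diameters.
* **Determinism.** All sampling runs under R's Mersenne-Twister with the
  supplied seed (recorded in the output parameters); identical seeds
  give bit-identical images, labels and geometry.

What the simulator does **not** emulate: cell morphology and texture,
lipid-droplet granularity (only an optional brightness-attenuation
"shading" field for dark areas in training crops), uneven illumination,
chromatic mixing of co-stained pixels, and camera noise statistics
beyond isotropic Gaussian color jitter. Passing the end-to-end tests
therefore demonstrates that the machinery is correct — training recovers
planted color clusters, classification recovers planted labels, rings
recover planted radial structure — not that any particular accuracy will
be attained on real micrographs, where cluster overlap is larger and
structured.

## Verification approach and problem sizes

The test suite checks every stage against an independent oracle:
nearest-centroid labels for well-separated clusters, brute-force
per-pixel enumeration for ring partitions, closed-form two-replicate
SD for aggregation, byte-comparison for determinism, and the simulator's
ground truth for end-to-end recovery. Suite defaults are sized for fast
iteration — 1000 training pixels per class, colonies up to 512×512 px,
12 replicates for the radial-recovery check — which keeps the full run
in seconds while leaving the statistical margins (e.g. ≥ 99% per-pixel
agreement at channel SD 10) wide.

## Known limitations

* Pixel independence is a modeling choice: no neighborhood context, no
  blob-size reasoning. A minimal spatial escape hatch (minimum-blob-area
  filtering) is deliberately not applied by default.
* Color deconvolution / stain unmixing is out of scope; heavily
  co-stained pixels are forced into one class.
* Only circular confinements are supported; ring profiling of other
  geometries would need a different coordinate.
* Reported training accuracy is an apparent (resubstitution) accuracy,
  the field's convention for this assay; it is optimistic relative to
  held-out accuracy when clusters overlap.
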