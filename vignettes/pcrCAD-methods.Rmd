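---
title: "pcrCAD: models, design choices and what the synthetic tests show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pcrCAD: models, design choices and what the synthetic tests show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcrCAD)
```

## The problem

After neoadjuvant chemotherapy (NAC), a fraction of breast-cancer patients
reach pathological complete response (pCR): no residual invasive tumor in
the primary lesion. Reading post-NAC MR images for pCR is experience-bound
and variable between radiologists, which motivates computer-aided
diagnosis (CAD): segment the residual mass, describe its shape and
internal texture numerically, and classify pCR vs non-pCR with a
maximum-margin classifier. pcrCAD implements this pipeline end to end —
segmentation, 13 shape + 48 texture features, SVM under a 5-part split
rotation, and the reader-study statistics used to evaluate such systems —
together with a synthetic lesion phantom generator so that every stage is
testable without clinical images.

## Lesion phantoms

A phantom contour is a star-convex radial function

$$ r(\theta) = R\,\bigl(1 + a\cos(k\theta + \phi)\bigr) \;+\;
   \sum_{s} \ell R \,\max\!\bigl(0,\, 1 - |\theta - \psi_s| / w\bigr), $$

a single radial harmonic of order $k$ (lobulation: a $k$-th harmonic gives
exactly $k$ lobes, which is what makes the leaflet-count feature testable
against a known truth) plus triangular spicules of length $\ell R$ at
seeded random angles $\psi_s$ with angular half-width $w = 0.1$ rad. A
single harmonic rather than a mixture keeps lobulation and spiculation
independently controllable — precisely the two axes the shape panel must
detect. The analytic area $\pi R^2 (1 + a^2/2)$ of the harmonic contour
anchors a rasterization-consistency test (5% tolerance for $R \ge 10$ px).

Interior texture is either *homogeneous* (constant foreground 180 of 255,
plus Gaussian noise) or *heterogeneous*: the foreground is multiplied by a
seeded Gaussian random field smoothed with a $\sigma = 2.5$ px kernel and
scaled to $1 \pm 0.35$, imitating necrosis-like internal patches. The
background carries noise only. Images are 8-bit, which leaves 8 intensity
steps per bin at the default 32-level GLCM quantization.

`makeCohort()` draws per-case specs with exact class and molecular-subtype
margins. Non-pCR lesions are drawn from a rougher distribution than pCR
lesions; the gap is controlled by `classEffect` $\in [0,1]$:

* lobulation amplitude: $U(0.02, 0.10)$, plus
  `classEffect` $\cdot\, U(0.12, 0.22)$ for non-pCR;
* spicules: $\mathrm{Bin}(2, 0.15)$, plus
  $\mathrm{Bin}(6, 0.65\cdot\texttt{classEffect})$ for non-pCR;
* heterogeneous texture with probability $0.15$, plus
  $0.70\cdot\texttt{classEffect}$ for non-pCR.

At `classEffect = 0` the two class distributions are *identical* (the same
random draws are consumed either way), which is what makes the
permutation-null check meaningful. At `classEffect = 1` the spicule-count
and amplitude ranges barely overlap, so a working pipeline should recover
the label with high AUC — by construction, not by tuning. Subtypes are
assigned by a seeded shuffle and are independent of morphology: the
subtype breakdown exercises the *reporting* machinery, not a biological
claim. Radii are drawn as $U(0.125, 0.22)\cdot$`imageSize` so lesions with
their worst-case spicules always fit the canvas. No pixel spacing is
modelled; all geometry is in pixels. The phantoms do **not** mimic DCE-MRI
enhancement kinetics, partial-volume fuzz at the margin, biopsy clips, or
multi-focal disease — a classifier that separates the phantom classes has
been shown to work mechanically, nothing more.

## Segmentation

The segmenter is a small U-Net-style encoder-decoder written directly on
matrix operations: residual conv units
$\mathrm{relu}(W_{3\times3} * x + W_{1\times1} x + b)$, $2\times$
max-pooling per encoder stage, nearest-neighbour upsampling with skip
concatenation per decoder stage, and a $1\times1$ head giving per-pixel
foreground logits. It is optimized with Adam (additive L2 weight decay) on
pixel-wise binary cross-entropy, one image per step in fixed order, so a
given seed reproduces training bit for bit.

The default `segTrainConfig()` mirrors the full-scale recipe this family
of CAD systems trains with — learning rate $10^{-5}$, 500 epochs, weight
decay $5\times10^{-4}$, Adam, cross-entropy. The package's own test runs
use the desk-scale variant (32 px images, depth 2, 8 base channels,
learning rate $3\times10^{-3}$, 120 epochs), which trains in seconds on
one CPU and reaches held-out Dice above 0.95 on easy high-contrast
phantoms; the tested acceptance bar is 0.8. Binarization threshold is 0.5
(configurable), and only the largest 8-connected component is kept, since
the downstream features assume a single lesion and multi-focal cases are
evaluated on their largest mass. An all-background probability map raises
a classed `emptySegmentationError` rather than passing an empty mask
downstream. Batch size, normalization (intensities divided by 255) and the
absence of augmentation are deliberate simplifications of an otherwise
standard recipe.

## The 13 shape features

The shape panel is classic normalized-radial-length (NRL) morphometry.
The boundary is the set of in-mask pixels with a 4-neighbour outside,
ordered counterclockwise by polar angle about the pixel-center centroid
(ties broken by radius); radial lengths are normalized by their maximum,
$nd_i = d_i / \max_j d_j$. Features, in canonical column order:
roundness $4\pi A/P^2$; min-area rotated bounding-box aspect ratio; NRL
mean, population SD and 10-bin histogram entropy; area ratio
$\sum_i \max(nd_i - \overline{nd}, 0) / (\overline{nd}\,N)$; elongation
and direction angle from the second-central-moment (inertia) ellipse;
leaflet count; spiculation; boundary roughness
$\mathrm{mean}\,|\Delta nd|$; perimeter over the Ramanujan perimeter of
the inertia ellipse; and the Jaccard overlap with that ellipse rendered in
place. Two distinct aspect ratios are on purpose: the rotated-bounding-box
ratio responds to envelope geometry, the moment ratio to mass
distribution; they diverge for spiculated masses.

Numerical choices that matter:

* **Perimeter.** The raw angle-ordered boundary polygon overestimates
  length by a few percent (half-pixel zigzag), enough to push disk
  roundness to 0.94. The polygon is therefore smoothed with a light
  (1/4, 1/2, 1/4) circular kernel before measuring length. Digitized
  disks then land slightly *above* 1 (area and perimeter discretize with
  opposite bias, $\sim\!13\%$ at $R = 8$, $\sim\!3\%$ at $R = 20$), which
  is why the documented range of roundness is $(0, 1+\varepsilon]$.
* **Leaflets.** Local maxima of the circularly smoothed NRL series
  (moving-average window $N/16$, minimum 3) with topographic prominence
  $\ge 0.05$. The prominence gate is what separates a genuine lobe from
  residual pixel ripple.
* **Spiculation.** Density of sign changes of the first circular NRL
  difference, with differences below one pixel of radial change
  ($1/\max_j d_j$) treated as flat. Without that quantization floor a
  plain disk out-scores a spiculated mass, because half-pixel jitter
  alternates sign at almost every boundary step.
* **Scale behavior.** Everything except spiculation and boundary
  roughness is scale-free up to discretization (tested at $<5\%$ drift
  under $2\times$ upscaling). Those two are first-difference statistics
  of the NRL series and scale with boundary sampling density — i.e. with
  lesion size in pixels — by definition. They are kept in their classic
  per-step form; comparisons across very different lesion sizes should
  keep that in mind. The direction angle is undefined in any meaningful
  sense for near-isotropic contours.
* Translation invariance is exact up to floating-point roundoff; under
  90° rotation every feature is stable within 5% and the direction angle
  shifts by $\pi/2$ modulo $\pi$.

Masks with fewer than 8 boundary pixels, several components, or no
foreground raise a `featureUndefinedError`.

## The 48 texture features

In-mask intensities are quantized to 32 equal-width levels over the
in-mask min–max range (constant regions map to level 0). For each of
3 offset distances {1, 2, 3} px and 4 directions {0°, 45°, 90°, 135°}, a
gray-level co-occurrence matrix is accumulated over all pixel pairs with
*both* ends inside the mask, symmetrized by adding its transpose, and
normalized to sum 1. Four Haralick statistics per offset — energy
$\sum p^2$, correlation
$\sum (i-\mu_x)(j-\mu_y)p\,/\,\sigma_x\sigma_y$, contrast
$\sum (i-j)^2 p$, entropy $-\sum p \log_2 p$ — give
$4 \times 3 \times 4 = 48$ features named `<stat>_d<distance>_a<angle>`,
ordered statistic-major. Symmetrization plus normalization is what
guarantees correlation $\in [-1, 1]$. Two degenerate rules are fixed and
tested rather than left to NaN: $\sigma_x\sigma_y = 0$ (all mass on one
level) defines correlation $= 1$, and an offset with no valid pair returns
the constant-ROI statistics (energy 1, contrast 0, entropy 0,
correlation 1) with the matrix flagged `degenerate`. Entropy uses base-2
logarithms; any fixed base only rescales. The implementation is vectorized
but is held exactly equal — integer counts before normalization — to a
brute-force double loop over pixel pairs in the test suite.

## Classifier and split rotation

Cases are dealt into 5 parts per class by a seeded shuffle (per-class part
sizes differ by at most one case, e.g. 123 positives split 25/25/25/24/24).
Rotation $r$ tests on part $r$, validates on part $(r \bmod 5) + 1$, and
trains on the other three parts; across rotations each case is tested
exactly once, and metrics are computed on the pooled test-role
predictions (pooling, rather than averaging per-rotation metrics, keeps
every case's weight equal and yields a single ROC).

Within a rotation: per-feature z-standardization is fitted on the
training rows only (margins are distances, so features must be on
comparable scales); the soft-margin cost is selected from
{0.01, 0.1, 1, 10} by validation AUC; classes are weighted by inverse
prevalence (the pCR class is a 26% minority in the emulated cohort);
and the operating threshold for binary calls is fixed on the validation
part by the Youden index, then frozen for the test part. The kernel is
linear by default — matching the separating-hyperplane formulation — with
RBF available. The quadratic program itself is solved by libsvm via
\pkg{e1071}; in the separable hard-margin limit the exposed $(w, b)$
satisfy $|w^\top x + b| = 1$ on support vectors, which the tests assert to
$10^{-6}$. A leakage canary test (a feature informative only in a test
part) verifies that neither standardization nor model selection ever sees
test rows.

## Evaluation statistics

`confusionMetrics()` reports sensitivity, specificity and accuracy as
percentages and an AUC: Mann–Whitney with a DeLong 95% CI when scores
exist, and the single-operating-point trapezoid $(Se + Sp)/2$ for
call-only deciders (a binary reader has one ROC point; the two-segment
curve through it has exactly that area). Rounding everywhere is half away
from zero — percentages to 2 decimals, AUCs to 3 — because that is how
diagnostic tables are printed, and `reconstructCounts()` exploits it:
from a printed $(Se, Sp)$ pair and the class sizes it recovers the integer
TP/TN counts and the accuracy and AUC they imply, making published tables
internally checkable without the underlying images. On the example
operating-point table shipped with the package this reconstruction
reproduces the printed accuracies and AUCs at printed precision, with two
instructive exceptions: the CAD row's accuracy computes to 83.62 vs a
printed 83.61, and the HER2+ subgroup's implied AUC is 0.855 vs a printed
0.827 — the only row whose printed AUC is inconsistent with its own
printed sensitivity/specificity under the rule that reproduces every
other row.

CAD-assisted reading is OR-fusion: positive iff the reader or the CAD is
positive. Fused sensitivity can only rise and fused specificity only
fall relative to each component, which is asserted on every synthetic
pair. Method comparisons default to the unpaired Pearson chi-square on
the correct/incorrect-by-method table (no continuity correction, so the
statistic equals $\sum (O-E)^2/E$); because two methods read the same
cases, the paired McNemar variant is provided and the choice is recorded
with the output. The default significance level is 0.05. Subtype
summaries flag (rather than fail on) subgroups where only one truth class
is present.

## Problem sizes used by the checks

The test suite and the acceptance script run entirely on generated
phantoms: a 60-case cohort (16 pCR / 44 non-pCR) for the separated-class
rotation run; twenty 470-case null cohorts at the emulated study margins
(123/347; subtypes 105/178/101/86) for the chance band; 8 training + 4
held-out 32 px phantoms for the desk-scale segmentation run; 200 random
instances each for the GLCM and AUC brute-force oracles. These sizes give
stable statistics while keeping a full run in a couple of minutes on one
CPU. A `classEffect = 1` cohort is separable nearly perfectly (pooled
AUC ≈ 1); this validates the mechanics and says nothing about clinical
performance, where class distributions overlap heavily.

## Known limitations

* Phantoms are 2D, single-lesion, star-convex, with stylized texture; no
  claim of DCE-MRI realism is made or needed for the checks they serve.
* Spiculation and boundary roughness depend on lesion size in pixels (see
  above).
* The segmenter is a deliberately small CPU implementation; it makes no
  attempt to reproduce any clinically trained network's weights or its
  real-data segmentation quality.
* Reader simulation treats per-case errors as independent Bernoulli draws
  at a fixed operating point — no case-difficulty correlation between
  readers, which real reader studies do exhibit.
* The DeLong interval shows its usual mild small-sample undercoverage;
  the coverage test uses 50 cases per class where it behaves nominally.
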