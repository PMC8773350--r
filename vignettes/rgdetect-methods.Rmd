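---
title: "Detecting retinal microaneurysms with ring gradient descriptors"
author: "RGDetect authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting retinal microaneurysms with ring gradient descriptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RGDetect)
```

## The problem

Microaneurysms (MAs) are saccular dilations of retinal capillaries and the
earliest visible sign of diabetic retinopathy. In a color fundus photograph
an MA is a dark, roughly circular blob a handful of pixels wide, with low
local contrast, embedded in a retina crossed by much larger dark vessels.
Automated MA detection is therefore a small-object detection problem whose
main confuser is the vasculature: almost any intensity-based candidate
extractor fires on vessel fragments as readily as on true lesions.

RGDetect implements a classical candidate-and-classify pipeline:

1. **Preprocessing** — resize to a fixed working width, normalize
   illumination and amplify local contrast, mask the field of view (FOV).
2. **Candidate extraction** — dual-gray-threshold segmentation with
   suppression of large (vessel) components.
3. **Feature extraction** — a 40-dimensional vector per candidate:
   6 first-order salience statistics, 24 co-occurrence texture features,
   and 10 *ring gradient descriptors* (RGD), the package's core feature.
4. **Classification** — a gradient-boosted regression-tree classifier on
   the logistic deviance, written from first principles.
5. **Evaluation** — candidate-level ROC/AUC and lesion-level FROC with the
   mean-sensitivity score (Fscore) and normalized partial area (FAUC).

## Preprocessing

Each channel is transformed as
$I' = \alpha I + \tau \, (G_\sigma * I) + \gamma$,
with defaults $\alpha = 4$, $\tau = -4$, $\gamma = 128$ and
$\sigma = w/30$ at working width $w$ (default 1400 px). Because
$\alpha = -\tau$, any locally smooth region maps to exactly
$\gamma = 128$: slow illumination and color variation are erased while
structures smaller than $\sigma$ keep an amplified contrast against a flat
128 background. This is what makes fixed gray thresholds meaningful across
images.

Numerical choices: the Gaussian kernel is truncated at $3\sigma$; the
convolution uses symmetric-reflection padding (the FOV rim, where
reflection is a poor model, is erased anyway by eroding the FOV mask — a
disc of radius 8 px at width 1400, scaled in the examples below). The FOV
mask itself is obtained by thresholding the red channel at 20 (red is the
brightest channel inside the FOV), keeping the largest 8-connected
component and filling holes. Rasters stay real-valued internally and are
only rounded to 8 bit on export.

## Candidate extraction

Two thresholds are applied to the preprocessed green channel (where MA
contrast is highest), both restricted to the FOV. The higher threshold
$T_h$ (default 110, sensible range 100–115) captures the connected vessel
tree; 8-connected components with area strictly greater than $S = 400$ px
form the vessel mask. The lower threshold $T_l$ (default 95, range 90–100)
captures lesion-dark pixels. The vessel mask is dilated with a $5 \times 5$
square so vessel *edges* are suppressed too, and subtracted from the
low-threshold image. Surviving 8-connected components with area
$\ge 2$ px (single pixels are treated as noise) become candidates,
summarized by centroid and area.

Two unstated conventions had to be fixed: connectivity (8-connected
throughout) and the treatment of the vessel-mask expansion, which we
implement as dilation — shrinking the vessel mask would defeat the stated
purpose of removing vessel edges. The thresholds have no per-image
selection rule; they are configuration constants at their range midpoints.

## The ring gradient descriptor

For a candidate-centered context window, let the central area be
$l \times l$ and consider the square annulus of width $b$ immediately
around it. A $b \times b$ scan box slides along the annulus with unit
step — each side contributes $b + l$ placements, $4(b+l)$ in total — and
the placement with the minimum arithmetic mean is retained. The descriptor
is

$$\mathrm{RGD} = \min_k \overline{A_k} \;-\; \sum_{ij} A_{ce}(i,j)\, G(i,j;\sigma),$$

the minimum surround mean minus the Gaussian-weighted mean of the center
($G$ is an $l \times l$ kernel normalized to unit sum, so a constant
window scores exactly zero; the weighting emphasizes the darkest core of a
lesion). For an isolated dark blob even the *darkest* surround patch is
bright, so RGD is large and positive; a vessel continues into the annulus,
the scan box finds its continuation, and RGD collapses toward zero. The
descriptor is invariant to adding a constant to the window and scales
linearly with intensity scaling.

Ten parameter settings are evaluated per candidate —
$b \in \{3, 5\}$ crossed with $l \in \{5, 7, 9, 11, 13\}$, with
$\sigma$ tracking $l$ as $(0.9, 0.7, 0.5, 0.5, 0.5)$ — spanning lesion
widths of roughly 3–13 px; all ten share one $23 \times 23$ window
($= \max l + 2 \max b$). A per-pixel descriptor map
(`rgdMap()`, defaults $b=5$, $l=7$, $\sigma=0.6$) supports stand-alone
pixel-level detection after min–max normalization; the printed source for
these three map parameters is garbled ("5.7, and 0.6") and our reading of
it is exposed as configuration.

Other open points we fixed: the salience "third moment" is the third
central moment of the 256-bin intensity histogram divided by $255^2$, and
"contrast" is the smoothness statistic $1 - 1/(1 + \sigma^2/255^2)$, both
from the standard first-order descriptor set; salience entropy is in bits
while co-occurrence entropy uses the natural log; co-occurrence matrices
use $N_g = 8$ uniform bins over $[0, 255]$ (no level count is stated in
the source material), are symmetric, and a zero-variance patch reports
correlation 0 rather than an error.

## The boosted-tree classifier

The classifier is additive logistic boosting with CART base learners,
implemented directly from its defining recursions: the initial score is
the prior log-odds $F_0 = \log \frac{p}{1-p}$; each round fits a
regression tree to the residuals $r_i = y_i - \mathrm{sigmoid}(F(x_i))$ by
exhaustive SSE-minimizing splits (midpoint thresholds, deterministic
tie-breaking toward the lowest feature index and threshold), replaces each
leaf mean with the one-step Newton value
$\sum r_i \,/\, \sum (y_i - r_i)(1 - y_i + r_i)$ (denominator floored at
$10^{-12}$ for pure leaves), and adds the leaf contributions shrunk by the
learning rate $\varepsilon$.

Defaults are $\varepsilon = 0.03$ with $M = 80$ boosting rounds. The
source material's tree-complexity constant is ambiguous (it could denote
rounds, depth or leaves); we read it as the number of rounds, with a fixed
depth limit of 3 and a minimum leaf size of 5 — all four are configuration
keys. No resampling or class weighting is applied; model selection uses
five-fold cross-validation by image.

## Evaluation conventions

Candidate-level: ROC over score thresholds, AUC by trapezoid (equal to
the Mann–Whitney pair-counting statistic). Lesion-level: detections are
matched to annotated centers greedily in descending score order, one match
per lesion, within 10 px at the 1400-px working scale (the matching rule
is plumbing we had to invent; the radius is configurable). The FROC curve
sweeps the score threshold, plotting sensitivity (over all lesions)
against false positives per image. Sensitivities at FPI
$\in \{1/8, \dots, 8\}$ use the conservative step convention — the best
sensitivity achieved at or below the target FPI — with linear
interpolation available by configuration. FAUC integrates the linear
envelope of the curve over $[1/8, 8]$ and divides by $8 - 1/8$, so a
perfect detector scores 1; the literal divide-by-8 reading is also
selectable.

## The synthetic generator

Real fundus datasets cannot ship with the package, so every claim the test
suite makes is grounded in a seeded generator
(`generateFundus()`): a bright FOV disc on black, a smooth tilted-plus-
radial illumination field, vessels drawn as smoothed random polylines with
Gaussian cross-profiles and slowly modulated depth, lesions as circular
Gaussian dips (radius 1–6 px, i.e. widths ≈ 3–13 px, matching the
descriptor grid), and additive Gaussian noise.

Intensities are calibrated by construction, not by fitting: background
120 maps to ≈ 128 after enhancement; lesion depths 25–60 map their centers
far below the $T_l = 95$ threshold; half the vessels are long and deep
enough to enter the vessel mask, while the rest are short, faint segments
that deliberately *escape* the area filter and become the vessel-fragment
candidates a classifier must reject — together with noise clusters, about
40 negatives per image against ~10 planted lesions, echoing the
strongly candidate-imbalanced regime of real screening data. What the
generator does **not** model: optic disc, fovea, exudates, hemorrhages,
camera artifacts, compression, or inter-device color variation. Passing
tests on this material demonstrates the internal correctness and the
qualitative feature behavior of the pipeline, not clinical performance.

Benchmark sizes used by the tests and the acceptance script: 40 images of
480 × 480 px (the pipeline configured at working width 480, so
$\sigma = 16$, erosion radius 3), ~10 lesions per image, five-fold
cross-validation by image — roughly 2,000 candidates. These sizes were
chosen as the smallest set on which fold-to-fold variation stops dominating
the feature-set comparison.

## Known limitations

* Thresholds $T_h$, $T_l$ are global constants; images whose enhanced
  background deviates from 128 inside dark lesions' neighborhoods (e.g.
  very low-contrast scans) shift the operating point.
* The vessel mask is a thresholded-component heuristic, not a vessel
  segmentation; thin low-contrast vessels below the area cutoff surface as
  candidates by design and must be rejected by the classifier.
* The boosted-tree implementation is exact but single-threaded R; for
  datasets beyond ~10^4 candidates an optimized library will be faster
  (one such library is used in the test suite as an agreement oracle, at
  matched hyperparameters, never as the implementation).
* Detection quality on real photographs depends on annotation coordinate
  frames; annotations are expected either in the working frame or in
  original coordinates together with the recorded resize factor.
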