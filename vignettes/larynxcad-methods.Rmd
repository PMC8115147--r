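---
title: "Quantitative laryngoscopy with LarynxCAD: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative laryngoscopy with LarynxCAD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

LarynxCAD turns a laryngoscopic video or still image into a lesion label
through six stages: frame screening, brightness compensation, contrast
enhancement, adaptive glottis/cord segmentation, feature extraction, and a
decision-tree-structured SVM. This vignette explains the models behind each
stage, the tunable parameters with their defaults and units, what the
synthetic phantom generator does and does not emulate, and the design
choices made where the problem was genuinely open.

## Frame screening

Endoscopic video mixes sharp frames with frames blurred by swallowing,
motion or saliva. Screening exploits a structural fact: the glottal space
images as a dark inverted triangle between the pale cords, and blur shrinks
its thresholded area. The stage therefore:

1. discards frames whose PSNR to the preceding frame falls below
   `psnrMin` (default 20 dB) — large inter-frame error indicates motion or
   noise bursts. The decision rule on inter-frame error admits more than
   one reading; we discard low-PSNR frames relative to their predecessor
   and expose the threshold, and we treat the first frame (which has no
   predecessor) as always eligible.
2. thresholds each surviving frame with the four-interval fast Otsu
   search. The intervals `[0, icp_b]`, `[icp_b, icp_m]`, `[icp_m, icp_f]`,
   `[icp_f, 255]` jointly cover the whole gray axis, so the search is a
   reorganization, not an approximation: `fastOtsu()` provably returns the
   exhaustive-search threshold, and the test suite verifies zero mismatches
   against a brute-force oracle on 200 seeded Gaussian-mixture images.
3. labels the dark (sub-threshold) class into 8-connected components and
   applies three structural conditions: centroid row within [50, 240] at
   the 288-row reference height (rescaled proportionally for other frame
   heights, since fixed pixel bounds would break on other sensors),
   bounding-box aspect ratio (width/height) at most 0.85 (the glottis is
   taller than wide; this also removes the image-wide dark endoscope
   border), and area at least 900 px. All bounds are inclusive and
   config-owned.
4. keeps, over all surviving frames, the frame whose largest screened
   glottal block has maximal area; ties resolve to the earliest frame for
   determinism.

The glottis is taken to be *darker* than the mucosa, so the "foreground"
for glottal screening is the sub-threshold class.

## Brightness compensation

Lens distance changes illumination: far lenses give dark images. The
histogram-translation compensation `I = O + (S − O_m)` shifts every pixel
by the difference between the set value `S` (default 125, low enough that
clipping is rare for endoscopic material) and the image mean `O_m`. When a
validity mask is supplied, the black endoscope border — which is defined
to be gray level 0 — is excluded from `O_m` so it cannot bias the mean;
the shift is still applied everywhere. The output is kept as numeric
grayscale rather than being re-quantized, so when nothing clips the
output mean equals `S` exactly and the operation is exactly idempotent.
The hue feature (a standard deviation) is invariant under this shift,
which is what makes it comparable across endoscopes and light sources.

## Contrast enhancement

CLAHE (default clip limit 2, 8×8 tiles) counteracts low local contrast,
and a small Gaussian smoothing (default 5×5 kernel, σ = 1 px) suppresses
noise before thresholding. The exact CLAHE and Gaussian settings are
deliberately configuration-owned defaults chosen from common practice; no
downstream contract depends on their precise values. The enhanced image
feeds *thresholding only*. The active contours evolve on the compensated
image with the segmented glottis removed: CLAHE's local histogram
remapping changes gradient magnitudes in a tile-dependent way, which
would distort the physical gradient scale the snake's stopping behavior
relies on.

## Adaptive active-contour segmentation

**Glottis.** `segmentGlottis()` is the screening chain (fast Otsu → 8-connected
components → structural conditions) ending in the largest surviving
region's mask.

**Seeds.** The glottis is transected horizontally through its centroid and
cut vertically through its lowest point (maximal row — the inferior apex;
rows grow downward, 1-based, origin top-left throughout the package). Thin
lateral bands hugging the glottis boundary between those two lines, one on
each side of the vertical cut, are the cord seed regions. The construction
of the "seed image" from these two cuts admits several readings; the
lateral-band reading used here is our documented interpretation, and every
geometric choice (band width, default 5 px) is a parameter.

**Snake.** Each cord contour is initialized as a thin closed band along the
full glottis boundary (median-smoothed over 9 rows so a ragged thresholded
boundary cannot tangle the polygon; the initial lateral offset is 6 px)
and evolved by a greedy Kass-style snake over the fixed functional

E = Σᵢ w_c (dᵢ/d₀)² + w_k |vᵢ₋₁ − 2vᵢ + vᵢ₊₁|²/d₀² − w_g G(vᵢ) − w_p s A/d₀

with defaults w_c = 1, w_k = 1, w_g = 1.2, w_p = 0.35. dᵢ is the spacing
to the previous vertex and d₀ the mean spacing of the initial contour,
frozen at initialization so the functional never changes during
evolution. G is the gradient magnitude of the Gaussian-smoothed image
(σ = 1 px), normalized by a *saturating physical scale* (default
12 gray/px): every anatomical edge at or beyond that gradient saturates
to strength 1, so a strong glottis rim cannot make the subtler lateral
cord edge invisible, while noise-level gradients stay weak. A is the
signed (shoelace) enclosed area and s its sign on the initial contour, so
the area term acts as an outward pressure: it carries the front across
homogeneous cord tissue, where a pure gradient snake has no force, and
the saturated edges stop it. The weight ordering matters: the pressure
gain of a one-pixel outward move (≈ w_p) must exceed the curvature cost
of starting a front wave in flat tissue but stay below the image-energy
loss of crossing a saturated edge; the defaults satisfy both with margin
on the phantom conditions. Each greedy vertex update evaluates *every*
term the vertex participates in (two continuity terms, three curvature
terms, its image term, its shoelace contribution) over a 3×3
neighborhood and requires strict improvement, so total energy is
non-increasing at every sweep by construction — asserted on every test
run.

**Stopping rule.** Lens distance rescales the anatomy, so no fixed sweep
count fits all acquisitions. Instead, the Shannon entropy (log₂, 256-bin
histogram) of the *growth range* — the pixels enclosed by the contour,
excluding the removed glottis — is recorded at every sweep. While the
front grows through the cord the enclosed histogram keeps changing; once
the contour settles on the cord boundary it stabilizes, and consecutive
entropies agree. Candidate k compares sweeps 12+k and 13+k, and the
selected count is 12+k* with k* the (earliest) argmin of |ΔH|, hard-bounded
to [13, 41]; a minimal difference at the 23rd candidate therefore selects
iteration 35, with saturation between sweeps 35 and 36. Evaluating the last
candidate requires evolving one sweep past the upper bound; the returned
count never exceeds 41. |ΔH| is minimized as a magnitude, and the log base
is immaterial to the argmin. Left and right cords run independently, so an
asymmetric lesion can change one side's count. The final cord mask is the
contour's interior minus the glottis mask and minus any sub-threshold
(dark-class) pixels — the thresholded glottis can under-cover the true
glottal space by a pixel or two, and those dark pixels belong to the
glottal gap, not the pale cord.

On noise-free phantoms across cord scales 0.5–2.0 the cord-area relative
error `100·|auto − reference|/reference` against ground truth stays below
10% (the package's own bar, asserted in the acceptance suite; the
corresponding validation against physician annotations requires clinical
data and is out of scope).

## Features

For each cord, the medial (glottis-facing) edge is extracted per row and a
straight baseline is drawn along the fold through its anterior-most and
posterior-most points, after trimming 8% of rows at each end — the
segmented cord tapers where it meets the anterior commissure and the
arytenoid region, and untrimmed endpoints would tilt the line. Then:

* **maxDeviation / protrusion length** — maximal perpendicular deviation of
  edge points beyond the baseline toward the glottis (px);
* **protrusion width** — extent along the baseline of the contiguous
  deviating run (beyond a 0.75 px rasterization tolerance) containing the
  maximum;
* **length-to-width ratio** — their quotient: ≈ 0.5 for a semicircular
  bump of any radius, lower for broad-based swellings. Defined only when a
  protrusion exists;
* **geometric abnormality** — maxDeviation above a threshold of 3 px at a
  reference cord length of 110 rows, scaled linearly with the measured
  cord extent so the judgement is lens-distance invariant. The clinical
  literature judges this visually; the numeric threshold is ours and
  config-owned;
* **gray-level standard deviation** — population s.d. of the compensated
  gray values in the cord interior (the mask eroded by 2 px, so boundary
  pixels straddling the adjacent mucosa do not inflate the variance).

The semicircle identity (max deviation r, width 2r, ratio 0.5), shift
invariance, translation/180°-rotation equivariance and monotonicity in
bump radius are all property-tested against brute-force oracles.

## Classifier

The tree topology is declared, not learned, and mirrors the feature
narrative: tumors change both hue and texture, leukoplakia mainly hue,
polyps and cysts mainly geometry.

* **geometry** node: protruding (polyp/cyst) vs. not — consumes
  maxDeviation, length-to-width ratio, abnormality flag;
* **polypCyst** node: polyp vs. cyst — ratio and deviation;
* **hue** node: healthy vs. elevated gray s.d.;
* **leukoTumor** node: leukoplakia vs. tumor — gray s.d. and deviation.

Every node is an RBF-kernel SVM (`e1071::svm`, default cost 10, γ = 0.5)
trained on the samples its parent routes to it, with per-node
standardization that tolerates zero-variance columns. Per-image inputs
aggregate the two cords (worse-cord geometry, larger s.d.). Routing is
exhaustive and exclusive — every input reaches exactly one of the five
leaves — and the audit path of node decisions is returned alongside the
label. The exact binary splits of the clinical study's tree are not
recoverable from its text; this topology is our reading of its feature
logic. "10 hierarchical cross-validation" is implemented as stratified
10-fold CV (class-wise round-robin fold assignment under a seed).

## The phantom generator

`generatePhantom()` renders: an elliptical endoscope field (semi-axes
0.485·height, 0.48·width) on a zero border; a dark inverted-triangle
glottis (base up, 76·s px wide, 116·s px tall at cord scale s, intensity
≈ 40); a pale cord band (16·s px, intensity ≈ 180) along each slanted
edge; an optional lesion; a quadratic radial illumination falloff
(default 20 gray at the field edge); additive Gaussian noise (default
σ = 4 gray); and Gaussian blur (default σ = 0.8 px). Those defaults are
the package's standard test conditions. Lesion models:

* **polyp** — half-elliptical medial bump, perpendicular height 6–10 px,
  height/width 0.45–0.65 (narrow base);
* **cyst** — broader, lower bump, height 4–7 px, ratio 0.15–0.30;
* **leukoplakia** — elliptical bright patch inside the band, 55–80 gray
  above the cord (capped at 252);
* **tumor** — per-pixel texture noise (σ 25–35 gray) plus a mild
  quasi-periodic medial irregularity (amplitude 1.5–2.5 px), below the
  geometric-abnormality threshold.

No quantitative lesion appearance model exists in the clinical
literature this emulates; these class-conditional ranges are the
package's own, chosen so the three features separate noise-free classes,
and they live in one place (`.benchmarkRanges`). Sequences derive frames
from one base render by seeded integer-pixel translation (zero-padded)
and per-frame blur, the simplest motion model that exercises frame
screening.

**What the phantom does not emulate:** specular highlights, color,
mucus strands, vignetting beyond the radial falloff, stroboscopic cord
vibration, perspective distortion, or real lesion texture. Passing the
synthetic benchmark therefore demonstrates that the pipeline's stages
compose correctly and that its invariants hold — not clinical accuracy.
The clinical study's recognition rates were measured on a private
284-patient dataset and cannot be reproduced here; the package's
synthetic bar (held-out accuracy ≥ 0.90 at 40 phantoms per class,
default noise) is deliberately its own.

## Numerical choices and degenerate inputs

* Coordinates are R-native: 1-based [row, col], origin top-left, rows
  grow downward; "lowest point" = maximal row.
* Compensated images stay numeric; Otsu and entropy round to 256 bins.
* Constant images are a degenerate input for Otsu (error); empty masks
  are errors for entropy and features; contours with fewer than three
  distinct vertices are degenerate for the snake.
* Ties: Otsu takes the smallest maximizing threshold, the stopping rule
  the smallest candidate, frame selection the earliest frame.
* Polygon interiors use even-odd scanline rasterization at pixel centers.
* RGB converts to gray with luma weights 0.299/0.587/0.114.
* Video containers are not decoded (no codec dependency); frames are read
  from numbered image directories.

## Problem sizes in the test suite

The default suite renders phantoms at 288×352 px: a 20-phantom scale
batch (0.5–2.0) for the iteration-bound checks, 50 seeded three-frame
sequences for frame selection, and a 200-image benchmark (40 per class)
for the end-to-end accuracy bar, which completes in a few minutes on one
CPU. Larger batches change none of the asserted properties; the sizes
were chosen as the smallest that exercise every code path with
non-trivial statistics.

## Known limitations

* The snake's pressure/edge balance assumes edges at or above
  ~12 gray/px after smoothing; acquisitions with weaker cord/mucosa
  contrast need a lower `gradientScale` (and correspondingly lower
  pressure).
* The entropy stopping rule needs *some* intensity variation inside the
  growth range; on perfectly flat synthetic tissue with zero noise,
  shading and blur, all differences vanish and the rule returns the lower
  bound. Real tissue (and the phantom defaults) always carry texture.
* Features summarize each cord by its worst protrusion and one s.d.;
  multiple simultaneous lesions on one cord collapse into whichever
  signature dominates.
* The classifier's leaves are fixed; new lesion classes require a new
  topology, not just retraining.
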