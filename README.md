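# LarynxCAD

Computer-aided analysis of laryngoscopic images for five laryngeal
conditions: healthy vocal cords, polyps, cysts, leukoplakia and tumors.

Laryngoscopic diagnosis depends heavily on the examiner: the endoscope
cannot be held at a fixed distance or illumination, frames are blurred by
swallowing and motion, and judgements of cord color and shape are
subjective. LarynxCAD implements an objective pipeline for
otolaryngology image analysis:

1. **Frame screening** — the clearest frame of an endoscopic sequence is
   found by rejecting frames with low inter-frame PSNR
   (10·log₁₀(255²/MSE)), thresholding each remaining frame with a
   four-interval *fast Otsu* search (restricted to
   [0, icp_b], [icp_b, icp_m], [icp_m, icp_f], [icp_f, 255], where icp_m is
   the global mean and icp_b/icp_f the sub-/supra-mean class means, and
   provably equal to exhaustive Otsu), and keeping the frame whose dark
   glottal block — screened by centroid height, bounding-box aspect ratio
   ≤ 0.85 and area ≥ 900 px — is largest.
2. **Brightness compensation** — histogram translation
   `I(x,y) = O(x,y) + (S − O_m)` with set value `S = 125`, giving every
   acquisition the same brightness scale regardless of lens distance.
3. **Contrast enhancement** — CLAHE plus a small Gaussian smoothing.
4. **Adaptive segmentation** — the glottis mask seeds a greedy active
   contour (snake) per vocal cord, with energy
   `E = Σ w_c (d_i/d_0)² + w_k |v_{i−1} − 2v_i + v_{i+1}|²/d_0² − w_g G(v_i)
   − w_p s·A/d_0`. The number of sweeps is not fixed: the Shannon entropy of
   the growth range (the region enclosed by the contour) is recorded each
   sweep, and evolution is stopped at the iteration with minimal
   consecutive entropy difference, bounded to [13, 41]. A minimal
   difference at the 23rd candidate therefore selects iteration 35.
5. **Feature extraction** — per cord: a straight baseline along the fold,
   the maximal medial protrusion beyond it, the protrusion
   length-to-width ratio (≈ 0.5 for a semicircular, narrow-based polyp;
   lower for a broad cyst), and the grayscale standard deviation of the
   cord area (elevated by leukoplakia patches and tumor texture).
6. **Classification** — a decision-tree-structured SVM: geometry node
   (protruding vs. not) → polyp/cyst node; hue node (quiet vs. elevated
   gray s.d.) → healthy leaf or leukoplakia/tumor node. Each node is an
   RBF-kernel SVM trained on the samples routed to it.

Because clinical laryngoscopies cannot ship with a package, LarynxCAD
includes a seeded **synthetic laryngeal phantom generator**
(elliptical endoscope field, dark inverted-triangle glottis, paired pale
cord bands, parametric lesions, illumination falloff, noise, blur, motion
jitter) that produces images *and* ground-truth masks, so every stage of
the pipeline is tested end to end.

## Worked example

```r
library(LarynxCAD)

# a synthetic patient: polyp on the left cord; the sequence adds motion
# jitter and per-frame blur around one sharp frame
spec <- phantomSpec(seed = 400, noiseSigma = 0, blurSigma = 0,
                    lesion = lesionSpec("polyp", side = "left",
                                        protrusionRadius = 9, baseWidth = 16))
seq <- generateSequence(spec, blurSchedule = c(6, 0, 6), jitter = 2)

sel <- selectClearestFrame(seq)
sel$index
#> [1] 2
frame <- frames(seq)[[sel$index]]

comp <- compensateBrightness(frame, validMask = frame > 0)
glottis <- segmentGlottis(enhanceImage(comp))
seg <- segmentCords(comp, glottis)
seg
#> SegmentationResult
#>   glottis area: 4001 px
#>   cord areas (L/R): 2117 / 1995 px
#>   adaptive iterations (L/R): 31 / 15

extractFeatures(comp, seg)[, c("leftAbnormal", "leftMaxDev", "leftLwRatio",
                               "leftGrayStd", "rightAbnormal", "rightGrayStd")]
#>   leftAbnormal leftMaxDev leftLwRatio leftGrayStd rightAbnormal rightGrayStd
#> 1         TRUE   9.170605      0.3625    1.080627         FALSE      1.07465
```

The sharpest of the three frames (index 2) is selected; the glottis and
both cords are segmented with adaptively chosen iteration counts inside
[13, 41]; the left cord is flagged geometrically abnormal with a
protrusion of ≈ 9 px and a length-to-width ratio ≈ 0.36 — the
narrow-based geometry the polyp/cyst node of the classifier separates —
while the gray-level standard deviations of both cords stay low (no hue
lesion). Train a model on a phantom benchmark with
`buildTree(features, labels)` and attach it to `runPipeline(input,
model = ...)` to obtain labeled JSON reports; `crossValidate()` gives
stratified 10-fold recognition rates.

A command-line front end over the same functions ships in
`inst/scripts/larynx-cad.R` (subcommands `simulate`, `screen`, `segment`,
`features`, `train`, `classify`, `run`).

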