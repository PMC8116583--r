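---
title: "Imaging indicators of the optic disc: models and methods"
author: "fundusIOD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imaging indicators of the optic disc: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fundusIOD)
```

# The problem

Myopic elongation of the eye reshapes the optic disc (tilt, torsion) and
its temporal surroundings (peripapillary atrophy, PPA), and thins the
choroid. Choroidal thickness (ChT) — macular (mChT) and peripapillary
(pChT), both in micrometres — is measured on OCT, which is not always
available; colour fundus photographs are cheap and ubiquitous. The
package builds *imaging indicators of the optic disc* (IODs): linear
combinations of a small number of fundus-photograph features that track
ChT. An IOD is expressed in units of 10 µm, so a model coefficient of
~9 µm per IOD unit means a one-unit drop in the indicator corresponds to
roughly 9 µm of choroidal thinning.

# From photograph to feature pool

**Geometry.** Each case carries a manual (or synthetic) annotation: the
disc contour, the PPA contour, the fovea and a vessel mask, all in pixel
coordinates (origin top-left, x rightward, y downward, sub-pixel
precision). Pixel measurements become millimetres through Bennett's
axial-length-only adjustment of Littmann's formula, `q = 0.01306 (AL −
1.82)`; the per-case scale is a camera constant times `q`, so lengths
scale linearly and areas quadratically in `q`.

From the disc contour we take the second-moment principal axes of the
polygon: the longest diameter (LD) and shortest diameter (SD) are the
contour extents along them; the **ovality index** is SD/LD (1 for a
circular disc, smaller when tilted). The **torsion angle** is the signed
angle between the long axis and the perpendicular to the disc-centre →
fovea line: positive when the superior (image-up) end of the long axis
tips towards the nasal side, negative towards the temporal side. Discs
with ovality above 0.995 report torsion 0 — the long axis of a
near-circle is numerically meaningless. Note that this convention is
anatomical: mirroring a whole case (contours *and* fovea) swaps eye
laterality but leaves the sign unchanged, which is exactly why no code
downstream ever needs to know which eye it is looking at.

PPA metrics: area of the PPA region minus any disc overlap (evaluated on
a fine sub-pixel grid, 240 cells across the contour's bounding box —
about 0.2 % worst-case quantisation on crescents of realistic size),
contour perimeter, width (the extent of the region along the ray from
disc centre through the fovea) and the disc-centroid-to-fovea distance.
The width and the centroid endpoint are package choices; the figure-only
definitions in the literature do not pin down either.

**ROIs.** ETDRS circles of 3 and 6 mm diameter centred on the disc
centroid define the inner ring (disc margin to 3 mm circle) and outer
ring (3–6 mm). Quadrants are 90° sectors centred on the temporal
(towards the fovea), superior, nasal and inferior directions; boundary
angles join the counter-clockwise sector so the partition is exact. The
four feature ROIs are the disc (D), the inner ring (I), and the temporal
quadrants of the two rings (IT, OT). PPA pixels stay inside the ring
masks deliberately — the atrophy signal the indicators rely on lives
there — and vessel pixels are removed from every ROI. IT is a subset of
I by construction (it is the temporal quadrant *of* the inner ring); D,
I and OT are pairwise disjoint.

**Features.** Photographs are converted sRGB → CIELAB (D65). Per ROI ×
channel the package computes 19 first-order statistics on the raw
channel values and five texture families — 24 GLCM, 16 GLRLM, 16 GLSZM,
5 NGTDM, 14 GLDM — on discretised levels, plus 10 channel-independent 2D
shape descriptors per ROI. Naming is `<ROI>_<channel>_<operator>`
(`IT_L_range`, `OT_A_skewness`, …). Together with the 6 geometric
indices the pool has 6 + 4 × (10 + 3 × 94) = 1174 features.

Texture choices the reference literature leaves open, fixed here once:

* discretisation is ROI-local — masked values affinely rescaled to
  0–255, then fixed bin width 25 (≤ 11 levels). ROI-locality keeps
  features of one region independent of pixels outside it;
* co-occurrence and run-length matrices at distance 1 over the four 2D
  directions, symmetric GLCM, features averaged over directions (not
  merged matrices);
* zones by 8-connectivity; NGTDM/GLDM neighbourhoods Chebyshev-1; GLDM
  α = 0 with dependence counting the centre pixel (j = k + 1);
* degenerate conventions on constant regions: skewness 0, kurtosis 0,
  GLCM correlation and MCC 1;
* the shape perimeter uses a four-direction Cauchy–Crofton estimate
  rather than the marching-squares contour length: the iso-contour of a
  binary raster is staircase-biased (+5–6 % on disks), while the Crofton
  estimate is isotropic to well under 1 % at the radii used here. The
  mesh surface still comes from the marching-squares 0.5-level contour.

Every texture feature is checked in the test suite against an
independent brute-force loop implementation on ≥ 100 random masked
images, to 1e-10.

# Model construction

Cases are split 70/30 at random (no stratification). On the training
set, features are standardised and ordered by their first entry along a
decreasing-λ LASSO path (ties broken by absolute correlation with the
response, then name). For each k, the first k features are refit by
*unpenalised* OLS on the training set and adjusted
R² = 1 − (1 − R²)(n − 1)/(n − p − 1) is evaluated on training and test
sets. The chosen k\* is the last k of the initial strictly-increasing
run of the held-out trace — its first local maximum, the point where
added features stop generalising. Path entry ordering plus OLS refits is
a package decision: selection procedures of this family report adjusted
R² per feature count and final unpenalised coefficient tables, which
pins down the refit but not the path bookkeeping. Standardisation
parameters always come from the training set only.

The final IOD model is OLS of ChT (µm) on the k\* standardised features;
the indicator is the fitted value divided by 10. By the OLS intercept
property, mean(IOD) × 10 equals mean(ChT) on the training set. The two
published six-feature sets (for mChT: PPA width, disc–fovea distance,
OT_A_skewness, IT_L_range, OT_A_range, OT_B_range; for pChT: PPA
perimeter, I_B_skewness and the same four intensity features) ship as
`iodTemplates()` so they can be refit on new data; no per-feature
coefficients from the original cohort are available to distribute.

# The synthetic cohort

No imaging data accompany the source cohort, so the package synthesises
one with the statistical structure the analysis assumes. Marginals match
the published cohort: AL 25.51 ± 1.34 mm, ovality 0.79 ± 0.10, torsion
4.98 ± 19.78°, PPA area 0.68 ± 0.63 mm² (lognormal with matched moments
— a normal would go negative), mChT 211.00 ± 62.03 µm, pChT
143.33 ± 45.58 µm; age uniform 16–40, sex Bernoulli(0.5). A latent
standard-normal *atrophy factor* m couples the pieces: PPA area loads on
m through a Gaussian copula (ρ = 0.6), ovality anti-correlates with AL
(ρ = 0.5, truncated to (0.4, 1]), and

ChT = mean − slope·(AL − meanAL) − sd·√f·m + e,

with `signalFraction` f the fraction of ChT variance carried by m
(default 0.5) and slope 20 µm/mm; the residual variance is set so the
marginal ChT variance hits its target (clamped at zero if the AL slope
already exhausts it, which happens only for extreme parameter choices).
The defaults are the study conditions; they are not tuned per run.

Rendering (right-eye layout, fovea temporally along +x) draws a textured
background, the disc as the exact ellipse polygon later reported in the
annotation, a temporal PPA crescent whose max width is root-solved so
its area matches the planted value, 4–8 dark vessel arcs with an exact
mask, and a foveal darkening. Temporal peripapillary pixels (disc edge
to 3 mm, ±45°) get CIELAB values `centre + range·(u^γ − ½)` with u
uniform: the planted per-channel *range* is the span and γ is solved in
closed form so the planted *skewness* is hit; both are linear in the
(clamped) atrophy factor, so thin choroid ⇔ brighter, higher-contrast,
more right-skewed temporal tissue. Recovery tests allow 15 % on range
and 0.25 on skewness for 8-bit quantisation and finite ROIs.

One geometric default deviates from the obvious choice: a 0.0075 mm/px
scale on a 1024-px frame (7.68 mm field) cannot hold the 3-mm nasal
ETDRS margin *plus* a 4.2–4.8 mm disc–fovea distance once per-case
Littmann scaling shrinks mm/px for shorter eyes. The default camera
constant therefore spans an 11-mm field at the mean AL
(`defaultCameraConstant()`), with the disc centred 3.05 mm from the
nasal edge.

What the generator does *not* emulate: real fundus optics (vignetting,
chromatic blur), pathology beyond tilt/torsion/PPA, vessel branching
realism, OCT B-scans. Passing the end-to-end tests therefore shows that
the pipeline recovers a planted linear intensity–ChT relationship
through rendering, annotation, magnification correction, feature
extraction and selection — not that real fundus photographs carry that
relationship.

# Problem sizes and numerical choices

Analysis runs default to 192-px renderings (11-mm field ⇒ 57 µm/px);
the ROIs then hold a few hundred to a few thousand pixels each, which
keeps the planted intensity statistics recoverable while a 300-case
pipeline completes in well under a minute. The generator's own default
stays at 1024 px for visual inspection. The end-to-end validation runs
20 seeds of n = 300 at signalFraction 0.5 and requires positive held-out
Spearman correlation between indicator and planted ChT in ≥ 95 % of
seeds; the feature-count rule is validated on pools with exactly six
informative features at moderate noise, where the modal selected k
across seeds is six.

Other numerics: polygon areas/moments by the shoelace formulas;
point-in-polygon by even-odd crossing with a tolerance so touching
crescent tips are not "self-intersections"; model JSON written with 17
significant digits so save→load→predict is bit-identical; two-sided
p-values throughout and *no* multiple-testing correction (the reported
p-values are uncorrected by design).

# Known limitations

* The pipeline consumes annotations; it does not segment discs, PPA or
  vessels from raw photographs.
* The marching-squares/Crofton shape estimates are raster approximations;
  contour-based metrics (`discShapeMetrics`, `ppaMetrics`) are the
  precise ones and are preferred for the geometric indices.
* The inner ring deliberately keeps PPA pixels: the atrophy signal the
  temporal-region features rely on lives there, and excluding it would
  blind the indicators to exactly the tissue change they quantify.
* The LASSO λ grid (200 points, min ratio 1e-4) caps how finely entry
  order can be resolved; features entering in the same λ step are
  ordered by correlation with the response.
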