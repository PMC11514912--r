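---
title: "Quantitative 3D blastocyst morphometry and euploidy prediction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative 3D blastocyst morphometry and euploidy prediction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(blastometry)
```

## The measurement problem

A Day-6 human blastocyst is, to good approximation, a fluid-filled sphere: a
monolayer of trophectoderm (TE) cells tessellates the surface, and the inner
cell mass (ICM) sits against it as a compact cap. A single microscope image
shows at most half of this surface, strongly foreshortened toward the limb, so
2D morphology (or a human grade assigned from it) discards most of the TE and
measures the ICM at an arbitrary orientation. The package implements the
alternative: the embryologist rotates the blastocyst in small steps while a
fixed camera captures a view at each step, and the views are stitched into a
full 3D surface model on which morphology is measured quantitatively.

Five parameters are produced per blastocyst: diameter $D$ (µm), TE cell
number $N$, TE cell density ($1000\,N / (\pi D^2)$, cells per 1,000 µm²), TE
cell size variance (the standard deviation of the individual TE cell surface
areas, µm²), and ICM area (µm²). Downstream, the package provides the
association statistics between these parameters and PGT-A ploidy outcomes
(univariate and forward stepwise logistic regression, two-sample tests,
correlations), an interpretable decision-rule classifier for euploidy, and a
six-model benchmark harness with exact confidence intervals.

## Geometry: the sphere Ω and its surface map

All measurement happens on a sphere $\Omega$ with center $O$ and diameter
$D$, both fitted from the one image captured in the blastocyst's mid-plane.
Rim pixels are extracted by gradient thresholding; because the rim is a dark
band with two edges, only the outermost gradient ring per angular sector is
kept, each sector contributing its gradient-magnitude-weighted mean radius,
and an algebraic (Taubin) circle fit gives $O$ and $D$. On rendered test
disks this recovers the diameter to within half a micron.

Every view is cropped to $D \times D$ around $O$ (side rounded up to an odd
pixel count so the center pixel is preserved). A pixel at offset $(u, v)$ µm
from $O$ back-projects to the camera-facing hemisphere point
$(u, v, \sqrt{R^2 - u^2 - v^2})$ with $R = D/2$; the camera is orthographic,
which is accurate for the long working distances of micromanipulation optics.

The stitched surface lives on an equirectangular latitude–longitude grid
(`sphere_label_map`, default 256 × 512; all acceptance-level results also
hold at 128 × 256). Bin areas are exact,
$R^2\,\Delta\lambda\,(\sin\varphi_{top} - \sin\varphi_{bottom})$, so the grid
always sums to $4\pi R^2 = \pi D^2$ regardless of resolution. Latitude runs
from the equator toward the $+y$ (image-vertical) pole, matching the typical
rotation axis so the poorly observed polar caps coincide with the grid poles.
Connected components on this grid respect the sphere topology: longitude
wraps, and the top and bottom rows connect through their poles, so a TE cell
that straddles the date line or a pole is still counted once.

## Registration: rotations between views

The imaging protocol constrains the motion: the blastocyst is held on a
pipette and pushed through steps smaller than 35° (more than 10 views per
revolution), so consecutive views always share surface. Because cropping
fixes the center and the geometry is orthographic, the inter-view
transformation is a pure 3D rotation about $O$.

The estimator is feature-based with a geometric refinement:

1. **Shading flattening.** Under orthographic viewing of a Lambertian
   sphere the shading field is $z/R$, known exactly from the geometry; it is
   divided out, making the surface texture approximately viewpoint-invariant.
2. **Keypoints.** Difference-of-Gaussian extrema over a small scale pyramid
   (σ from 1.1 to 9 px), excluding a 5° zone at the limb where
   $z = \sqrt{R^2 - u^2 - v^2}$ has unbounded gradient.
3. **Descriptors in the tangent plane.** Each keypoint is back-projected to
   the sphere and a 16 × 16 sampling grid is laid out in the *tangent plane*
   of the surface (geodesic offsets in µm) and projected back into the
   image. This removes the orthographic foreshortening between views, which
   defeats purely planar descriptors at 30° steps. From the sampled patch a
   dominant gradient orientation is estimated and a 4 × 4 × 8
   orientation-histogram descriptor (128-D, L2-normalized, 0.2-clamped) is
   accumulated in orientation-normalized coordinates. Because the pixel
   scale is fixed and the projection orthographic, there is no scale change
   between views, so descriptors use a fixed metric patch size.
4. **Matching.** Nearest-neighbour descriptor matching with the Lowe ratio
   test (0.75) plus a mutual-best cross-check; matches within 5° of the limb
   are discarded (unreliable $z$).
5. **Robust rotation.** RANSAC samples two correspondences per hypothesis
   and solves the exact two-point rotation (orthonormal triad alignment);
   inliers are scored by angular residual (default 2°), and the final
   rotation is refit on the inliers by the orthogonal-Procrustes (SVD)
   solution with $\det = +1$ enforced.
6. **Photometric refinement.** The feature estimate is refined by
   minimizing the mean squared difference between the flattened target view
   and the reprojected source view over the three-parameter rotation group
   (local exponential map, Nelder–Mead). On textured views this brings the
   pairwise error well below the keypoint localization noise.

Pairwise rotations are chained into global view-to-reference rotations
($G_1 = I$, $G_{i+1} = G_i P_i^{-1}$). On noiseless synthetic sequences the
chained global rotations stay within a few hundredths of a degree of truth;
with 2% image noise they stay within a fraction of a degree, in both cases
well inside the tolerance that the morphometry requires.

## Stitching, label fusion and area measurement

Each in-disk pixel of each view is back-projected, rotated into the global
frame, and deposited in its latitude/longitude bin with weight
$w = z_{view}/R$, the cosine of the viewing angle. For the categorical label
map, a bin keeps the label of its highest-weight contribution — labels are
categorical, so a hard argmax is used rather than averaging — with ties
broken toward the lower view index, which makes re-projection of the same
view a no-op. Bins never touched (grazed polar caps, sub-pixel gaps at high
latitude) stay 0 (unobserved).

Cell and ICM *areas* are not measured by counting argmax bins: hard
assignment quantizes each area to whole bins and the accumulated border
noise inflates the cell-size dispersion. Instead the projection also
accumulates, per bin and label, the weight mass deposited there, and each
bin's exact area is split among labels in proportion (soft fractional bin
membership). Three refinements matter, all found by comparing against
oracle pipelines on synthetic truth:

- *Best-view composition.* A bin's composition is estimated from the most
  face-on view observing it, not a mixture of all views: oblique
  observations lose small cells entirely (their band-eroded interior drops
  below one pixel), and every surface point away from the rotation poles is
  seen near-normally in some view.
- *Band attribution.* Membrane-band pixels are split between the two
  geodesically nearest region labels in inverse proportion to their surface
  distances. The band is centred on the true cell border, so each adjacent
  cell owns half of it; hard nearest-neighbour assignment erodes the
  concave (small-cell) side of curved borders, and per-bin proportional
  splits transfer border area from small cells to large ones.
- *Leftover bins.* Bins with no region-label weight are assigned whole to
  the dominant label of the geodesically nearest weighted bin; iterative
  grid dilation would sweep entire polar rows in a few steps because
  longitude bins shrink toward the poles.

The label areas partition the sphere exactly ($\sum_i A_i + A_{ICM} =
\pi D^2$), and on synthetic truth with known rotations the per-cell areas
are recovered to a fraction of a percent. When per-view masks lack
cross-view-consistent cell ids (the classical segmenter's watershed labels),
cells are instead the boundary-separated connected components of the
collapsed cell class on the argmax map.

## Segmentation

The per-view segmenter is deliberately classical: shading flattening, a
darkness ridge (local surround minus pixel, with normalized convolution so
the dark exterior does not bias the surround near the limb), hysteresis
thresholding restricted to the half-maximum band of the local ridge (so the
detected band tracks the membrane width regardless of per-cell contrast),
watershed from cell-interior maxima, and ICM detection as the largest dark
compact region at a coarse scale. A strict contract (`load_external_masks`)
ingests masks produced by any external segmenter — e.g. a trained network —
after alphabet mapping and shape validation, and the downstream pipeline is
identical from that point on.

**Known limitation.** At grazing viewing angles the membrane band projects
below one pixel; even with detector-footprint integration, a classical
per-view segmenter plateaus around Dice 0.80–0.84 against the point-sampled
rendered truth and undercounts per-view cells by 10–20%. This is the
physical reason
multi-view stitching exists: every surface point is seen near-normally in
some view. The measurement pipeline's accuracy claims are therefore stated
for the stitched 3D model, and the synthetic validation of the five
parameters uses ground-truth masks to isolate geometric errors from
segmentation errors.

## Morphometry

From the stitched surface model: TE cell number is the count of distinct
non-ICM regions above a minimum-area floor (default 10 µm², suppressing
stitching slivers); TE cell size variance is the sample (n−1) standard
deviation of the soft region areas (a population-SD toggle exists); ICM
area is the area of the ICM region; density is
$1000\,N / (\pi D^2)$. Two conventions are config-exposed because the
measurement definition admits both: the density denominator is the full
sphere area $\pi D^2$ (this reproduces the cohort's printed class means
arithmetically, e.g. $110 / (\pi\,183.9^2/1000) \approx 1.04 \approx 1.1$),
and the ICM area is the spherical surface area rather than a projected
planar area, consistent with measuring on the 3D surface model.

On synthetic blastocysts spanning the realistic range (60–160 cells,
150–220 µm, area CV 0.2–0.6), the full pipeline — diameter fit, registration,
stitching with truth masks, morphometry — recovers all five parameters with a
maximum relative error well inside the 6.7% measurement-error budget; the
`scripts/acceptance.R` script recomputes this end to end.

## The synthetic generator

Ground truth is a sphere tessellated by a spherical Voronoi diagram outside
an ICM cap. Cell-area dispersion is controlled by Lloyd-style relaxation:
plain Lloyd steps reduce the coefficient of variation of areas, inverse
steps (site moved away from its area centroid) raise it; iteration stops
within 0.05 of the target CV or at 200 iterations (an infeasible target
warns and records the best CV reached). A minimum site separation
($0.8/\sqrt{n}$ rad) excludes degenerate near-coincident generators whose
shared bisector band would swallow both cells. Since no spherical-polygon
library is available in this stack, cell areas are computed by exact-bin-area
quadrature on a fine grid (1536 × 3072) and rescaled by one global factor so
that the partition identity $\sum_i A_i + A_{ICM} = \pi D^2$ holds exactly
with the closed-form cap area; quadrature areas agree with a Monte-Carlo
assignment oracle to well under 1% per cell (median).

Rendering is orthographic with Lambertian shading $z/R$, per-cell albedo,
granular intracellular spots (the texture registration locks onto), a dark
constant-width (2 µm) membrane band along every cell border — the band is
defined by the exact geodesic distance to the bisector great circle,
$\arcsin|p \cdot n|$; the simpler half-difference of site distances balloons
the band wherever generator sites are far apart, which is not how a physical
membrane behaves and measurably biases cell areas — a darker featureless ICM
cap, and optional Gaussian noise. Views are rendered with 3× supersampling —
each pixel is the mean of nine subpixel samples — emulating the integration
over a real detector's pixel footprint; without it, strongly foreshortened
membranes near the limb fall between pixel centers and vanish, which no
segmenter could recover. Masks hold the true label at each pixel center
(point-sampled: averaging categorical labels over a grazing pixel's large
surface footprint would destroy them, and the area measurement relies on
the mask being an unbiased sample of the surface partition). The mid-plane
image is a bright disk with a dark rim on a bright (culture-medium)
background, edges anti-aliased over one pixel.

The feature-table simulator draws the five parameters class-conditionally
with moments matching the observed cohort (euploid fraction 0.571 by
default): truncated normals for diameter, TE count and ICM area, a lognormal
matched to the class mean/SD for size variance — dispersions of positive
areas are right-skewed, and the lognormal is the minimal choice — and density
derived deterministically. What the generator does *not* emulate: optical
blur and depth of focus, zona pellucida and blastocoel structures,
non-spherical or collapsing blastocysts, Day-5 early-blastocyst morphology,
and segmentation errors correlated across views. Passing synthetic tests
therefore validates the geometry, registration, stitching and statistics,
not robustness to every real-world imaging artifact.

## Statistics and prediction

All tests are two-tailed. Univariate associations are single-predictor
logistic regressions (OR = $e^\beta$, Wald 95% CI, Wald p). The multivariate
model is forward stepwise logistic regression in the SPSS "Forward: LR"
sense: likelihood-ratio entry at 0.05, removal at 0.10, iterated to a
fixpoint; unselected features are echoed with an aOR sentinel of 1.000,
mirroring the conventional table layout. The t-test defaults to Welch
(pooled toggle); no result in the package depends on the choice.

The decision-rule classifier predicts euploid iff TE count > 94, or size
variance ≤ 478 µm² and ICM area > 8007 µm² (inequality strictness exactly as
stated; all three thresholds config-overridable). The benchmark harness
trains six learners (logistic regression, decision tree, XGBoost, random
forest, RBF-SVM, MLP) with a small documented grid per model (≤ 24
combinations), selected by mean validation AUC over k = 5 stratified folds
(k is a parameter; 5 is the package default), refit on the full 80%
training split, with the operating threshold chosen on training scores as
the ROC point closest to (0, 1) (a Youden toggle exists; the two criteria
coincide on well-behaved curves but not always). Because the original
train/test split seed is not derivable, the harness reports the metric
distribution over split seeds rather than one point estimate.

Evaluation uses exact Clopper–Pearson intervals for all proportion metrics
(this choice uniquely reproduces printed intervals such as 84.9–99.5% for
43/45), the Mann–Whitney AUC with DeLong placement-value variance and a
logit-transformed CI, DeLong's paired z-test for AUC comparison, the exact
binomial McNemar test for paired accuracy, and permutation importance (mean
AUC drop over shuffles) uniformly across all six model types. The underlying
learners come from established implementations (`rpart`, `xgboost`,
`randomForest`, `e1071`, `nnet`, `stats::glm`); everything above them is
implemented here.

## Numerical choices and degenerate inputs

- Rotation matrices are validated to orthogonality and $\det = +1$ at 1e-9;
  serialized rotations are quaternions (no gimbal issues).
- RANSAC is seeded from configuration; every stochastic routine takes an
  explicit seed, and generators restore the caller's RNG state.
- Perfect separation in logistic fits returns a flagged infinite-OR result,
  not an error; zero-variance t-tests with equal means return p = 1;
  identical score vectors give DeLong p = 1; constant scores make the ROC
  threshold an error (no discrimination exists).
- `icm_area` on a map without ICM labels raises a missing-ICM error,
  distinct from a legitimate zero-area result; smaller ICM fragments beyond
  the largest are reported, not silently merged.
- Cropping tolerates the fitted diameter exceeding the frame by up to 3 px
  (padded with background — the overhang is beyond the limb), erroring on
  larger clipping.

## Reproducing the validation

`scripts/acceptance.R --seed <int> --out <path>` regenerates 10 synthetic
blastocysts across the realistic parameter range, runs the full measurement
pipeline (registration included; ground-truth masks), and writes the maximum
relative parameter error (percent) as JSON. The testthat suite covers every
module; three association/benchmark tests additionally require the released
cohort table placed at `inst/extdata/supplementary_table5.csv` and fail
until it is supplied.
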