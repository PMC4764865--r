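---
title: "Segmenting soft-tissue structures in micro-CT stacks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting soft-tissue structures in micro-CT stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microCTseg)
```

## The problem

Contrast-stained micro-CT makes it possible to image the brain of a
small insect such as a bumblebee inside its intact head capsule, at a
few micrometres of isotropic resolution, without dissection. What the
scanner delivers, after reconstruction and re-slicing along a viewing
plane, is a stack of 8-bit greyscale slice images: dark background and
unstained material, bright stained neural tissue. Turning that stack
into per-structure volumes — mushroom bodies (MB), antennal lobes
(AL), medullas (Me), lobulas (Lo), central body (CB) — requires three
things: deciding which voxels are "tissue" (thresholding), deciding
which tissue belongs to the structure of interest (contour masking),
and counting voxels (volumetrics). `microCTseg` implements that
workflow, the cleanup applied before volumes are reported, the
statistics used to validate such measurements, and a phantom generator
that provides ground truth for all of it.

## Data model and conventions

A stack is a 3D integer array indexed `[z, y, x]` with intensities in
0 (black) to 255 (white) and a single isotropic voxel size in
micrometres (4.6 um is the standardised export size this workflow was
designed around; anisotropic stacks are rejected rather than silently
accepted). Slice 1 is the first file in natural numeric filename
order; `y` grows downward and `x` rightward, as in the image files
themselves. Geometry (contours, phantom solids) lives in continuous
0-based coordinates with pixel centres at integers, so "pixel (y, x)"
and "point (x-1, y-1)" refer to the same location. Only axis-aligned
re-slicing (permutation and flips) is provided: the orientation of the
export plane is a judgement call made in the reconstruction software,
and re-implementing free-angle resampling would add interpolation
error without adding capability the pipeline needs.

## Thresholding

A voxel is *active* when its intensity lies in the inclusive range
`[base, top]`. Two ways of choosing the range are supported:

* **Tracing ranges** are chosen by the user by eye, so that the binary
  view separates background from head tissue, keeps each structure's
  identifying features, and separates the structure from the tissue
  touching it. The package validates such ranges but deliberately does
  not choose them.
* **Histogram ranges** are estimated automatically: on each of a
  subsample of slices (default 15 slices at 10-slice intervals,
  centred mid-stack; the interval shrinks proportionally for shorter
  stacks or smaller structures) the base is read off as the top of the
  *second peak* of the slice's smoothed intensity histogram — the
  first peak being dark background, the second the stained tissue.
  The per-slice bases are averaged (arithmetic mean, rounded half-up)
  into a single range applied to every slice; `top` stays at 255.

Peak detection is where all the numerical care sits. The histogram is
smoothed with a centred moving average (default window 5). Local
maxima closer together than `minSeparation` grey levels (default 32,
one eighth of the intensity scale) are merged into the taller apex:
features that close are not resolvable as distinct tissue classes, and
the rule absorbs two artefacts that otherwise masquerade as peaks —
the spike that clamping intensities at 0 carves off the background
peak whenever the noise is appreciable, and Poisson bumps riding on
the tissue peak itself. Surviving maxima must additionally have a
topographic prominence of at least `minProminence` (default 1%) of the
histogram maximum and at least half their own height (`valleyRatio`),
so a shoulder whose separating saddle stays shallow never counts as a
peak on its own. The reported grey level is the rounded centroid of
the peak's upper half (the contiguous bins at or above half the apex
height), which coincides with the apex for clean or plateau peaks and
localises a noisy apex far more stably than the single tallest bin.
Slices on which no second peak qualifies — featureless slices beyond
the structure, or pure-noise bumps failing the prominence floor — are
dropped; fewer than three usable slices is an error rather than a
guess.

Both bounds of the threshold are inclusive. Inclusivity matters for
noiseless synthetic data, where all tissue sits exactly at the tissue
mean: with `base` equal to the second-peak intensity, `base <= I`
keeps every tissue voxel.

## Keyframe contours and interpolation

Structures are annotated as *tracks*: closed polygonal contours
("looped splines") drawn on every fifth slice, all with the same node
count. Contours are stored with normalised orientation (positive
shoelace area) and interpolated linearly node-by-node across the
intervening slices, after aligning each consecutive keyframe pair by
the cyclic node rotation minimising the sum of squared node distances.
At a keyframe slice the stored contour is reproduced exactly. The
contour family is polygonal rather than a smooth spline: polygons have
exact, testable geometry (shoelace areas, point-in-polygon), and any
smooth curve is approximated to below volumetric tolerance by
densifying nodes (`densifyContour()`); the default ground-truth
contours use 64 nodes, at which the polygon-vs-circle area deficit is
0.16%.

Rasterization uses the even-odd rule on pixel centres, with a centre
exactly on the boundary counted inside. The segmented structure is
then the intersection of the per-slice contour masks with the
thresholded stack: only active voxels inside the loop belong to the
structure, so a generously drawn contour admits no background.

Degenerate interpolated polygons (area collapsing to zero, possible
when keyframes are inconsistent) produce a per-slice warning and an
empty mask for that slice rather than an error: the condition is
visible in the output volume and in the warning, and aborting a long
batch for one bad slice helps nobody.

## Cleanup

Island removal deletes connected components smaller than a voxel
threshold (default connectivity 26; 6 and 18 available). It is
idempotent, never increases the count, and logs every component size
into the structure's provenance. Smoothing is a Gaussian blur of the
0/1 mask re-binarized at 0.5, with replicate padding at the array
edges so a flat boundary is preserved exactly; it exists to produce
cleaner renderings and surfaces. Volumes are reported on the
island-removed, *unsmoothed* mask: smoothing in the original workflow
happens on the rendering side while voxel counting happens on the
editing side, and keeping that separation makes the volume definition
unambiguous. Passing a smoothed structure to `computeVolume()`
explicitly is the supported sensitivity analysis.

## Volumetrics and validation statistics

`volume_mm3 = voxel_count * (voxel_size_um / 1000)^3`. Everything
downstream is ordinary statistics, chosen to match how such
measurements are validated:

* **Percent difference** between two volumes is symmetric:
  `100 |a-b| / mean(a, b)` (a one-sided variant is available behind a
  flag). **Method agreement** summarises per-pair percent differences
  between two segmentations of the same structures as mean, median and
  IQR per label, and reports unmatched records instead of dropping
  them.
* **Repeatability** of n repeat segmentations reports the sample sd
  (n-1), the coefficient of variation, and a repeatability score of
  `2 * sd` — under normality, the bound that the difference of two
  repeats stays below with roughly 95% probability.
* **Paired symmetry** regresses right on left (OLS) per bilateral
  label across specimens, reporting r², slope, intercept and the mean
  percent difference; bilateral neuropils develop near-symmetrically,
  so slopes near 1 with high r² indicate the method measures tissue
  rather than artefact, and the residual asymmetry is an upper bound
  on measurement error.
* **Allometry** regresses total structure volume (left + right) on
  thorax width — the standard bumblebee body-size proxy, measured with
  callipers and averaged over replicate measurements at ingest — and
  reports the slope with its 95% CI. Single-structure OLS only; no
  mixed models, no multiple-testing machinery.

The OLS path is the closed-form normal-equation fit; the test-suite
cross-checks it against `lm()` on every fixture. A constant response
is assigned r² = 0 (the regression explains nothing) rather than NaN.

## The phantom generator

Phantoms emulate what matters about the real stacks: a dark background
mean (default 20), a bright tissue mean (default 180), optional
additive Gaussian noise rounded and clamped to [0, 255], bilateral
structure pairs mirrored exactly across the mid-sagittal plane, and
non-convex "lobed" solids (unions of overlapping spheres) standing in
for structures like mushroom-body calyces. Noise presets: `"clean"`
(sd 0), `"moderate"` (10), `"hard"` (25). The clean preset is exactly
noise-free by design: the histogram threshold sits at the tissue mode,
and with symmetric noise any threshold at the mode excludes about half
the tissue voxels — so volumetric ground-truth experiments use clean
phantoms, while the noisy presets exercise threshold *estimation*,
which is robust across the full preset range. That split is what the
phantoms can and cannot say about real data: they validate the
geometry and bookkeeping of the pipeline exactly, and the estimator's
peak recovery under noise, but they do not model partial-volume blur,
beam hardening, ring artefacts, or stain gradients, so absolute
accuracy on real scans still rests on the agreement, repeatability and
symmetry statistics computed from the scans themselves.

Ground truth comes in three forms: analytic volumes (closed form for
spheres and ellipsoids; two-sphere unions by inclusion-exclusion;
larger unions by fine-grid numeric integration at 3x supersampling),
exact voxel-count volumes (pixel-centre membership), and ground-truth
keyframe tracks. Truth contours are polygonal cross-sections of the
solids placed *half a pixel outside* the surface: an annotator tracing
around active pixels encloses whole pixels, so the loop runs outside
the pixel centres. The margin is load-bearing for interpolation
accuracy: linear interpolation of a convex radius profile chords
inward, clipping several percent of a sphere's volume when contours
sit exactly on the surface, whereas with the margin the full-pipeline
sphere recovery (`spherePipelineExperiment()`) lands within a fraction
of a percent of the analytic volume. It costs nothing in specificity
because the mask is intersected with the threshold. Lobed solids keep their lobe
offsets small enough that every cross-section is connected and
star-shaped about the lobe-centre mean, which makes the radial
ray-cast contour exact.

The cohort generator emulates a multi-specimen study: thorax widths
drawn uniformly from 4-6 mm and bilateral pair totals following
`a + b * width`, split equally between mirrored sides, with optional
relative noise per side emulating segmentation error. The defaults
span pair totals of 0.06-0.18 mm^3 — centred near twice the observed
single-medulla volume (~0.075 mm^3) with a roughly threefold spread
between the smallest and largest brain. The spread is a study
condition, not a free dial: left-right r² under per-side measurement
noise is attenuation-limited by the ratio of noise to true
between-specimen variation, and a cohort with realistic biological
spread is exactly what makes symmetry regressions informative.

## Validation experiments

Four packaged experiments reproduce the validation protocol at desk
scale, and `scripts/acceptance.R` re-runs all of them from scratch:

* `methodAgreementExperiment()` segments each phantom with both
  threshold-selection workflows. The tracing arm (truth contours every
  5 slices plus a midpoint trace threshold) inherits
  contour-interpolation error, which grows with shape complexity; the
  histogram arm (automatic threshold plus island removal, no contours)
  inherits threshold-inclusion error. On clean phantoms the smooth
  cohort disagrees by well under 2% on average and the lobed cohort by
  more (under 6%) — the same ordering seen when the two methods are
  compared on simple medullas versus convoluted calyces.
* `repeatabilityExperiment()` re-segments one phantom four times with
  0.5 px Gaussian node jitter, emulating manual placement variability;
  the volume c.v. stays well under 2%.
* `secondPeakExperiment()` runs the threshold estimator over 20
  phantoms at noise sd 10-25 and counts recoveries of the tissue mode
  within +/-2 grey levels (expected: nearly all).
* `spherePipelineExperiment()` runs the entire pipeline — histogram
  threshold, truth keyframes at interval 5, interpolation, masking,
  island removal, voxel counting — on a clean r = 15 sphere; the
  volume lands within a fraction of a percent of 4/3 pi r^3.

Problem sizes (stack edges of 36-80 voxels, spheres of radius 13-30,
cohorts of 19) were chosen so each experiment has adequate statistical
power — e.g. enough tissue pixels per sampled slice that the histogram
peak stands clear of count noise — while the whole suite stays
comfortably interactive.

## Numerical choices and edge cases, in one place

* Threshold bounds inclusive on both ends; histogram mean rounded
  half-up; sampled slices centred mid-stack.
* Peak detection: smoothing window 5, prominence floor 1% of the
  maximum, valley ratio 0.5, minimum separation 32 levels, FWHM
  centroid localisation. All exposed as arguments.
* Contours stored counter-clockwise (positive shoelace); node
  correspondence by best cyclic rotation; boundary-on-centre counts
  inside; degenerate interpolants warn and rasterize empty.
* Island removal before volume; connectivity 26 unless asked
  otherwise; smoothing is blur + re-binarize at 0.5 with replicate
  padding, and never silently replaces the mask volumes are read from.
* Mirroring reflects centres across `x = (width - 1) / 2`, so mirrored
  truth masks are voxel-exact mirror images and paired truth counts
  are identical.
* Volume arithmetic: voxel counts are exact integers; mm^3 values are
  doubles and additive to floating-point rounding.

## Limitations

The phantom noise model is additive Gaussian on a two-level image;
real scans have structured noise and graded stain uptake, so the
histogram estimator's +/-2-level guarantee is a statement about the
model, not about every scanner. Pure-threshold segmentation (the
histogram arm of the agreement experiment) has no defence against
bright distractor tissue touching the structure; the contour workflow
exists precisely because real heads contain such tissue. Whole-MB
volumes are computed as the union of separately segmented calyx and
lobe masks. Oblique re-slicing, 16-bit stacks, DICOM, mesh-based
smoothing and interactive editing are out of scope.
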