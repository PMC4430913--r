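---
title: "Localizing a coronary stenosis in 3D by angiogram/CTA registration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localizing a coronary stenosis in 3D by angiogram/CTA registration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stenoreg)
```

`stenoreg` connects the two standard coronary imaging modalities. An
X-ray angiogram shows the contrast-filled arteries as dark curvilinear
structures on a bright, noisy background; a CTA stack shows them as
small bright cross-sections moving from slice to slice. The package
segments and labels the main arteries in both, registers them through
anatomical landmarks (artery start, bifurcations, end) and maps a
stenosis marked on the 2D frame to a 3D voxel. This vignette explains
the models and the choices behind each stage; the numerical results it
refers to are the ones computed by the test suite and
`scripts/acceptance.R`, not new claims.

## Conventions

Images are numeric matrices `[row, col]` with 0-based point coordinates
`(u, v) = (col − 1, row − 1)`; volumes are arrays `[z, y, x]` with `z`
the slice index from the top of the stack and 0-based Cartesian
coordinates `(x, y, z)`. All convolutions use whole-sample mirror
padding: symmetric boundaries avoid the edge ramps that, with zero
padding, mimic vessel responses in the wavelet detail planes.

## Angiogram stage

**Denoising.** Angiograms carry substantial quantum noise, and plain
smoothing erases thin arteries. `denoise_dwt()` uses a 3-level
orthonormal Haar transform with hard thresholding at the universal
threshold $\sigma\sqrt{2\log n}$, estimating $\sigma$ as
$\mathrm{MAD}/0.6745$ of the finest diagonal subband. Vessel structure
concentrates in few large coefficients and survives; dispersed noise
energy does not. A perfectly noise-free image gives
$\hat\sigma = 0$ and passes through unchanged, so the function also
accepts a known `sigma` for controlled experiments.

**Starlet analysis.** The starlet (isotropic undecimated) transform
smooths with an à-trous dilated separable kernel and keeps the
differences $w_j = c_{j-1} - c_j$, so reconstruction is exact by
construction — the suite verifies $c_0 = c_L + \sum_j w_j$ to
$10^{-9}$ on random images. The even-length filter
$h^0 = [1,3,3,1]/8$ needs a centring convention: taps sit at offsets
$\{-2,-1,0,+1\}$, dilated by $2^{j-1}$ at level $j$. The choice shifts
responses by at most a pixel or two and is held fixed throughout.

**Segmentation.** Vessels are dark, and the detail-sum segmentation
expects bright objects, so the denoised image is inverted first. The
detail sum over levels $\{2,3,4,5\}$ — thin arteries appear at small
levels, thick ones at larger levels — is thresholded at
$k\hat\sigma$ above zero with $\hat\sigma = \mathrm{MAD}/0.6745$ of the
detail sum and $k = 2$ by default; the sum is exactly zero on flat
background, so noise-free inputs need no tuning. Components whose
skeleton is shorter than `min_length` (default 30 px) are treated as
clutter, and holes are filled. On the noise-free three-branch phantom
the resulting Dice overlap with the drawn tubes is about 0.87; the
halo of the detail sum makes the mask slightly generous, which the
downstream mask-radius construction tolerates.

**Centrelines and landmarks.** The mask is thinned by Zhang–Suen
iterations (no installed package provides 2D skeletonization). The 3×3
ones-kernel count classifies skeleton pixels — 2 marks an end, ≥ 4 a
branch — but a diagonal staircase pixel can also reach 4, so branch
classification additionally requires at least three circular
transitions in the 8-neighbourhood; adjacent branch pixels at one
junction collapse to a single representative. Detachment removes the
branch pixels and every skeleton pixel at least as close to a branch
point as to the background (ties removed, so diagonal contact across a
junction is cut), drops fragments below `min_len` (default 10 px) and
labels the rest. For the selected labels, the mask radius $r$ is the
maximum distance-to-background over the selected centreline pixels,
the artery mask is the centreline dilated by a disc of radius $r$
intersected with the segmentation, and the control points are the
landmarks inside it, ordered along the skeleton. The start is taken at
the endpoint with the larger local radius (proximal arteries are
wider); since a constant-width phantom makes that cue uninformative,
the registration step also evaluates the reversed ordering and keeps
the orientation with the smaller fit residual.

## CTA stage

**Tissue bands.** `HU = raw·slope + intercept` (slope 1, intercept
−1024 are typical scanner values), clipped to ±1100. Four bands
classify the anatomy: air/lung up to −225, soft tissue to +30,
myocardium-range to +390, contrasted structures to +1000. The printed
clinical bounds abut at −226/−225; a half-open convention
(≤ −225 / > −225) makes the bands a strict partition, which the suite
asserts. The lung mask binarizes band 1 per slice and fills its holes
so pulmonary vessels vanish with the lung they sit in. The aorta is
detected on the initial slices (default: the top 10% of the stack) by
a circle Hough transform over a radius range, keeping candidates whose
perimeter support exceeds half the ring.

**Vesselness.** The Hessian at scale $\sigma$ uses
$\sigma^2$-normalized Gaussian second-derivative kernels; eigenvalues
are ordered $|\lambda_1|\le|\lambda_2|$ and scored by
$v = e^{-R_B^2/2\varphi_1^2}(1 - e^{-s^2/2\varphi_2^2})$ with
$R_B = |\lambda_1|/|\lambda_2|$, $s = \sqrt{\lambda_1^2+\lambda_2^2}$,
$\varphi_1 = 0.75$, $\varphi_2 = 25$, maximized over
$\sigma \in \{1,2,3,4\}$. The default zero branch is
"$0$ if $\lambda_1 < 0$"; because the standard convention for bright
tubes instead zeroes $\lambda_2 > 0$, a
`polarity = "bright_vessels"` switch provides it, and the binarization
helper uses that form. A dense explicit-kernel oracle in the tests
pins the separable implementation to $10^{-8}$.

**Intersection Tracking.** Tracking exploits slice-to-slice continuity
of the artery cross-section. From a seeded component the tracker
intersects each next slice, records the start centroid, then resolves
events: if the region splits (or a Y-shaped cross-section is detected
by in-slice thinning, accepted only when at least two sub-regions
continue into the next slice — spurious junctions do not), all
branches are tracked to completion and the branch reaching deepest is
kept, which is exactly the longest root-to-leaf path of the branch
graph; terminating branches are sub-arteries and are discarded, except
that for the RCA a terminating branch tracked over at least
`preserve_len` slices (default 15) is preserved, capturing R-PDA and
R-PLB. An empty intersection triggers backtracking: the region is
dilated by `dilate_px` (default 3) and up to `lookahead` slices
(default 3) are searched forward, bridging short dropouts; bridged
slices are reported as gaps. The LM is tracked with
`stop_at_bifurcation`, and the two daughter regions just below its
bifurcation become the LAD and LCX seeds (leftmost-in-image = LAD by
default; a three-way split is reported as ambiguous rather than
guessed). Ostium seeds themselves are configuration inputs — automatic
seed detection fails on anatomies with a separate Conus artery, so the
choice is deliberately manual.

## Registration and localization

The tracked model is rotated (x→y→z order, right-handed, about the
volume centre) and projected orthographically; each pixel keeps the
provenance of its viewer-nearest voxel. Control points are normalized
to centroid zero and RMS distance $\sqrt 2$ — the classic conditioning
step for landmark fits — and the affine is solved on normalized
coordinates, exactly for three landmarks and by least squares beyond,
then de-normalized. Under the row-vector convention the transform maps
projected-CTA coordinates to angiogram coordinates, so warping the
angiogram into the projection plane is an inverse lookup and the
stenosis travels through $T^{-1}$.

If the mapped stenosis lands within `tol_px` (default 2 px) of the CTA
artery it is snapped to the artery's centreline — the localization is
always reported on the vessel axis. Otherwise both channels are
thinned, the intersection points of the two centrelines are clustered,
the bracketing pair around the stenosis is chosen so their geodesic
passes through it, and the proportional lengths
$l_1 = l_1' L/(l_1'+l_2')$, $l_2 = l_2' L/(l_1'+l_2')$ place the
stenosis on the CTA centreline; $l_1 + l_2 = L$ holds identically.
Geodesic length on the 8-connected skeleton uses step 1 axially and
$\sqrt 2$ diagonally. Back-projection reads the provenance voxel at
the located pixel (searching within `snap_radius`, default 2 px, if
the exact pixel carries none) and converts to millimetres via the
voxel spacing.

## The phantom study

The phantoms define the conditions under which the pipeline is
verified. The 2D generator draws anti-aliased dark tubes
(pixel-centre-within-radius rule; the anti-aliasing ramp stays strictly
below half opacity outside the tube, so the midpoint threshold
reproduces the truth mask exactly) over a bright background with
additive clipped Gaussian noise. The 3D generator fills a volume with
air, optional soft-tissue/lung/myocardial cylinders, an aortic
cylinder and contrast-valued artery tubes (HU 450) rasterized by the
same distance rule, clipped to each curve's slice range so a tube
spanning slices $z_0..z_1$ occupies exactly those slices; a stenosis
narrows the radius inside a window of twice the parent radius around
its arclength position. Truth includes per-label masks, keypoints, the
stenosis voxel and the exact projection geometry of the paired
synthetic angiogram.

The demo study (`demo_pipeline_config()`) uses a 96³ volume with a
C-shaped main artery (14-voxel bow over an 85-voxel course, the kind
of curvature a left coronary branch shows), radius 3, two terminating
side branches, a mid-artery stenosis narrowed to radius 1.2, and a
view (−90°, 0°, 10°) roughly perpendicular to the artery's course, as
an angiographic working view would be. The curvature matters for more
than realism: landmarks on a perfectly straight artery are collinear
and leave the across-artery direction of the affine unconstrained.
The stenosis sits mid-artery, where lesions commonly are and where the
proportional placement is least sensitive to the slight inward
retraction of skeleton endpoints. Tracking recovery is exercised at
128³ with the same geometry scaled up, two terminating side branches,
one re-bifurcating branch and one ablated slice.

What the phantoms do not model: cardiac and respiratory motion between
the modalities (the dominant clinical error source), beam hardening,
cone-beam perspective, intensity inhomogeneity, and touching or
crossing vessels of different labels. Passing the phantom suite
therefore demonstrates the correctness of the algorithms under their
stated assumptions, not clinical-grade accuracy; on clinical data the
registration residual is dominated by the deformation between
acquisitions.

## Numerical choices and degenerate inputs

* Connectivity is 8-connected everywhere (components, skeletons,
  geodesics); EBImage's 4-connected labeler is wrapped by a 2×
  upsampling bridge to get it.
* All-constant angiograms segment to an empty mask (not an error);
  empty masks are rejected where a centreline is required.
* Metrics with zero denominators are reported as `NA`, never coerced,
  so empty masks cannot inflate scores.
* The affine solve refuses collinear source landmarks; normalization
  refuses coincident points.
* Tie-breaks: equal-depth branches at a bifurcation fall back to voxel
  volume; equal-radius endpoint roles fall back to the upper endpoint,
  and the registration's orientation check makes the pipeline
  insensitive to that guess.
* Determinism: every stochastic element (phantom noise, jitter) is
  seeded; identical configs reproduce identical reports, asserted
  bit-for-bit in the suite.

## Problem sizes

The suite and the acceptance script run on 96³–128³ volumes and
112–170 px projected angiograms — sizes chosen so the full study,
including 20 jittered registration trials, completes in well under a
minute per component on one CPU while leaving every algorithmic branch
(bifurcation resolution, preservation, backtracking, both localization
branches) exercised. Clinical 512×512×450 stacks are within the same
code paths, only slower.

## Known limitations

* The tracker assumes arteries progress monotonically down the stack;
  a vessel segment running parallel to the axial plane for many slices
  would need in-plane tracking the method does not attempt.
* Bifurcation splitting handles two daughters; three-way splits are
  reported as ambiguous errors by the seed-derivation step.
* The 2D/3D correspondence assumes the same number of detectable
  landmarks on both sides; when counts differ the pairing trims to the
  start, the first common bifurcations and the end.
* Orthographic projection ignores the divergence of a real X-ray beam;
  with uncalibrated view angles this is absorbed by the affine fit only
  to first order.
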