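---
title: "Linked registrations and distance-map label fusion: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linked registrations and distance-map label fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models implemented by `linkfuse`, the
parameters that matter, the synthetic study design, and the numerical
decisions taken where more than one reasonable choice existed.

## The segmentation-transfer model

A deformable registration of a moving image $M$ to a fixed image $F$ is a
spatial transform $T_{M \leftarrow F}$ mapping fixed-space coordinates to
moving-space coordinates, used by pull-back: the registered image is
$R(x) = M(T_{M \leftarrow F}(x))$, and the moving atlas's label map is
carried along the same transform. Registrations are *linked* by function
composition: with an intermediate atlas $I$,
$T_{M \leftarrow I(1) \leftarrow F} = T_{M \leftarrow I} \circ T_{I \leftarrow F}$,
and chains of $l$ intermediates compose $l + 1$ transforms. Because the
atlas-to-atlas transforms can be pre-computed, a new image costs one
runtime registration regardless of the atlas count; the price is that each
link contributes its own registration error.

Two transform representations are supported. A cubic B-spline free-form
deformation stores 3-vector coefficients (mm) on a regular control lattice
(8 mm spacing by default, a common choice for head-and-neck CT work); the
displacement at a point is the 64-term tensor-product basis expansion, and
the basis's partition of unity makes constant coefficients an exact
translation. A dense displacement field stores one vector per voxel and is
evaluated by trilinear interpolation. Compositions are materialized as
dense fields on the output grid — one interpolation per link — which is the
representation a production system would pre-save; the exact
B-spline-of-B-spline functional composition is retained in the test suite
as the oracle that bounds the interpolation error of this choice.

## Label fusion by signed distance maps

Each atlas proposal is converted to one binary mask per structure. For a
mask $B_j$, the signed distance map

$$D_j(x) = \pm \min_{b \in \partial B_j} \lVert x - b \rVert$$

holds the exact Euclidean distance in millimetres (anisotropic voxel
spacing honored) to the border voxel set $\partial B_j$ — object voxels
6-connected to background — negative inside the object and exactly zero on
the border itself. The fused map is the weighted voxelwise mean
$D_{fus} = \sum_j w_j D_j / \sum_j w_j$ and the consensus segmentation is
its iso-level-zero region.

Weights come from each atlas's image similarity: with $SIM_i$ the
normalized cross correlation between the fixed image and atlas $i$'s
registered image over a structure-local band (the region $D \le r$; $r = 0$
for sharp-boundary structures such as bone, 10 mm otherwise),

$$w_i = \tfrac{1}{2}\left(1 - \operatorname{erf}\!\left(\tfrac{1}{\sqrt 2}
\tfrac{k}{s}\,(SIM_{best} - SIM_i)\right)\right),$$

the upper-tail normal probability of the similarity deficit scaled by
$k/s$. The best atlas always receives $0.5$; $k/s = 0$ reduces to equal
weighting. Rather than estimating $k$ (regression slope of quality on
similarity) and $s$ (residual spread) directly, $k/s$ is parameterized by a
line angle $\theta$ and swept (default $-89^\circ..89^\circ$ in $1^\circ$
steps): at slope $\tan\theta$ the ratio is
$\sqrt{N}\tan\theta / \sqrt{ss_{yy} + ss_{xx}\tan^2\theta - 2\,ss_{xy}\tan\theta}$
with centered sums over the pooled (similarity, quality) sample, which at
the ordinary-least-squares angle equals the fitted slope divided by the
residual standard deviation (with $N$ in the denominator). Negative angles
invert the preference and are swept honestly rather than clamped.

## Quality metrics

The Dice similarity coefficient $2|B_1 \cap B_2|/(|B_1|+|B_2|)$ scores
overlap; two empty masks count as identical (DSC 1, with a warning) so that
a structure leaving the field of view does not poison an evaluation table,
and an empty-vs-nonempty pair scores 0. The fMAD curve reports, for each
query distance, the fraction of one mask's surface voxels within that
distance of the reference surface — asymmetric and cumulative, computed
from the same exact distance transform seeded on the reference surface (a
KD-tree-free choice that is grid-exact; the brute-force pairwise search is
the test oracle).

## The synthetic study

No clinical data ships with the package; a generator stands in for it.

* **Template.** A $64 \times 64 \times 48$ phantom at $2 \times 2 \times 3$
  mm (CT-like anisotropy, slice thickness above in-plane pixel size) with
  eight structures emulating a head-and-neck set: paired parotid-like and
  submandibular-like ellipsoids, a mandible-like arc, a medulla-like tube
  and two nodal-level slabs, each with its own intensity over a soft-tissue
  background plus Gaussian noise (sd 5).
* **Subjects.** Each of the (default six) subjects is the template warped
  by a random cubic B-spline field $H_i$ on the 8 mm lattice, scaled to a
  1.5 mm RMS displacement magnitude — small enough that fields stay
  invertible (coefficient spread well under half the control spacing), with
  a numerical-Jacobian positivity check that regenerates the rare folding
  draw. Labels are carried by nearest neighbor.
* **Ground-truth pairwise maps.** The exact fixed-to-moving transform
  between subjects $i$ and $j$ is $H_j^{-1} \circ H_i$ (through the
  template frame); $H_j^{-1}$ is obtained once per subject by fixed-point
  field inversion ($g \leftarrow -d(x + g)$, tolerance 0.01 mm). Composing
  the ground-truth $i\!\leftarrow\!k$ and $k\!\leftarrow\!j$ maps
  reproduces the direct $i\!\leftarrow\!j$ map to within half a voxel in
  the interior, so any quality decay observed under linking is attributable
  to injected error, not to the plumbing — the zero-noise control in the
  test suite asserts exactly this (median absolute relative DSC change
  below one percent).
* **Registration error.** A synthetic "registration" is the exact map
  pre-composed with an independent random B-spline error field of stated
  RMS magnitude (2 mm by default), drawn deterministically per ordered
  pair. Error fields are independent across pairs, so composing $l + 1$
  noisy transforms accumulates error roughly like a random walk and median
  DSC falls approximately linearly in $l$ — the phenomenology the
  evaluation engine measures. The 2 mm default places direct-registration
  DSCs in the 0.7–0.9 band typical of clinical deformable registration of
  soft tissue, leaving headroom for degradation.

What the generator deliberately does not model: CT physics and calibrated
Hounsfield units, pathology, sliding organs, or registration errors that
correlate with image appearance. The last point matters for the weight
calibration: because the injected error is independent of the images, the
structure-local similarity carries no information about proposal quality,
and the $\theta$ sweep on synthetic data correctly settles at $k/s \approx 0$
(equal weighting). The calibration machinery's ability to *find* an
informative optimum is therefore tested on constructed cases where
similarity ranks quality by design; a gain from $k/s > 0$ on real data is
expected only where similarity and registration quality actually correlate.

## Evaluation design

With $n$ atlases, the leave-one-out engine enumerates all $n(n-1)$ direct
pairs and all $n(n-1)(n-2)$ one-link chains, and samples longer chains
uniformly without replacement (seeded); at most $n - 2$ intermediates are
possible since all ids in a chain are distinct. Relative DSC change is
computed on matched pairs (same fixed, moving and structure; linked versus
direct) in percent. Fused evaluation follows the one-intermediate design:
for each (fixed $i$, hub $k$) pair every other atlas contributes through
$k$, while $k$ itself contributes its own labels through its direct
transform to $i$ — the only reading consistent with $i$ being the fixed
image. Summaries use type-7 interpolated quartiles; linked-versus-direct
distributions are compared with a two-sided Wilcoxon rank-sum test (exact
for tie-free samples up to 20, tie-corrected normal approximation
otherwise); and the median-DSC-versus-links trend is an ordinary
least-squares line whose intercept estimates zero-link quality.

The standard experiment in the tests and the acceptance script uses six
subjects, links $0..4$ (the maximum the six-subject design permits), full
enumeration of one-link chains and 30 sampled chains per longer count, all
under seed 1. At these sizes the experiment runs in about three minutes on
one CPU; the problem scales were chosen so the whole suite stays
comfortably interactive while keeping 240 scored segmentations per link
count.

## Numerical choices and edge cases

* **Iso-level tie-break:** $D_{fus} \le 0$ is object. Border voxels of a
  single input are exactly 0, so single-input fusion round-trips the mask;
  a strict inequality would erode the border layer. Consequence: in
  many-atlas fusion an arbitrarily small positive contribution excludes
  that zero-valued shell, so the large-$k$ limit of "$k$ identical masks
  plus one outlier" is the consensus interior, one voxel thinner than the
  consensus itself — visible on coarse grids, negligible on fine ones.
* **Out-of-domain policy:** displacement fields edge-clamp; B-spline
  transforms contribute zero displacement outside their lattice support;
  mask and label warps return background for points leaving the moving
  volume; image warps edge-clamp (cubic interpolation mirrors, matching
  its prefilter's mirror boundary).
* **Label interpolation:** nearest neighbor, preserving label integrity.
  At 2 mm voxels this is the dominant resampling cost: even error-free
  transfers of a 10 mm structure score DSC around 0.85–0.93 because both
  the subject labels and the transferred labels carry half-voxel surface
  jitter. Warping distance maps and re-thresholding would trade this for
  smoother surfaces but couples structures to their fusion representation;
  it was left out of scope.
* **Distance transform:** exact squared-Euclidean transform
  (lower-envelope-of-parabolas, separable per axis with physical spacing)
  rather than a chamfer approximation, so the 1-Lipschitz property and the
  brute-force oracle hold to rounding error.
* **Cubic image interpolation** uses the standard recursive prefilter
  (pole $\sqrt 3 - 2$, gain 6, mirror boundaries) so that spline
  evaluation interpolates the original samples.
* **erf** is evaluated through the normal CDF of R's math library;
  agreement with a 60-term series expansion to $10^{-12}$ is asserted in
  the tests.
* **Degenerate inputs:** empty or full masks have no border and are
  rejected by the distance transform; atlases whose warped structure is
  empty are dropped from that structure's fusion with a warning; all-zero
  weight vectors and mismatched grids are errors, not silent recycling.

## Limitations

Axis-aligned geometry only (no orientation matrices or oblique
acquisitions); no DICOM or RT-STRUCT IO; transforms arrive from files or
the generator — the registration optimizer itself (similarity metric,
optimizer, pyramids) is out of scope; no inverse-transform computation in
the public transform algebra (the generator's internal field inversion
serves only the synthetic ground truth); global per-structure fusion
weights, not locally varying ones; and conclusions drawn from the phantom
transfer to clinical data only insofar as the error model above is
adequate.
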