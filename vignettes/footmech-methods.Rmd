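---
title: "Methods: bone registration, ligament morphing and load-case kinematics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bone registration, ligament morphing and load-case kinematics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`footmech` quantifies internal foot mechanics from serial CT scans of a
statically loaded foot. This vignette explains the models and numerical
choices; the README shows the worked example and the test suite checks
every figure quoted here.

## Problem setting and assumptions

A loading series consists of one carefully segmented reference scan
(one binary mask per bone) and many loaded scans that are only
thresholded, producing a single *skeleton* mask per configuration in
which bones are not separated — thresholded foot bones routinely touch
at the joints, so connected-component labelling cannot split them. The
core assumptions are:

* bones are rigid bodies: each bone's motion between the reference and
  a loaded configuration is a rotation plus translation;
* the scanner grid is axis-aligned with known spacing (volumes with
  non-identity direction matrices are rejected rather than silently
  reoriented);
* ligaments are straight fibers between two attachment points that move
  rigidly with their bones, so engineering strain
  `100 * (L - L_ref) / L_ref` is well defined per fiber.

## Rigid registration

For a bone cloud `p_i` (i = 1..Np) and a skeleton cloud, the objective
is the mean squared distance from each transformed bone point to its
nearest skeleton point; the matched point is recomputed at every
evaluation because it depends on the candidate transform. Rotations are
parameterized by intrinsic Z-Y-X Euler angles (with `euler = c(ax, ay,
az)`, `R = Rz(az) Ry(ay) Rx(ax)`) taken about the cloud centroid so that
rotation and translation live on comparable scales; only the action on
points is convention-independent, so accuracy statements are always
about point positions, never raw angles.

The minimizer is BFGS with numerical gradients (restarted until the
cost stops decreasing), followed by closest-point Kabsch iterations
that are accepted only while the cost decreases. Near-rotationally
symmetric bones (metatarsal shafts, phalanges) have genuine local
minima roughly 0.2 rad from the optimum even on exact data; when the
converged cost exceeds `escape_cost` (0.5 mm², i.e. clearly worse than
voxel noise), a deterministic stencil of six ±0.2 rad angle offsets is
probed and the best basin re-descended. Inside the hierarchy the
previous level supplies a good initial solution, so the stencil is
disabled there and the point budget reduced (1000 points per segment,
evenly strided); the final residual is always evaluated on the full
cloud.

**Hierarchy.** Cold per-bone starts fail when a bone's displacement is
comparable to the spacing between similar neighbours (one phalanx locks
onto the next one's target). Segments are therefore optimized
coarse-to-fine — whole foot; tibia+fibula; ankle; midfoot; the five
rays; metatarsus; the phalanx rows; finally bone by bone from the tibia
to the distal phalanges — with each segment's solution initializing its
members at the next level. During the bone-by-bone pass, skeleton
points within one voxel diagonal (≈1.37 mm at 0.66×0.66×1.0 mm; the
capture radius is configurable) of each already-placed bone can be
subtracted so the small distal bones are fitted on remaining points
only.

**Residuals.** Two quality figures are reported. The cloud residual is
the mean non-squared closest-point distance of the bone cloud to the
skeleton cloud — the direct by-product of the optimized objective, but
floor-limited near 0.4 mm by voxel-center quantization (two voxelized
samplings of the same surface sit about half a voxel apart on average).
The surface residual refines each transform by trimmed point-to-surface
closest-point iterations of the bone surface onto the skeleton
isosurface (both isosurfaces extracted at level 0.5) and reports the
mean bone-surface-to-skeleton-surface distance; this is the
registration-quality measure of the workflow, and it is what the
acceptance run compares against the sub-voxel quality bound.
Correspondences beyond four times the median distance are dropped each
iteration so joint-contact zones and neighbouring bones do not bias the
fit.

## Generic-to-patient morphing

The protocol has three stages, each monitored by the symmetric
Hausdorff RMS distance (HRMSd): the root mean square of
vertex-to-opposite-surface (point-to-triangle) distances pooled over
both directions. Symmetric was chosen as the stricter, order-free
variant.

1. **Alignment.** Source centroid onto target centroid; principal axes
   aligned, choosing among the four right-handed sign combinations the
   rotation with maximal trace (smallest angle); isotropic scale from
   the ratio of mean centroid-to-vertex distances. Near-spherical
   sources (top eigenvalue gap below 0.1%) fall back to centroid +
   scale with a warning.
2. **Normal projection.** Each source vertex moves along its unit
   normal — flipped to point toward the nearest target surface point —
   by `w(t) * d_i`, with the capped linear schedule `w(t) =
   min(a (1 + t), w1)`, `a = 0.025`, `w1 = 1`: small early steps keep
   far-from-target meshes stable, full steps finish the approach.
   Windowed-sinc (Taubin lambda/mu, passband 0.1, 20 iterations)
   smoothing after every step prevents accumulated mesh degradation;
   the lambda/mu pair acts as a low-pass filter whose near-unit gain in
   the passband keeps the enclosed volume within 1%. Iterations stop
   when HRMSd falls below 0.3 mm (configurable) or after 500 steps.
3. **RBF morphing, 5 passes.** For each target vertex, the line along
   its normal is cast onto the source; the hit is the landmark `p_j`,
   the target vertex its destination `p_j*` (fallback: closest source
   point when no hit lands within 5 source mean edge lengths). Pairs
   are ranked by displacement magnitude, spatially deduplicated at one
   source mean edge length (ties broken by vertex index), and an
   increasing fraction (0.10, 0.25, 0.45, 0.70, 1.00) used per pass.
   Solving `K_land W = D_land` makes the interpolation exact at the
   landmarks; every vertex then moves by its kernel-interpolated
   displacement, followed by slight smoothing (5 windowed-sinc
   iterations — heavier smoothing would undo the exact landmark fit).

**Kernel choice.** Two kernels are provided. The capped-exponent
inverse multiquadric `k(d) = (d² + d·c)^(-β)`, `β = min(b·d, k1)` with
`b = 10`, `k1 = 0.1` and `c` the minimum deformed-source-to-target
distance (floored at 1e-6 mm) is exported and unit-tested against hand
evaluations, with the alternative typographic reading `d² + d^c`
selectable. With these constants, however, the exponent never exceeds
0.1, so the kernel is nearly flat across a bone: exact interpolation of
dense landmark sets is then catastrophically ill-conditioned and the
interpolant oscillates by millimetres between sub-millimetre landmarks
(we verified this across landmark densities, with and without affine
augmentation). The morph protocol therefore defaults to the compactly
supported Wendland C² kernel `k(d) = (1 - d/s)⁴ (4 d/s + 1)` with
support `s` three times the median nearest-landmark spacing: positive
definite, local, sparse (solved by Cholesky on a sparse matrix), and
exactly interpolating — which is what lets the final pass, whose
landmarks cover the target at mesh resolution, bring the morphed
surface within the discretization floor of the target. That floor is
the facet sagitta (`edge² / 8·curvature-radius`), which is why
micron-level HRMSd statements require meshes sampled near CT
resolution.

**Attachment transfer.** Attachment points in source space ride through
the alignment similarity, then through the barycentric interpolation of
the per-vertex displacement field on their closest aligned-source
triangle (points farther than 5 mm from the surface are an error naming
the offending fiber). Constructed affine or translation displacement
fields are recovered essentially exactly — the transfer machinery adds
no error of its own. End to end, however, a surface-matching morph can
only recover the *geometric* correspondence: any tangential sliding of
material points between the generic and patient anatomies is invisible
to surface distances, so attachment accuracy is bounded by the
magnitude of that tangential component, not by the HRMSd. This is a
limitation of the method class, not of the implementation, and the
phantom tests bound it explicitly.

## Biomechanical measures

The anatomical frame is not derivable from the data alone, so a
documented construction is used: superior = tibia long principal axis
oriented from the talus toward the tibial plateau; anterior = calcaneus
COM → second-metatarsal COM, orthogonalized; medial = superior ×
anterior for a left foot, negated for a right foot. All angle outputs
carry this frame. Angles are the signed (counterclockwise-positive,
atan2-based, in (-180°, 180°]) projections of three bone centers of
mass onto the sagittal (anterior/superior), coronal (medial/superior)
or transverse (anterior/medial) plane, with the vertex at the middle
bone; centers of mass come from the divergence theorem over closed
meshes. The tracked angles are TibTalCal (sagittal: plantar-dorsal
flexion; coronal: varus-valgus) and CalTalSM with the medial sesamoid
COM as third point (sagittal: arch sagging; transverse:
abduction-adduction). Reported quantities are amplitudes: configuration
minus reference (the bare unloaded scan). Translation amplitude is the
COM displacement under the motion relative to the frame bone (tibia
keeps whole-leg placement, calcaneus removes the foot-segment motion);
rotation amplitude is the geodesic angle `acos((tr R - 1)/2)`.

## Statistics

Bare and shod values are paired by (orientation, load) per entity and
compared with the Wilcoxon signed-rank test: zero differences dropped
(the classical convention), average ranks for ties, exact null via the
signed-rank distribution for n ≤ 25 without ties, normal approximation
with continuity and tie corrections otherwise. No multiple-testing
correction is applied; p-values are reported raw, with the per-entity
median difference, and the summary is the fraction of entities
significant at alpha = 0.05. Pooling vs per-foot testing is a grouping
flag.

## The phantom: what it emulates and what it does not

The phantom provides every input the workflow needs with known ground
truth: 30 superellipsoid bones (exponent 2.3, smooth radial noise of
0.4 mm) in an anatomical layout with joint gaps above 1 mm, voxelized
at 0.66 × 0.66 × 1.0 mm; load cases as a whole-foot motion (4°, 3 mm —
chosen so that, with the ~125 mm lever arm of distal bones, every
per-bone displacement stays within the stated 15°/15 mm plausibility
caps) composed with per-bone perturbations (≤2°, ≤1.5 mm); an optional
one-voxel dilation that reproduces the joint interconnections that
defeat connected-component segmentation; a generic model built by
retessellating each bone and applying a known smooth warp (5% scale,
±5% per-axis anisotropy, ≤6° twist, six Gaussian bumps of up to 2 mm)
with attachments carried through the warp; and 20 ligament fibers
including a five-fiber plantar aponeurosis group. Everything is a pure
function of the specification and seed.

What passing phantom tests does *not* show: real bones are not
superellipsoids (no trabecular texture, no thin cortical structures,
no marrow-intensity ambiguity in thresholding); real generic-vs-patient
shape differences are anatomically structured rather than random smooth
warps; the phantom's noise-free "CT" has no beam hardening, metal or
motion artifacts; and cadaveric load responses are far richer than
rigid per-bone perturbations. The phantom validates the algorithmic
chain and its numerical accuracy, not clinical performance.

## Problem sizes and numerical defaults

The validation study uses: bones sampled at icosphere subdivision 3
(642 vertices) for registration, 4 (2562) for routine morphing pairs
and 6 (40962) for the dense calcaneus-scale pair; segment optimization
on at most 1000 evenly strided points; BFGS relative tolerance 1e-9
with up to 500 iterations per segment; ridge 1e-9 plus iterative
refinement for near-singular dense kernel systems; kernel scale floored
at 1e-6 mm; landmark systems solved sparsely beyond a few hundred
landmarks. The end-to-end pipeline example runs one bare/shod pair; the
acceptance script registers one full 30-bone load case and morphs ten
bone pairs plus one dense pair, a few minutes on one CPU.

## Known limitations

* Recovered Euler angles are convention-dependent; only point actions
  are comparable across implementations.
* The surface-residual refinement assumes the thresholded skeleton
  isosurface is locally the bone surface; heavy joint contact (strong
  dilation) biases it, which is why the trimmed correspondence is used.
* Attachment transfer inherits the tangential ambiguity discussed
  above.
* The printed inverse-multiquadric constants are retained for
  comparison but are not numerically viable for dense exact
  interpolation; the Wendland default is the supported path.
* Statistical power with few configurations is minimal; the Wilcoxon
  machinery is exact, but n is whatever the loading protocol provides.
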