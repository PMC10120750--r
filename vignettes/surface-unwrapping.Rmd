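---
title: "Surface-guided unwrapping of 3D cell surfaces: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface-guided unwrapping of 3D cell surfaces: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cellwrap)
```

## The problem

Cell surfaces imaged by light-sheet microscopy are rugged, closed (ideally)
triangle meshes decorated with protrusions — globular blebs, sheet-like
lamellipodia, hair-like filopodia — and with membrane-associated fluorescence
signals attached to their vertices. Most quantitative operations one wants to
perform (segmenting individual protrusions, tracking them over time,
averaging a signal over a moving patch) are awkward on an arbitrary embedded
surface but straightforward on a sphere, a plane, or a height field.
`cellwrap` builds bijective maps between five equivalent representations of
one cell:

1. the input Cartesian surface `S(x,y,z)`;
2. a smooth genus-0 **reference surface** obtained by conformalized mean
   curvature flow (cMCF), a proxy for the cortical cell body;
3. the **unit sphere**, via a quasi-conformal parameterization that can be
   relaxed continuously between angle-preserving and area-fraction-preserving;
4. the **topographic space** `(d, u, v)`: a curvilinear volume normal to the
   reference surface in which every protrusion points "up";
5. the equirectangular **2D plane** `(u, v)`.

Because every map is bijective, measurements and segmentations made in the
friendliest representation can be pushed back onto the original surface.

## Models and procedures

### Conformalized mean curvature flow

Mean curvature flow evolves vertex positions by the Laplace–Beltrami
operator of the evolving metric; conformalizing the flow freezes the
cotangent Laplacian at its initial value `L0` while the barycentric mass
matrix `M_t` is rebuilt every iteration:

$$ (M_t - \delta t\, L_0)\, v^{t+1} = M_t\, v^t . $$

Freezing `L0` preserves local face aspect ratios (the flow is conformal) and
avoids the pinching that makes plain MCF terminate early on thin features.
Face connectivity never changes, so the flow is bijective by construction.
After each implicit step the surface area is renormalized to 1 and the
centroid recentred, which stabilises the numerics; the mean absolute
Gaussian curvature (vertex angle deficit) is recorded per iteration.

**Stopping rule.** The useful reference shape is not the flow limit (a round
sphere) but the "elbow" where protrusions have been absorbed and the cortical
shape remains. `auto_stop()` returns the first iteration whose change in
mean |K| falls below `delta_thresh` in magnitude (never earlier than
`t_min`). The description of this rule in the source literature can also be
read literally as "first iteration whose change *exceeds* the threshold";
on the monotonically flattening traces the flow actually produces, that
reading fires immediately and contradicts the elbow intent, so the
magnitude-below-threshold reading is the default and the literal one is
available via `mode = "exceed"`.

For protrusion *quantification* we deliberately run the flow past the elbow
(`segmentation_pipeline_config()` sets `t_min = 25`): any bump remnant left
in the reference subtracts directly from the measured protrusion height
`h = d - d_ref`, and a cleaner cortex is worth a slightly smoother
reference. When the flowed mesh is rescaled back to cell size, volumes are
matched rather than areas — an area match inflates the smooth shape outside
the cortex (smooth shapes enclose more volume per unit area), which would
bias every height measurement.

### Spherical parameterization and area-distortion relaxation

A closed genus-0 surface is mapped to the unit sphere by running cMCF to
spherical convergence, projecting radially, and Möbius-centering so the
spherical area centroid sits at the origin; residual flipped triangles (rare)
are repaired by local tangential smoothing. The contract is
representation-level: the map must be bijective (zero flipped spherical
faces) with a global conformal error `Q` close to 1.

Conformal maps of elongated or bumpy shapes compress entire protrusions into
tiny spherical regions. The relaxation therefore advects vertices along
`V = -∇ log λ`, where `λ` is the per-face ratio of normalized source to
sphere areas: the field carries the sphere's area density from compressed to
stretched regions, exactly equalising area fractions in the limit. One
iteration: normalize areas, form `λ`, average `log λ` to vertices, take the
per-face finite-element gradient, rescale the field so its *median* norm
equals the mean edge length, average to vertices, project into the tangent
plane, take one implicit active-contour step of size `epsilon`, recentre and
reproject to the sphere.

Two numerical safeguards keep every accepted iterate bijective: per-vertex
displacements are capped at `clamp` (default 3) mean edge lengths — the raw
gradient is sharply peaked at protrusion rims, with maxima two orders of
magnitude above the median — and the step size is halved (up to 16x) until
the candidate has no flipped faces. If no admissible step exists the run
stops and returns the last valid iterate with `collapsed = TRUE`.

Four stopping criteria are evaluated along the cached trajectory and any of
them can be extracted post hoc: *equiareal* (`|λ − 1|` below `equi_tol`,
default 0.005), *conformal/MIPS* (iteration 0; the MIPS energy
`σ2/σ1 + σ1/σ2` is minimal for conformal maps), *isometric*
(`(1-θ) Q + θ log λ`, interior minimum, `θ = 0.5`), and *area-preserving
MIPS* (`(σ2/σ1 + σ1/σ2)(σ1σ2 + 1/(σ1σ2))^θ`, `θ = 1`). The printed form of
the area-preserving MIPS in the source literature is typographically
garbled; the implementation follows the standard product form above.

### UV chart and unwrapping axis

The equirectangular chart has rows sampling the pole-to-pole arc (length π)
and columns the equator (length 2π), hence the fixed 1:2 aspect. Pixel
directions are matched to spherical triangles deterministically (candidates
from the 2-ring of the nearest vertex; the face maximising the minimum
barycentric coordinate wins, ties to the smallest index) and the barycentric
weights are reused to look up any bijective partner mesh or vertex field.
Pole rows carry the largest area distortion, so the pole axis is chosen by
weighted PCA of the spherical vertex positions (weights typically `|H|` of
the reference): the smallest-eigenvalue direction becomes the axis, sending
high-weight features toward the equator. The printed weighted-covariance
formula in the source is ambiguous; the standard weighted second-moment
matrix is used. `v = 0` faces the `+e3` pole and `u = 0` the `+e1` azimuth.

### Topographic space

The reference chart is propagated along the steepest gradient of the signed
distance function of the voxelized reference surface, in steps of
`alpha = 0.5` voxels, outward until the cell is fully enclosed and inward a
configurable number of steps, yielding a `(D, rows, cols)` lookup of
Cartesian coordinates. Two details matter numerically:

* the signed-distance grid is **upsampled** (default 2x) so one UV pixel
  spans less than one grid voxel — without this the voxel staircase imprints
  ~1-step noise onto every propagated sheet;
* each sheet is box-filtered (window 5, periodic in u) for stability, but
  only the **tangential** component of the smoothing displacement is kept —
  unconstrained smoothing contracts curved sheets toward their centre and
  systematically shrinks the offset radii.

On analytic sphere phantoms the propagated sheets match the true offset
spheres to well under half a voxel, and the signed distance is strictly
monotone along every trajectory (the discrete statement that `d` preserves
the curvilinear normal distance). The inverse map `(x,y,z) -> (d,u,v)` is a
nearest-lookup-node search refined by Gauss–Newton iterations on the
trilinear interpolant; round trips stay below one voxel.

### Protrusion segmentation

The topographic surface is approximated by a height image (per-(u,v) longest
contiguous foreground run, which automatically ignores detached internal
structures), and an asymmetric Whittaker fit (`p = 0.25`, `lam = 1`, 10
reweighting iterations) estimates the smooth cortical baseline `d_ref`: data
above the fit get weight `p`, data below `1 - p`, so upward excursions —
protrusions — are suppressed while the fit tracks the lower envelope. The
fit is solved after a fixed 8x downsampling and resized back: with the
penalty weight `lam = 1`, the downsampling itself provides most of the
smoothness regularization, so keeping the factor fixed (rather than the
working resolution) preserves the intended stiffness across chart sizes —
solving closer to full resolution lets the baseline creep up the
protrusions.

Binary segmentation thresholds the height `h = d - d_ref` at its mean,
removes components below 200 (chart-scaled) pixel², diffuses with two-class
label spreading over the combined affinity
`A = γ A_dist + (1-γ) A_convex` (`γ = 0.9`; distance kernel on 1-ring edge
lengths, convexity kernel on the cosine distance of neighbouring vertex
normals, each scaled by its mean), re-binarizing the foreground probability
at 0.25 each iteration, and removes remnants below 500 (scaled) pixel².
The published pairwise affinity matrices are dense; assembling them sparsely
over the 1-ring gives identical diffusion behaviour at tractable size.
Area thresholds are stated for the reference 1024 x 512 chart and scale with
chart area; the diffusion runs 5 iterations on charts at or below 512 rows
(each iteration advances the boundary by roughly one vertex ring, so the
iteration count must follow the mesh resolution).

Instance segmentation finds protrusion tops as connected regions of high
topographic mean curvature (`H = -0.5 ∇·n̂` from the signed distance
transform of the topographic binary): 3-class k-means on σ=1-smoothed `H`
(blebs/filopodia) or a 3-class Gaussian mixture on σ=1,3,5 features
(lamellipodia), fitted on 10,000 sampled shell voxels with a fixed seed,
keeping the highest-mean class. Components ≥ 500 voxels become seeds,
expanded 3 voxels, transferred to the mesh, intersected with the binary
segmentation, diffused (10 iterations, no re-binarization) and re-masked.
Finally the protrusive definition is applied once more *per instance*,
judged by the instance's curvature top (its seed region — diffusion
deliberately grows the skirt downhill): the seed's mean height must exceed
the global mean height by more than the robust spread `mad(h)` of the
height field. Cortex undulations produce seeds at cortex level
(`h ≈ h̄ ± mad`) while genuine protrusion tops stand several `mad` above
it, so the margin separates them without any free threshold; instances
failing it (including internal structures, whose `d` never exceeds
`d_ref`) are removed. On bumpy-sphere phantoms this pipeline recovers
every planted bleb exactly once with no spurious instances.

Under-segmented (conjoined) blebs are split in 2D: the labelled submesh is
hole-imputed, quarter-downsampled, unwrapped to a 128 x 128 square via a
harmonic disk map plus area relaxation and the elliptical disk-to-square
mapping, its mapped curvature thresholded at the upper 3-class Otsu
threshold of the whole-mesh `H`, closed with a disk of radius 1, and the
seed-free gradient watershed of the Euclidean distance transform separates
the touching circular regions. Refined labels are diffused back on the full
mesh and the binary mask re-applied.

Volume decomposition renders the protrusion-free surface as a `d_ref(u,v)`
image, imputes the missing pixels under removed protrusions by
Laplace-diffusion inpainting (the fast-marching inpainting of the reference
implementation is not available in R; the diffusion fill satisfies the same
boundary-interpolation contract), takes `{d < d_ref}` as cortex, and
propagates surface labels through the cell volume by a slice-wise marker
watershed on the slice distance transform, top slice to bottom, previous
slices taking precedence. Cortex plus protrusion volumes partition the cell
to within 2% on phantoms. The alternative fully-Cartesian decomposition
closes each protrusion with a minimal-bending (biharmonic) cap over its
boundary loop; the cap is refined with concentric rings rather than midpoint
subdivision so its boundary conforms exactly to the coarse protrusion
boundary and the merged meshes stay watertight.

### Dynamics

Pixel statistics on an equirectangular chart are biased by the area element;
every timeseries is therefore a `dA`-weighted mean
(`corrected_mean()`), which matches direct 3D area-weighted means to within
1% on phantoms. Bleb tracking links per-frame bounding boxes (on
spherically padded label images: periodic in u, pole rows reflected and
u-flipped) by flow-predicted greedy IoU matching (accept > 0.25), bridges
gaps up to 5 frames, and applies the lifetime, curvature, unique-label and
box-jump repairs as gating rules. The dense flow backend is a pluggable
callable; the packaged reference is a coarse block-matching estimator, and
tests drive the tracker with ground-truth synthetic flow so the gating logic
is tested independently of any flow estimator's quality. Event alignment
smooths per-track area series (window 3), detects peaks with prominence
> 0.5 separated by ≥ 3 timepoints, and averages ±14-timepoint windows.
Ruffle speeds are split into slow (retrograde-flow-like) and fast
(travelling-ruffle-like) populations by reporting the two 3-class Otsu
thresholds of the per-track mean speeds — a convention that conflates
thresholds with population means; a 2-component Gaussian-mixture estimate is
returned alongside for comparison. The 95% confidence band of the
cross-correlation curves uses the normal approximation across ROI tracks.

## The phantom generator

`phantom_spec()` fixes the study conditions for every test: a sphere of
radius 30 voxels (similar, relative to typical light-sheet voxel sizes, to a
small rounded cell) carrying hemispherical-cap blebs of height a quarter of
the radius and angular width 0.45 rad — proportions matching micrometre-scale
blebs on a ~10 µm cell — plus optional Gaussian-crest ridges
(lamellipodium-like), thin spikes (filopodium-like), punched holes and
welded handles for genus defects. The mesh is an icosphere lattice
(`10 k² + 2` vertices, `k = 45` by default, ~20k vertices), all randomness
derives from the integer seed, and phantoms are reproducible bit-identically.
What the phantoms do *not* emulate: microscope noise and PSF anisotropy,
meshing errors that swallow internal volumes, densely packed protrusions at
the chart poles, and temporal shape drift; passing phantom tests therefore
demonstrates the correctness of the mappings and the segmentation logic, not
robustness to every pathology of real microscopy data.

## Problem sizes and numerical choices

The default analyses in the tests and the reproduction script run at desk
scale, chosen so the full suite completes on a single CPU: ~20k-vertex
phantoms for the spherical parameterization (the published workflow
recommends > 40k for the most extreme shapes; our phantoms relax safely at
half that), 128-row topographic charts for segmentation (the reference
configuration is 512), 48-to-64-row charts for round-trip and robustness
tests, and a 20-phantom robustness battery at radius ~14. Sparse systems are
solved by direct Cholesky/LU factorization per iteration (the mass matrix
changes every step); cotangent weights are clamped at zero in the `"robust"`
operator variant, which is also the automatic fallback on non-manifold
input. Marching cubes uses the classic lookup-table variant at isovalue 0.5
after σ = 1 Gaussian smoothing of binaries; either classic or topology-aware
variants satisfy the watertightness contract on the binaries produced here.
The isotropic remesher is a deterministic Lloyd clustering with
cluster-connectivity enforcement and a small-defect repair pass (dropping
faces on over-shared edges and fan-filling holes up to 12 edges), which
yields watertight, near-equilateral meshes (median radius ratio > 0.8 on
ball binaries) with a fixed internal seed.

## Known limitations

* Spherical parameterization is restricted to genus-0 surfaces; higher-genus
  inputs must pass through the reference-surface route, and fail cleanly if
  voxel closing cannot remove their handles.
* The equiareal relaxation equalises *global* area fractions; individual
  faces inside extremely thin spikes may remain distorted (the submesh
  unwrapper's quarter-downsample fallback exists for exactly this case).
* Topographic charts under-represent surface regions far from the reference
  surface; tall dense protrusions are smoothed in the reconstructed twin.
* The slice-wise watershed decomposition assigns contested voxels by
  top-down precedence, which can transfer a few voxels between touching
  protrusions; the partition remains conservative to ~2%.
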