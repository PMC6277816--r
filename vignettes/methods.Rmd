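---
title: "Methods: left-atrial model construction and monodomain electrophysiology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: left-atrial model construction and monodomain electrophysiology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models and numerical procedures implemented by
atriofiber, the assumptions behind them, the tunable parameters with their
defaults and units, and the design decisions taken where the method left
genuine freedom. Units are fixed package-wide: mm, ms, mV, S/cm, µF/cm²;
conversions happen only at I/O boundaries.

## 1. Statistics-based wall segmentation

The left-atrial wall is thin (roughly 0.5–3 mm) and, on contrast-enhanced CT,
separated from the bright blood pool only by an intensity gradient. The
segmentation therefore works from *sample statistics*: the user (or the
phantom generator) marks three sample regions in the myocardium and three in
the atrial cavity; means and standard deviations are pooled over the union of
the sample voxels, never averaged per region. Thresholds follow as

* `LT = mean_myo − 3·sd_myo` (lower bound of viable myocardium),
* `UT = mean_blood + 3·sd_blood` (upper bound of blood),
* `MT = (mean_myo + mean_blood)/2` (the common boundary between the two
  overlapping populations).

`LT ≥ MT` means the two populations are inseparable and is reported as a
degenerate-statistics error. A median prefilter (default kernel: voxel plus
its 6 face neighbors, border-replicated) suppresses impulse noise; the named
vendor filter it replaces is not publicly defined, so the kernel is an
explicit parameter.

The blood pool is the 6-connected component of the `[MT, UT]` band containing
a required **seed point** (a physical coordinate; a largest-component
heuristic would be fooled by decoy bright structures such as the ventricle).
The wall is then

```
wall = (⋃_{k=1..K} dilate^k(blood) ∩ viable) ∪ (dilate^1(blood) \ blood)
```

with `viable = [LT, MT)` and `K = floor(max_thickness / min(spacing))`
6-connected dilation steps realizing the physical **3 mm thickness cap**
(`cap_mode = "euclidean"` additionally crops by true Euclidean distance). The
1-voxel dilation ring guarantees minimum wall thickness wherever the wall
band is locally absent. Because K city-block steps cover at most
`K·min(spacing)` mm, the Euclidean distance of any wall voxel to the blood
pool is bounded by the cap by construction; the acceptance report measures it
explicitly.

MV and PV orifices are cut by analytic geometries from 3 user points each:
the circumcircle of the 3 points defines, for the MV, a thin spherical shell
(center and radius of the circumcircle; a sphere through 3 points is
under-determined, so the circumcircle convention with a configurable shell
thickness, default 2 mm, is the package's documented choice), and for each PV
a finite cylinder along the circle normal (radius × `cyl_margin`, default
1.2; height `cyl_height`, default 3 mm). Voxels disconnected from the
blood-pool seed after cutting are removed ("distal to the LA"); orifice tags
are kept only where they touch the retained component. The classes
{wall, mv, pv} always partition the myocardium — this tag algebra is enforced
by construction and asserted in the tests.

## 2. Constrained smoothing and isotropic resampling

Voxelized thin walls show staircase artifacts. The binary wall is embedded as
a signed Euclidean distance field whose zero level reproduces the binary
interface exactly (distances are measured to the midpoints of inside/outside
voxel pairs — using voxel centers instead biases the surface by half a
voxel). Smoothing is a Taubin-style two-pass relaxation (λ = 0.5 forward,
µ = −λ/(1 − 0.15λ) backward, 50 iterations): the negative pass compensates
the volume shrinkage of pure Laplacian (curvature-flow) smoothing, so an
already-smooth sphere keeps its volume to better than 1 % while staircase
frequencies are damped (the radius scatter of a 2 mm-voxel sphere drops by
more than half). After every iteration the field is clamped to
`d0 ± cap` with `cap = max_displacement_fraction × min(spacing)` (default
0.5): since `|∇d0| ≈ 1`, this bounds the geometric displacement of the zero
level set. **Displacement is measured as |d0| interpolated at the smoothed
zero-crossing points** — i.e. distance to the continuous reference
isosurface, which avoids the sampling bias of nearest-point queries against
a discrete crossing cloud. On staircase inputs the corners displace up to the
cap, so the measured maximum sits at exactly 50 % of the voxel size.

Resampling interpolates the smoothed field trilinearly onto an isotropic
grid (reference 100 µm; the pipeline default is 200 µm to keep desk-scale
runtimes) and transfers class tags from the nearest original voxel.
Upsampling only: a target spacing coarser than the input is refused.

## 3. Meshes, boundary surfaces and the region atlas

Meshes are plain indexed structures (surface triangles / tetrahedra with
optional per-element integer tags and unit fiber axes) with CARP
(`.pts/.elem/.lon`, fixed to mm, 0-based indices, one axis per element),
legacy-ASCII VTK and MetaImage I/O. Boundary extraction collects faces owned
by exactly one tetrahedron, wound outward, and groups them by breadth-first
search over shared edges. For geometries with orifices cut through the wall
the boundary is a single closed surface; a **feature-angle** limit (the BFS
refuses to cross creases sharper than, e.g., 50–60°) separates the endo- and
epicardial sheets from the narrow rim bands. Open rims are traced as closed
vertex loops. Non-manifold boundary edges are an error.

The full human atlas (hundreds of landmarks/lines/regions) is not
reconstructible from published material; the package instead defines a
serializable JSON atlas format (landmarks, auxiliary lines as vertex paths,
regions with seeds and per-region boundary assignments) and ships a
simplified ellipsoid-atrium atlas generated constructively (Section 6).
Auxiliary lines are shortest Euclidean-weighted paths computed by an
in-package Dijkstra restricted to explicit *corridor* triangle sets, with a
deterministic lexicographic-predecessor tie-break; igraph serves as an
independent oracle in the tests, never in the implementation. Region growing
floods triangle adjacency without crossing line edges; leaks between seeds
and unreached triangles are hard errors naming the culprit.

Landmark transfer is nearest-neighbor (ties to the lowest vertex index) from
an atlas surface to a registered surface of identical topology — the
diffeomorphic registration itself is out of scope and accepted as input.
Derived landmarks support equal-arc rim subdivision and geodesic midpoints.

## 4. Laplace–Dirichlet surface and transmural fibers

All solves use P1 (piecewise-linear) Galerkin stiffness matrices — the
cotangent form on triangles (intrinsic tangent-plane gradients, no global
parametrization) and the gradient-product form on tetrahedra — with sparse
direct factorization of the reduced SPD system. Dirichlet values are
satisfied exactly, everything else is a natural zero-flux boundary, the
relative residual is below 1e−10, vertices referenced by no element are
excluded, and a mesh component without Dirichlet support is a
singular-system error. Linear fields are reproduced to round-off and the
annulus/spherical-shell harmonics converge at O(h²) (verified over
refinement in the tests).

Per region, the fiber axis is the normalized in-plane gradient evaluated per
triangle. Rim-encircling patterns (PVs, MV, LAA) need the axis *along* the
rim while the gradient of a rim-to-outer-line solve points *across* it; the
atlas therefore carries a per-region `orthogonal` flag that rotates the axis
90° in the triangle plane (`axis ← n̂ × axis`). This realizes the two
boundary-condition colorings of the region scheme. Degenerate gradients
(‖∇u‖ < 1e−8) are left undefined and filled by the sign-aligned average of
defined edge-neighbors (axes are **line fields**: every average in the
package flips representatives into a common hemisphere first, otherwise
antipodal axes cancel). Interregional smoothing averages each triangle with
its edge-neighbors within `band_width` edge-hops of a line (default 2 hops,
3 passes — "proximity" is not prescribed anywhere, so both are exposed), and
a final tangential projection (`axis ← normalize(axis − (axis·n̂)n̂)`)
restores exact in-plane unit axes; axes degenerated by the projection are
refilled from neighbors.

Transmurally, the same solver produces the wall coordinate φ (0 endocardium,
1 epicardium; open rims zero-flux). Each tetrahedron stores φ as the mean of
its 4 nodal values clamped to [0,1], the unit field-line direction
∇u/‖∇u‖, and the endo-/epicardial triangles hit by tracing the field
downhill/uphill from the barycenter. Tracing is exact element-hopping: the
gradient is constant per tetrahedron, so the exit face is a ray/plane
intersection and the trace advances face-to-face deterministically. Discrete
field lines of a piecewise-constant field can converge at a face (the two
adjacent gradients both point into it); the tracer detects the resulting
ping-pong and slides along the face using the face-projected mean direction.
Traces that leave through an open rim fall back to the nearest surface
triangle and are flagged in the provenance table rather than failing — open
rims are a normal feature of the geometry.

The transmural interpolation weight ω(φ) comes in four schemes: 2-layer
(step at φ = 0.5), 5-layer (steps 0, 0.25, 0.5, 0.75, 1 at 0.2/0.4/0.6/0.8),
linear (ω = φ) and sigmoidal. The sigmoidal profile is implemented as
`ω = (1 + tanh(5(φ − 0.5)))/2`: the bare `tanh` form has range ≈(−0.5, 0.5),
which cannot serve as a convex-combination weight, so the affine
normalization onto [0,1] is adopted (its graph matches the intended
0-to-1 sigmoid profile). The per-element fiber is
`f = ((1−ω) f_ED + ω f_EP)/‖·‖` with f_EP sign-aligned to f_ED first (the
two surface solves carry arbitrary signs), then projected orthogonal to the
local field line and renormalized; projection degeneracies are neighbor-
filled. When endo and epi fields coincide, every scheme reproduces the
surface field exactly through the wall.

## 5. Monodomain electrophysiology

The tissue model is the monodomain reaction–diffusion equation with the CRN
human atrial ionic model (21 state variables, 12 membrane currents,
published resting state V ≈ −81.2 mV). The cell model and the 1-D cable
integrator are compiled (Rcpp); integration is Rush–Larsen for the 15 gates,
explicit for V and the 5 concentrations, and the diffusion step is implicit
(backward Euler) with a lumped P1 mass matrix, factored once per simulation.
The global step defaults to the reference **dt = 10 µs**. Key parameters:

| parameter | default | unit | rationale |
|---|---|---|---|
| `beta_m` | 1400 | 1/cm | standard surface-to-volume ratio; not independently constrained — the CV fit absorbs its scaling |
| `C_m` | 1 | µF/cm² | standard monodomain value (the CRN per-cell 100 pF capacitance lives inside the cell model) |
| `sigma_l`, `sigma_t` | fitted | S/cm | from the CV fit below |
| `dt` | 0.01 | ms | reference global step |
| LAT threshold | −20 | mV | first upward crossing, linearly interpolated in time to remove dt granularity |
| stimulus | 50 pA/pF × 2 ms | | suprathreshold current clamp; location is configuration, not inference |

Steady-state pacing runs a single cell at BCL 1000 ms (reference protocol
1000 beats; the tests and the acceptance report use a 50-beat limit cycle)
and reports the maximum relative state change across the final cycle as a
convergence metric. At 50 beats this is ≈0.4 % — dominated by the slow
intracellular Na⁺/K⁺ drift, which takes hundreds of beats to settle; it does
not measurably move the fitted conduction velocities.

Conductivity fitting uses the continuum scaling CV ∝ √σ: on a 2 cm cable at
the target resolution, `σ ← σ·(CV_target/CV_measured)²` until the re-measured
CV (between the 25 % and 75 % cable positions) is within 0.5 % of the target,
at most 10 iterations; discrete propagation failure at a low trial σ scales
σ up and retries. Longitudinal and transverse directions are fitted
independently (the transverse fit is the same 1-D problem with its own
target). At 200 µm/10 µs the reference targets 1.20 and 0.40 m/s are met to
≈0.15 %, and the fitted σ_l/σ_t ratio is consistent with the square of the
CV ratio. The isotropic reference material combines the same anisotropic
tensor with per-element axes drawn uniformly on the sphere from a fixed
seed.

## 6. Synthetic phantoms — what they do and do not establish

The voxel phantom is a two-compartment Gaussian-intensity image (wall mean
250 ± 30, cavity 450 ± 40, background 50 ± 10 HU-like units, 0.4 mm voxels,
1.5 mm wall by default) in slab or spherical-shell geometry, with three
sample boxes per class and a known ground-truth wall — it emulates the
bimodal intensity histograms and the sampling protocol of a contrast-enhanced
acquisition, not CT physics (no beam hardening, motion, or partial-volume
streaks).

The shell atrium is a cube-sphere structured lattice (no polar degeneracy)
mapped onto an ellipsoid (semi-axes 14 × 11 × 9 mm endocardial), wall
thickness graded 1→3 mm inferior→superior, hexahedral cells split into 12
tetrahedra around cell centroids with a global minimum-vertex-id diagonal
rule (conforming everywhere by construction), and openings cut through the
wall for 4 PVs, the MV and the LAA (with a local outward bulge standing in
for the appendage pouch). Its atlas has one encircling ring region per
opening (rim → Γ_I, outer border → Γ_II, `orthogonal` set) and four
azimuthal wall patches with parallel-line conditions — exercising every
boundary-condition pattern, the open-rim fallbacks and multi-region
interfaces. Region labels are emitted constructively, islands pinched off by
the rings are merged into wall patches so every region is edge-connected,
and the opening layout uses an even lattice count (default n = 10; n = 8
also verified) — odd counts place hole centers between lattice cells and
degrade the thin rings. The geometry is deliberately parametric, **not
anatomical**: green tests establish algorithmic correctness (partitions,
circulation, tracing, propagation ordering), not fidelity to any real
atrium, and the true human atlas with its hundreds of regions is explicitly
out of scope.

On these phantoms the test suite verifies, among others: wall recovery at
Dice > 0.9; the 3 mm cap as a measured Euclidean bound; winding number ±1 of
the fiber field around every rim; the slab transmural angle profile against
the closed form of the blend (max deviation < 2°); a point-stimulus
isochrone long/short axis ratio of 3 ± 10 % on a 2-D sheet; and that aligned
fibers activate an elongated slab's far end earlier than the random-fiber
isotropic reference. The ordering experiment uses a slab elongated along the
fiber axis with a planar stimulus: anisotropy then acts as a fast highway,
the mechanism behind the latest-activation-in-isotropic observation; on a
compact domain with a corner stimulus the transverse bottleneck can invert
the ordering, which is a geometry effect, not a solver property.

## 7. Known limitations

* Single fiber axis per element; no sheet/normal secondary axes.
* Homogeneous cellular electrophysiology; no regional heterogeneity or
  remodeling variants; monodomain only (no bidomain, no extracellular
  stimulation).
* Segmentation assumes contrast between blood pool and wall; no
  registration- or learning-based fallback, no inhomogeneity correction.
* The structured shell mesher replaces octree-based local refinement; mesh
  resolution is globally uniform.
* Diffeomorphic surface registration is consumed as an input, never
  computed.
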