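---
title: "Registering 3D coronary centerlines to 2D angiograms: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Registering 3D coronary centerlines to 2D angiograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cororeg)
```

## The registration problem

A single-plane X-ray angiogram is a cone-beam projection: every 3D point
of a contrast-filled coronary artery is mapped along a ray from the X-ray
source to the detector. The projection destroys depth, merges crossing
vessels, and the segmentation that extracts 2D centerlines from the live
image adds its own defects — gaps where contrast is weak, false branches
from catheters and rib shadows. A 3D centerline tree of the same
patient's coronaries, extracted earlier from CT angiography, has clean
topology but was acquired at a different cardiac phase and patient pose.
`cororeg` brings the two into correspondence in three conceptual steps:
a bounded rigid alignment, a discrete topology reconstruction, and a
continuous nonrigid deformation.

This vignette explains each model, the tunable parameters and the reason
for every default, what the built-in simulator does and does not emulate,
and the numerical choices a maintainer would want recorded.

## Projection model

The acquisition geometry is fully described by five DICOM quantities:
the two positioner angles (LAO/RAO about the patient's long axis,
cranial/caudal about the transverse axis), the imager pixel spacing, and
the source-to-detector (SID) and source-to-patient (SOD) distances. Both
distances appear in the geometry, which is only meaningful for a
*perspective* projection — an orthographic model would need neither — so
points are mapped by similar triangles,

$$ (u, v) = \frac{\mathrm{SID}}{\mathrm{SOD} + z_\mathrm{cam}} (x, y), $$

after rotating patient coordinates into the gantry frame (secondary
rotation about x composed after the primary rotation about y, both about
the isocenter). The isocenter is placed at the 3D tree centroid: the
DICOM header fixes the gantry relative to the isocenter but not the
patient origin, and centroid-centering keeps the bounded rigid search
meaningful. Detector coordinates are millimetres with the origin at the
raster centre, +u rightward and +v downward; pixel conversion happens
only at I/O boundaries. All distances everywhere in the package are
metric (mm), because every tolerance of interest — marker errors around
1 mm, bifurcation tolerances of 3 mm — is metric.

`backproject_ray()` inverts the projection up to depth: it returns the
source position and unit direction such that every point of the ray
projects to the given detector point (verified to 1e-9 mm in the tests).
The nonrigid image energy is built on these rays.

## Bounded rigid registration

The rigid stage minimizes the mean Euclidean distance from the projected
(and transformed) 3D centerline points to the nearest 2D centerline
point. Design choices:

* **Asymmetric distance.** Only 3D→2D distances enter the objective. The
  2D set may contain false branches and clutter; an asymmetric chamfer
  mean prevents them from pulling on the model.
* **Bounds.** `|T| <= d_max = 30 mm`, `|R| <= th_R = 10°`. The DICOM
  geometry already provides a coarse alignment, so only a residual
  motion must be recovered; the bounds encode that prior and shrink the
  search space. Both are configurable.
* **Optimizer.** A direction-set (Powell) minimizer with Brent line
  searches, written in-package since no installed library provides one.
  Optimization runs translation-first, then all six parameters — the
  translation valley is wide and nearly quadratic, and seeding the joint
  search from its bottom avoids rotation-translation cross-talk.
  Bounds are enforced by a quadratic penalty outside the box (Powell is
  an unconstrained method; a smooth penalty preserves the line-search
  behaviour), and the returned parameters are clipped to the box.
* **Depth.** Translation along the viewing ray is almost unobservable
  from one view: it changes only the magnification, by roughly 1% per
  7.5 mm at the default geometry. The recovery protocol therefore
  separates the in-plane error (bounded, typically < 0.3 mm median) from
  the along-ray depth error, which is reported but not bounded. Metrics
  that matter clinically are evaluated on the detector plane, where depth
  drops out.

## Topology reconstruction

The 2D segmentation is reduced to *smallest-unit segments*: maximal
branch-free polylines, split at junctions and at mutual crossings. The 3D
tree keeps its anatomical edge structure. For each 3D edge, 2D segments
with mean nearest-point distance below `D_cand = 3 mm` become candidates
— 3 mm matches the bifurcation tolerance used throughout evaluation and
comfortably exceeds the post-rigid residual (rigid error plus projected
cardiac-motion displacement, typically under 2.7 mm at default
magnification).

Candidates are chained into *candi-lines*: connected structures in which
each appended segment touches the chain's free endpoint and exposes its
other end. A candi-line is identified by its segment set, and the
enumeration is a dynamic program over (set, last segment, free end)
states, so its cost is bounded by the number of distinct structures
rather than by orderings within dense endpoint clusters. When a
projected crossing shatters a region into many mutually reachable
fragments and the structure count would still exceed `max_paths`
(default 10,000; the pipeline uses a tighter 400-structure budget per
edge because selection cost is linear in the count), the candidate
threshold for that edge is automatically tightened by 25% and the
enumeration retried — the true segments, being the nearest, survive the
tightening.

**Connection tolerance.** Two segments are connectable when endpoints
come within `conn_tol = 3.5 mm`. This is deliberately larger than the
skeleton quantization scale: segmentation *gaps* are exactly what the
reconstruction must bridge, and with the simulator's default 3 mm gaps a
sub-millimetre tolerance makes the distal piece of a gapped parent edge
unreachable, which then cascades into the loss of every descendant
candi-line during pruning. Sizing the tolerance just above the expected
gap length restores the intended behaviour; it is configurable for data
with different gap statistics.

Pruning then walks the 3D tree from the root outward: a child edge's
candi-line survives only if one of its endpoints comes within the
connection tolerance of some surviving candi-line of the parent edge
(root candi-lines always survive). Because the 3D tree is seamlessly
connected, 2D hypotheses that cannot attach to their parent are
artefacts. The operation is idempotent.

## Point matching and similarity selection

Matching couples proximity with direction. For projected 3D point $i$
and candidate 2D point $u$,

$$ c(i, u) = \frac{1}{2n+1} \sum_{k=-n}^{n} d_\perp(u,\,
   \ell_{i+k}) \; + \; \lVert u - p_i \rVert, $$

where $\ell_{i+k}$ is the tangent line at window point $i+k$ (total
least-squares fit over a symmetric window, anchored at the projected 3D
point, represented by a direction vector so vertical tangents stay
finite) and $d_\perp$ is the exact point-to-line distance. The window
(default $n = 3$) smooths single-point tangent noise; the tangent term
rejects decoys that are marginally closer but cross the vessel at an
angle. Matches with Euclidean distance beyond `Max_dist = 5 mm`
(comfortably above the residual nonrigid displacement the matcher must
tolerate) are flagged invalid and exert no force later. Both term
weights are configurable; setting the line weight to zero recovers plain
nearest-neighbour matching, which the tests exploit as an oracle.

Each candi-line is then scored

$$ SM = \alpha\,D^\theta + \beta\,\bar d_2 + \gamma\,D^{Th} +
   \delta\,D^L $$

with defaults $\alpha=0.4$, $\beta=0.7$, $\gamma=0.25$, $\delta=0.15$
(simulation-calibrated values): $D^\theta$ is the mean per-pair
point-to-tangent distance normalized by the pair's matching distance
(floored at 0.1 mm so nearly coincident pairs cannot blow the ratio up);
$\bar d_2$ the mean matched Euclidean distance; $D^{Th}$ the RMS
difference between projected 3D diameter (2 × radius × local cone-beam
magnification) and the 2D thickness from the distance transform — RMS
rather than mean-square so the term carries mm units like its neighbours
(the mean-square form is available via a flag); and $D^L$ the relative
length mismatch, which is what distinguishes a half-covering fragment
from the full structure when both sit at the same perpendicular offset.
The minimizer wins; ties break by smaller $\bar d_2$, then input order.

## Nonrigid deformation

The selected candi-lines drive a snake-type energy minimization over the
3D points:

$$ E = \sum_i \mu\,E_{cont}(v_i) + \tau\,E_{curv}(v_i) +
   \varphi\,E_{image}(v_i), \qquad \mu = 0.5,\; \tau = 0.4,\;
   \varphi = 0.6 . $$

* $E_{cont}(v_i) = (\bar d - \lVert v_i - v_{i-1}\rVert)^2$ with
  $\bar d$ the mean spacing of the *initial* centerline, frozen. This is
  the classic continuity term that keeps sampling uniform; a plain
  squared-segment-length form would collapse the curve toward zero
  spacing rather than maintain it, contradicting its stated purpose.
* $E_{curv}(v_i) = \lVert v_{i-1} - 2v_i + v_{i+1}\rVert^2$, the
  finite-difference Laplacian with unit parameter spacing (the
  centerline is sampled near-uniformly, and $\bar d$ is held fixed by the
  continuity term).
* $E_{image}(v_i) = H(v_i)\, d(v_i, \mathrm{ray}(\dot u_i))^2$: the
  matched 2D point $\dot u_i$ lives on the detector while $v_i$ is 3D,
  so the residual is taken to the back-projected source ray — the unique
  reading that deforms in 3D while leaving the unobservable depth
  unconstrained. (Projecting $v_i$ and comparing on the detector would
  couple the update to the projection Jacobian and still leave depth
  free; the ray form is the same constraint expressed directly in 3D.)

Minimization is plain gradient descent with analytic gradients (verified
against central differences to 1e-5), step 0.05, up to 500 iterations,
relative tolerance 1e-6. Correspondences are refreshed every 10
iterations and held fixed in between, so the objective is well defined
and provably non-increasing between refreshes for small steps (asserted
in the tests at step 1e-4). If the energy rises five iterations in a
row the step is halved, at most five times. Points shared by several
branches — bifurcations — receive the summed gradient of all incident
branches and move as one, so junctions never tear. Descent is global
over all points rather than per-point greedy; greedy coordinate updates
converge to the same fixed points on these energies but make the
monotonicity bookkeeping murkier.

## The simulator

`make_case()` fabricates the full study setting with exact ground truth:

* **Trees**: binary-branching, seven branches by default, 22–40 mm per
  branch, sinusoidally bent (8% of branch length), root radius 2.5 mm
  tapering by 0.8 per generation — coronary-scaled values that fill
  roughly 80 mm of a 143 mm field of view.
* **Geometry**: 512 × 512 detector at 0.279 mm pixel spacing (the
  midpoint of common angiographic imager spacings), SID 1000 mm /
  SOD 750 mm, default gantry angles −29.3° / −18.7°.
* **Ground-truth motion**: a rigid offset drawn uniformly within 0.8 of
  the search bounds, plus a smooth displacement field — a sum of three
  low-frequency sinusoidal modes normalized to a 2 mm maximum. A real
  cardiac motion model would be periodic and organ-constrained; any
  smooth bounded field exercises the same machinery and admits exact
  per-point error oracles, which is the point of simulation.
* **Corruption**: acting on the *vector* centerlines (so ground-truth
  labels stay exact; the raster is derived afterwards): Poisson-placed
  3 mm gaps (rate 0.2 per edge), short false branches leaving true
  vessels at 35–90° (rate 0.2 per edge), and optionally an overlaid
  branch copy forcing a crossing.

What the simulator does **not** emulate: photorealistic radiographs
(Hounsfield blending), contrast propagation, cardiac periodicity,
correlated segmentation noise, or catheters with vessel-like geometry.
Passing the seeded protocols therefore demonstrates that the algorithms
are implemented correctly and behave as designed under controlled
corruption — not that clinical-grade accuracy would be reached on real
angiograms, where segmentation quality dominates.

## Validation protocols and problem sizes

Three seeded protocols (exported, and re-run from scratch by
`scripts/acceptance.R`) quantify the chain, at sizes chosen to give
stable medians while keeping a full validation run within a few minutes
on one core:

1. **Rigid recovery** — 20 clean cases, offsets within 0.8 × bounds:
   median in-plane error, rotation geodesic error, final residual.
2. **Graph robustness** — 40 corrupted cases, ground-truth alignment:
   survival of the ground-truth candi-line through candidates + pruning,
   and pure-selection rate under the similarity score.
3. **Nonrigid recovery** — 20 corrupted cases with the 2 mm field,
   ground-truth rigid alignment (isolating the deformation machinery
   from registration failure modes, which protocol 1 measures): pre/post
   projected residuals and marker ADD on the detector plane and in 3D.

Markers are evaluated on the detector plane as the primary ADD because
that is where marker positions are observable; the 3D ADD, which only a
simulation can measure, is reported alongside and absorbs the along-ray
depth ambiguity.

## Degenerate inputs and numerical details

Centerlines must have ≥ 2 distinct points and strictly positive radii;
zero-length curves error on resampling. Tangents at curve ends use
clamped windows; a window of identical points errors. Vertical tangents
are finite in direction-vector form. The gradient-term normalization
floor (0.1 mm), the BCE clipping constant (1e-7), the shape-loss
smoothing (1e-7) and the endpoint-matching tolerance of tree edges
(1e-6 mm) are all fixed constants, not tunables. Segmentation masks are
thinned with Guo–Hall rather than Zhang–Suen: the latter deletes
two-pixel diagonal strokes entirely, and projected vessels are full of
them. The chamfer map is the exact Euclidean distance transform; the
integer 3-4 chamfer approximation it replaces is strictly less accurate
and no cheaper here.

## Known limitations

Single-view registration cannot observe depth; along-ray errors survive
the whole chain by construction. Candi-line selection is per 3D edge
with no cross-edge joint optimization, so two 3D edges may claim the
same 2D segment. The matcher allows many-to-one matches (a consequence
of projective foreshortening) and performs no global assignment. The 2D
graph handles simple crossings but does not attempt loop topology beyond
chains. Rigid registration uses a single deterministic start by default;
an 8-start translation grid is available for stress cases and costs
proportionally more time.
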