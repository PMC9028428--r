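# cororeg — 2D/3D coronary-artery centerline registration

During percutaneous coronary intervention the interventionalist works from
2D X-ray angiograms (XA), which show contrast-filled vessels in real time
but lose all depth information and suffer from background clutter, vessel
overlap and segmentation gaps. A 3D centerline tree of the same patient's
coronaries, extracted beforehand from CT angiography (CTA), carries the
missing structure. `cororeg` aligns the two: it projects the 3D tree
through the C-arm acquisition geometry, registers it rigidly to the 2D
centerlines, reconstructs the corrupted 2D topology against the clean 3D
topology, and then deforms the 3D centerline nonrigidly until its
projection meets the angiogram — giving a depth-annotated overlay of the
3D vessels on the live 2D image.

The package is aimed at researchers in vascular image analysis who need a
tested, scriptable reference implementation of this registration chain,
together with a seeded synthetic vascular-tree simulator that provides
exact ground truth for every stage.

## The method

Given a 3D tree `T3D = (V, E, r)` whose edges carry centerlines
`f3D: E -> R^(3n)` with per-point radius, and a 2D centerline set
segmented from one XA frame:

1. **C-arm projection.** The five DICOM quantities
   (PositionerPrimaryAngle, PositionerSecondaryAngle, ImagerPixelSpacing,
   DistanceSourceToDetector = SID, DistanceSourceToPatient = SOD) define a
   cone-beam projection `(u, v) = SID/(SOD + depth) * (x, y)` after the
   gantry rotation; magnification at the isocenter is `SID/SOD`.
2. **Bounded rigid registration.** The six parameters
   `(Tx, Ty, Tz, Rx, Ry, Rz)`, constrained by `|Ti| <= d_max`,
   `|Ri| <= th_R`, minimize the mean Euclidean distance of the projected
   3D centerline to the 2D centerline, via a derivative-free direction-set
   (Powell) optimizer run translation-first, then all six parameters.
3. **Graph reconstruction.** The 2D segmentation is decomposed into
   smallest-unit segments (split at junctions and crossings). For each 3D
   edge, all 2D segments within a candidate distance `D_cand` are
   collected and every connectable chain of them — a *candi-line* — is
   enumerated; chains that cannot touch any surviving candi-line of the
   3D parent edge are pruned.
4. **Point matching.** Each projected 3D point is matched to the
   candi-line point minimizing a windowed cost: the mean exact
   point-to-tangent-line distance over `2n + 1` neighbouring tangents plus
   the Euclidean distance `d2`. Matches farther than `Max_dist` are
   invalidated (`H = 0`).
5. **Similarity selection.** Each candi-line is scored
   `SM = alpha*D_theta + beta*d2 + gamma*D_Th + delta*D_L`
   (gradient, distance, thickness, relative-length terms; defaults
   0.4 / 0.7 / 0.25 / 0.15) and the minimizer is selected.
6. **Nonrigid deformation.** The 3D points descend the snake energy
   `E = sum_i mu*E_cont + tau*E_curv + phi*E_image` (defaults
   0.5 / 0.4 / 0.6), where `E_cont = (dbar - |v_i - v_{i-1}|)^2` keeps the
   sampling spacing, `E_curv = |v_{i-1} - 2v_i + v_{i+1}|^2` keeps the
   shape smooth, and `E_image = H(v_i) * dist(v_i, ray(u_i))^2` pulls each
   matched point onto the X-ray source ray through its 2D match, leaving
   the unobservable depth along the ray unconstrained.
7. **Evaluation.** Marker ADD (`mean ||p_i - q_i||` over marker pairs),
   point and bifurcation precision/recall/F1 at 1 mm / 3 mm tolerances,
   and projected centerline residuals.

## Worked example

```r
library(cororeg)

case <- make_case(seed = 3)         # synthetic CTA tree + corrupted XA projection
case
#> <simulation_case seed 3> 7 3D edges, 9 2D segments, rigid |T| = 15.1 mm, field <= 2.0 mm

res <- run_pipeline(case, pipeline_config(run_rigid = FALSE), verbose = TRUE)
#> rigid: residual 0.718 mm
#> selection: 7/7 edges matched
#> nonrigid: 2D 0.708 -> 0.068 mm, ADD 0.768 mm
round(unlist(res$report[c("pre_2d_mm", "post_2d_mm", "add_2d_mm", "add_3d_mm")]), 3)
#>  pre_2d_mm post_2d_mm  add_2d_mm  add_3d_mm
#>      0.708      0.068      0.666      0.768
```

The projected residual of the aligned-but-undeformed tree (0.708 mm, the
trace of the simulated 2 mm cardiac-motion field) drops to 0.068 mm after
energy minimization — about a quarter of a detector pixel — and the
ten-marker average distance difference settles around 0.77 mm in 3D
(0.67 mm measured on the detector plane, where the unobservable
along-ray depth component vanishes).

A command-line driver for shell use is installed under
`inst/cli/cororeg.R` with verbs `simulate`, `rigid`, `run`, `experiment`:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/cororeg.R", package = "cororeg"))') \
    simulate --seed 7 --out case7/
```

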