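---
title: "condylefit: model, methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{condylefit: model, methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the kinematic
model and its assumptions, the parameters that matter, what the synthetic
generator does and does not emulate, the numerical choices, and the known
limitations.  It states no empirical result that the test suite does not
itself compute.

## 1. The kinematic model

Each fly leg is a serial chain of rigid segments (coxa, trochanter, femur,
tibia, tarsus) connected at the tracked joints ThCx, CxTr, TrFe, FeTi,
TiTar, ending at the tarsus tip (Tar).  Every joint is modelled as a
ball-and-socket with up to three rotational DOFs:

* the **yaw** axis is anatomical: the unit vector between the joint's two
  articulation condyles, passing through the joint center.  Condyle
  positions come from a µCT-derived landmark file (or from the synthetic
  generator);
* the **roll** axis lies along the segment the joint controls (joint
  center to the next joint center; to the tarsus tip for TiTar), so roll
  is a longitudinal rotation;
* the **pitch** axis is `yaw × roll`, completing the spherical joint.

TiTar has no roll DOF (a monolithic tarsus has no meaningful longitudinal
rotation), giving 14 DOFs per chain.  Each DOF is independently *mobile*
or *fixed*; the **reference configuration** mobilizes ThCx-yaw/pitch/roll,
CxTr-yaw, FeTi-yaw and TiTar-yaw/pitch (7 DOFs), and the **final front-leg
configuration** adds TrFe-roll.  Mobility is fully config-driven
(`default_dof_config()`, `build_chain(dof_config = ...)`), so any
ablation/augmentation configuration is expressible.

### Assumptions

* Segments are rigid; all compliance of the five real tarsomeres is
  absorbed into a single tarsus segment with two TiTar DOFs and a
  per-frame adjustable length.
* Only the yaw axes are anatomically anchored; pitch and roll placements
  are the stated simplifications, and joints have no translational DOFs.
* The body is rigid during a sequence: one static body coordinate system
  per fly (origin at the scutellum apex ThAp, x anterior, y toward the
  left wing hinge, z dorsal).

### Initial-posture straightening

A landmark file reflects the (bent) scanning posture.  Starting from the
raw chain, the yaw angle of every joint distal to the ThCx is adjusted so
consecutive segments become collinear, and the rotated condyle positions
are stored as the new reference: thereafter *zero angles denote the
extended posture*.  The extension angle is found in closed form (the inner
segment angle about a yaw axis is sinusoidal in the rotation angle, so its
maximizer is an `atan2`), not by numerical search.  Pitch and roll are
left untouched — adjusting them would destroy the anatomical relation
between segments and axes.  If a yaw axis is parallel to both adjoining
segments the joint cannot be extended and an error names it.  The ThCx has
no proximal segment and is not straightened.

### Denavit–Hartenberg construction

Each DOF's local frame takes z = rotational axis.  The x axis and origin
depend on the relation to the previous axis: (a) skew axes — x along the
common normal, origin at its foot on the DOF's own axis; (b) intersecting
axes — x along the normal of the plane they span, origin at the
intersection; (c) parallel axes — x along the common normal through the
DOF's joint center, which is also the origin.  The first frame (no
predecessor) takes x = z × (body x axis) with origin at the ThCx; the
end-effector frame reuses the last TiTar axis with origin at the tarsus
tip (a case-(c) relation, so the D-H transform to it is exact even when
the tip is laterally offset).

θ and α are signed angles between consecutive x axes (about z) and z axes
(about the new x).  The link offsets are taken from the common-normal
feet: `d` is the signed offset along zₙ from the frame origin to the foot,
`r` the signed length of the common normal.  When consecutive axes
intersect, the foot *is* the intersection point: `r = 0`, while `d` keeps
the (generally nonzero) offset along zₙ — setting `d = 0` there would
collapse every segment whose endpoints host intersecting axes (e.g., the
entire coxa).  `build_dh()` verifies after construction that composing the
transforms reproduces every local frame to 1e-9 (scale-aware) and that
each inter-origin offset decomposes into the d/r plane; a failure is a
hard error, never a silent fix-up.  Independently of that internal check,
the test suite compares the D-H forward kinematics against a sequential
Rodrigues axis-angle oracle that never touches the D-H code.

Case classification tolerances are scale-aware: axes are *parallel* when
the cross product of their directions is below 1e-9, *intersecting* when
the minimal inter-axis distance is below 1e-9 × (summed segment length).

### Keypoint attachment and the variable tarsus

Each keypoint is rigidly attached to the first frame of its distal joint
(CxTr → frame 4, …, Tar → the end frame), stored in local coordinates at
build time, so zero angles reproduce the reference posture exactly.  The
tarsus tip is stored as (TiTar center + L·û) in end-frame coordinates with
û the reference tarsus direction; `set_tarsus_length()` only changes L, so
the tip moves along the tarsus axis and nothing proximal is affected.

### Scaling to an individual

`scale_to_fly()` maps the model's reference triangle (leg ThCx, right and
left wing hinge) onto the fly's by a similarity transform (Kabsch rotation
+ uniform scale; an affine map fitted to three points would be
underdetermined out of plane and could shear the axes), then rescales each
segment except the tarsus to its median tracked length by translating the
distal landmark cluster along the segment, preserving all axis directions.

### The orthogonalized variant

`orthogonalize()` replaces every yaw axis by the signed body axis with the
largest |cosine| (ties broken preferring y, then z, then x — yaw axes are
predominantly mediolateral, so y is the natural first candidate), writes
condyles at center ± axis, and linearizes the leg so segments point
straight down from the ThCx with their original lengths.  The
orthogonalized angle-bound table is installed automatically.  On a
synthetic fly with zero axis obliquity the variant is exactly the original
chain; the acceptance suite asserts FK identity at 1e-9.

## 2. Inverse kinematics

`fit_frame()` minimizes Σₖ (wₖ·dₖ)² over the mobile-DOF angles, where dₖ
are the model-to-target distances of CxTr, TrFe, FeTi, TiTar, Tar and the
weights multiply the *distances before squaring*.  Default weights are 1,
with (TrFe, FeTi, TiTar) = (1.5, 2.0, 1.5) for front and (1.25, 1.5, 1.25)
for middle legs.  Box bounds (per-DOF min/max in degrees, tabulated for
right legs; yaw/roll bounds sign-flipped for left legs) exclude unnatural
postures.

**Solver.** The box-bounded quasi-Newton PORT solver (`stats::nlminb`)
with numerical gradients.  The termination contract is: relative
cost-change tolerance 1e-3, iteration cap 100 × (number of mobile DOFs).
The historical contract also names 1e-3 step and gradient criteria for a
trust-region solver; PORT's relative-step test has different semantics (it
fires on the step relative to the iterate, not a trust-region bound), and
setting it to 1e-3 was measured to leave ~1e-3 rad of angle error — about
5 µm of keypoint error on a 2 mm leg, an order of magnitude above what the
cost criterion alone achieves (sub-nanometre on zero-residual problems,
because near such an optimum the relative cost reduction per step stays
large until convergence).  The step and gradient criteria therefore remain
at the solver's tighter defaults; `ik_control(tol=)` exposes the cost
tolerance.  PORT's "false convergence" return (it cannot *verify* a tiny
predicted reduction, the normal outcome when started at an exact optimum)
is reported as converged.

**Initialization.** For the first frame, each joint's mobile DOFs are
optimized in isolation, proximal to distal, against the keypoint that
joint most directly moves (ThCx → CxTr, CxTr → TrFe, TrFe → FeTi, FeTi →
TiTar, TiTar → Tar); other joints hold their current values.  The contract
leaves the per-joint target open; the distal keypoint of the controlled
segment is the natural reading because it is the only tracked point whose
position the joint's DOFs change at first order when the rest of the chain
is held.  Subsequent frames warm-start from the previous solution, carried
across invalid (NaN) frames; the tarsus length is set per frame from the
tracked TiTar–Tar distance before fitting.

**Redundancy.** No uniqueness claim is made on angles.  Acceptance is
stated on reconstructed keypoint positions; angle recovery is asserted
only for the reference configuration on interior postures, where the
7-DOF/15-coordinate problem is locally non-redundant.

**Monotone configurations.** Enlarging the mobile-DOF set cannot increase
the *global* minimum, but a local solver can violate the inequality by
converging to a worse basin.  The acceptance protocol therefore fits each
configuration multi-started from the solutions of all its strict subsets
(embedding a subset solution with the extra DOFs at zero reproduces the
subset's converged cost exactly, and the solver never increases its start
value), which makes monotonicity a property of the protocol.  This mirrors
how nested model comparisons should be run in practice.

## 3. Gait phases on the spherical treadmill

During stance the tarsus-tip distance to the treadmill-ball center equals
the ball radius (3 mm); during swing it is larger.  `estimate_ball_center`
minimizes Σ wᵢ(‖pᵢ−c‖ − r)² with wᵢ = 100 for tips *inside* the sphere —
the asymmetric penalty encodes that tips cannot physically be inside the
ball — using BFGS with an analytic gradient, multi-started from the tip
centroid and the centroid − r·ẑ.  The penalized fit coincides with the
plain least-squares sphere fit whenever no point is inside the fitted
sphere at the optimum.  Collinear tip clouds are rejected as
unidentifiable.

`detect_phases` labels stance iff distance ≤ threshold, with the threshold
per leg and user-set (the experimental workflow sets it manually per leg
and fly); the synthetic default is radius + 0.05 mm, an explicit margin
well above tracking noise and below the generator's swing clearance.
Touchdowns are swing→stance transitions, lift-offs the reverse; by
construction lift-off and touchdown counts differ by at most one.  An
optional debounce (minimum phase duration, default 3 frames at 400 Hz)
mimics the manual correction of single-frame misclassifications; it is off
by default because noiseless synthetic data does not glitch.

`normalize_phase` resamples every *complete* swing and stance interval
onto 100 samples of normalized time 0→1 by linear interpolation;
incomplete boundary intervals are dropped and intervals shorter than two
frames are dropped with a warning.

## 4. Analytics

* **Model error**: summed Euclidean distance of the five keypoints, in µm;
  positions can be converted to global coordinates first (rigid, so
  distances are unchanged — the conversion exists for unit consistency
  with global-coordinate outputs).  Frames with missing keypoints are
  excluded and flagged.
* **Simpson AUC**: composite Simpson on the uniform 100-point grid.  99
  intervals are odd, so the composite rule covers the first 96 and a 3/8
  rule the last three — both exact for cubics, and the quadrature is a
  fixed linear functional (linearity is asserted at 1e-12).
* **Angle post-processing**: left-leg yaw and roll signs are inverted
  first (pitch exempt), then 180° is added to CxTr-yaw and FeTi-yaw so 0°
  reads fully flexed and 180° fully extended.  Inverting before shifting
  keeps the flexion convention identical on both sides.
* **ROM**: max − min per DOF, per group (fly) and pooled mean ± SD across
  groups.
* **Femur–tibia plane rotation**: normal = femur × tibia, sign kept
  continuous across frames (flip when the dot with the previous normal is
  negative) to avoid spurious 180° jumps; the range is the angle between
  the first and last normals of the interval.
* **DOF ablation**: frame 1 posed with all fitted angles; later frames
  update only the chosen subset, the rest frozen at frame-1 values; the
  plane-rotation range of the re-posed trajectory is compared to the full
  model's.  Updating the full set reproduces the full trajectory
  identically.
* **Pooling**: time-course aggregation defaults to the pooled mean of
  per-fly means (the AUC integrates the pooled mean time course);
  per-step pooling is available by passing the per-step matrices directly.

## 5. The synthetic fly

`make_synthetic_fly()` emulates an adult *Drosophila* at the
experimental scale: leg spans around 2 mm, wing hinges anterior and
slightly ventral of the ThAp, condyle separations of 60 µm, and a
per-joint **obliquity** pattern that tilts each condyle axis away from the
mediolateral body axis (default 15°; 0° reproduces the orthogonalized
geometry exactly, which the acceptance suite exploits).  Reference legs
hang straight down, so the zero pose is already extended.  The seed only
jitters segment lengths (±2 %) before mirroring, keeping bilateral
symmetry exact.  The hind femur–tibia condyles are labelled so that the
positive yaw range admitted by the angle constraints flexes the tibia
toward the ball, as in the animal.

`simulate_walking()` drives the mobile DOFs with smooth cosine waveforms
phase-locked to each leg's step cycle (tripod groups R1/L2/R3 and L1/R2/L3
in antiphase; stance is the first half of the cycle at duty 0.5, cadence
8 Hz, 400 Hz frames).  Per-leg-pair base postures — front legs splayed
~30° forward, hind ~35° backward, all pairs abducted, tarsi tilted toward
the ball — were chosen once so that all six tips are kinematically
compatible with a single 3 mm ball, and are sign-mirrored for left legs.
The ball is placed on the body midline under the stance-tip centroid with
its depth fitted by least squares, then lowered until every TiTar clears
radius + swing-gap + 0.06 mm.  Stance frames pin the tip *exactly* onto
the sphere by solving the tarsus length (line–sphere intersection, root
nearest the nominal length — emulating tarsus bending); swing frames
follow a clearance profile radius + 0.08 mm + 0.25 mm·sin(πτ), clamped
into the per-frame reachable band of the tarsus, so the swing distance
always exceeds radius + 0.08 mm.  This construction *guarantees* exact
label recovery at the default threshold on noiseless data — a green phase
test therefore validates the detector's thresholding and event logic, not
its robustness to marginal contacts.  Gaussian keypoint noise (µm) is
added on top of the retained ground truth.

What the generator does **not** emulate: occlusions and tracking outliers,
soft-tissue and body-pitch motion, correlated (non-isotropic) tracking
error, ball rotation and slippage, real inter-leg coordination variability
and speed modulation, and genuinely articulated tarsomeres.  Green tests
on synthetic data establish algorithmic correctness at the stated
tolerances, not field performance on deposited recordings.

`make_camera_rig()` arranges six pinhole cameras with mild radial and
tangential distortion at ~50 mm around the fly (≈5.9 µm/px), and
`render_observations()` projects keypoints with optional pixel noise (no
occlusion model).

## 6. Numerical choices and degenerate inputs

* Units: mm and radians internally; degrees and µm at every interface.
* `undistort`: fixed-point iteration in normalized coordinates, ≤50
  iterations, tolerance 1e-10; non-convergence is an error with the
  residual magnitude.  The inversion identity is asserted for normalized
  radii ≤ 0.5.
* Triangulation requires ≥2 valid observations from *distinct* cameras;
  rank-deficient DLT systems and points at infinity are named errors;
  out-of-image observations only warn (they can be legitimate with
  partial-view rigs).
* Angle sanity bound: |angle| ≤ 360° in FK (bounds enforcement is the
  solver's job, not FK's).
* The body-frame construction's two typeset variants (halved and unhalved
  reflection midpoints) are positive multiples of each other and identical
  after normalization, so no variant switch exists.
* Condyle labelling fixes the yaw-axis sign; yaw-angle signs therefore
  depend on the landmark file's labelling convention.  Left legs may be
  delivered directly or mirrored from right legs
  (`mirror_leg_landmarks()`), and FK mirror symmetry under yaw/roll sign
  inversion is asserted at 1e-9.
* With no TiTar-roll DOF, the end-effector frame duplicates the last TiTar
  frame's axis at the tarsus tip; its x axis follows the case-(c) rule so
  the transform chain stays exact.

## 7. Known limitations

* Pitch and roll axes are modelling conventions, not anatomy; fitted roll
  ROMs in particular inherit that convention.
* The monotone-configuration guarantee is a property of the nested
  multi-start protocol; single-start fits of a larger configuration can
  land in worse local minima.
* The tarsus length is fitted per frame from the tracked TiTar–Tar
  distance, so tarsus-tip tracking error leaks directly into the model's
  effective tarsus length.
* No temporal smoothing across frames: warm starts propagate information,
  but each frame's fit is independent, and angle time courses can carry
  frame-to-frame tracking noise.
* Statistical hypothesis testing (permutation tests, t-tests) is out of
  scope; the analytics report descriptives only.
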