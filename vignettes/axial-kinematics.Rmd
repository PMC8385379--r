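---
title: "Measuring axial kinematics of fish feeding strikes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring axial kinematics of fish feeding strikes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vertkin)
```

## The measurement problem

During suction feeding, many fishes rotate the head dorsally to enlarge
the mouth cavity. That cranial elevation is the summed output of small
rotations distributed along the post-cranial column: the craniovertebral
joint plus a series of intervertebral joints. Resolving *where* the
rotation happens requires tracking each bone as an independent rigid body
— in practice with biplanar videoradiography of implanted radio-opaque
markers (XROMM) — and expressing the motion of each bone relative to its
caudal neighbour in anatomically meaningful axes.

`vertkin` implements that analysis chain, and pairs it with a forward
model of a vertebral chain so that every stage can be checked against
known ground truth. This vignette documents the model, the conventions,
and the numerical choices.

## Rigid-body pose from markers

Each bone carries ≥3 markers whose bone-fixed (CT-frame) coordinates are
known. For a frame with observed marker positions $q_i$ and reference
positions $p_i$, `fit_rigid_pose()` solves the orthogonal Procrustes
problem

$$\min_{R \in SO(3),\,t} \sum_i \lVert R p_i + t - q_i \rVert^2$$

by the SVD construction: centre both sets, form $H = \tilde P^\top \tilde
Q$, take $H = U \Sigma V^\top$, and set $R = V\,\mathrm{diag}(1, 1, d)\,
U^\top$ with $d = \mathrm{sign}(\det(VU^\top))$ so $R$ is a proper
rotation even for reflective noise configurations; $t$ follows from the
centroids. The per-frame RMSE is reported, and the unit tests verify the
solution against a brute-force optimizer over Euler angles on random
noisy problems.

Frames in which a bone retains fewer than 3 visible markers become *gaps*
(`NA` poses) rather than extrapolations; gaps propagate through
filtering, joint traces, and the batch pipeline.

Marker quality is summarized by `tracking_precision()`: the mean over
marker pairs of the standard deviation over frames of inter-marker
distance. For independent per-axis Gaussian noise of s.d. $\sigma$ this
converges to $\sigma\sqrt{2}$, which the tests confirm; at the bench
scale of $\sigma \approx 0.03$–0.05 mm precision stays well below 0.1 mm.

## Coordinate systems and sign conventions

Anatomical coordinate systems (`build_acs`) use **+x cranial, +y dorsal,
+z left** (right-handed). A joint coordinate system (`jcs`) pairs the ACS
on the proximal bone with the ACS on the distal bone; both coincide at
the reference (CT) pose, so all six degrees of freedom read zero there by
construction.

`jcs_decompose()` forms the relative transform $T = W_p^{-1} W_d$ and
decomposes its rotation with **intrinsic z–y–x Euler angles**,
$R = R_z(\gamma) R_y(\beta) R_x(\alpha)$:

$$\beta = \operatorname{asin}(-R_{31}), \quad
  \gamma = \operatorname{atan2}(R_{21}, R_{11}), \quad
  \alpha = \operatorname{atan2}(R_{32}, R_{33}).$$

With the axis convention above, the z angle is rotation in the sagittal
plane — exactly the dorsoventral bending of interest — so it is extracted
first and is unpolluted by the (small) y and x rotations. Near gimbal
lock ($|\beta| \to 90^\circ$) the z and x angles become degenerate; the
decomposition pins $\alpha = 0$ there and every row carries a `gimbal`
flag raised within 0.5° of the singularity. Feeding-strike sagittal
rotations live far from this band.

Two sign details matter:

- **Intervertebral joints** place the proximal ACS on the cranial bone
  and negate the raw z angle (`sign_flip_z = TRUE`), so *dorsal*
  (extension) rotation is positive at every joint regardless of which
  neighbour moved.
- **Cranial elevation** (`elevation_trace`) is the z rotation of the
  neurocranium relative to a *body plane* fitted to markers in the caudal
  half of the fish, so whole-body pitching does not masquerade as neck
  motion. With this convention, for planar strikes the elevation equals
  the sum of the individual joint z rotations — an additivity property the
  acceptance tests verify to 1e-6° on 1-, 2-, and 12-joint programs.

## Filtering

`lowpass_filter_poses()` applies a zero-phase Butterworth (order 2,
forward and backward, so the effective order doubles and phase cancels)
to the three translations and to the rotation expressed as a unit
quaternion with sign continuity enforced; filtered quaternions are
renormalized and the rotation re-orthonormalized by SVD. Filtering
rotations through quaternions avoids both Euler wrapping artifacts and
the non-orthogonality that comes from filtering matrix entries directly.

Edge handling matters because baselines and peaks are read near recording
edges. The implementation reflects the signal symmetrically (even
reflection) over 15 samples at each end before filtering. The common
alternative — odd reflection about the endpoint value, as in MATLAB/scipy
`filtfilt` — pins the endpoint exactly, which *preserves* endpoint noise
rather than smoothing it; with even reflection the endpoints are smoothed
and unbiased when the signal is near-flat there, which holds for the
pre-strike rest and post-strike hold. The filter recursion starts from
zero state, so the mean is removed before filtering and restored after:
constant signals pass through exactly and the operator remains linear,
which in turn makes filtering commute with rigid re-expression of the
world frame (a property under test).

Cutoff choice is supported by the closed-form zero-phase gain

$$G(f) = \frac{1}{1 + \left(\tan(\pi f / f_s) / \tan(\pi f_c / f_s)\right)^{2n}},$$

(`butter_zero_phase_gain`), which accounts for bilinear-transform
frequency warping; the tests verify measured sinusoid attenuation against
it. The presets use 60 Hz at 500 fps (trout-like) and 100 Hz at 1000 fps
(frogfish-like): strike content sits below ~30 Hz, marker noise is
broadband.

## Strike analysis

`analyze_strike()` chains the stages: fit pose sequences from markers
(optionally filter), compute the elevation trace, detect onset (first
frame exceeding 5% of peak and holding for 5 frames), apply the inclusion
rule (peak ≥ 5°, boundary-inclusive), decompose every joint, and report:

- **Joint deltas at peak** — each joint's z rotation at the elevation
  peak minus its value at the *first frame* of the recording. The first
  frame, not the detected onset, is the baseline: recordings begin at
  rest, and a rest-referenced delta is insensitive to onset-detector
  jitter.
- **Curvature profile** — dorsoventral displacement of a landmark per
  bone (craniovertebral pivot for the neurocranium, centrum centroid for
  vertebrae), expressed in the ACS of the caudal-most vertebra and
  baseline-subtracted. `per_centrum_translation()` takes caudal-neighbour
  first differences. Note a geometric subtlety: when a single joint
  rotates, every bone cranial to it moves as one rigid unit, so the first
  differences step *uniformly* at all positions cranial of the joint and
  vanish caudal of it — the profile localizes the caudal *boundary* of
  bending, not a single bone.
- **Cohort statistics** — `cohort_summary()` (mean, s.e., max, n) and
  `mean_trace()`, which aligns strikes on onset (or peak) and averages
  only where at least two strikes overlap.

## The synthetic chain generator

`chain_model()` builds a neurocranium plus $N$ vertebrae laid along +x,
articulated by single-axis (sagittal) rotational joints at the
intervertebral interfaces, with pivots at the cranial endplate of the
caudal partner. Forward kinematics anchor the caudal-most vertebra;
optional non-zero reference angles give a resting curvature (the
frogfish-like preset holds a resting S-curve). Each bone carries four
markers placed like real implants — centrum ends plus neural-arch and
neural-spine points — because marker-constellation geometry governs how
marker noise maps to orientation noise; a compact constellation inflates
angular error roughly in proportion to its inverse radius. Four
"intramuscular" markers over the caudal half define the body plane.

`joint_program()` drives selected joints with a smoothstep rise to
programmed amplitudes (zero velocity at both ends, so no spectral
leakage from kinks); `simulate_strike()` renders marker trajectories with
Gaussian noise and optional dropout and returns the ground-truth poses
and joint angles alongside. `strike_cohort()` adds per-strike amplitude
jitter for realistic between-strike variance. Presets:

- `"frogfish"`: 18 vertebrae graded 12→6 mm, 18 mm neurocranium, resting
  S-curve, stationary body, 1000 fps. The preset program concentrates
  rotation cranially (18° and 24° at the two cranial-most joints, small
  rotations elsewhere, ~41° summed peak).
- `"trout"`: 25 uniform 4 mm vertebrae, 10 mm neurocranium, 50 mm/s
  swimming lead-in, 500 fps. The preset program distributes small
  (< 3°) rotations along many joints (~11° summed peak).

**Limits.** Joints are purely rotational and sagittal — no axial
twisting, lateral bending, translation, or tissue compliance; marker
noise is i.i.d. Gaussian, whereas real X-ray reconstruction error is
correlated across frames and markers; bones are rigid and marker
positions exact in the reference, so CT-registration error is not
modelled. The generator is a test instrument for the *analysis* chain,
not a biomechanical model of a fish.

## Numerical choices worth knowing

- Rotation distance in tests uses $2 \operatorname{asin}(\lVert Q - I
  \rVert_F / 2\sqrt 2)$ rather than the trace/acos formula, whose
  derivative is infinite at 0 and floors near 1e-6 degrees in double
  precision.
- Quaternion extraction uses Shepperd's branch selection (largest of
  trace and diagonal entries), stable at all rotation magnitudes
  including ~180°.
- Filtered or averaged rotations are always re-projected to $SO(3)$ by
  SVD before further use; `pose_sequence()` validates orthonormality,
  unit determinant, and the affine last row on construction.
- Typical problem sizes (a few dozen bones × a few thousand frames) run
  in seconds; the implementation favours clarity (per-frame loops, exact
  linear algebra) over vectorized opacity.

## Batch use

`cmd_simulate()`, `cmd_analyze()` and `cmd_validate()` (wrapped by
`inst/cli/vertkin.R`) write cohorts to per-strike CSV directories with a
YAML chain description and checksummed manifest, analyze such a directory
into tidy result tables (elevation traces, joint deltas, curvature
profiles, exclusions, cohort summary), and compare recovered kinematics
against stored truth with a pass/fail report — the same loop used by the
package's own end-to-end tests.
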