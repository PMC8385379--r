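# vertkin

Axial skeleton kinematics for fish feeding strikes, from marker
trajectories to joint rotations.

Many fishes raise the head dorsally during suction feeding. That cranial
elevation is not produced at a single "neck" joint: it is the summed output
of dorsal rotations distributed along the craniovertebral joint and the
anterior intervertebral joints. Measuring where along the column the
rotation happens requires tracking each vertebra as a rigid body — e.g.
with biplanar videoradiography of implanted radio-opaque markers (XROMM) —
and expressing the relative motion of neighbouring bones in anatomical
joint coordinate systems. `vertkin` implements that pipeline end to end,
plus a forward model of a vertebral chain so every stage can be validated
against known ground truth.

## What the package does

- **Rigid-body pose estimation** (`fit_rigid_pose`, `fit_pose_sequence`):
  least-squares fit of a bone's pose from ≥3 tracked markers per frame
  (SVD/Kabsch), with per-frame RMSE and gap handling for frames with too
  few visible markers. `tracking_precision` reports marker quality as the
  s.d. of inter-marker distances.
- **Coordinate systems** (`build_acs`, `jcs`, `jcs_decompose`,
  `joint_trace`): anatomical coordinate systems with +x cranial, +y
  dorsal, +z left; joint coordinate systems whose proximal and distal
  frames coincide at the reference (CT) pose; intrinsic z–y–x Euler
  decomposition so the z angle reads directly as dorsoventral (sagittal)
  rotation, with gimbal-proximity flagging. Intervertebral joints are
  signed so dorsal (extension) rotation is positive.
- **Filtering** (`lowpass_filter_poses`): zero-phase low-pass Butterworth
  applied to translations and sign-continuous unit quaternions, with
  closed-form expected gain (`butter_zero_phase_gain`) for picking
  cutoffs.
- **Strike analysis** (`analyze_strike`, `elevation_trace`,
  `joint_rotation_deltas_at_peak`, `curvature_profile`, `cohort_summary`,
  `mean_trace`): cranial elevation relative to a body plane, onset
  detection, the ≥5° inclusion rule, per-joint rotation changes from the
  strike's first frame to peak elevation, dorsoventral displacement
  profiles along the column, and cohort statistics across strikes.
- **Synthetic chains** (`chain_model`, `build_preset`, `joint_program`,
  `simulate_strike`, `strike_cohort`): a forward-kinematic model of a
  neurocranium + vertebral chain that emits marker trajectories with
  configurable noise and dropout alongside the true poses and joint
  angles. Two presets bracket the biological range: a `"frogfish"`-type
  chain (18 vertebrae, large cranial joint rotations, resting S-curve,
  1000 Hz) and a `"trout"`-type chain (25 vertebrae, small distributed
  rotations, swimming lead-in, 500 Hz).
- **Batch CLI** (`inst/cli/vertkin.R`, or `cmd_simulate` /
  `cmd_analyze` / `cmd_validate` from R): simulate cohorts to CSV + YAML
  on disk, analyze a directory of recordings to tidy result tables with a
  checksummed manifest, and validate recovered kinematics against stored
  truth.

## Worked example

```r
library(vertkin)

chain <- build_preset("frogfish")
chain
#> <chain_model> [frogfish] 19 bones (neurocranium + 18 vertebrae), 18 joints @ 1000 Hz

program <- preset_program(chain)          # cranially concentrated dorsal rotations
strike <- simulate_strike(chain, program, duration_s = 0.05,
                          noise = noise_model(sigma_mm = 0.05), seed = 1)
strike
#> <strike_recording> 'strike1' (frogfish), 51 frames @ 1000 Hz, 19 bones

res <- analyze_strike(strike, filter_cutoff = "chain")  # preset 100 Hz cutoff

attr(res$elevation, "peak_deg")           # peak cranial elevation, deg
#> 41.21
res$included                              # passes the >= 5 deg inclusion rule
#> TRUE
round(res$deltas_deg[1:4], 2)             # joint rotations, strike start -> peak
#> joint_1 joint_2 joint_3 joint_4
#>   18.17   24.19    2.76    2.92

tracking_precision(strike$markers, paste0("neurocranium_m", 1:4))
#> 0.073  # mm, consistent with 0.05 mm per-axis marker noise
```

The two cranial-most joints (craniovertebral and first intervertebral)
carry 18° and 24° of the ~41° peak elevation; the remaining sixteen joints
contribute little — the distributed-to-concentrated pattern the joint
coordinate systems are designed to resolve. With `noise_model(0)` and
`filter_cutoff = NULL` the same pipeline recovers every programmed joint
trace to better than 1e-6 degrees (see `tests/testthat/test-acceptance.R`).

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "vertkin", load_package = "installed")'
```

~860 assertions: closed-form oracles for rotations and filters, a
brute-force optimizer oracle for pose fitting, world-frame invariance
properties, exact noise-free round trips on both presets, and noisy
end-to-end recovery bounds.

## Documentation

The methods vignette (`vignettes/axial-kinematics.Rmd`) documents the
kinematic model, sign conventions, filter design, the synthetic-strike
generator and its limits, and the package's numerical choices.
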