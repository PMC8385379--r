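Package: vertkin
Title: Vertebral Column and Cranial Kinematics from Marker-Based Motion Capture
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for measuring skeletal kinematics of the fish axial
    column from 3D marker trajectories and rigid-body pose sequences, as
    produced by biplanar X-ray motion capture (XROMM). Provides rigid-body
    pose estimation by least-squares superposition, tracking-precision
    statistics, zero-phase Butterworth filtering of pose sequences, joint
    coordinate systems with intrinsic z-y-x Euler decomposition at
    craniovertebral and intervertebral joints, cranial-elevation and
    vertebral-curvature analyses, cohort summaries, and a forward-kinematics
    chain simulator emulating trout-like and frogfish-like feeding strikes
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
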