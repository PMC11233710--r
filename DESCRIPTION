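Package: condylefit
Title: Anatomically Landmarked 3D Kinematic Leg Models for Walking Drosophila
Version: 0.1.0
Authors@R:
    person("condylefit", "developers", email = "condylefit@example.org",
           role = c("aut", "cre"))
Description: Builds per-leg kinematic chains for Drosophila melanogaster in
    which the main (yaw) rotational axis of every joint is derived from the
    positions of its articulation condyles, rather than being placed
    generically perpendicular to the leg segments.  Provides
    Denavit-Hartenberg forward kinematics, box-bounded weighted
    inverse-kinematic fitting of the chains to 3D motion-captured leg
    postures, multi-view triangulation of 2D keypoints with lens-distortion
    correction, swing/stance phase detection on a spherical treadmill,
    range-of-motion and femur-tibia plane-rotation analytics, and a
    synthetic-fly generator so the entire pipeline can be exercised against
    known ground truth without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
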