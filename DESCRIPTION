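Package: aimtrack
Title: Model-Based 3D Knee Kinematics from Interleaved Bi-Plane Fluoroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Measures six-degree-of-freedom bone poses and 3D knee joint
    kinematics from clinically interleaved (asynchronous) bi-plane
    fluoroscopy. Builds statistical shape models (SSM) of the distal femur
    and proximal tibia from corresponded training meshes, reconstructs
    subject-specific bone models from multiple static radiograph pairs by a
    two-phase pose-and-shape optimization against digitally reconstructed
    radiographs (DRRs), and tracks bone motion with alternating
    interpolation-based model tracking (AIMT): particle-filter 2D template
    registration, motion-compensated frame interpolation to synthesize
    pseudo-synchronous image pairs, and bi-plane 3D/2D registration driven
    by a gradient-correlation similarity metric and a genetic algorithm.
    Includes radio-stereometric marker triangulation, anatomical coordinate
    systems with z-x-y Cardan joint angles, a complete accuracy-metric
    suite (RMSe, mTRE/mmTRE/pmTRE, MAD/PAD), and a synthetic fluoroscopy
    simulator that provides ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    RNifti,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
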