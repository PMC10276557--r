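---
title: "Measuring 3D knee kinematics from interleaved bi-plane fluoroscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring 3D knee kinematics from interleaved bi-plane fluoroscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Clinical bi-plane fluoroscopes fire their two X-ray units alternately: at
an effective 60 fps the units expose in turn with a constant 1/60 s
offset, so no two images are ever simultaneous. Model-based 3D/2D
registration — posing a subject-specific volumetric bone model so that its
simulated radiographs (DRRs) match the measured images — normally assumes
a synchronous pair. Treating interleaved frames as synchronous biases the
recovered six-degree-of-freedom (6-DOF) pose whenever the joint moves.

`aimtrack` implements a complete measurement pipeline for this setting:

1. **Statistical shape modeling (SSM).** Corresponded training surfaces
   are aligned by generalized Procrustes analysis (GPA) and decomposed by
   PCA into a mean shape plus orthonormal variation modes, so any
   plausible bone is `mean + modes %*% b`.
2. **Subject-specific reconstruction.** From one to three static bi-plane
   image pairs (the subject standing on a rotating plate; pairs
   co-registered through radio-stereometric triangulation of lead skin
   markers), a two-phase optimization recovers the subject's bone shape
   and pose: phase 1 searches the 6 pose parameters plus the first 10 mode
   coefficients; phase 2 refines modes 11–20 with the phase-1 result
   frozen.
3. **AIMT tracking.** Alternating interpolation-based model tracking
   processes each dynamic frame in three stages: (i) a particle-filter 2D
   template registration estimates the bone's in-plane pose increment in
   each view and predicts the 3D pose; (ii) motion-compensated frame
   interpolation synthesizes the partner plane's image at the frame's
   instant, forming a pseudo-synchronous pair; (iii) a bi-plane 3D/2D
   registration refines the pose by maximizing gradient correlation.
4. **Kinematics and metrics.** Anatomical coordinate systems (x anterior,
   y superior, z right) yield the tibial pose in the femoral frame,
   decomposed by the z-x-y Cardan sequence into flexion/extension,
   adduction/abduction and internal/external rotation; accuracy is
   quantified by point-to-surface RMSe, per-frame mTRE (with its mean
   mmTRE and peak pmTRE, success defined as mTRE < 1.5 mm) and
   component-wise MAD/PAD.

A synthetic fluoroscopy simulator generates every input with known ground
truth, so the whole pipeline is testable without clinical data.

## Similarity metric and search

The registration cost for a pose $p$ over $N$ views is
$\sum_{k=1}^{N} -f_{GC}^{(k)}(p)$ where $f_{GC}$ is the gradient
correlation: both images are filtered with the horizontal and vertical
3×3 Sobel templates and the normalized cross-correlations of the two
horizontal-gradient images and of the two vertical-gradient images are
summed. $f_{GC} \in [-2, 2]$, equals exactly 2 for identical non-flat
images, and is invariant to positive affine intensity maps — so 8-bit
quantization and detector gain cannot bias the optimum. Border pixels are
excluded from the sums (the Sobel response is undefined there), and a
flat region raises an error rather than returning an arbitrary value.

The similarity is evaluated inside the projected bounding box of the
posed model dilated by a fixed **6.25 mm margin on the detector**
(10 px at the clinical 0.625 mm/px resolution). A fixed *physical* margin
matters: at reduced test resolutions a fixed pixel margin would cover
several times the intended area and pull the neighbouring bone's edges
into the window, which we measured to bias the registered pose by
~0.3 mm vertically at 128 px.

Minimization uses a real-coded Holland-style genetic algorithm:
tournament selection (size 3), blend crossover (rate 0.9), per-gene
Gaussian mutation (rate 0.1, SD 5% of the bound width), elitism 2,
population 60 × 40 generations by default, fully seeded. For per-frame
tracking refinement the package uses a compact budget (population 32, 10
generations) inside a ±3 mm / ±3° box about the predicted pose, followed
by a bounded Nelder–Mead polish (≤60 iterations); the polish is exposed
as a flag and disabled in the plain `biplane_register()` default.

## Particle-filter template tracking

Between consecutive same-plane frames, 300 particles over
(Δu, Δv, Δθ) propagate by a random walk (SD 2 px, 2 px, 1°), are
weighted by `exp(NCC / τ)` against the template extracted at the previous
pose, and are resampled systematically; three propagate/weight/resample
sweeps with a halving random-walk scale let the particles migrate to the
likelihood mode. We use τ = 0.01: NCC differences near the optimum are of
order 10⁻², so a softer temperature (e.g. 0.05) leaves the likelihood
nearly flat and the weighted-mean increment dominated by the prior —
measured static jitter then exceeds 0.4° versus <0.1° at τ = 0.01.

The per-view 2D increments are back-projected and **summed** into a 3D
increment (translations scaled by pixel spacing over the magnification at
the bone centroid depth; in-plane rotations become rotations about each
view's principal axis). For orthogonal planes the vertical axis is seen
by both views and is therefore counted twice; this is deliberate — the
increment is only a prediction, and the ±3 mm registration box absorbs
the approximation.

## Frame interpolation

The pseudo-synchronous partner image is the motion-compensated midpoint
of the two neighbouring same-plane frames: hierarchical block matching
(16 px then 8 px blocks, ±8 px search, smaller displacement preferred on
ties), 3×3 vector-median smoothing of the flow, and bidirectional
half-way warping with equal blending. If the two frames are essentially
uncorrelated (correlation < 0.2) the method falls back to plain averaging
and flags the frame as degenerate. The first and last frames of a
sequence have no bracketing partners and are paired with the nearest
frame, flagged accordingly.

## Shape model and reconstruction

- **Correspondence**: trimmed (95%) rigid ICP, then a Gaussian-kernel
  regularized nonrigid registration — each reference vertex is attracted
  to its closest point on the target surface and the displacement field is
  smoothed with a kernel of width 10% of the bounding-box diagonal
  (30 iterations, step 0.5), ending with a closest-point projection. The
  rigid ICP tries two deterministic initializations (centroid shift and
  principal-axes alignment with skewness-resolved signs) and keeps the
  better fit; closest-point ties resolve to the lowest vertex index.
- **GPA without scale**: bone size is a genuine shape feature that the
  reconstruction must recover in millimetres, so scale is not normalized
  (a `scale` switch exists).
- **PCA** on raw mm coordinates; eigenvalues are the per-mode variances
  (mm²); coefficients are bounded at ±3 SD during optimization. The
  default 20 retained modes mirrors the 10 + 10 two-phase split.
- **Per-candidate voxelization** is the reconstruction hotspot, so GA
  candidates are voxelized at 1.0 mm and only the final model at 0.5 mm
  (the clinical slice resolution). Voxel values are 700 HU inside and
  −1000 HU outside, emulating homogeneous bone in air.
- The phase-1 objective sums −f<sub>GC</sub> over *all* images of all
  pairs (consistent with the multi-view cost); phase 2 seeds the zero
  vector into its population, so with elitism the refined objective can
  never be worse than phase 1's.

## DRR rendering and voxelization

Rays are cast from the point source to each detector pixel and the line
integral of (value − air) is accumulated with trilinear interpolation at
a step of half the smallest voxel spacing; a brute-force eighth-spacing
reference stays within 1%. Interior/exterior labeling uses ray-crossing
parity along slice rows with the voxel lattice offset half a voxel from
the mesh bounding box, so rays cannot graze vertices that sit at exact
grid coordinates; non-watertight input is rejected with the offending
edges listed. Missed rays render as background 0. Float images are kept
for similarity computation; 8-bit min–max quantization is applied only
when emulating the fluoroscope's output.

## Pose conventions and degenerate inputs

The optimizer parameterizes rotations as intrinsic x→y→z rotations
(`R = Rx(α) Ry(β) Rz(γ)`), deliberately decoupled from the z-x-y Cardan
sequence used for clinical reporting. Both decompositions raise an error
within ~1e-9 of their gimbal configurations (|β| = 90°, |x-rotation| =
90°) naming the degenerate axis. Angles are wrapped to (−180°, 180°].
`define_acs()` uses area-weighted inertia axes (independent of surface
sampling density) and errors on geometry whose leading axis gaps fall
below 2% (a sphere has no distinguishable axes); the articular origin is
the centroid of the extreme 15% of the surface along the superior axis
(distal end for the femur, proximal for the tibia). This geometric ACS is
a documented stand-in for anatomical-landmark definitions; consistency
between models is guaranteed by transferring the reference ACS through
ICP rather than re-deriving it.

## The synthetic simulator — and what it does not emulate

Bone analogs are procedural 64 mm segments (distal-femur and
proximal-tibia analogs on a closed UV-sphere topology) with condyle-like
lobes, a tibial plateau with medial/posterior/anterior asymmetries —
enough asymmetry to define an anatomical frame and make all six pose DOF
observable in silhouettes — sized so the whole joint stays inside the
160 mm isocenter field of view across the full flexion arc. Populations
deform the base by k = 5 smooth orthonormal modes (SDs 2, 1.5, 1.2, 0.9,
0.7 mm) that are explicitly projected orthogonal to the six rigid-motion
generators: a "shape mode" with a rigid component would let GPA leak
alignment into the shape subspace and break eigen-rank recovery. An
optional iid vertex residual (`vertex_noise_sd`) emulates the full
eigen-spectrum of real CT populations for reconstruction studies.

The scene places orthogonal X-ray units (source–isocenter 500 mm,
source–detector 1000 mm, 320 mm field of view; 512 px / 0.625 mm per
pixel at clinical fidelity, 128 px by default for desk-scale runs), a
sinusoidal 0–60° flexion of the tibia about the mediolateral knee axis
over 2 s, six lead markers around the joint, additive Gaussian intensity
noise (SD 2 gray levels) and 8-bit quantization.

Deliberately **not** emulated: polyenergetic X-ray physics, scatter and
detector response; soft-tissue and overlapping-anatomy clutter beyond the
second bone; CT segmentation error; marker occlusion; out-of-plane
detector distortion. Passing tests therefore demonstrate correctness of
the geometry, the optimization and the metric chain under controlled
conditions — not clinical-grade robustness to image artifacts.

## Problem sizes used by the test suite

The packaged studies run at reduced resolution chosen once for desk-scale
runtimes: 128×128 images (96×96 for the interpolation-benefit study),
1.0 mm truth voxels, training populations of 30–60 shapes, reconstruction
GAs of 20×8 and tracking GAs of 32×10 with a 60-iteration polish. The
2 s / 30 fps-per-plane tracking study (120 frames) and the 10-seed
reconstruction comparison dominate the runtime. Clinical-fidelity
settings (512 px, 0.5 mm voxels, GA 60×40) are available through the same
interfaces.

## Known limitations

- The magnification model in the 3D pose prediction is evaluated at the
  bone centroid; strongly off-center bones make the prediction (not the
  final registration) less accurate.
- Closest-vertex rigid ICP can stall for initial rotations beyond ~30°
  even with the dual initialization; reconstruction and ACS transfer
  assume roughly known orientation, as in the clinical protocol.
- The interpolation assumes locally translational motion between
  consecutive same-plane frames (1/30 s); strongly rotating structures
  degrade toward the blended fallback.
- Tracking is per-bone; no joint-contact or multi-bone constraints are
  imposed.
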