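---
title: "Correcting dental signal voids in MR-based attenuation maps: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting dental signal voids in MR-based attenuation maps: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(muinpaint)
```

## The problem

PET attenuation correction on combined PET/MR systems is derived from a
Dixon MR acquisition segmented into air, lung, fat and soft tissue.
Metallic dental work causes susceptibility signal voids much larger than
the implants themselves; the segmentation assigns them air
(μ = 0 cm⁻¹), and the attenuation correction then underestimates the
reconstructed activity in and near the mouth. Two topologies occur: voids
fully enclosed by the anatomical surface (*inner*), and voids that breach
the body contour and merge with the background air (*outer*). The package
implements an automatic correction and a simulation study design that
measures what the correction changes.

## The correction model

### Void detection and classification

Voids are connected components (26-connectivity) of sub-threshold voxels
(μ < 0.005 cm⁻¹, well below fat at 0.086 cm⁻¹ and above float noise)
that intersect the body envelope, defined as the largest connected non-air
component plus its internal cavities. A component is *outer* iff its air is
6-connected to the border-reaching background; 6-connectivity makes the
breach test conservative while 26-connectivity merges voids generously.
Both are configurable.

A breached void is topologically part of the background: on the mu-map
alone it is indistinguishable from the free air outside the patient, and
only its rim intersects the naive envelope. The package therefore detects
breaches the way the original method parameterizes itself — by inspecting
the PET signal outside the mu-map body (`outer_void_evidence()`): voxels
outside the envelope whose non-attenuation-corrected PET (NAC-PET)
intensity is well above the outside background level mark body regions the
mu-map lost. The contour-closing step runs when this evidence exceeds 2 mL
(the smallest breached voids observed clinically are ~9 mL; the blur halo
of an intact body stays far below the threshold).

### Step 1 — contour closing (outer voids)

The body contour is evolved by a two-channel Chan–Vese level set
(φ > 0 inside):

φ_t = δ(φ) [ ν κ + λ_mr (1−w) ((I_mr−c2)² − (I_mr−c1)²)
            + λ_pet w ((I_pet−c2p)² − (I_pet−c1p)²) ]

where `w` is 1 on a dilation (default 8 mm) of the breach evidence and
outer-class void air, and 0 elsewhere. Both channels are normalized to
[0, 1] by a robust 1st–99th percentile stretch, which makes the
parameterization invariant to global PET scaling and transferable across
tracers. The mu-map channel uses the usual adaptive two-region means. The
PET channel uses *fixed* region levels set from the data: `c2p` is the mean
normalized PET outside the body, and `c1p` the 10th percentile of the
evidence region — a dim-tissue reference. This is a deliberate deviation
from fully adaptive Chan–Vese: without attenuation correction the PET
intensity deep inside a large void is strongly suppressed, and adaptive
means absorb it into the background class, stalling the contour half-way
across the breach. With a fixed dim-tissue reference the relevant contrast
(tissue ≥ ~0.04 versus background ≈ 0 after normalization) is preserved
throughout the void.

Numerics: φ is initialized as the signed distance to the naive mu-map body
threshold and reinitialized by a distance transform every 50 iterations;
the explicit update is normalized by the 98th percentile of |update| in a
narrow band and clipped, so the interface moves at most 0.8 voxels per
iteration; the automatic PET weight is λ_pet = 2 / contrast, clamped to
[0.5, 10], with λ_mr = 1. Convergence is declared when the fraction of
voxels changing sign stays below 2×10⁻⁵ for five consecutive iterations,
after a 30-iteration warm-up; the warm-up and the tolerance (rather than
10⁻⁴) are needed because a moving front across a medium-sized breach flips
only a few dozen voxels per iteration on this grid — the looser tolerance
halts the contour mid-breach. Hard cap 300 iterations, with a
`converged = FALSE` flag and warning.

Closing then fills every background-connected void voxel enclosed by the
recovered contour with exactly 0.1 cm⁻¹, the soft-tissue attenuation
value used throughout.

### Step 2 — atlas template masking (both classes)

An atlas is the voxelwise mean Dixon-water image of artifact-free subjects
(default 30). Two masks are derived from the population air frequencies:

* the *oral-cavity template* — the largest internal air component present
  in ≥ 90% of subjects, dilated one voxel (compensating the consensus
  erosion) and then by the 14-mm dental margin, restricted to the
  median-consensus body. This is the region in which signal voids are
  assumed metallic in origin. (The body outline uses the *median*
  consensus; a 90% consensus can thin the cheek wall below one voxel and
  topologically merge the cavity with the background, defeating the hole
  filling.)
* the *anatomical air* masks — air in ≥ 20% of subjects (dilated one
  voxel) identifies components that are normal anatomy; air in ≥ 50%
  of subjects (the median anatomy) protects individual voxels from being
  filled.

The patient water image is aligned to the atlas by a 12-dof affine
(mean squares on normalized, 4-mm-smoothed images, two-level
multi-resolution, BFGS; sub-threshold patient voxels — air and signal
voids — are excluded from the metric so large voids cannot drag the fit).
Remaining void components are then filled where they overlap the warped
template; per component, an overlap fraction strictly above 0.80 completes
the fill, strictly below 0.10 reverses it, and fractions in between keep
the partial fill (fractions exactly at a threshold fall in the
kept-partial band — a literal reading of "more than 80%" / "less than
10%"). The high completion threshold is what keeps sinuses connected to a
dental void from being filled.

Two guards beyond the published description were required for the method
to be a projection (idempotent) and the identity on artifact-free inputs:
components whose air lies almost entirely (> 95%) inside the
anatomical-air union are recognized as normal anatomy (oral cavity,
sinuses) and skipped; and no fill action may overwrite median-anatomy air.
The voxel protection for the template fill dilates the internal air by one
voxel, absorbing the residual registration error (the contour fill is
bounded by the patient-specific contour and uses the undilated mask, which
restores the void rim near the body surface). Without these guards the
normal ~9 mL oral cavity of any subject overlaps the template almost
completely and would be converted to soft tissue.

## The simulation harness

### Phantom

The generator emulates a head/neck patient on the mu-map grid of the
simulated protocol (96×96×64 voxels at 2.6×2.6×3.1 mm, a reduced matrix at
the clinical spacing so volumes in mL are faithful): a head ellipsoid and
neck cylinder of soft tissue (μ = 0.1 cm⁻¹) with a thin scalp fat cap
(0.086 cm⁻¹), an oral air cavity (~9 mL) behind an 18-mm cheek wall,
two sinus spheres, a high-uptake brain compartment and the four reference
ROIs (tongue, lower tongue, masticatory muscles as a left/right union,
cerebellum). Activity is piecewise constant per tissue class (arbitrary
SUV-equivalent units: soft tissue 1.0, tongue 1.5, masticatory 0.8, brain
4.0) with a seeded smooth ±5% texture; the water image maps tissue to high
and fat to medium signal with seeded smooth noise. Anatomical jitter
(2.5 mm global translation plus smaller per-structure perturbations)
produces atlas populations and patients. ROI sizes and positions are the
generator's own choices — the clinical study drew them manually and gives
no dimensions.

Artifacts are seeded unions of random ellipsoids near the anterior
oral-cavity wall (the teeth region), grown connectedly until the zeroed
tissue reaches the target volume within 15%; supported targets span the
clinically observed 1.6–520.8 mL. Inner voids are confined to the dental
band and an eroded body so even their one-voxel dilation stays enclosed;
outer voids additionally carve a 6-mm-radius channel through the cheek to
the background. Both the mu-map and the water image are zeroed on the void
(the MR signal is lost, not just the segmentation). The stock study uses
5 inner targets (2–16 mL, bracketing the reported 6 mL inner mean) and
5 outer targets (12–300 mL, around the reported 133 mL outer mean).

What the phantom does *not* emulate: bone and metal attenuation (the
corrected maps are soft-tissue-only by design), MR physics and
sequence-specific void shapes, anatomical detail beyond ellipsoids,
motion. Passing tests therefore demonstrate the correction and bias
mechanics, not clinical-grade accuracy on real anatomy.

### Projector and reconstruction

The scanner model is 2-D parallel-beam, slice-by-slice: the bias mechanism
is in-plane attenuation mismatch, and full 3-D adds cost, not coverage.
The projector is an explicit sparse system matrix (126 angles over
[0, π), 128 radial bins at 2.6 mm; line integrals by bilinear sampling at
half-voxel steps, path lengths in cm), so the back projector is its exact
transpose and the adjoint identity holds to machine precision. Attenuation
factors are exp(−∫μ dl) through the same matrix. Expected prompts are
attenuated line integrals of activity plus an optional flat background (a
scatter/randoms surrogate, default 0; it is labelled a surrogate, not a
model of any product scatter algorithm), Poisson-sampled per bin
(2×10⁶ expected true counts per phantom by default).

Reconstruction is ordinary-Poisson OSEM: multiplicative updates with the
attenuation factors of the chosen AC map in the system model and the
background in the denominator, angle-interleaved (bit-reversed) subsets,
uniform initialization over the field of view, voxels with zero
sensitivity excluded. Defaults follow the simulated protocol: 3
iterations, 21 subsets, 4-mm Gaussian post filter (σ = FWHM/2.3548,
in-plane and axial, applied last). NAC-PET is the same reconstruction with
unit attenuation factors.

### Bias metrics

Relative and absolute differences are computed on the mean and maximum SUV
per ROI; −100% marks a total loss of activity. Voxelwise difference images
define 0/0 as 0 so they are displayable, and count (in an attribute) the
undefined voxels where only the corrected image is zero; both cases are
masked from summaries. The `inpainted_area` ROI is the exact set of voxels
the correction changed. Cohort summaries report mean, sample standard
deviation (n−1) and range per ROI and artifact class, the volume-versus-
bias table with its Spearman rank correlation, and Euclidean distance
shells from the void operationalize the distance dependence of the bias.
The Wilcoxon matched-pairs test uses the exact 2ⁿ sign-permutation null up
to n = 12 (valid under ties via midranks), the exact signed-rank
distribution for larger tie-free samples, and the tie/continuity-corrected
normal approximation otherwise; no normality pre-test is performed, the
test is applied directly.

## Study sizes and determinism

The stock experiment (10 phantoms, a 30-subject atlas, four
reconstructions per phantom — NAC, uncorrected, corrected, and the
true-map reference) was sized to run in minutes while keeping the
spacing-dependent quantities at clinical scale. Every stage draws its seed
deterministically from the experiment seed and the manifest records all of
them; rerunning a configuration reproduces the output bitwise.

## Known limitations

* Very small inner artifacts (around the 1.6 mL end of the observed range)
  that hug the oral cavity can fall entirely inside the atlas
  anatomical-air union and are then skipped as normal anatomy — the
  correction leaves such maps unchanged. This mirrors the failure mode the
  clinical method reported for unusually small artifacts; the experiment
  driver reports such cases in its success rate.
* The registration is a global affine; the oral cavity carries
  per-structure jitter the affine cannot express, so its wall position is
  uncertain by about one voxel after alignment. Filling decisions next to
  the cavity inherit that uncertainty — small inner artifacts hugging the
  cavity keep an unfilled one-voxel rim, and the agreement of the
  corrected reconstruction with the true-map reconstruction is weakest
  there.
* The contour step fills the void air enclosed by the recovered contour;
  where a void swallowed the oral cavity, protected median-anatomy air is
  spared, but air the atlas cannot predict (a patient's unusually shaped
  cavity) is filled as tissue, as in the original method.
* Measured void volumes for breached components are only meaningful after
  contour closing; before it, only the rim of a breach intersects the
  envelope.
* The 2-D projector ignores axial attenuation mismatch; out-of-plane
  spill of the bias (e.g. into the cerebellum) is therefore smaller than
  in fully 3-D reconstruction.
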