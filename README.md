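# muinpaint

Metallic dental work destroys the MR signal around the implants. On a
PET/MR system, where attenuation correction (AC) is computed from the
Dixon-VIBE MR image, these susceptibility voids are segmented as air
(mu = 0 cm⁻¹) in the attenuation map, and the reconstructed PET activity in
and around the mouth is severely underestimated — lesions near the mandible
can lose most of their apparent uptake. `muinpaint` implements an automatic
correction ("inpainting") of these signal voids together with a full
simulation harness that reproduces and quantifies the bias mechanism, for
researchers working on MR-based attenuation correction.

## What the package does

**Correction.** Signal voids are detected as connected sub-threshold
components of the mu-map and classified by their topology: *inner* voids are
enclosed by the anatomical surface, *outer* voids breach it and connect to
the background air. The correction runs in two steps:

1. *Contour closing* (outer voids only). A two-channel Chan–Vese level set
   delineates the body contour: outside void regions the data term follows
   the mu-map; inside a switch field around the breach it follows the
   non-attenuation-corrected PET image (NAC-PET), whose apparent body edge
   survives the MR void. Void air enclosed by the recovered contour is set
   to the soft-tissue value, exactly 0.1 cm⁻¹. All level-set parameters are
   set automatically by inspecting the PET signal outside the mu-map body.
2. *Template masking* (both classes). The patient's Dixon-water image is
   registered (12-dof affine) to an atlas built from artifact-free subjects;
   remaining void components overlapping the atlas oral-cavity template are
   filled with 0.1 cm⁻¹. Components filled more than 80% are completed,
   components filled less than 10% are considered registration errors and
   reversed — the high threshold keeps connected sinuses from being filled.

**Quantification.** Each phantom is reconstructed twice (OP-OSEM, 3
iterations, 21 subsets, 4-mm Gaussian post filter) — once with the
uncorrected map (PET_DIXON) and once with the corrected map
(PET_INPAINTED) — and compared per ROI with

    eps_rel = (SUV_DIXON − SUV_INPAINTED) / SUV_INPAINTED × 100%
    eps_abs =  SUV_DIXON − SUV_INPAINTED

on the mean and the maximum SUV, plus voxelwise difference images,
distance-shell profiles, Wilcoxon matched-pairs tests and Table-2-style
cohort summaries.

**Simulation.** Because no patient data ship with the package, a seeded
head/neck phantom generator provides the ground truth: a body envelope with
oral cavity and sinuses, a true mu-map, a smooth activity map with reference
ROIs (tongue, lower tongue, masticatory muscles, cerebellum), a
Dixon-water-like image, and injectable artifact voids of both topological
classes spanning the 1.6–520.8 mL range. A 2-D parallel-beam attenuated
projector (explicit sparse system matrix, exact adjoint) and an
ordinary-Poisson OSEM reconstructor close the loop.

## Worked example

```r
library(muinpaint)

ph    <- make_phantom(phantom_spec())                      # head/neck anatomy
ph    <- inject_artifact(ph, artifact_spec("outer", 133, seed = 12))
sim   <- simulate_case(ph, seed = 7)                       # counts + NAC-PET
pop   <- make_population(phantom_spec(), 30, seed = 3)
atlas <- build_atlas(lapply(pop, function(p) p$water))

ip <- inpaint(ph$mu_dixon, sim$pet_nac, ph$water, atlas)
ip
#> <inpaint_result> 7658 voxels inpainted (160.5 mL); 1 initial component(s)
#>   id n_voxels  fraction     action voxels_changed
#> 1  1      683 1.0000000 anatomical              0
#> 2  2      122 0.0000000 anatomical              0
#> 3  3       99 0.0000000 anatomical              0
#> ...
```

The 133-mL breached void (realized at 124.6 mL, plus the oral cavity it
swallowed) is closed and filled by the contour step; the air components
left afterwards — the oral cavity remnant and the sinuses — are recognized
as anatomical and stay untouched. Reconstructing with both maps and
comparing:

```r
pd <- reconstruct_osem(sim$sino, ph$mu_dixon)
pi <- reconstruct_osem(sim$sino, ip$mu_inpainted)
rep <- roi_report(pd, pi, ph$rois, inpainted_mask = ip$changed_mask)
rep[, c("roi", "eps_rel_mean", "eps_rel_max")]
#>                   roi eps_rel_mean eps_rel_max
#> 1              tongue       -46.41      -34.46
#> 2        lower_tongue       -36.49       -7.26
#> 3          cerebellum        -0.88       -1.10
#> 4 masticatory_muscles       -11.30      -14.83
#> 5      inpainted_area       -64.76      -48.16
```

The uncorrected reconstruction loses ~65% of the mean activity inside the
inpainted region, ~46% in the adjacent tongue, and under 1% in the distant
cerebellum — the underestimation decays with distance from the void. A
command-line wrapper for the same stages is in `inst/cli/muinpaint.R`
(`simulate`, `recon`, `close-contour`, `correct`, `experiment`).

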