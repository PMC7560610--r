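# multireg

Co-registration of in vivo radiologic images (PET, T2-weighted MRI) with ex
vivo optical images of cleared brain-tissue slices, for cross-validating
tumor measurements in preclinical glioma models.

## The problem

Wide-field fluorescence imaging of optically cleared 1-mm brain slices shows
tumor burden directly (e.g. a tdTomato reporter), but the animal has to be
sacrificed first. In vivo MRI and PET see the tumor indirectly and at coarser
resolution. Quantitative statements like "the tumor margin on MRI is within a
few hundred micrometres of the fluorescence-defined margin" require every
image to sit in one spatial frame of reference — the ex vivo MRI — which
takes a chain of registrations:

1. **PET → in vivo MRI** — rigid (6 DOF), guided by a water/tracer-filled
   tube loop taped to the multimodality bed, visible in both scans. Only a
   mask over this fiducial phantom enters the objective.
2. **In vivo MRI → ex vivo MRI** — full affine (12 DOF), to absorb the few
   percent of tissue shrinkage from perfusion and fixation. Masks drawn
   around the brain on both images restrict the objective.
3. **Fluorescence slab → ex vivo MRI slice** — the brain is scanned ex vivo
   inside the pathology slice block and then cut into 1-mm slabs, so each
   slab maps to a known through-plane interval of MRI slices. In-plane, six
   landmarks on the brain edge drive a closed-form 2D similarity fit (rigid
   plus one uniform scale, for clearing-induced shrinkage/expansion).

Stages 1–2 maximise mutual information (MI) of a joint intensity histogram
over the mask, with a derivative-free simplex search run coarse-to-fine.
Stage 3 is the least-squares similarity (Umeyama-style, reflection
excluded):

```
minimise over s, R, t :   Σ_i || s·R·x_i + t − y_i ||²,   det(R) = +1
```

Agreement is then quantified the way the bench protocol reports it: paired
landmark distances (median / IQR / range, in µm), symmetric surface
distances between the MRI-defined and fluorescence-defined tumor ROIs on
the 34.4-µm fluorescence grid, tumor volumes in mm³, and the brain-volume
change between the in vivo and ex vivo scans. The fluorescence tumor ROI is
segmented by a deterministic rule: the lowest threshold that admits no
voxel of the contralateral (tumor-free) hemisphere.

Because studies of this kind rarely deposit raw animal data, the package
ships a synthetic digital phantom (`phantom_spec()` / `simulate_study()`)
that generates all four modalities with known ground-truth transforms, so
every stage is testable end to end with no downloads.

## Worked example

```r
library(multireg)
study <- simulate_study(phantom_spec(rng_seed = 1))

# per-slab 2D landmark similarity (fluorescence -> MRI slice space)
fit <- fit_similarity_2d(study$landmarks[[5]]$template_fluor,
                         study$landmarks[[5]]$template_mri)
fit
#> <similarity_fit2d> s = 1.040426, theta = -4.074 deg, t = (-0.7778, 0.5421) mm, rms = 0.0 um over 6 landmarks

# the full chain: PET registration, affine registration, slab matching,
# per-slab similarity fits, threshold segmentation, agreement metrics
report <- run_pipeline(pipeline_config(verbose = FALSE), study = study)
report
#> <pipeline_report>
#>   full-chain landmark error: <distance_summary> median 46 um, IQR 26-67 um, range 5-83 um, mean 46 (sd 26), n = 32
#>   pooled tumor surface distance: <distance_summary> median 206 um, IQR 146-269 um, range 0-577 um, mean 206 (sd 94), n = 2198
#>   brain volume change: -13.9%
#>   tumor volume MRI 17.3 mm^3 vs fluorescence 24.6 mm^3
#>   8 slabs processed
```

Reading the output: the slab-5 similarity fit recovered that slab's
placement (4° rotation, 4% scale) with numerically zero residual; after
composing all recovered transforms, landmarks placed independently in
in-vivo MRI space land a median of 46 µm from their true fluorescence-space
positions; the fluorescence-thresholded tumor ROI and the MRI tumor ROI
carried through the chain disagree by a median of 206 µm at their surfaces;
the fluorescence tumor volume exceeds the MRI volume (24.6 vs 17.3 mm³),
the expected asymmetry when thresholding picks up the diffuse signal skirt
that T2w partial volume hides; and the brain "shrank" by 13.9% in volume,
consistent with the phantom's 5% linear shrinkage (0.95³ ≈ 0.86).

`plot_surface_distances(report)` draws the per-slab box plot of surface
distances. `write_study()` / `read_study_layout()` move a study to and from
disk (NIfTI volumes, TIFF slabs, landmark CSVs, YAML layout), and
`inst/cli/multireg.R` wraps the main entry points for shell use
(`simulate`, `run`, `register-slice`, `match-slices`, `volume-diff`,
`landmark-error`).

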