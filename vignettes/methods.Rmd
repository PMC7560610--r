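---
title: "Methods: multimodal co-registration of in vivo and ex vivo rodent brain images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal co-registration of in vivo and ex vivo rodent brain images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models and numerical choices behind
`multireg`: how the registration chain is defined, what each tunable
parameter means, what the synthetic phantom does and does not emulate,
and where the design was genuinely open.

## Geometry

All spatial reasoning happens in physical millimetre coordinates, never
voxel indices. An `image3d` is an axis-aligned grid: voxel `(i, j, k)`
(1-based) has its **centre** at `origin + (i−1, j−1, k−1) · spacing`.
Transforms (`affine_transform`) are homogeneous matrices acting on
physical coordinates, tagged `rigid`, `similarity` or `affine`, with the
tag verified against the matrix on construction and propagated through
composition as the weakest of the operands. Resampling is a pull-back:
`resample(moving, t, target)` evaluates the moving image at `t(x)` for
every target voxel centre `x`, so `t` maps target space into moving
space; pass `invert()` of a forward transform. Out-of-grid samples take
a constant background (default 0) — nothing is extrapolated. Oblique
(direction-cosine) grids are deliberately not represented: the readers
flip negative-stride axes to this convention and reject oblique xforms,
because every acquisition in the intended workflow is axis-aligned and
carrying direction cosines through all the geometry would buy nothing
but bug surface.

Linear interpolation is used for intensities and nearest-neighbour for
masks and labels. The choice of linear interpolation for the MRI
upsampling step is our default, stated rather than inferred: protocols
of this kind typically do not record it.

## Mutual-information registration

Stages 1 (PET → in vivo MRI, rigid) and 2 (in vivo → ex vivo MRI,
12-DOF affine) maximise mutual information

$$\mathrm{MI} = \sum_{ij} p(i,j)\,\log\frac{p(i,j)}{p(i)\,p(j)}$$

of a plain joint histogram (no Parzen windowing) over the voxels of a
fixed-image mask. The estimator details, all settable through
`registration_settings()`:

* **Bins** (`histogram_bins`, default 32): intensity bin edges span each
  image's masked range after percentile clipping (`clip_percentiles`,
  default 1st–99th) and stay fixed during optimisation; out-of-range
  samples are clamped into the end bins so the total count always equals
  the sample count. At subsampled pyramid levels the bin count shrinks
  automatically to keep roughly five samples per occupied marginal bin —
  a 32×32 histogram fed a few hundred samples rewards spurious
  alignments, which we observed as coarse-level divergence before adding
  the rule.
* **Off-lattice sampling** (`sample_jitter`, default on): each masked
  voxel contributes a sample at a position drawn uniformly inside the
  voxel (deterministically from `rng_seed`), and both images are
  interpolated there. Together with a mild pre-smoothing of both images
  (`smooth_vox`, default 0.5 voxel) this suppresses the classic
  grid-alignment interpolation artifact of histogram MI, which otherwise
  plants a false optimum wherever the two grids become commensurate —
  in our phantom experiments that artifact was strong enough to swallow
  a 2° in-plane rotation entirely.
* **Optimiser**: Nelder–Mead over transform parameters — translations in
  mm, rotations as Euler angles, the affine's linear part as 9 raw
  entries about the mask centroid — with `parscale` chosen so one
  optimiser unit is ≈ 1 mm of displacement at the object radius. The
  search runs coarse-to-fine over mask-subsampling strides (`levels`,
  default every 4th voxel then all), restarts at the coarsest level with
  seeded jitter (`n_restarts`, `jitter_mm`), re-runs the simplex up to
  six times per level (a restarted simplex escapes premature collapse),
  and finishes with a BFGS polish at full resolution — the jittered,
  smoothed objective is smooth enough for finite differences, and the
  12-parameter affine case measurably under-converges on the simplex
  alone.
* **Capture range**: before the simplex, a translation-only grid search
  (`presearch_mm` ± 2 mm in `presearch_step` 0.5 mm steps) stands in for
  the manual rough pre-alignment that bench protocols perform
  interactively. MI has a limited capture range; initialisations several
  millimetres off without a pre-search may return the init with a
  warning — which is the documented failure mode, not an exception.
* **Minimum improvement** (`tol_mi`, default 0.01 nats): an optimised
  transform replaces the initialisation only if it improves MI by more
  than the quantisation noise of the binned estimator (we measured
  spurious gains up to ~0.003 nats on identical-content images, versus
  ~0.08 nats for a genuine 0.05 mm refinement). This is what makes
  self-registration return its init *exactly*, and the degenerate
  pipeline produce exact zeros.

**Masks.** The fixed-image mask defines the MI sample set: the fiducial
loop ROI for the PET stage, the ex vivo brain ROI for the affine stage.
The moving-side brain mask is accepted and validated for interface
parity, but by default it does not alter the moving intensities. We
initially hard-zeroed non-brain moving voxels (to keep the sample set
fixed), and found it stamps a brain-shaped pseudo-edge into the moving
image whose alignment with the fixed brain's partial-volume rim biases
the recovered shrinkage scale by a systematic ≈ +1.2% across phantom
seeds; without zeroing the bias falls below 0.5%. Zeroing remains
available as `moving_mask_mode = "zero"`.

## Slab matching and the 2D similarity fit

The pathology slice block gives each 1-mm slab a known through-plane
interval in ex vivo MRI coordinates: slab *k* spans
`[face0 + k·pitch, face0 + (k+1)·pitch)`. `match_slices()` returns every
MRI slice whose centre falls inside (with 0.5-mm slices and 1-mm slabs
that is exactly two) plus the single representative slice nearest the
slab centre; downstream comparisons use the representative by default
because the 2-to-1 ambiguity is real and should be explicit, not
averaged away silently.

`fit_similarity_2d()` solves the least-squares similarity (uniform scale
`s`, rotation `θ`, translation) between labelled landmark pairs in
closed form via the SVD of the 2×2 cross-covariance, with the
determinant sign-corrected so no reflection can appear — tissue slices
cannot be mirror-imaged by the slicing process. Slabs placed upside
down are handled by an explicit pre-flip (`allow_reflection = TRUE`)
that is kept only if it halves the residual. Collinear landmark
configurations are accepted (the similarity is still well-posed for two
or more distinct points); fully coincident points are rejected. The
six-point template (four brain-edge points at ±45°/±135°, two midline
points) is the default placement the synthetic study generates.

## Threshold segmentation

The fluorescence tumor ROI uses a deterministic re-statement of the
interactive rule "lowest threshold that includes no contralateral brain
voxel": the threshold is the smallest *observed* in-brain intensity
strictly greater than the contralateral maximum (one ulp above it for
float images when no observed value qualifies), and the ROI is every
brain pixel at or above it. The no-contralateral-voxel invariant then
holds by construction and is asserted on every call. Whether the ROI
should be restricted to one connected component is not specified by the
protocol; the largest-component postfilter therefore exists but
defaults to off. The contralateral reference is user-supplied or
mirrored from the brain mask across a stated midline
(`mirror_contralateral()`, with a 0.5-mm guard band).

## Agreement metrics

* `landmark_errors()` — per-label Euclidean distances in µm, after an
  optional transform of the first set.
* `summarize_distances()` — median, quartiles (type-7 linear
  interpolation between order statistics, fixed and regression-tested so
  summaries are bit-stable), range, mean, sd (n−1; a single distance
  reports sd 0 with `sd_defined = FALSE`).
* `surface_distance()` — surface voxels are foreground voxels with a
  face-adjacent background or out-of-bounds neighbour (6-connectivity in
  3D, 4 in 2D). For every surface voxel of each ROI, the minimum
  centre-to-centre distance to the other ROI's surface; both directions
  are pooled into one distribution because the protocol summarises
  "across the surfaces" of both ROIs (an asymmetric mode exists behind
  `symmetric = FALSE`). Distances are to surface voxels, not the full
  voxel set — the protocol wording admits either reading; we implement
  surface-to-surface and note the alternative. No sub-voxel surface mesh
  is fitted. The nearest-neighbour search accumulates squared
  coordinate differences directly (not the expanded inner product), so
  results are exact — the test suite holds it to bitwise agreement with
  a double-loop oracle.
* `volume_percent_difference()` — `100 (V_ex − V_in)/V_in` with volumes
  as voxel count × voxel volume on each mask's own grid; negative means
  shrinkage.

## The synthetic study

`phantom_spec()` defines the study conditions; `simulate_study()`
realises them deterministically from `rng_seed`. What it emulates:

* **Anatomy**: an ellipsoidal brain (semi-axes 5.5 × 8 × 4.5 mm) with
  two ventricles, smooth intra-tissue T2 texture shared — through the
  shrinkage map — by the in vivo and ex vivo scans (the same tissue is
  imaged twice), and a tumor: a 1.6-mm-radius sphere for the
  well-circumscribed growth pattern, or a central blob with radiating
  filaments for the diffuse, infiltrative one.
* **Fiducial loop**: the bed phantom is an open arc (radius 7 mm, 3-mm
  tube) whose ends continue as straight tails down the bed, with a
  1-mm out-of-plane warp. The gap, tails and warp reflect how a
  hand-taped flexible tube actually lies, and they are what makes all
  six rigid degrees of freedom observable from the loop alone — a
  perfect planar torus leaves out-of-plane translation and in-plane
  rotation ill-determined, which we verified directly on early drafts.
* **Acquisitions**: in vivo T2w at 0.25 × 0.25 × 0.5 mm with 0.3-mm
  partial-volume blur and Gaussian noise (sd 0.01 against tissue ≈ 0.5,
  a realistic SNR for a 15-minute RARE protocol); PET at 0.5 mm
  isotropic in a bed frame offset by the true rigid, blurred to 1.5-mm
  FWHM with signal-scaled (Poisson-like) noise; ex vivo MRI equal to
  the in vivo anatomy through the true shrinkage affine (5% uniform
  linear contraction, i.e. ≈ −14% volume, plus a 1° rotation and small
  translation); fluorescence slabs as 1-mm mean projections of the
  tumor-signal volume, resampled to 34.4-µm pixels and perturbed by
  per-slab similarities drawn from ±10° rotation, 0.95–1.05 scale,
  ±1 mm translation.
* **Masks**: drawn generously (0.75-mm margin; twice that for the
  phantom, whose PET appearance is blurred), as a human drawing "a mask
  around" a structure does. Exact-boundary masks are not only
  unrealistic, they bias the affine stage: the fixed brain's
  partial-volume rim then rewards over-shrinkage.
* **Landmarks**: the six-point template and a separate four-point
  evaluation set per slab, with true positions recorded in every space
  of the chain. Placements are exact — simulated observers do not
  jitter — so landmark-driven stages are noise-free by construction;
  this is a stated limitation, not an oversight (see below).

`phantom_spec_degenerate()` is the fully degenerate condition: no noise,
no blur, no texture, no ventricles, identity truths, and the ex vivo
scan sharing the in vivo intensity map (its grid is then an exact
sub-grid of the in vivo one). Under these conditions identity is the
exact MI optimum, the registrations return it exactly, and tumor ROIs
thresholded on the MRI-contrast and fluorescence-contrast slab
projections coincide pixel for pixel.

**Problem sizes.** The default grids are 96 × 112 × 32 (in vivo),
56 × 64 × 30 (PET) and 64 × 80 × 28 (ex vivo) voxels, with ~9 slabs of
~630 × 750 fluorescence pixels — sizes chosen so a full simulate +
register + validate cycle completes in about two minutes on one CPU
while keeping every spacing at its real value. The test suite
additionally uses a reduced-FOV phantom for structural checks.

**What passing tests do not show.** The phantom has ideal geometry
(true ellipsoids, analytic loop), exact landmark placements, Gaussian
noise, and no deformation beyond a global affine — no susceptibility
distortion, no slicing damage, no tissue tearing, no uneven clearing,
no autofluorescence structure. Recovery tolerances met on it bound the
*algorithmic* error of the chain, not the biological or observer error
of a real study; the bench protocol's own published accuracy numbers
come from manual landmarks on real tissue and are expected to be an
order of magnitude larger than the phantom's.

## Pipeline and reporting

`run_pipeline()` chains all stages and reports per-slab similarity
parameters, thresholds, surface-distance summaries, volumes, and the
full-chain landmark evaluation; reports are written as per-slab CSV
plus summary CSV and plain-text transforms, and the whole run is
bit-reproducible from the seeds. Stage outputs are simply rewritten on
re-run: at these problem sizes every stage costs seconds, so
content-hash caching would add failure modes without benefit. Exit
codes of the command-line wrapper: 0 success, 2 configuration error,
3 stage failure.

## Known limitations

* Rigid/similarity/affine only — no deformable registration, so tissue
  damage or nonuniform shrinkage ends up in the error budget.
* The MI estimator is a plain histogram; heavily non-overlapping
  initialisations need the pre-search or a manual init.
* Landmark placement error is not simulated; real six-point protocols
  carry observer noise that propagates directly into the slice fits.
* The threshold rule is an extreme-value statistic of the contralateral
  region: a single bright artifact pixel there raises the threshold and
  shrinks the ROI. The protocol's interactive step had the same
  property; the largest-component filter mitigates the converse
  (satellite noise above threshold).
* 2D in-plane similarity per slab assumes the block held the brain
  parallel to the MRI slices; residual through-plane tilt is not
  modelled.
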