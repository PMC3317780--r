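# tractrepro

Scan–rescan reproducibility of tractography-derived tract morphology and
tract metrics, studied end-to-end on synthetic diffusion-MRI phantoms.

Tractography chains many estimation steps — diffusion tensor and fiber
orientation modeling, probabilistic streamline propagation, segmentation,
spatial normalization — and the uncertainty that accumulates along that
chain decides whether tract measures can detect pathology.  This package
implements the full chain and measures its test–retest behavior the way
scan–rescan studies do, but on phantoms with known ground truth and exactly
known inter-session motion, so every source of variability is controlled:

* **Phantoms** — multi-tensor fiber bundles (straight, arc, 90° crossing,
  fanning ends) rendered at 2 mm isotropic resolution, b = 1200 s/mm²,
  electrostatically spread gradient directions, Rician noise at b0 SNR 20;
  scan pairs with independent noise and a small known rigid perturbation.
* **Reconstruction** — per-voxel tensor fit (FA, ADC) and constrained
  spherical deconvolution (response from FA > 0.7 voxels, lmax = 8,
  45 spherical harmonics, non-negative FODs via interior-point constrained
  least squares).
* **Tracking** — probabilistic FOD rejection sampling (step 0.2 mm,
  curvature radius 1 mm ⇒ 11.478° per step, amplitude threshold 0.1),
  bidirectional from seed ROIs with target-ROI retention, in *proximal*
  (truncated at targets) and *extended* (to the edge of FOD support) modes,
  plus whole-mask seeding for track-density imaging (TDI).
* **Statistics** — Dice similarity coefficient of common-space
  segmentations, DSC = 2·N(t₁∩t₂)/(N(t₁)+N(t₂)); within-subject coefficient
  of variation COV = σ_ws/µ; one-way random-effects intraclass correlation
  ICC = (BSMSS − WSMSS)/(BSMSS + (k−1)·WSMSS); paired t-tests and
  Bland–Altman summaries.

## Worked example

A single scan–rescan pair on a fanning-end bundle, from simulation to the
two Dice coefficients:

```r
library(tractrepro)

scheme <- make_gradient_scheme(64, b_value = 1200, n_b0 = 1, seed = 7)
cfg    <- run_config(n_subjects = 1, tracts = "fanning", n_streamlines = 150)
geo    <- tractrepro:::phantom_tract_geometry("fanning", cfg, radius = 3.3)

pair <- make_session_pair(
  geo$bundles, scheme,
  sim_params   = list(grid_shape = c(20, 20, 40), voxel_size = 2,
                      s0 = 1000, noise_sigma = 50),          # b0 SNR 20
  perturbation = rigid_transform(rotation_matrix(c(0, 1, 0), 1),
                                 c(0.8, -0.5, 0.3)),
  seeds = c(3L, 4L))

common <- map_grid(c(20, 20, 40), pair$session_a$grid_to_world)
segs <- list()
for (s in list(list(dwi = pair$session_a, truth = pair$truth,
                    tc = pair$a_to_common, id = "a"),
               list(dwi = pair$session_b, truth = pair$truth_b_native,
                    tc = pair$b_to_common, id = "b"))) {
  tf   <- fit_tensor(s$dwi, scheme)
  resp <- estimate_response(s$dwi, scheme, tf, fa_threshold = 0.7)
  fod  <- csd_fit(s$dwi, scheme, resp, lmax = 8,
                  mask = tractrepro:::dilate_mask(s$truth$wm_mask))
  rois <- make_rois(s$truth, geo$roi_planes)
  for (mode in c("proximal", "extended")) {
    tg  <- track_tract(fod, rois$seed, rois$targets,
                       tracking_params(n_streamlines = 150), mode = mode,
                       seed = 101, brain_mask = array(TRUE, c(20, 20, 40)),
                       space = s$id)
    seg <- segment_from_density(density_map(tg, common), 0.05)
    segs[[paste(s$id, mode)]] <- apply_transform_mask(seg, s$tc, common, 0.01)
  }
}
c(prox = dice(segs[["a proximal"]], segs[["b proximal"]]),
  ext  = dice(segs[["a extended"]],  segs[["b extended"]]))
```

```
     prox       ext 
0.7852650 0.7555453 
```

Both sessions reconstruct the bundle with high overlap, and the proximal
segmentation (truncated before the fanning end) is more reproducible than
the extended one — the fanning region responds to noise differently in each
session, which is exactly the deep-vs-subcortical contrast this design
probes.  Over five replicate pairs the means are 0.79 (proximal) vs 0.72
(extended), with the ordering holding in every replicate.

## The analysis

The numbered scripts under `analysis/` run the full desk-scale study
(4 subjects × 2 sessions × 3 tract geometries):

```sh
Rscript analysis/01_simulate_phantoms.R
Rscript analysis/02_fit_models.R
Rscript analysis/03_track_tracts.R
Rscript analysis/04_segment_metrics.R
Rscript analysis/05_reproducibility.R
```

Tables land in `results/` (`tract_metrics.tsv`, `dsc_per_subject.tsv`,
`report_dsc.tsv`, `report_metrics.tsv`, `bland_altman.tsv`); imaging
volumes (NIfTI, TCK) in `scratch/`.  `run_pipeline()` exposes the same
chain as a single call.

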