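---
title: "Tract-specific reproducibility of CSD tractography on synthetic phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tract-specific reproducibility of CSD tractography on synthetic phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What this package computes

Tractography pipelines chain many estimation steps — tensor and fiber
orientation modeling, streamline propagation, segmentation, spatial
normalization — and each step contributes variability to the quantities a
clinical study would actually report: tract morphology and tract-averaged
metrics.  `tractrepro` implements that full chain on synthetic
diffusion-weighted phantoms with known ground truth, imaged twice under
independent noise and known rigid inter-session motion, and quantifies
test–retest reproducibility the way scan–rescan studies do:

* **morphology** — Dice similarity coefficient (DSC) of binary tract
  segmentations compared in a common space,
  $DSC = 2\,N(t_1 \cap t_2) / (N(t_1) + N(t_2))$;
* **metrics** — per-tract mean FA, mean ADC, volume and mean track density
  (TDI), summarized by the within-subject coefficient of variation
  $COV = \sigma_{ws}/\mu$ and the one-way random-effects intraclass
  correlation coefficient
  $ICC = (BSMSS - WSMSS)\,/\,(BSMSS + (k-1)\,WSMSS)$;
* **proximal vs. extended** — every tract is segmented twice, once
  truncated at its target regions (deep white matter analogue) and once
  propagated to the edge of FOD support (including the degraded, fanning
  ends), with paired t-tests between the two.

Because no real scan–rescan data are bundled, all empirical statements the
package makes are about its phantoms; the test suite and
`scripts/acceptance.R` recompute every number reported anywhere in this
documentation.

## The phantom generator

`simulate_dwi()` renders fiber bundles (straight, arc, crossing components,
and fanning geometries) into a multi-tensor signal
$S(g) = S_0\left(\sum_i f_i e^{-b\,g^\top D_i g} + f_{bg} e^{-b\,ADC_{bg}}\right)$
on a 2 mm isotropic grid at $b = 1200$ s/mm², with gradient directions
spread by antipodally symmetric electrostatic repulsion and a single
$b = 0$ volume.  Key choices, fixed once:

* **Eigenvalues** $(1.7, 0.2, 0.2)\times 10^{-3}$ mm²/s for coherent white
  matter (FA 0.87), an isotropic background of $0.9\times10^{-3}$ mm²/s — a
  gray-matter-like surround that keeps background FOD amplitudes below the
  0.1 tracking threshold, so streamlines terminate where coherent structure
  ends.
* **Partial volume** — per-voxel bundle fractions come from a 3× supersampled
  voxel subdivision (27 subpoints), giving reproducible partial-volume
  behavior at bundle boundaries, the phenomenon that degrades subcortical
  tracking in vivo.
* **Noise** — Rician (magnitude of a complex Gaussian perturbation), the
  standard model for magnitude MR data.  The b0 signal-to-noise ratio is
  defined as in-mask mean(b0)/`noise_sigma`; the study conditions use
  SNR 20.  (The SNR estimator had to be fixed here because scan-rescan
  reports usually quote SNR without defining the estimator.)
* **Sessions** — a scan pair shares one ground truth; session B's anatomy is
  rigidly displaced (≤ 1 voxel translation, ≤ 2° rotation) and its
  `b_to_common` transform is the exact inverse of the applied motion.
  Registration *estimation* is deliberately out of scope: phantom sessions
  carry ground-truth transforms, so reproducibility numbers isolate
  noise- and sampling-driven variability from registration error.
* **Between-subject variation** — the cohort driver varies bundle radius
  (8% log-normal) and the leading eigenvalue (4%) across subjects, giving
  the between-subject variance without which ICC is undefined in practice.

What the phantoms do **not** emulate: EPI distortion, eddy currents,
motion during a scan, multi-shell acquisitions, or realistic anatomy.
Passing tests therefore demonstrate the pipeline's internal consistency and
its sensitivity to noise/partial-volume effects — not performance on real
brains.

## Reconstruction

`fit_tensor()` is ordinary least squares on the log signal
($\ln S = \ln S_0 - b\,g^\top D g$), exactly invertible on noise-free data;
voxels with non-positive signal are excluded, negative eigenvalues are
clamped to zero and flagged rather than dropped so tract means stay defined.

`estimate_response()` selects voxels with FA > 0.7, rotates the gradient
scheme so each voxel's principal eigenvector maps to $+z$, fits even-order
zonal harmonics, and averages — alignment removes orientation, which is what
makes averaging a noise reduction.  `csd_fit()` then deconvolves the
b0-normalized signal by the response in a real orthonormal even-order SH
basis with $l_{max} = 8$ (45 coefficients; ordering $l$ ascending then $m$
ascending, a purely internal convention).

The non-negativity constraint is implemented as inequality-constrained
least squares: directions of a fixed antipodally symmetric 300-point set
whose amplitude falls below $\tau = 0.1 \times$ the mean initial amplitude
join a monotonically growing constraint set on which the FOD must be
non-negative.  The constrained problem is solved by a log-barrier
interior-point method from a strictly feasible isotropic start, so the
returned FOD satisfies the constraint *by construction* (iterates never
leave the feasible cone).  Soft-penalty and primal active-set alternatives
were rejected during development: the former leaves negative lobes of a few
percent of the mean amplitude, and the latter cycles at the
dimension-limited vertex once more than 44 constraints activate.  Only the
150 unique directions of the 300-point set are constrained — even-order
bases satisfy amp(d) = amp(−d) identically, and the duplicate rows only
degrade the solver's conditioning.

## Tracking

Probabilistic streamlines are grown bidirectionally from each seed (the
seed ROIs are mid-tract cross-sections, so unidirectional growth would halve
sensitivity): an initial direction is drawn from the FOD over the whole
sphere, then each step samples uniformly within the curvature cone of
half-angle $2\arcsin(step/2R) = 11.478°$ (step 0.2 mm, radius 1 mm) and
accepts with probability proportional to the trilinearly interpolated FOD
amplitude; candidates below the 0.1 amplitude threshold always reject.  The
rejection envelope is the maximum of 12 cone probes times 1.5, capping
sampler bias at modest cost; the attempt cap is 1000 per step.  Proximal
half-tracks truncate at the first target-ROI entry; extended ones continue
to the edge of FOD support or the brain mask.  ROI and mask hits are tested
at quarter-step sub-samples of every segment so a 3-voxel-thick ROI cannot
be stepped over.  `max_length_mm` defaults to 10× the grid diagonal purely
as an infinite-loop guard.

Each seeding attempt runs on its own derived RNG substream, which has a
useful consequence: proximal and extended runs with the same seed draw
identical randomness, making every proximal streamline a truncation of its
extended counterpart — an invariant the test suite checks directly.

## Segmentation, metrics, statistics

Density maps count each streamline at most once per element (the natural
reading of "number of streamlines per voxel"); traversal clips every
segment exactly at voxel boundary-plane crossings, so streamline counts are
conserved against any independent voxel walk — an independently written
walker in the test suite checks exactly that.  (A faster sub-sampling
traversal was tried first and abandoned: it misses sub-millimeter corner
clips, which breaks exact conservation.)  Segmentations threshold at 5% of the
map maximum, inclusively (ties are deterministic).  Known transforms
resample the 0/1 field trilinearly and re-binarize at 0.01, again
inclusively.  Metrics are computed in native space, morphology in common
space, TDI on a 2× refined grid — the same division of labor as the
scan–rescan design this emulates.  $\sigma_{ws}$ is the square root of the
one-way within-subject mean square (for $k = 2$,
$\sqrt{\sum_i d_i^2 / 2n}$); $\mu$ is the grand mean, which coincides with
the mean of subject means for the balanced panels this pipeline produces.
Subjects with missing sessions are dropped per metric, never imputed;
p-values are reported raw.

## Problem sizes

The analysis scripts run 4 subjects × 2 sessions × 3 tract geometries on
20×20×40-voxel grids with 64 directions, 400 streamlines per tract and
8,000 whole-mask streamlines — the package's desk-scale defaults, scaled
down from the 128-direction / 10,000-streamline / 5,000,000-track
acquisition-scale design it emulates (scale factors are recorded in the
configuration object).  The test suite uses smaller quotas still.  Counts
are configuration, not method: every operation is identical at any scale.

## Known limitations

* The rejection sampler's envelope is probed, not exact; amplitudes above
  1.5× the probed maximum are accepted with certainty, slightly flattening
  the sampling distribution at very sharp FOD peaks.
* Hard non-negativity trades signal fit for positivity: a band-limited
  delta has negative ringing of about half its peak, so the non-negative
  FOD that best explains a sharp single-fiber signal leaves a residual of
  several percent RMS where a soft penalty would leave under 1% (and
  negative lobes).  The package prefers the exact constraint because the
  tracking threshold semantics assume non-negative amplitudes.
* Streamline coordinates serialize to TCK as little-endian Float32 (the
  format's standard datatype); round-trip precision is the Float32 spacing
  at the coordinate magnitude, about 5e-6 mm at 80 mm.
* Fanning geometry tilts directions about a virtual cone apex; the field is
  mildly discontinuous at the trunk–fan junction (well inside the per-step
  curvature allowance).
* The DSC-of-ICC variant some reports print is ambiguous for a single
  session pair per subject; the report emits mean ± between-subject SD of
  DSC instead, plus the paired proximal-vs-extended test.

## Interfaces

The numbered scripts under `analysis/` are the study drivers (simulate,
fit, track, segment/measure, summarize); each is a thin narrative over the
exported functions, writes tables to `results/` and volumes to `scratch/`.
`run_pipeline()` packages the same chain as one call for programmatic use
and for the test suite.  No shell CLI beyond `Rscript` is provided — for an
analysis artifact the scripts and the package surface are the interface.
On-disk formats are NIfTI-1 (+ FSL-style bvals/bvecs), MRtrix TCK for
streamlines, TSV for tables, with JSON sidecars recording the SH basis
convention and response coefficients.
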