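#!/usr/bin/env Rscript
# Stage 1: simulate the phantom cohort.
#
# For every subject and tract geometry, generates a scan-rescan session pair:
# the same ground-truth fiber bundles imaged twice with independent Rician
# noise, session B rigidly perturbed (<= 1 mm translation, <= 1 degree
# rotation) with the exactly known inverse stored alongside.  Between-subject
# anatomy varies through the bundle radius and the leading tensor eigenvalue.
# Writes each session as NIfTI + bvals/bvecs under scratch/ and the full
# simulation state for the later stages.

source("analysis/00_config.R")

scheme <- make_gradient_scheme(CFG$n_directions, CFG$b_value, CFG$n_b0,
                               seed = substream_seed(MASTER_SEED, "scheme"))
noise_sigma <- CFG$s0 / CFG$snr

cohort <- list()
for (subj in seq_len(CFG$n_subjects)) {
  set.seed(substream_seed(MASTER_SEED, "subject-anatomy", subj))
  radius <- CFG$bundle_radius_mm * exp(rnorm(1, 0, CFG$radius_jitter_frac))
  ev <- CFG$eigenvalues
  ev[1] <- ev[1] * exp(rnorm(1, 0, CFG$lambda1_jitter_frac))
  perturb <- tractrepro:::draw_perturbation(
    CFG, substream_seed(MASTER_SEED, "subject-motion", subj))

  for (tract in CFG$tracts) {
    geo <- tractrepro:::phantom_tract_geometry(tract, CFG, radius)
    pair <- make_session_pair(
      geo$bundles, scheme,
      sim_params = list(grid_shape = CFG$grid_shape,
                        voxel_size = CFG$voxel_size, s0 = CFG$s0,
                        eigenvalues = ev, noise_sigma = noise_sigma,
                        bg_adc = CFG$bg_adc),
      perturbation = perturb,
      seeds = c(substream_seed(MASTER_SEED, sprintf("s%d-%s-a", subj, tract)),
                substream_seed(MASTER_SEED, sprintf("s%d-%s-b", subj, tract))))
    key <- sprintf("sub%02d_%s", subj, tract)
    write_dwi(pair$session_a, file.path(SCRATCH_DIR, paste0(key, "_sesA")))
    write_dwi(pair$session_b, file.path(SCRATCH_DIR, paste0(key, "_sesB")))
    write_nifti_volume(pair$truth$wm_mask + 0L,
                       file.path(SCRATCH_DIR, paste0(key, "_wm.nii.gz")),
                       pair$truth$grid_to_world, "uint8")
    cohort[[key]] <- list(subject = subj, tract = tract, pair = pair,
                          geo = geo, radius = radius, eigenvalues = ev)
    message(key, ": wm voxels ", sum(pair$truth$wm_mask),
            ", b0 SNR ", round(mean(pair$session_a$signal[, , , 1][
              pair$truth$wm_mask]) / noise_sigma, 1))
  }
}

saveRDS(list(scheme = scheme, cohort = cohort, noise_sigma = noise_sigma),
        state_path("01_cohort"))
message("simulated ", length(cohort), " subject-tract session pairs")
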