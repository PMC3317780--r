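#!/usr/bin/env Rscript
# Stage 2: per-session reconstruction.
#
# Fits the diffusion tensor (FA/ADC maps), estimates the single-fiber
# response from FA > 0.7 voxels, and deconvolves the constrained FODs
# (lmax = 8, 45 coefficients) in a dilated white-matter neighborhood.
# The response is estimated per session, so session differences propagate
# through the full reconstruction chain exactly as in a scan-rescan study.

source("analysis/00_config.R")

st <- readRDS(state_path("01_cohort"))
fits <- list()
for (key in names(st$cohort)) {
  entry <- st$cohort[[key]]
  sessions <- list(A = list(dwi = entry$pair$session_a,
                            truth = entry$pair$truth),
                   B = list(dwi = entry$pair$session_b,
                            truth = entry$pair$truth_b_native))
  for (sn in names(sessions)) {
    se <- sessions[[sn]]
    tf <- fit_tensor(se$dwi, st$scheme)
    resp <- estimate_response(se$dwi, st$scheme, tf,
                              fa_threshold = CFG$fa_thresh, lmax = CFG$lmax)
    fod <- csd_fit(se$dwi, st$scheme, resp, lmax = CFG$lmax,
                   mask = tractrepro:::dilate_mask(se$truth$wm_mask))
    pre <- file.path(SCRATCH_DIR, sprintf("%s_ses%s", key, sn))
    write_nifti_volume(tf$fa, paste0(pre, "_fa.nii.gz"), tf$grid_to_world)
    write_nifti_volume(tf$adc, paste0(pre, "_adc.nii.gz"), tf$grid_to_world)
    write_nifti_volume(fod$coeffs, paste0(pre, "_fod.nii.gz"),
                       fod$grid_to_world)
    jsonlite::write_json(
      list(lmax = CFG$lmax,
           basis = "real orthonormal, even degrees, l ascending then m ascending",
           response_zonal = resp$zonal_coeffs,
           n_response_voxels = resp$n_voxels_used),
      paste0(pre, "_fod.json"), auto_unbox = TRUE, digits = NA)
    fits[[paste0(key, "_", sn)]] <- list(tensor = tf, response = resp,
                                         fod = fod)
    message(key, " ses", sn, ": response from ", resp$n_voxels_used,
            " voxels, ", sum(fod$nonconverged), " non-converged FODs")
  }
}
saveRDS(fits, state_path("02_fits"))
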