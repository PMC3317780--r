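#!/usr/bin/env Rscript
# Stage 3: probabilistic tractography.
#
# For every session: tract tracking from the seed ROI with target-ROI
# retention, once truncated at the targets (proximal) and once continued to
# the edge of FOD support (extended), plus whole-mask seeding for track
# density imaging.  Streamlines are written as TCK.

source("analysis/00_config.R")

st <- readRDS(state_path("01_cohort"))
fits <- readRDS(state_path("02_fits"))
params <- tracking_params(step_mm = CFG$step_mm,
                          curvature_radius_mm = CFG$curvature_radius_mm,
                          fod_threshold = CFG$fod_threshold,
                          n_streamlines = CFG$n_streamlines)
brain <- array(TRUE, CFG$grid_shape)

tracks <- list()
for (key in names(st$cohort)) {
  entry <- st$cohort[[key]]
  truths <- list(A = entry$pair$truth, B = entry$pair$truth_b_native)
  for (sn in c("A", "B")) {
    fit <- fits[[paste0(key, "_", sn)]]
    rois <- make_rois(truths[[sn]], entry$geo$roi_planes)
    for (mode in CFG$modes) {
      tg <- track_tract(fit$fod, rois$seed, rois$targets, params, mode = mode,
                        seed = substream_seed(MASTER_SEED,
                                              paste(key, sn, sep = "-")),
                        brain_mask = brain, space = sn)
      write_tck(tg, file.path(SCRATCH_DIR,
                              sprintf("%s_ses%s_%s.tck", key, sn, mode)))
      tracks[[paste(key, sn, mode)]] <- tg
      message(sprintf("%s ses%s %s: %d streamlines, acceptance %.0f%%",
                      key, sn, mode, length(tg$streamlines),
                      100 * tg$acceptance_rate))
    }
    wb <- track_whole_mask(fit$fod, truths[[sn]]$wm_mask,
                           CFG$n_tdi_streamlines, params,
                           seed = substream_seed(MASTER_SEED,
                                                 paste(key, sn, "tdi",
                                                       sep = "-")),
                           brain_mask = brain, space = sn)
    tracks[[paste(key, sn, "whole")]] <- wb
  }
}
saveRDS(tracks, state_path("03_tracks"))
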