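# One scan-rescan replicate on the fanning-end phantom: simulate two
# sessions (independent noise, small known rigid motion), reconstruct,
# track proximally and extended, segment, map to common space, and return
# both Dice coefficients.
fanning_dsc_replicate <- function(rep_seed, n_streamlines = 120) {
  cfg <- run_config(n_subjects = 1, tracts = "fanning",
                    n_streamlines = n_streamlines)
  sch <- fixture("scheme64")
  geo <- tractrepro:::phantom_tract_geometry("fanning", cfg, 3.3)
  perturb <- rigid_transform(rotation_matrix(c(0, 1, 0), 1), c(0.8, -0.5, 0.3))
  pair <- make_session_pair(
    geo$bundles, sch,
    sim_params = list(grid_shape = c(20, 20, 40), voxel_size = 2, s0 = 1000,
                      eigenvalues = c(1.7e-3, 0.2e-3, 0.2e-3),
                      noise_sigma = 50),
    perturbation = perturb, seeds = c(rep_seed * 2 + 1, rep_seed * 2 + 2))
  common_grid <- map_grid(c(20, 20, 40), pair$session_a$grid_to_world)
  segs <- list()
  sessions <- list(
    a = list(dwi = pair$session_a, truth = pair$truth, tc = pair$a_to_common),
    b = list(dwi = pair$session_b, truth = pair$truth_b_native,
             tc = pair$b_to_common))
  for (sn in names(sessions)) {
    se <- sessions[[sn]]
    rois <- make_rois(se$truth, geo$roi_planes)
    tf <- fit_tensor(se$dwi, sch)
    resp <- estimate_response(se$dwi, sch, tf, 0.7, 8)
    fod <- csd_fit(se$dwi, sch, resp, 8, mask = dilate_once(se$truth$wm_mask))
    brain <- array(TRUE, c(20, 20, 40))
    ng <- map_grid(c(20, 20, 40), se$dwi$grid_to_world)
    for (mode in c("proximal", "extended")) {
      tg <- track_tract(fod, rois$seed, rois$targets,
                        tracking_params(n_streamlines = n_streamlines),
                        mode = mode, seed = rep_seed * 100 + 1,
                        brain_mask = brain, space = sn)
      seg <- segment_from_density(density_map(tg, ng), 0.05)
      segs[[paste(sn, mode)]] <- apply_transform_mask(seg, se$tc, common_grid,
                                                      0.01)
    }
  }
  c(prox = dice(segs[["a proximal"]], segs[["b proximal"]]),
    ext = dice(segs[["a extended"]], segs[["b extended"]]))
}
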