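# End-to-end pipeline: phantom cohort -> tensor + CSD fits -> proximal /
# extended tract tracking + whole-mask TDI -> segmentations, metrics,
# common-space comparison -> reproducibility report.
#
# Desk-scale defaults (recorded in the report header): 20x20x40 grids at
# 2 mm, 64 gradient directions, 1000 streamlines per tract, 20000 whole-mask
# streamlines, scaled down from the acquisition-scale 128 / 10,000 /
# 5,000,000 the pipeline emulates.

PIPELINE_DEFAULTS <- list(
  n_subjects = 2L,
  tracts = c("straight", "crossing"),
  grid_shape = c(20L, 20L, 40L),
  voxel_size = 2,
  n_directions = 64L,
  b_value = 1200,
  n_b0 = 1L,
  s0 = 1000,
  snr = 20,
  eigenvalues = c(1.7e-3, 0.2e-3, 0.2e-3),
  bg_adc = 0.9e-3,
  bundle_radius_mm = 4,
  radius_jitter_frac = 0.08,      # between-subject anatomy variation
  lambda1_jitter_frac = 0.04,
  perturb_max_translation_mm = 1, # session-B rigid motion bounds
  perturb_max_rotation_deg = 1,
  step_mm = 0.2,
  curvature_radius_mm = 1.0,
  fod_threshold = 0.1,
  lmax = 8L,
  fa_thresh = 0.7,
  n_streamlines = 1000L,
  n_tdi_streamlines = 20000L,
  sr_factor = 2L,
  segment_fraction = 0.05,
  rebinarize_threshold = 0.01,
  modes = c("proximal", "extended"),
  write_volumes = FALSE
)

#' Validated pipeline configuration
#'
#' Returns the default configuration with any overrides applied; unknown
#' keys are rejected.  Defaults equal the acquisition-matched parameter
#' values where one exists (step 0.2 mm, curvature radius 1 mm, FOD
#' threshold 0.1, segmentation fraction 0.05, re-binarization 0.01, lmax 8,
#' response FA threshold 0.7, b = 1200 s/mm^2) and desk-scale sizes
#' elsewhere.
#'
#' @param ... named overrides of the defaults.
#' @return named list of class `run_config`.
#' @export
run_config <- function(...) {
  over <- list(...)
  unknown <- setdiff(names(over), names(PIPELINE_DEFAULTS))
  if (length(unknown) > 0)
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  cfg <- PIPELINE_DEFAULTS
  cfg[names(over)] <- over
  if (sh_basis_size(cfg$lmax) > cfg$n_directions)
    stop("n_directions must be >= the SH coefficient count for the chosen lmax")
  stopifnot(cfg$n_subjects >= 1, all(cfg$modes %in% c("proximal", "extended")))
  structure(cfg, class = "run_config")
}

# bundle geometry + ROI planes for one named phantom tract, centred in the
# grid; all positions in world mm
phantom_tract_geometry <- function(tract, cfg, radius, grid_shape = cfg$grid_shape) {
  vs <- cfg$voxel_size
  ext <- grid_shape * vs                 # world extent
  cx <- (grid_shape[1] - 1) * vs / 2     # center of the grid, world mm
  cy <- (grid_shape[2] - 1) * vs / 2
  zlo <- 4 * vs
  zhi <- ext[3] - 4 * vs - vs
  mid_k <- round(grid_shape[3] / 2)
  lo_k <- round(zlo / vs) + 2L
  hi_k <- grid_shape[3] - (round(zlo / vs) + 3L)
  main <- switch(tract,
    straight = bundle_straight(c(cx, cy, zlo), c(cx, cy, zhi), radius,
                               name = "straight"),
    crossing = bundle_straight(c(cx, cy, zlo), c(cx, cy, zhi), radius,
                               kind = "crossing-component", name = "crossing-main"),
    fanning = fiber_bundle(
      cbind(cx, cy, seq(zlo, zhi, length.out = 60)), radius,
      kind = "fanning", fan_frac = 0.62, spread = 0.35, name = "fanning"),
    arc = bundle_arc(center = c(cx - 0.3 * ext[1], cy, zlo + 4),
                     arc_radius = 0.45 * ext[3], from_deg = 10, to_deg = 80,
                     u = c(1, 0, 0), v = c(0, 0, 1), radius = radius,
                     name = "arc"),
    stop("unknown tract kind: ", tract))
  extra <- if (tract == "crossing") {
    mid_z <- (zlo + zhi) / 2
    list(bundle_straight(c(2 * vs, cy, mid_z), c(ext[1] - 3 * vs, cy, mid_z),
                         radius, kind = "crossing-component",
                         name = "crossing-secondary"))
  } else list()
  rois <- if (tract == "arc") {
    # end cross-sections of the arc: one near-vertical, one near-horizontal
    list(list(axis = 3L, index = mid_k, bundle = 1L),
         list(axis = 1L, index = lo_k, bundle = 1L),
         list(axis = 3L, index = hi_k, bundle = 1L))
  } else if (tract == "fanning") {
    fan_k <- round(0.55 * grid_shape[3])  # target just before the fan
    list(list(axis = 3L, index = round(0.35 * grid_shape[3]), bundle = 1L),
         list(axis = 3L, index = lo_k, bundle = 1L),
         list(axis = 3L, index = fan_k, bundle = 1L))
  } else {
    list(list(axis = 3L, index = mid_k, bundle = 1L),
         list(axis = 3L, index = lo_k, bundle = 1L),
         list(axis = 3L, index = hi_k, bundle = 1L))
  }
  list(bundles = c(list(main), extra), roi_planes = rois)
}

# random small rigid perturbation for a session pair
draw_perturbation <- function(cfg, seed) {
  set.seed(substream_seed(seed, "perturbation"))
  tr <- runif(3, -1, 1) * cfg$perturb_max_translation_mm
  ax <- rnorm(3)
  ang <- runif(1, -1, 1) * cfg$perturb_max_rotation_deg
  rigid_transform(rotation_matrix(ax, ang), tr)
}

#' Run the full reproducibility pipeline
#'
#' Simulates a cohort of phantom subjects (two sessions each, independent
#' noise, small known rigid motion), fits tensors and CSD FODs per session,
#' tracks every configured tract in proximal and extended mode, builds
#' native-space segmentations and metrics, maps segmentations to common
#' space for Dice comparison, runs whole-mask tractography for TDI, and
#' assembles the reproducibility report.
#'
#' @param config `run_config`.
#' @param out_dir output directory for tables (and volumes when
#'   `write_volumes`); created if missing.  `NULL` writes nothing.
#' @param seed master RNG seed; all stages derive named substreams from it.
#' @return list with `report` (`repro_report`), `metrics` (long data.frame),
#'   `dsc_table`, `panels`, `config`, and (if written) `files`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL, seed = 1L) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  scheme <- make_gradient_scheme(cfg$n_directions, cfg$b_value, cfg$n_b0,
                                 seed = substream_seed(seed, "scheme"))
  noise_sigma <- cfg$s0 / cfg$snr
  params <- tracking_params(step_mm = cfg$step_mm,
                            curvature_radius_mm = cfg$curvature_radius_mm,
                            fod_threshold = cfg$fod_threshold,
                            n_streamlines = cfg$n_streamlines)
  metrics_rows <- list()
  dsc_rows <- list()
  files <- character(0)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  for (subj in seq_len(cfg$n_subjects)) {
    set.seed(substream_seed(seed, "subject-anatomy", subj))
    radius <- cfg$bundle_radius_mm *
      exp(rnorm(1, 0, cfg$radius_jitter_frac))
    ev <- cfg$eigenvalues
    ev[1] <- ev[1] * exp(rnorm(1, 0, cfg$lambda1_jitter_frac))
    perturb <- draw_perturbation(cfg, substream_seed(seed, "subject-motion", subj))

    for (tract in cfg$tracts) {
      geo <- phantom_tract_geometry(tract, cfg, radius)
      pair <- make_session_pair(
        geo$bundles, scheme,
        sim_params = list(grid_shape = cfg$grid_shape,
                          voxel_size = cfg$voxel_size, s0 = cfg$s0,
                          eigenvalues = ev, noise_sigma = noise_sigma,
                          bg_adc = cfg$bg_adc),
        perturbation = perturb,
        seeds = c(substream_seed(seed, sprintf("s%d-%s-a", subj, tract)),
                  substream_seed(seed, sprintf("s%d-%s-b", subj, tract))))
      common_grid <- map_grid(cfg$grid_shape, pair$session_a$grid_to_world)

      sess_list <- list(a = list(dwi = pair$session_a, truth = pair$truth,
                                 to_common = pair$a_to_common),
                        b = list(dwi = pair$session_b,
                                 truth = pair$truth_b_native,
                                 to_common = pair$b_to_common))
      segs_common <- list()
      for (sn in names(sess_list)) {
        ses <- sess_list[[sn]]
        rois <- make_rois(ses$truth, geo$roi_planes)
        tf <- fit_tensor(ses$dwi, scheme, mask = NULL)
        resp <- estimate_response(ses$dwi, scheme, tf,
                                  fa_threshold = cfg$fa_thresh,
                                  lmax = cfg$lmax)
        fit_region <- dilate_mask(dilate_mask(ses$truth$wm_mask))
        fod <- csd_fit(ses$dwi, scheme, resp, lmax = cfg$lmax,
                       mask = fit_region)
        brain <- array(TRUE, cfg$grid_shape)
        native_grid <- map_grid(cfg$grid_shape, ses$dwi$grid_to_world)
        tdi_grid <- refine_grid(native_grid, cfg$sr_factor)
        wb <- track_whole_mask(fod, ses$truth$wm_mask,
                               cfg$n_tdi_streamlines, params,
                               seed = substream_seed(seed,
                                 sprintf("s%d-%s-%s-tdi", subj, tract, sn)),
                               brain_mask = brain, space = sn)
        tdi_map <- density_map(wb, tdi_grid)

        for (mode in cfg$modes) {
          tg <- track_tract(fod, rois$seed, rois$targets, params,
                            mode = mode,
                            seed = substream_seed(seed,
                              sprintf("s%d-%s-%s", subj, tract, sn)),
                            brain_mask = brain, space = sn)
          dens <- density_map(tg, native_grid)
          seg <- segment_from_density(dens, cfg$segment_fraction)
          seg_tdi <- segment_from_density(
            super_resolution_tdi(tg, cfg$sr_factor, native_grid),
            cfg$segment_fraction)
          met <- tract_metrics(seg, tf$fa, tf$adc, tdi_map, seg_tdi)
          metrics_rows[[length(metrics_rows) + 1L]] <- data.frame(
            subject = subj, session = sn, tract = tract, mode = mode,
            mean_fa = met$mean_fa, mean_adc = met$mean_adc,
            volume_mm3 = met$volume_mm3, mean_tdi = met$mean_tdi,
            acceptance = tg$acceptance_rate, partial = tg$partial)
          segs_common[[paste(sn, mode)]] <- apply_transform_mask(
            seg, ses$to_common, common_grid, cfg$rebinarize_threshold)
          if (isTRUE(cfg$write_volumes) && !is.null(out_dir)) {
            pre <- file.path(out_dir, sprintf("sub%02d_%s_%s_%s", subj,
                                              tract, sn, mode))
            files <- c(files,
                       write_tck(tg, paste0(pre, ".tck")),
                       write_nifti_volume(dens$counts + 0L,
                                          paste0(pre, "_density.nii.gz"),
                                          dens$grid_to_world, "int32"),
                       write_nifti_volume(seg$mask + 0L,
                                          paste0(pre, "_seg.nii.gz"),
                                          seg$grid_to_world, "uint8"))
          }
        }
      }
      for (mode in cfg$modes) {
        dsc_rows[[length(dsc_rows) + 1L]] <- data.frame(
          subject = subj, tract = tract, mode = mode,
          dsc = dice(segs_common[[paste("a", mode)]],
                     segs_common[[paste("b", mode)]]))
      }
    }
  }

  metrics <- do.call(rbind, metrics_rows)
  dsc_table <- do.call(rbind, dsc_rows)

  panels <- list()
  for (tract in cfg$tracts) for (mode in cfg$modes)
    for (metric in c("mean_fa", "mean_adc", "volume_mm3", "mean_tdi")) {
      sub <- metrics[metrics$tract == tract & metrics$mode == mode, ]
      vals <- matrix(NA_real_, cfg$n_subjects, 2)
      for (s in seq_len(cfg$n_subjects)) {
        vals[s, 1] <- sub[[metric]][sub$subject == s & sub$session == "a"]
        vals[s, 2] <- sub[[metric]][sub$subject == s & sub$session == "b"]
      }
      panels[[length(panels) + 1L]] <-
        metric_panel(vals, metric_name = metric, tract_name = tract,
                     mode = mode)
    }

  report <- if (cfg$n_subjects >= 2) build_report(dsc_table, panels) else NULL

  if (!is.null(out_dir)) {
    files <- c(files,
               write_tsv(metrics, file.path(out_dir, "metrics.tsv")),
               write_tsv(dsc_table, file.path(out_dir, "dsc.tsv")))
    if (!is.null(report)) {
      files <- c(files,
                 write_tsv(report$dsc, file.path(out_dir, "report_dsc.tsv")),
                 write_tsv(report$metrics,
                           file.path(out_dir, "report_metrics.tsv")))
      ba_rows <- do.call(rbind, lapply(panels, function(p) {
        ba <- bland_altman(p)
        data.frame(tract = p$tract_name, mode = p$mode,
                   metric = p$metric_name, subject = seq_len(nrow(p$values)),
                   mean = ba$pairs$mean, difference = ba$pairs$difference,
                   bias = ba$bias, loa_low = ba$loa_low,
                   loa_high = ba$loa_high, slope = ba$slope,
                   slope_p = ba$slope_p)
      }))
      files <- c(files, write_tsv(ba_rows,
                                  file.path(out_dir, "bland_altman.tsv")))
    }
    manifest <- data.frame(file = basename(files),
                           md5 = unname(tools::md5sum(files)))
    files <- c(files, write_tsv(manifest, file.path(out_dir, "manifest.tsv")))
  }

  list(report = report, metrics = metrics, dsc_table = dsc_table,
       panels = panels, config = cfg, files = files)
}
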