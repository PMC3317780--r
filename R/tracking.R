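# Probabilistic streamline tractography by FOD rejection sampling:
# parameter container, curvature geometry, single-streamline propagation
# (bidirectional, compiled core), seed/target tract tracking with proximal /
# extended termination, and whole-mask seeding for track-density imaging.

TERMINATION_LABELS <- c("target-reached", "mask-exit", "low-amplitude",
                        "angle-fail", "max-length")

#' Tracking parameter set
#'
#' Defaults follow the acquisition-matched tracking configuration: step
#' 0.2 mm, maximum curvature radius 1 mm (turning angle 11.478 degrees per
#' step), FOD amplitude threshold 0.1 on b0-normalized FODs.
#'
#' @param step_mm step length (mm).
#' @param curvature_radius_mm maximum curvature radius (mm); must be at
#'   least `step_mm / 2`.
#' @param fod_threshold minimum FOD amplitude along an accepted direction.
#' @param max_length_mm maximum streamline length; default (`NULL`) resolves
#'   to 10 x the grid diagonal at tracking time.
#' @param n_streamlines retained-streamline quota for tract tracking.
#' @param max_attempts_per_step rejection-sampling attempt cap per step.
#' @param n_probe probe directions used to estimate the rejection envelope.
#' @param envelope_factor safety factor applied to the probed maximum.
#' @return object of class `tracking_params`.
#' @export
tracking_params <- function(step_mm = 0.2, curvature_radius_mm = 1.0,
                            fod_threshold = 0.1, max_length_mm = NULL,
                            n_streamlines = 10000L,
                            max_attempts_per_step = 1000L,
                            n_probe = 12L, envelope_factor = 1.5) {
  stopifnot(step_mm > 0, fod_threshold >= 0, n_streamlines >= 1)
  if (curvature_radius_mm < step_mm / 2)
    stop("curvature_radius_mm must be >= step_mm / 2 (a step is a chord of the curvature circle)")
  structure(list(step_mm = step_mm, curvature_radius_mm = curvature_radius_mm,
                 fod_threshold = fod_threshold, max_length_mm = max_length_mm,
                 n_streamlines = as.integer(n_streamlines),
                 max_attempts_per_step = as.integer(max_attempts_per_step),
                 n_probe = as.integer(n_probe),
                 envelope_factor = envelope_factor),
            class = "tracking_params")
}

#' Maximum turning angle implied by a curvature radius
#'
#' A step of length `step_mm` is a chord on the osculating circle of radius
#' `radius_mm`; the corresponding turning angle between consecutive steps is
#' `2 * asin(step / (2 * radius))`.  The defaults (0.2 mm, 1 mm) give
#' 11.478 degrees.
#'
#' @param step_mm step length (mm).
#' @param radius_mm curvature radius (mm).
#' @return maximum turning angle in degrees.
#' @export
max_angle_from_curvature <- function(step_mm, radius_mm) {
  if (radius_mm < step_mm / 2)
    stop("radius must be >= step / 2: a chord cannot exceed the diameter")
  2 * asin(step_mm / (2 * radius_mm)) * 180 / pi
}

#' Draw one propagation direction from an FOD by rejection sampling
#'
#' Candidates are drawn uniformly within the curvature cone around
#' `previous_dir` (uniformly over the whole sphere when `previous_dir` is
#' `NULL`, i.e. at seeding) and accepted with probability proportional to
#' the FOD amplitude; candidates below `fod_threshold` are always rejected.
#'
#' @param coeffs SH coefficient vector of the local FOD.
#' @param previous_dir previous step direction (unit 3-vector) or `NULL`.
#' @param params `tracking_params`.
#' @return unit 3-vector, or a zero-length numeric with attribute `reason`
#'   ("low-amplitude" or "angle-fail") on failure.
#' @export
sample_direction <- function(coeffs, previous_dir = NULL,
                             params = tracking_params()) {
  lmax <- lmax_from_ncoeffs(length(coeffs))
  theta_max <- max_angle_from_curvature(params$step_mm,
                                        params$curvature_radius_mm) * pi / 180
  propose <- function(n) {
    if (is.null(previous_dir)) {
      z <- runif(n, -1, 1)
      phi <- runif(n, 0, 2 * pi)
    } else {
      z <- 1 - runif(n) * (1 - cos(theta_max))
      phi <- runif(n, 0, 2 * pi)
    }
    r <- sqrt(pmax(0, 1 - z^2))
    d <- cbind(r * cos(phi), r * sin(phi), z)
    if (!is.null(previous_dir)) {
      u <- previous_dir / sqrt(sum(previous_dir^2))
      a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      b <- c(u[2] * a[3] - u[3] * a[2], u[3] * a[1] - u[1] * a[3],
             u[1] * a[2] - u[2] * a[1])
      b <- b / sqrt(sum(b^2))
      cc <- c(u[2] * b[3] - u[3] * b[2], u[3] * b[1] - u[1] * b[3],
              u[1] * b[2] - u[2] * b[1])
      d <- d %*% rbind(b, cc, u)
    }
    d
  }
  probes <- propose(max(params$n_probe, 12L))
  env <- max(fod_amplitude(coeffs, probes)) * params$envelope_factor
  if (env <= 0) return(structure(numeric(0), reason = "low-amplitude"))
  best <- -Inf
  tried <- 0L
  while (tried < params$max_attempts_per_step) {
    nbatch <- min(64L, params$max_attempts_per_step - tried)
    cand <- propose(nbatch)
    amp <- fod_amplitude(coeffs, cand)
    u <- runif(nbatch)
    best <- max(best, max(amp))
    ok <- which(amp >= params$fod_threshold & u * env < amp)
    if (length(ok) > 0) return(cand[ok[1], ])
    tried <- tried + nbatch
  }
  structure(numeric(0),
            reason = if (best < params$fod_threshold) "low-amplitude" else "angle-fail")
}

# max steps per half-track from the length cap
max_steps_per_half <- function(params, shfield) {
  len <- params$max_length_mm
  if (is.null(len)) {
    d <- dim(shfield$mask) * shfield$voxel_size
    len <- 10 * sqrt(sum(d^2))
  }
  max(1L, as.integer(ceiling(len / params$step_mm / 2)))
}

#' Propagate one bidirectional streamline
#'
#' Grows two half-tracks from the seed (the second is reversed and
#' concatenated), sampling each step direction from the trilinearly
#' interpolated FOD.  In proximal mode a half-track is truncated at its
#' first entry into a target ROI; in extended mode propagation continues to
#' the brain-mask edge; whole-mask mode ignores targets.
#'
#' @param shfield `sh_field`.
#' @param seed_point world-mm seed position (inside `brain_mask`).
#' @param params `tracking_params`.
#' @param stop_rois binary array marking target ROI voxels (or `NULL`).
#' @param brain_mask binary array; propagation terminates on exit.
#' @param mode "proximal", "extended", or "whole".
#' @param context precomputed tracking state (internal use by the tract
#'   trackers, which share one context across many seeds); `NULL` builds it.
#' @return object of class `streamline`: `points` (n x 3 world mm),
#'   `seed_point`, `termination` (length-2: forward, backward half),
#'   `reached` (logical, any target hit).
#' @export
propagate <- function(shfield, seed_point, params = tracking_params(),
                      stop_rois = NULL, brain_mask = NULL,
                      mode = c("proximal", "extended", "whole"),
                      context = NULL) {
  mode <- match.arg(mode)
  if (is.null(context))
    context <- tracking_context(shfield, stop_rois, brain_mask, params)
  dim3 <- dim(shfield$mask)
  vox <- round(drop(world_to_grid_points(shfield$grid_to_world, seed_point))) + 1
  if (any(vox < 1) || any(vox > dim3) ||
      !context$brain_mask[vox[1], vox[2], vox[3]])
    stop("seed point lies outside the brain mask")
  # the two half-tracks run on independent derived substreams so that a
  # proximal truncation of the forward half cannot shift the randomness of
  # the backward half (proximal tracks stay exact prefixes of extended ones)
  half_seeds <- sample.int(2147483646L, 2L)
  mode_int <- switch(mode, proximal = 0L, extended = 1L, whole = 2L)
  run_half <- function(phase, d0) {
    .propagate_half_cpp(context$coef_perm, context$dims,
                        context$brain_int, context$target_int,
                        context$w2v, shfield$lmax, as.numeric(seed_point),
                        phase, d0, params$step_mm, context$theta_max,
                        params$fod_threshold, context$max_steps, mode_int,
                        params$max_attempts_per_step, params$n_probe,
                        params$envelope_factor)
  }
  set.seed(half_seeds[1])
  fwd <- run_half(0L, c(0, 0, 0))
  if (!fwd$ok) {
    return(structure(list(points = matrix(as.numeric(seed_point), 1, 3),
                          seed_point = as.numeric(seed_point),
                          termination = TERMINATION_LABELS[c(fwd$term, fwd$term)],
                          reached = FALSE),
                     class = "streamline"))
  }
  set.seed(half_seeds[2])
  bwd <- run_half(1L, fwd$d0)
  n_b <- nrow(bwd$points)
  pts <- rbind(bwd$points[rev(seq_len(n_b)), , drop = FALSE],
               matrix(as.numeric(seed_point), 1, 3),
               fwd$points)
  structure(list(points = pts, seed_point = as.numeric(seed_point),
                 termination = TERMINATION_LABELS[c(fwd$term, bwd$term)],
                 reached = fwd$hit || bwd$hit),
            class = "streamline")
}

# precomputed per-tractogram tracking state: coefficient-first field layout,
# integer masks, world->voxel affine, step geometry
tracking_context <- function(shfield, stop_rois, brain_mask, params) {
  dim3 <- dim(shfield$mask)
  if (is.null(brain_mask)) brain_mask <- shfield$mask
  if (is.null(stop_rois)) stop_rois <- array(0L, dim3)
  list(coef_perm = as.numeric(aperm(shfield$coeffs, c(4, 1, 2, 3))),
       dims = as.integer(dim(shfield$coeffs)),
       brain_mask = brain_mask,
       brain_int = as.integer(brain_mask),
       target_int = as.integer(stop_rois),
       w2v = world_to_grid_matrix(shfield$grid_to_world),
       theta_max = max_angle_from_curvature(params$step_mm,
                                            params$curvature_radius_mm) * pi / 180,
       max_steps = max_steps_per_half(params, shfield))
}

# uniform random world point inside a random ROI voxel interior
draw_seed_point <- function(roi, affine) {
  idx <- which(roi)
  v <- arrayInd(idx[sample.int(length(idx), 1L)], dim(roi)) - 1
  drop(grid_to_world_points(affine, v + runif(3, -0.5, 0.5)))
}

new_tractogram <- function(streamlines, params, mode, space, seeds,
                           terminations, acceptance_rate, partial = FALSE) {
  structure(list(streamlines = streamlines, params = params, mode = mode,
                 space = space, seeds = seeds, terminations = terminations,
                 acceptance_rate = acceptance_rate, partial = partial),
            class = "tractogram")
}

#' @export
print.tractogram <- function(x, ...) {
  cat(sprintf("tractogram (%s): %d streamlines, acceptance %.1f%%%s\n",
              x$mode, length(x$streamlines), 100 * x$acceptance_rate,
              if (isTRUE(x$partial)) " [partial]" else ""))
  invisible(x)
}

#' Track a tract between seed and target ROIs
#'
#' Seeds are drawn uniformly at random from seed-ROI voxel interiors;
#' streamlines are retained only if they reach a target ROI.  Seeding
#' repeats until the quota `params$n_streamlines` is retained or the attempt
#' cap (100 x quota) is exhausted, in which case a partial tractogram is
#' returned with a warning.  Each attempt runs on its own derived RNG
#' substream, so proximal and extended runs with the same `seed` draw
#' identical per-streamline randomness.
#'
#' @param shfield `sh_field`.
#' @param seed_roi binary seed ROI array.
#' @param target_rois binary array or list of binary arrays.
#' @param params `tracking_params`.
#' @param mode "proximal" or "extended".
#' @param seed RNG seed.
#' @param brain_mask binary array (default: FOD mask).
#' @param space label recorded on the tractogram (e.g. session id).
#' @return `tractogram`.
#' @export
track_tract <- function(shfield, seed_roi, target_rois,
                        params = tracking_params(),
                        mode = c("proximal", "extended"), seed = 1L,
                        brain_mask = NULL, space = "native") {
  mode <- match.arg(mode)
  if (is.list(target_rois)) {
    tmask <- Reduce(`|`, target_rois)
  } else tmask <- target_rois
  if (!any(seed_roi) || !any(tmask)) stop("seed and target ROIs must be non-empty")
  dim3 <- dim(shfield$mask)
  stopifnot(all(dim(seed_roi) == dim3), all(dim(tmask) == dim3))
  if (is.null(brain_mask)) brain_mask <- shfield$mask

  quota <- params$n_streamlines
  cap <- 100L * quota
  ctx <- tracking_context(shfield, tmask, brain_mask, params)
  keep <- vector("list", quota)
  seeds_used <- matrix(NA_real_, quota, 3)
  terms <- character(0)
  n_keep <- 0L
  attempt <- 0L
  base <- substream_seed(seed, paste0("track-", space))
  while (n_keep < quota && attempt < cap) {
    attempt <- attempt + 1L
    set.seed(substream_seed(base, "streamline", attempt))
    sp <- draw_seed_point(seed_roi, shfield$grid_to_world)
    sl <- propagate(shfield, sp, params, mode = mode, context = ctx)
    terms <- c(terms, sl$termination)
    if (sl$reached && nrow(sl$points) >= 2) {
      n_keep <- n_keep + 1L
      keep[[n_keep]] <- sl
      seeds_used[n_keep, ] <- sp
    }
  }
  partial <- n_keep < quota
  if (partial) {
    warning(sprintf("tract tracking retained %d / %d streamlines after %d attempts",
                    n_keep, quota, attempt))
    keep <- keep[seq_len(n_keep)]
    seeds_used <- seeds_used[seq_len(n_keep), , drop = FALSE]
  }
  new_tractogram(keep, params, mode, space, seeds_used,
                 table(factor(terms, levels = TERMINATION_LABELS)),
                 acceptance_rate = n_keep / attempt, partial = partial)
}

#' Whole-mask tractography for track-density imaging
#'
#' Seeds uniformly over the white-matter mask with no target filtering;
#' streamlines with at least 2 points are retained.
#'
#' @param shfield `sh_field`.
#' @param wm_mask binary white-matter mask (seed domain).
#' @param n_streamlines number of seeding attempts retained or not.
#' @param params `tracking_params`.
#' @param seed RNG seed.
#' @param brain_mask propagation mask (default: FOD mask).
#' @param space label recorded on the tractogram.
#' @return `tractogram` with mode "whole-brain".
#' @export
track_whole_mask <- function(shfield, wm_mask, n_streamlines,
                             params = tracking_params(), seed = 1L,
                             brain_mask = NULL, space = "native") {
  if (!any(wm_mask)) stop("white-matter mask is empty")
  if (is.null(brain_mask)) brain_mask <- shfield$mask
  base <- substream_seed(seed, paste0("tdi-", space))
  ctx <- tracking_context(shfield, NULL, brain_mask, params)
  keep <- list()
  seeds_used <- NULL
  terms <- character(0)
  for (attempt in seq_len(n_streamlines)) {
    set.seed(substream_seed(base, "streamline", attempt))
    sp <- draw_seed_point(wm_mask, shfield$grid_to_world)
    sl <- propagate(shfield, sp, params, mode = "whole", context = ctx)
    terms <- c(terms, sl$termination)
    if (nrow(sl$points) >= 2) {
      keep[[length(keep) + 1L]] <- sl
      seeds_used <- rbind(seeds_used, sp)
    }
  }
  new_tractogram(keep, params, "whole-brain", space, seeds_used,
                 table(factor(terms, levels = TERMINATION_LABELS)),
                 acceptance_rate = length(keep) / n_streamlines)
}

# points of all streamlines stacked, with an index column
tractogram_points <- function(tractogram) {
  do.call(rbind, lapply(seq_along(tractogram$streamlines), function(i) {
    cbind(tractogram$streamlines[[i]]$points, i)
  }))
}
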