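# Synthetic diffusion phantoms: fiber bundle geometries, multi-tensor DWI
# signal with Rician noise, scan-rescan session pairs with exactly known
# rigid perturbations, and cross-sectional seed/target ROIs.
#
# The generator emulates the study conditions: 2 mm isotropic voxels,
# b = 1200 s/mm^2, electrostatically spread gradient directions + one b0,
# and SNR ~ 20 on the b0 (in-mask mean(b0) / noise_sigma).

DEFAULT_EIGENVALUES <- c(1.7e-3, 0.2e-3, 0.2e-3)  # mm^2/s, coherent white matter
DEFAULT_BG_ADC <- 0.9e-3                          # mm^2/s, isotropic background

#' Construct a fiber bundle
#'
#' A bundle is a tube of constant radius around an ordered 3-D centerline
#' (world mm).  `kind = "fanning"` additionally widens into a cone over the
#' last part of the centerline with fiber directions radiating from the
#' cone's virtual apex, emulating the fanning of subcortical projections.
#'
#' @param centerline m x 3 matrix of ordered world points (mm), consecutive
#'   spacing > 0.
#' @param radius bundle half-width (mm), > 0.
#' @param kind one of "straight", "arc", "crossing-component", "fanning".
#' @param fan_frac arc-length fraction at which fanning starts (fanning only).
#' @param spread envelope growth slope, mm of extra radius per mm of
#'   arc-length past the fan start (fanning only).
#' @param name optional label used in error messages.
#' @return object of class `fiber_bundle`.
#' @export
fiber_bundle <- function(centerline, radius,
                         kind = c("straight", "arc", "crossing-component", "fanning"),
                         fan_frac = 0.6, spread = 0.35, name = NULL) {
  kind <- match.arg(kind)
  centerline <- as.matrix(centerline)
  stopifnot(ncol(centerline) == 3, nrow(centerline) >= 2, radius > 0)
  seg <- diff(centerline)
  if (any(sqrt(rowSums(seg^2)) <= 0))
    stop("centerline points must be strictly ordered (consecutive spacing > 0)")
  structure(list(centerline = unname(centerline), radius = radius, kind = kind,
                 fan_frac = fan_frac, spread = spread,
                 name = if (is.null(name)) kind else name),
            class = "fiber_bundle")
}

#' Straight bundle between two world points
#' @param from,to endpoints (world mm).
#' @param radius bundle radius (mm).
#' @param n centerline points.
#' @param ... passed to [fiber_bundle()].
#' @export
bundle_straight <- function(from, to, radius, n = 50,
                            kind = "straight", ...) {
  t <- seq(0, 1, length.out = n)
  cl <- outer(1 - t, from) + outer(t, to)
  fiber_bundle(cl, radius, kind = kind, ...)
}

#' Circular-arc bundle
#' @param center arc center (world mm).
#' @param arc_radius radius of the centerline arc (mm).
#' @param from_deg,to_deg arc angle range (degrees) in the plane spanned by
#'   `u` and `v`.
#' @param u,v orthonormal in-plane axes.
#' @param radius bundle radius (mm).
#' @param n centerline points.
#' @param ... passed to [fiber_bundle()].
#' @export
bundle_arc <- function(center, arc_radius, from_deg, to_deg,
                       u = c(1, 0, 0), v = c(0, 0, 1), radius, n = 80, ...) {
  a <- seq(from_deg, to_deg, length.out = n) * pi / 180
  cl <- matrix(rep(center, each = n), n, 3) +
    arc_radius * (outer(cos(a), u) + outer(sin(a), v))
  fiber_bundle(cl, radius, kind = "arc", ...)
}

# arc-length profile of a centerline
centerline_arclength <- function(cl) {
  c(0, cumsum(sqrt(rowSums(diff(cl)^2))))
}

# Closest-point query against a polyline.  Returns, per query point:
# distance, arc-length position, and unit tangent of the nearest segment.
polyline_closest <- function(cl, pts) {
  n <- nrow(pts)
  m <- nrow(cl) - 1
  s0 <- centerline_arclength(cl)
  best_d2 <- rep(Inf, n)
  best_s <- numeric(n)
  best_seg <- integer(n)
  best_t <- numeric(n)
  for (i in seq_len(m)) {
    a <- cl[i, ]; b <- cl[i + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    ap <- sweep(pts, 2, a)
    t <- pmin(1, pmax(0, (ap %*% ab) / len2))
    proj <- outer(drop(t), ab)
    d2 <- rowSums((ap - proj)^2)
    upd <- d2 < best_d2
    if (any(upd)) {
      best_d2[upd] <- d2[upd]
      best_t[upd] <- t[upd]
      best_seg[upd] <- i
      best_s[upd] <- s0[i] + t[upd] * sqrt(len2)
    }
  }
  tangents <- diff(cl) / sqrt(rowSums(diff(cl)^2))
  list(dist = sqrt(best_d2), s = best_s, tangent = tangents[best_seg, , drop = FALSE])
}

# local envelope radius at arc-length s
bundle_radius_at <- function(bundle, s, total_len) {
  if (bundle$kind != "fanning") return(rep(bundle$radius, length(s)))
  s_fan <- bundle$fan_frac * total_len
  bundle$radius + bundle$spread * pmax(0, s - s_fan)
}

# true fiber direction at world points (rows of pts); uses the nearest
# centerline tangent, tilted radially past the fan start for fanning bundles
bundle_directions_at <- function(bundle, pts, closest = NULL) {
  if (is.null(closest)) closest <- polyline_closest(bundle$centerline, pts)
  dirs <- closest$tangent
  if (bundle$kind == "fanning") {
    total_len <- max(centerline_arclength(bundle$centerline))
    s_fan <- bundle$fan_frac * total_len
    past <- closest$s > s_fan
    if (any(past)) {
      # directions radiate from the cone's virtual apex on the trunk axis
      cl_fun <- function(s) {
        sl <- centerline_arclength(bundle$centerline)
        i <- findInterval(s, sl, all.inside = TRUE)
        t <- (s - sl[i]) / (sl[i + 1] - sl[i])
        bundle$centerline[i, ] * (1 - t) + bundle$centerline[i + 1, ] * t
      }
      fan_pt <- cl_fun(s_fan)
      tang <- polyline_closest(bundle$centerline,
                               matrix(fan_pt, 1, 3))$tangent[1, ]
      apex <- fan_pt - (bundle$radius / bundle$spread) * tang
      v <- sweep(pts[past, , drop = FALSE], 2, apex)
      dirs[past, ] <- v / sqrt(rowSums(v^2))
    }
  }
  dirs
}

# does every centerline point (padded by radius) fall inside the grid?
bundle_inside_grid <- function(bundle, dim3, affine) {
  lo <- grid_to_world_points(affine, c(-0.5, -0.5, -0.5))
  hi <- grid_to_world_points(affine, dim3 - 0.5)
  n <- nrow(bundle$centerline)
  all(bundle$centerline >= matrix(as.numeric(lo), n, 3, byrow = TRUE)) &&
    all(bundle$centerline <= matrix(as.numeric(hi), n, 3, byrow = TRUE))
}

#' Simulate a diffusion-weighted volume from fiber bundles
#'
#' Noise-free signal per voxel follows the multi-tensor mixture
#' \deqn{S(g) = S_0 (\sum_i f_i e^{-b g^T D_i g} + f_{bg} e^{-b ADC_{bg}})}
#' with volume fractions from bundle occupancy (3x supersampled voxel
#' subdivision) and an isotropic background compartment.  Rician noise
#' (magnitude of a complex Gaussian perturbation) is applied when
#' `noise_sigma > 0`.
#'
#' @param bundles list of [fiber_bundle()] objects.
#' @param scheme [make_gradient_scheme()] result.
#' @param grid_shape voxel counts per axis (length 3).
#' @param voxel_size mm per axis (scalar or length 3).
#' @param s0 non-diffusion-weighted intensity.
#' @param eigenvalues tensor eigenvalues (mm^2/s), descending; a single
#'   3-vector applied to all bundles or a list with one 3-vector per bundle.
#' @param noise_sigma Rician noise level (intensity units); the b0 SNR is
#'   `s0 / noise_sigma`.
#' @param seed RNG seed for the noise substream.
#' @param bg_adc isotropic background diffusivity (mm^2/s).
#' @return list with elements `dwi` (class `dwi_volume`) and `truth`
#'   (class `phantom_truth`).
#' @export
simulate_dwi <- function(bundles, scheme, grid_shape, voxel_size = 2,
                         s0 = 1000, eigenvalues = DEFAULT_EIGENVALUES,
                         noise_sigma = 0, seed = 1L, bg_adc = DEFAULT_BG_ADC) {
  if (inherits(bundles, "fiber_bundle")) bundles <- list(bundles)
  nb <- length(bundles)
  if (!is.list(eigenvalues) || is.numeric(eigenvalues[[1]]) && length(eigenvalues) == 3 && !is.list(eigenvalues))
    eigenvalues <- rep(list(as.numeric(unlist(eigenvalues)[1:3])), nb)
  stopifnot(length(eigenvalues) == nb, noise_sigma >= 0)
  for (ev in eigenvalues) {
    if (!(ev[1] >= ev[2] && ev[2] >= ev[3] && ev[3] > 0))
      stop("eigenvalues must satisfy l1 >= l2 >= l3 > 0")
  }
  dim3 <- as.integer(grid_shape)
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  affine <- grid_affine(voxel_size)

  for (b in seq_len(nb)) {
    if (!bundle_inside_grid(bundles[[b]], dim3, affine))
      stop(sprintf("bundle '%s' extends outside the simulation grid", bundles[[b]]$name))
  }

  nvox <- prod(dim3)
  centers <- voxel_centers(dim3, affine)

  # 3x supersampled subdivision offsets (voxel-center convention)
  off <- as.matrix(expand.grid(c(-1, 0, 1) / 3, c(-1, 0, 1) / 3, c(-1, 0, 1) / 3))
  off <- off %*% diag(voxel_size)

  occ <- matrix(0, nvox, nb)
  dirs <- vector("list", nb)
  for (b in seq_len(nb)) {
    bun <- bundles[[b]]
    total_len <- max(centerline_arclength(bun$centerline))
    rmax <- max(bundle_radius_at(bun, total_len, total_len))
    # bounding-box prefilter in world space
    lo <- apply(bun$centerline, 2, min) - rmax - max(voxel_size)
    hi <- apply(bun$centerline, 2, max) + rmax + max(voxel_size)
    inbox <- which(centers[, 1] >= lo[1] & centers[, 1] <= hi[1] &
                   centers[, 2] >= lo[2] & centers[, 2] <= hi[2] &
                   centers[, 3] >= lo[3] & centers[, 3] <= hi[3])
    if (length(inbox) == 0) next
    sub <- centers[rep(inbox, each = nrow(off)), , drop = FALSE] +
      off[rep(seq_len(nrow(off)), length(inbox)), , drop = FALSE]
    cq <- polyline_closest(bun$centerline, sub)
    inside <- cq$dist <= bundle_radius_at(bun, cq$s, total_len)
    occ_box <- colMeans(matrix(inside, nrow = nrow(off)))
    occ[inbox, b] <- occ_box
    hit <- inbox[occ_box > 0]
    dmat <- matrix(NA_real_, nvox, 3)
    if (length(hit) > 0)
      dmat[hit, ] <- bundle_directions_at(bun, centers[hit, , drop = FALSE])
    dirs[[b]] <- dmat
  }

  tot <- rowSums(occ)
  over <- tot > 1
  if (any(over)) occ[over, ] <- occ[over, ] / tot[over]
  f_bg <- pmax(0, 1 - rowSums(occ))

  # noise-free diffusion-weighted signal
  g <- scheme$directions
  bvals <- scheme$bvalues
  ndw <- nrow(g)
  sig_dw <- sweep(matrix(exp(-bvals * bg_adc), nvox, ndw, byrow = TRUE), 1, f_bg, "*")
  for (b in seq_len(nb)) {
    sel <- which(occ[, b] > 0)
    if (length(sel) == 0) next
    ev <- eigenvalues[[b]]
    e1 <- dirs[[b]][sel, , drop = FALSE]
    # deterministic perpendicular frame for the (rare) l2 != l3 case
    ref <- matrix(rep(c(0, 0, 1), each = length(sel)), ncol = 3)
    swap <- abs(e1[, 3]) > 0.9
    ref[swap, ] <- matrix(rep(c(1, 0, 0), each = sum(swap)), ncol = 3)
    e2 <- cbind(e1[, 2] * ref[, 3] - e1[, 3] * ref[, 2],
                e1[, 3] * ref[, 1] - e1[, 1] * ref[, 3],
                e1[, 1] * ref[, 2] - e1[, 2] * ref[, 1])
    e2 <- e2 / sqrt(rowSums(e2^2))
    c1 <- e1 %*% t(g)  # n_sel x ndw dot products
    c2 <- e2 %*% t(g)
    gDg <- ev[3] + (ev[1] - ev[3]) * c1^2 + (ev[2] - ev[3]) * c2^2
    att <- exp(-sweep(gDg, 2, bvals, "*"))
    sig_dw[sel, ] <- sig_dw[sel, ] + occ[sel, b] * att
  }
  sig_dw <- s0 * sig_dw
  sig <- cbind(matrix(s0, nvox, scheme$n_b0), sig_dw)  # b0 volumes first

  if (noise_sigma > 0) {
    set.seed(substream_seed(seed, "noise"))
    n1 <- matrix(rnorm(length(sig), 0, noise_sigma), nrow(sig))
    n2 <- matrix(rnorm(length(sig), 0, noise_sigma), nrow(sig))
    sig <- sqrt((sig + n1)^2 + n2^2)
  }

  nvol <- scheme_n_volumes(scheme)
  signal <- array(sig, dim = c(dim3, nvol))

  wm_mask <- array(rowSums(occ) > 0, dim = dim3)

  # closed-form FA/ADC of the composite tensor per in-mask voxel
  true_fa <- array(0, dim3)
  true_adc <- array(bg_adc, dim3)
  inm <- which(wm_mask)
  for (v in inm) {
    D <- diag(3) * f_bg[v] * bg_adc
    for (b in seq_len(nb)) {
      if (occ[v, b] <= 0) next
      ev <- eigenvalues[[b]]
      d1 <- dirs[[b]][v, ]
      Db <- ev[3] * diag(3) + (ev[1] - ev[3]) * tcrossprod(d1)
      if (ev[2] != ev[3]) {
        ref <- if (abs(d1[3]) > 0.9) c(1, 0, 0) else c(0, 0, 1)
        e2 <- c(d1[2] * ref[3] - d1[3] * ref[2],
                d1[3] * ref[1] - d1[1] * ref[3],
                d1[1] * ref[2] - d1[2] * ref[1])
        e2 <- e2 / sqrt(sum(e2^2))
        Db <- Db + (ev[2] - ev[3]) * tcrossprod(e2)
      }
      D <- D + occ[v, b] * Db
    }
    lam <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
    true_fa[v] <- fa_from_eigenvalues(lam[1], lam[2], lam[3])
    true_adc[v] <- mean(lam)
  }

  dwi <- structure(list(signal = signal, voxel_size = voxel_size,
                        grid_to_world = affine, scheme = scheme, s0 = s0,
                        noise_sigma = noise_sigma),
                   class = "dwi_volume")
  occ_arr <- array(occ, dim = c(dim3, nb))
  dir_arr <- lapply(dirs, function(d) array(d, dim = c(dim3, 3)))
  truth <- structure(list(orientation_field = dir_arr, occupancy = occ_arr,
                          wm_mask = wm_mask, true_fa = true_fa,
                          true_adc = true_adc, bundles = bundles,
                          eigenvalues = eigenvalues, bg_adc = bg_adc,
                          grid_to_world = affine, voxel_size = voxel_size,
                          seed_roi = NULL, target_rois = NULL),
                     class = "phantom_truth")
  list(dwi = dwi, truth = truth)
}

#' @export
print.dwi_volume <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf("dwi_volume: %d x %d x %d grid, %d volumes, voxel %s mm, sigma %g\n",
              d[1], d[2], d[3], d[4],
              paste(signif(x$voxel_size, 3), collapse = "x"), x$noise_sigma))
  invisible(x)
}

# transform a bundle's geometry by a rigid world transform
transform_bundle <- function(bundle, tf) {
  out <- bundle
  out$centerline <- transform_points(tf, bundle$centerline)
  out
}

#' Simulate a scan-rescan session pair
#'
#' Two acquisitions of the same ground-truth geometry with independent noise
#' realizations.  Session B's anatomy is rigidly perturbed relative to the
#' common (session A) space by `perturbation`; the returned
#' `a_to_common` / `b_to_common` transforms are the exactly known inverses of
#' the applied motion (no registration is estimated).
#'
#' @param bundles list of [fiber_bundle()] objects, defined in common space.
#' @param scheme gradient scheme.
#' @param sim_params named list of extra arguments to [simulate_dwi()]
#'   (grid_shape is required).
#' @param perturbation `rigid_transform` mapping session-B world coordinates
#'   to common space (small: <= 1 voxel translation, <= 2 degrees rotation).
#' @param seeds two distinct RNG seeds (session A, session B).
#' @return object of class `session_pair` with `session_a`, `session_b`,
#'   `truth` (common space), `a_to_common`, `b_to_common`.
#' @export
make_session_pair <- function(bundles, scheme, sim_params,
                              perturbation = rigid_transform(),
                              seeds = c(1L, 2L)) {
  stopifnot(inherits(perturbation, "rigid_transform"), length(seeds) == 2)
  if (seeds[1] == seeds[2])
    warning("identical session seeds: the two sessions will share the same noise realization")
  sim_a <- do.call(simulate_dwi,
                   c(list(bundles = bundles, scheme = scheme, seed = seeds[1]),
                     sim_params))
  bundles_b <- lapply(if (inherits(bundles, "fiber_bundle")) list(bundles) else bundles,
                      transform_bundle, tf = invert_transform(perturbation))
  sim_b <- do.call(simulate_dwi,
                   c(list(bundles = bundles_b, scheme = scheme, seed = seeds[2]),
                     sim_params))
  structure(list(session_a = sim_a$dwi, session_b = sim_b$dwi,
                 truth = sim_a$truth, truth_b_native = sim_b$truth,
                 a_to_common = rigid_transform(),
                 b_to_common = perturbation),
            class = "session_pair")
}

# binary dilation with a 3x3x3 structuring element
dilate_mask <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, d)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    xs <- pmin(pmax(1:d[1] + dx, 1), d[1])
    ys <- pmin(pmax(1:d[2] + dy, 1), d[2])
    zs <- pmin(pmax(1:d[3] + dz, 1), d[3])
    out <- out | mask[xs, ys, zs]
  }
  out
}

#' Build cross-sectional seed/target ROIs from phantom truth
#'
#' Each ROI is the bundle cross-section in a single grid slice, dilated once
#' with a 3x3x3 structuring element (final thickness 3 voxels along the slice
#' axis).  The first specification is the seed ROI, the rest are targets.
#'
#' @param truth `phantom_truth`.
#' @param plane_spec list of specs, each `list(axis =, index =, bundle =)`
#'   with `axis` in 1:3, `index` a 0-based slice index, and `bundle` a bundle
#'   index (default: union over bundles).
#' @return list with `seed` (binary array) and `targets` (list of binary
#'   arrays); also stored into a copy of `truth` returned as attribute-free
#'   fields `seed_roi` / `target_rois` when assigned by the caller.
#' @export
make_rois <- function(truth, plane_spec) {
  stopifnot(inherits(truth, "phantom_truth"), length(plane_spec) >= 1)
  d <- dim(truth$wm_mask)
  one_roi <- function(spec) {
    ax <- spec$axis
    idx1 <- spec$index + 1L  # 0-based slice index
    stopifnot(ax %in% 1:3, idx1 >= 1, idx1 <= d[ax])
    occ <- truth$occupancy
    sel <- if (is.null(spec$bundle)) apply(occ, 1:3, sum) > 0 else occ[, , , spec$bundle] > 0
    slice_mask <- array(FALSE, d)
    if (ax == 1) slice_mask[idx1, , ] <- TRUE
    if (ax == 2) slice_mask[, idx1, ] <- TRUE
    if (ax == 3) slice_mask[, , idx1] <- TRUE
    roi <- sel & slice_mask
    if (!any(roi))
      stop(sprintf("ROI plane (axis %d, slice %d) does not intersect the bundle", ax, spec$index))
    dilate_mask(roi)
  }
  rois <- lapply(plane_spec, one_roi)
  list(seed = rois[[1]], targets = rois[-1])
}
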