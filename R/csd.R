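# Constrained spherical deconvolution: single-fiber response estimation from
# high-FA voxels and per-voxel FOD fitting with a hard iterative
# non-negativity constraint on a fixed 300-direction antipodal set.
#
# Signals are normalized by the per-voxel mean b0 before deconvolution, so
# FOD amplitudes are dimensionless and the tracking threshold of 0.1 is
# comparable across phantoms.

# rotation taking unit vector v onto +z
rotation_to_z <- function(v) {
  v <- v / sqrt(sum(v^2))
  z <- c(0, 0, 1)
  c_ <- sum(v * z)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) return(diag(c(1, -1, -1)))
  axis <- c(v[2] * z[3] - v[3] * z[2], v[3] * z[1] - v[1] * z[3],
            v[1] * z[2] - v[2] * z[1])
  axis <- axis / sqrt(sum(axis^2))
  rotation_matrix(axis, acos(c_) * 180 / pi)
}

# split a 4-D volume into b0 mean and diffusion-weighted matrix (nvox x ndw)
split_b0_dw <- function(dwi) {
  d4 <- dim(dwi$signal)
  sig <- matrix(dwi$signal, prod(d4[1:3]), d4[4])
  nb0 <- dwi$scheme$n_b0
  list(b0 = rowMeans(sig[, seq_len(nb0), drop = FALSE]),
       dw = sig[, -seq_len(nb0), drop = FALSE])
}

#' Estimate the single-fiber response function
#'
#' For every voxel whose tensor FA exceeds `fa_threshold`, the gradient
#' directions are rotated so the principal eigenvector maps onto +z, the
#' b0-normalized signal is fitted with even-order zonal (m = 0) spherical
#' harmonics, and the zonal coefficients are averaged across voxels (the
#' alignment removes orientation, which is what permits averaging for noise
#' reduction).
#'
#' @param dwi `dwi_volume`.
#' @param scheme gradient scheme.
#' @param field `tensor_field` from [fit_tensor()].
#' @param fa_threshold FA cutoff selecting single-fiber voxels.
#' @param lmax maximum even SH degree of the response.
#' @return object of class `response_function` with `zonal_coeffs` (one per
#'   even degree 0..lmax), `lmax`, `n_voxels_used`, `source_fa_threshold`.
#' @export
estimate_response <- function(dwi, scheme, field, fa_threshold = 0.7, lmax = 8) {
  sel <- which(field$fit_mask & field$fa > fa_threshold)
  if (length(sel) == 0)
    stop(sprintf("no voxels with FA > %g: cannot estimate a single-fiber response", fa_threshold))
  if (length(sel) < 10)
    warning(sprintf("response estimated from only %d voxels (< 10)", length(sel)))
  sp <- split_b0_dw(dwi)
  g <- scheme$directions
  dim3 <- dim(field$fa)
  nl <- length(seq(0, lmax, by = 2))
  zc <- matrix(0, length(sel), nl)
  zidx <- sh_zonal_indices(lmax)
  for (i in seq_along(sel)) {
    v <- sel[i]
    vi <- arrayInd(v, dim3)
    e1 <- field$e1[vi[1], vi[2], vi[3], ]
    R <- rotation_to_z(e1)
    grot <- g %*% t(R)
    Z <- sh_basis(grot, lmax)[, zidx, drop = FALSE]
    s <- sp$dw[v, ] / sp$b0[v]
    zc[i, ] <- qr.solve(Z, s)
  }
  structure(list(zonal_coeffs = colMeans(zc),
                 lmax = as.integer(lmax),
                 n_voxels_used = length(sel),
                 source_fa_threshold = fa_threshold),
            class = "response_function")
}

#' @export
print.response_function <- function(x, ...) {
  cat(sprintf("response_function: lmax %d, %d voxels (FA > %g)\n",
              x$lmax, x$n_voxels_used, x$source_fa_threshold))
  cat("zonal coefficients:", signif(x$zonal_coeffs, 4), "\n")
  invisible(x)
}

# Per-coefficient spherical convolution factors: convolving an FOD with an
# axially symmetric kernel multiplies coefficient (l, m) by
# sqrt(4 pi / (2 l + 1)) * r_l (r_l = zonal coefficient of the kernel).
response_conv_factors <- function(response, lmax) {
  ls <- sh_degrees(lmax)
  rl <- response$zonal_coeffs[match(ls, seq(0, response$lmax, by = 2))]
  if (anyNA(rl)) stop("response lmax is lower than the requested fit lmax")
  sqrt(4 * pi / (2 * ls + 1)) * rl
}

#' Predict the single-voxel signal of a delta FOD convolved with a response
#'
#' Convolution identity used for validation: a unit-mass delta FOD along
#' `axis` (truncated at the basis lmax) convolved with the response should
#' reproduce the single-fiber signal.
#'
#' @param response `response_function`.
#' @param axis unit fiber direction.
#' @param directions n x 3 gradient directions.
#' @param lmax basis degree.
#' @return predicted b0-normalized signal at `directions`.
#' @export
reconvolve_delta <- function(response, axis, directions, lmax = response$lmax) {
  f <- drop(sh_basis(matrix(axis, 1, 3), lmax))  # delta FOD coefficients
  conv <- response_conv_factors(response, lmax)
  drop(sh_basis(directions, lmax) %*% (conv * f))
}

#' Fit constrained spherical deconvolution FODs
#'
#' Per voxel: an initial FOD is obtained by (lightly ridge-regularized)
#' linear deconvolution of the b0-normalized signal by the response; the
#' FOD is then evaluated on a fixed antipodally symmetric 300-direction set
#' and directions with amplitude below `tau_frac` x mean initial amplitude
#' join a hard constraint set on which the re-solved FOD amplitude is
#' required to be non-negative.  The constrained least-squares problem is
#' solved exactly by an active-set method (working set of zero-amplitude
#' equalities with multiplier-driven add/drop steps); the constraint set
#' grows monotonically until a fixed point (<= `max_iter` outer iterations;
#' non-converged voxels keep the last iterate and are flagged).
#'
#' @param dwi `dwi_volume`.
#' @param scheme gradient scheme.
#' @param response `response_function`.
#' @param lmax maximum even degree (default 8: 45 coefficients).
#' @param mask binary array of voxels to fit (default: all).
#' @param tau_frac constraint threshold as a fraction of the mean initial
#'   amplitude.
#' @param max_iter constraint iterations.
#' @return object of class `sh_field` with `coeffs` (4-D array, last axis =
#'   coefficients), `mask`, `lmax`, `nonconverged`, grid metadata.
#' @export
csd_fit <- function(dwi, scheme, response, lmax = 8, mask = NULL,
                    tau_frac = 0.1, max_iter = 50) {
  nc <- sh_basis_size(lmax)
  if (nc > nrow(scheme$directions))
    stop(sprintf("lmax %d needs %d coefficients but only %d gradient directions are available",
                 lmax, nc, nrow(scheme$directions)))
  d4 <- dim(dwi$signal)
  dim3 <- d4[1:3]
  if (is.null(mask)) mask <- array(TRUE, dim3)
  sp <- split_b0_dw(dwi)

  Bg <- sh_basis(scheme$directions, lmax)
  conv <- response_conv_factors(response, lmax)
  FWD <- Bg * matrix(conv, nrow(Bg), nc, byrow = TRUE)
  # constrain on the 150 unique directions of the antipodally symmetric
  # 300-direction set: even-order FODs satisfy amp(d) = amp(-d) exactly, so
  # the antipodal half adds only duplicate (rank-degenerate) rows
  A <- sh_basis(constraint_directions(300L)[seq_len(150L), , drop = FALSE],
                lmax)
  sel <- which(as.logical(mask) & sp$b0 > 0)
  coeffs <- matrix(0, prod(dim3), nc)
  nonconv <- logical(prod(dim3))
  if (length(sel) > 0) {
    S <- t(sp$dw[sel, , drop = FALSE] / sp$b0[sel])
    res <- .csd_solve_cpp(FWD, S, A, tau_frac, 1e-4, as.integer(max_iter))
    coeffs[sel, ] <- t(res$coeffs)
    nonconv[sel] <- res$nonconverged
  }
  structure(list(coeffs = array(coeffs, c(dim3, nc)),
                 mask = array(as.logical(mask), dim3),
                 lmax = as.integer(lmax),
                 nonconverged = array(nonconv, dim3),
                 response = response,
                 grid_to_world = dwi$grid_to_world,
                 voxel_size = dwi$voxel_size),
            class = "sh_field")
}

#' @export
print.sh_field <- function(x, ...) {
  cat(sprintf("sh_field: %s grid, lmax %d (%d coefficients), %d voxels in mask\n",
              paste(dim(x$mask), collapse = "x"), x$lmax,
              dim(x$coeffs)[4], sum(x$mask)))
  invisible(x)
}

# coefficient vector at a voxel index (1-based triplet)
sh_coeffs_at <- function(field, voxel) {
  field$coeffs[voxel[1], voxel[2], voxel[3], ]
}
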