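# Per-voxel diffusion tensor fit (ordinary least squares on the log signal)
# and the derived FA / ADC maps.

#' Fractional anisotropy from tensor eigenvalues
#'
#' \deqn{FA = \sqrt{1/2} \sqrt{\sum_{i<j} (\lambda_i - \lambda_j)^2} /
#'       \sqrt{\sum_i \lambda_i^2}}
#'
#' @param l1,l2,l3 eigenvalues (vectorized).
#' @return FA in [0, 1]; 0 where all eigenvalues are 0.
#' @export
fa_from_eigenvalues <- function(l1, l2, l3) {
  num <- (l1 - l2)^2 + (l2 - l3)^2 + (l3 - l1)^2
  den <- l1^2 + l2^2 + l3^2
  out <- sqrt(0.5) * sqrt(num / pmax(den, .Machine$double.xmin))
  out[den == 0] <- 0
  pmin(out, 1)
}

#' Mean diffusivity (ADC) from tensor eigenvalues
#' @param l1,l2,l3 eigenvalues (vectorized).
#' @return (l1 + l2 + l3) / 3.
#' @export
adc_from_eigenvalues <- function(l1, l2, l3) (l1 + l2 + l3) / 3

# log-linear design matrix: columns [ln S0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz],
# b0 rows first (matching the volume ordering)
tensor_design_matrix <- function(scheme) {
  g <- scheme$directions
  b <- scheme$bvalues
  dw <- cbind(1, -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
              -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
              -2 * b * g[, 2] * g[, 3])
  b0 <- matrix(0, scheme$n_b0, 7)
  b0[, 1] <- 1
  rbind(b0, dw)
}

#' Fit the diffusion tensor per voxel
#'
#' Ordinary least squares on the log signal,
#' `ln S(g) = ln S0 - b g' D g`, per voxel.  Voxels with any non-positive
#' signal or a non-finite fit are excluded from `fit_mask`; negative
#' eigenvalues are clamped to 0 for metric computation and the voxel is
#' flagged in `clamped`.
#'
#' @param dwi `dwi_volume`.
#' @param scheme gradient scheme (>= 6 non-collinear directions + >= 1 b0).
#' @param mask binary array of voxels to fit (default: all).
#' @return object of class `tensor_field` with per-voxel `tensor`
#'   (n_fit x 6, upper-triangle order xx,yy,zz,xy,xz,yz stored densely as
#'   arrays), `eigenvalues` (4-D array, descending), `e1` (principal
#'   eigenvector), `fa`, `adc`, `fit_mask`, `clamped`.
#' @export
fit_tensor <- function(dwi, scheme, mask = NULL) {
  d4 <- dim(dwi$signal)
  dim3 <- d4[1:3]
  nvol <- d4[4]
  stopifnot(nvol == scheme_n_volumes(scheme))
  X <- tensor_design_matrix(scheme)
  qrx <- qr(X)
  if (qrx$rank < 7)
    stop("rank-deficient tensor design matrix: gradient directions are collinear")
  if (is.null(mask)) mask <- array(TRUE, dim3)

  sig <- matrix(dwi$signal, prod(dim3), nvol)
  sel <- which(as.logical(mask))
  valid <- sel[rowSums(sig[sel, , drop = FALSE] <= 0) == 0]

  P <- solve(crossprod(X), t(X))  # 7 x nvol projector
  beta <- P %*% t(log(sig[valid, , drop = FALSE]))  # 7 x n_valid
  finite <- colSums(!is.finite(beta)) == 0
  valid <- valid[finite]
  beta <- beta[, finite, drop = FALSE]

  n <- length(valid)
  evals <- matrix(0, n, 3)
  e1 <- matrix(0, n, 3)
  clamped <- logical(n)
  for (i in seq_len(n)) {
    b <- beta[, i]
    D <- matrix(c(b[2], b[5], b[6],
                  b[5], b[3], b[7],
                  b[6], b[7], b[4]), 3, 3)
    es <- eigen(D, symmetric = TRUE)
    lam <- es$values  # descending
    if (any(lam < 0)) {
      clamped[i] <- TRUE
      lam <- pmax(lam, 0)
    }
    evals[i, ] <- lam
    e1[i, ] <- es$vectors[, 1]
  }

  to_arr <- function(vals, default = 0) {
    a <- array(default, dim3)
    a[valid] <- vals
    a
  }
  eig_arr <- array(0, c(dim3, 3))
  e1_arr <- array(0, c(dim3, 3))
  for (k in 1:3) {
    tmp <- array(0, dim3); tmp[valid] <- evals[, k]; eig_arr[, , , k] <- tmp
    tmp <- array(0, dim3); tmp[valid] <- e1[, k]; e1_arr[, , , k] <- tmp
  }
  tensor_arr <- array(0, c(dim3, 6))
  for (k in 1:6) {
    tmp <- array(0, dim3); tmp[valid] <- beta[k + 1, ]; tensor_arr[, , , k] <- tmp
  }

  fit_mask <- array(FALSE, dim3)
  fit_mask[valid] <- TRUE
  structure(list(tensor = tensor_arr,
                 eigenvalues = eig_arr,
                 e1 = e1_arr,
                 fa = to_arr(fa_from_eigenvalues(evals[, 1], evals[, 2], evals[, 3])),
                 adc = to_arr(adc_from_eigenvalues(evals[, 1], evals[, 2], evals[, 3])),
                 fit_mask = fit_mask,
                 clamped = to_arr(clamped, FALSE),
                 grid_to_world = dwi$grid_to_world,
                 voxel_size = dwi$voxel_size),
            class = "tensor_field")
}

#' FA and ADC maps from a fitted tensor field
#'
#' Recomputes both maps from the stored eigenvalues; 0 outside `fit_mask`.
#'
#' @param field `tensor_field`.
#' @return list with `fa` and `adc` arrays.
#' @export
tensor_metrics <- function(field) {
  stopifnot(inherits(field, "tensor_field"))
  l1 <- field$eigenvalues[, , , 1]
  l2 <- field$eigenvalues[, , , 2]
  l3 <- field$eigenvalues[, , , 3]
  fa <- fa_from_eigenvalues(l1, l2, l3)
  adc <- adc_from_eigenvalues(l1, l2, l3)
  fa[!field$fit_mask] <- 0
  adc[!field$fit_mask] <- 0
  list(fa = fa, adc = adc)
}

#' @export
print.tensor_field <- function(x, ...) {
  cat(sprintf("tensor_field: %s grid, %d fitted voxels (%d clamped)\n",
              paste(dim(x$fa), collapse = "x"), sum(x$fit_mask), sum(x$clamped)))
  invisible(x)
}
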