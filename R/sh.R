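# Real even-order spherical harmonics: basis evaluation, FOD amplitudes,
# deterministic sphere point sets, and dense-grid peak extraction.
#
# Basis convention (matches the compiled core): real orthonormal basis,
# even degrees only, coefficients ordered by l ascending then m ascending
# (-l..l).  This ordering is an internal convention; translating to other
# tools' orderings is an I/O concern.

#' Number of coefficients of an even-order spherical-harmonic basis
#'
#' With only even degrees retained (diffusion signals are antipodally
#' symmetric), a series truncated at degree `lmax` has
#' `(lmax + 1) * (lmax + 2) / 2` coefficients; `lmax = 8` gives 45.
#'
#' @param lmax maximum (even) spherical-harmonic degree.
#' @return integer coefficient count.
#' @export
#' @examples
#' sh_basis_size(8)  # 45
sh_basis_size <- function(lmax) {
  stopifnot(length(lmax) == 1L, is.numeric(lmax), lmax >= 0, lmax <= 16)
  if (lmax %% 2 != 0) stop("lmax must be even (odd degrees vanish for antipodally symmetric functions)")
  as.integer((lmax + 1) * (lmax + 2) / 2)
}

#' Evaluate the real even-order SH basis at unit directions
#'
#' @param dirs n x 3 matrix of unit direction vectors.
#' @param lmax maximum even degree.
#' @return n x `sh_basis_size(lmax)` matrix of basis values.
#' @export
sh_basis <- function(dirs, lmax) {
  dirs <- as_direction_matrix(dirs)
  sh_basis_size(lmax)  # validates lmax
  .sh_basis_cpp(dirs, as.integer(lmax))
}

# degree l of each coefficient, in basis order
sh_degrees <- function(lmax) {
  unlist(lapply(seq(0, lmax, by = 2), function(l) rep(l, 2 * l + 1)))
}

# column indices of the zonal (m = 0) coefficients, in basis order
sh_zonal_indices <- function(lmax) {
  ls <- seq(0, lmax, by = 2)
  idx <- integer(length(ls))
  off <- 0L
  for (i in seq_along(ls)) {
    l <- ls[i]
    idx[i] <- off + l + 1L  # m runs -l..l, m = 0 is position l + 1
    off <- off + 2L * l + 1L
  }
  idx
}

as_direction_matrix <- function(dirs) {
  if (is.null(dim(dirs))) dirs <- matrix(dirs, ncol = 3)
  dirs <- as.matrix(dirs)
  if (ncol(dirs) != 3) stop("directions must be 3-vectors")
  nrm <- sqrt(rowSums(dirs^2))
  if (any(abs(nrm - 1) > 1e-6)) stop("directions must be unit vectors")
  dirs / nrm
}

#' FOD amplitude along a direction
#'
#' Evaluates a real even-order SH series at one or more unit directions.
#' Even-order bases are antipodally symmetric, so
#' `fod_amplitude(x, d) == fod_amplitude(x, -d)`.
#'
#' @param coeffs SH coefficient vector.
#' @param direction unit 3-vector or n x 3 matrix of unit vectors.
#' @return amplitude(s), one per direction.
#' @export
fod_amplitude <- function(coeffs, direction) {
  lmax <- lmax_from_ncoeffs(length(coeffs))
  drop(sh_basis(direction, lmax) %*% as.numeric(coeffs))
}

lmax_from_ncoeffs <- function(n) {
  lmax <- (-3 + sqrt(1 + 8 * n)) / 2
  if (abs(lmax - round(lmax)) > 1e-9 || round(lmax) %% 2 != 0)
    stop("coefficient length does not match an even-order SH basis")
  as.integer(round(lmax))
}

#' Deterministic quasi-uniform unit vectors (Fibonacci spiral)
#'
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# Fixed antipodally symmetric constraint set used by the CSD fit.
constraint_directions <- function(n = 300L) {
  stopifnot(n %% 2 == 0)
  half <- fibonacci_sphere(n %/% 2)
  rbind(half, -half)
}

#' Extract FOD peaks by dense-grid search with local refinement
#'
#' Validation utility (not used by tracking): evaluates the FOD on a dense
#' deterministic sphere grid, greedily picks local maxima separated by at
#' least `min_sep_deg` (after antipodal folding), and refines each peak
#' direction with a local continuous optimization.
#'
#' @param coeffs SH coefficient vector.
#' @param n_grid grid size for the dense search.
#' @param min_sep_deg minimum angular separation between reported peaks.
#' @param peak_frac only maxima above `peak_frac * max amplitude` are kept.
#' @param max_peaks maximum number of peaks returned.
#' @return list with `directions` (k x 3) and `amplitudes` (length k),
#'   strongest first.
#' @export
fod_peaks <- function(coeffs, n_grid = 10242L, min_sep_deg = 25,
                      peak_frac = 0.33, max_peaks = 4L) {
  lmax <- lmax_from_ncoeffs(length(coeffs))
  grid <- fibonacci_sphere(n_grid)
  amp <- drop(sh_basis(grid, lmax) %*% as.numeric(coeffs))
  ord <- order(amp, decreasing = TRUE)
  amax <- amp[ord[1]]
  if (amax <= 0) return(list(directions = matrix(0, 0, 3), amplitudes = numeric(0)))
  cos_sep <- cos(min_sep_deg * pi / 180)
  peaks <- matrix(0, 0, 3)
  pamp <- numeric(0)
  for (i in ord) {
    if (amp[i] < peak_frac * amax || nrow(peaks) >= max_peaks) break
    d <- grid[i, ]
    if (nrow(peaks) == 0 || all(abs(peaks %*% d) < cos_sep)) {
      peaks <- rbind(peaks, d)
      pamp <- c(pamp, amp[i])
    }
  }
  # local refinement on the sphere via unconstrained 3-vector + renormalize
  refine <- function(d0) {
    f <- function(v) {
      v <- v / sqrt(sum(v^2))
      -fod_amplitude(coeffs, v)
    }
    res <- stats::optim(d0, f, method = "Nelder-Mead",
                        control = list(reltol = 1e-10, maxit = 400))
    v <- res$par / sqrt(sum(res$par^2))
    list(dir = v, amp = -res$value)
  }
  for (k in seq_len(nrow(peaks))) {
    r <- refine(peaks[k, ])
    peaks[k, ] <- r$dir
    pamp[k] <- r$amp
  }
  o <- order(pamp, decreasing = TRUE)
  list(directions = peaks[o, , drop = FALSE], amplitudes = pamp[o])
}
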