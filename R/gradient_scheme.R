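# Diffusion gradient schemes: antipodally symmetric electrostatic repulsion.

#' Build a diffusion gradient scheme by electrostatic repulsion
#'
#' Places `n_directions` unit vectors on the sphere by minimizing the
#' antipodally symmetric electrostatic energy
#' \deqn{E = \sum_{i<j} 1/\|g_i - g_j\| + 1/\|g_i + g_j\|}
#' with projected gradient descent and backtracking line search from a random
#' start, so that diffusion directions (which are sign-invariant) spread
#' homogeneously.  Deterministic given `seed`.
#'
#' @param n_directions number of diffusion-weighted directions (>= 6, the
#'   minimum for an identifiable tensor fit).
#' @param b_value diffusion weighting (s/mm^2), applied to every direction.
#' @param n_b0 number of non-diffusion-weighted (b = 0) volumes.
#' @param seed RNG seed for the random initialization.
#' @param max_iter descent iterations.
#' @return object of class `gradient_scheme` with fields `directions`
#'   (n x 3 unit vectors), `bvalues` (per-direction, s/mm^2), `n_b0`,
#'   and `energy` (initial and final electrostatic energy).
#' @export
make_gradient_scheme <- function(n_directions, b_value, n_b0 = 1L, seed = 1L,
                                 max_iter = 200L) {
  if (n_directions < 6)
    stop("n_directions must be >= 6: the diffusion tensor fit is unidentifiable below 6 directions")
  stopifnot(b_value > 0, n_b0 >= 1)
  set.seed(substream_seed(seed, "gradient-scheme"))
  g <- matrix(rnorm(3 * n_directions), ncol = 3)
  g <- g / sqrt(rowSums(g^2))

  e0 <- electrostatic_energy(g)
  e <- e0
  eta <- 0.01
  for (iter in seq_len(max_iter)) {
    gr <- electrostatic_gradient(g)
    accepted <- FALSE
    while (eta > 1e-12) {
      cand <- g - eta * gr
      cand <- cand / sqrt(rowSums(cand^2))
      ec <- electrostatic_energy(cand)
      if (ec < e) {
        g <- cand
        if (abs(e - ec) < 1e-10 * abs(e)) e <- ec else e <- ec
        accepted <- TRUE
        eta <- eta * 1.5
        break
      }
      eta <- eta / 2
    }
    if (!accepted) break
  }

  structure(list(directions = unname(g),
                 bvalues = rep(as.numeric(b_value), n_directions),
                 n_b0 = as.integer(n_b0),
                 energy = c(initial = e0, final = e)),
            class = "gradient_scheme")
}

electrostatic_energy <- function(g) {
  n <- nrow(g)
  G <- g %*% t(g)
  # |gi - gj|^2 = 2 - 2 gi.gj ; |gi + gj|^2 = 2 + 2 gi.gj
  dm <- sqrt(pmax(2 - 2 * G, 0))
  dp <- sqrt(pmax(2 + 2 * G, 0))
  up <- upper.tri(dm)
  sum(1 / dm[up]) + sum(1 / dp[up])
}

electrostatic_gradient <- function(g) {
  n <- nrow(g)
  gr <- matrix(0, n, 3)
  G <- g %*% t(g)
  dm3 <- (pmax(2 - 2 * G, 1e-12))^(-1.5)
  dp3 <- (pmax(2 + 2 * G, 1e-12))^(-1.5)
  diag(dm3) <- 0
  diag(dp3) <- 0
  # d/dgi 1/|gi-gj| = -(gi-gj)/|gi-gj|^3 ; similarly for the antipodal term
  for (a in 1:3) {
    ga <- g[, a]
    diff_term <- dm3 * (outer(ga, ga, "-"))   # (gi - gj) elementwise
    sum_term <- dp3 * (outer(ga, ga, "+"))
    gr[, a] <- -rowSums(diff_term) - rowSums(sum_term)
  }
  gr
}

#' Minimum pairwise angle of a scheme after antipodal folding
#' @param directions n x 3 unit vectors.
#' @return smallest pairwise angle (degrees), treating g and -g as equal.
#' @export
min_pairwise_angle <- function(directions) {
  G <- abs(directions %*% t(directions))
  diag(G) <- 0
  acos(pmin(1, max(G[upper.tri(G)]))) * 180 / pi
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat(sprintf("gradient scheme: %d directions at b = %g s/mm^2 + %d b0; min angle %.2f deg\n",
              nrow(x$directions), x$bvalues[1], x$n_b0,
              min_pairwise_angle(x$directions)))
  invisible(x)
}

# number of volumes along the 4th axis for a scheme (b0 volumes first)
scheme_n_volumes <- function(scheme) nrow(scheme$directions) + scheme$n_b0
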