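# Shared phantom fixtures, built once per test run and cached.
#
# Geometry note: bundles run along z with the axis at world x = y = 19 mm
# (between voxel centers on the 2 mm grid), radius 3.3 mm, spanning the
# whole grid so no end-cap lies inside it.  With 3x supersampled occupancy
# this yields a clean separation between pure voxels (occupancy 1) and
# boundary voxels (occupancy well below 1), so the FA > 0.7
# response-selection rule picks exactly the pure voxels.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, .build_fixture(name), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

.build_fixture <- function(name) {
  switch(name,
    scheme64 = make_gradient_scheme(64, 1200, 1, seed = 7),
    single = {
      # noise-free single straight bundle
      sim <- simulate_dwi(bundle_straight(c(19, 19, -1), c(19, 19, 79), 3.3),
                          fixture("scheme64"), grid_shape = c(20, 20, 40),
                          voxel_size = 2, s0 = 1000, noise_sigma = 0, seed = 1)
      sim$tensor <- fit_tensor(sim$dwi, fixture("scheme64"))
      sim$response <- estimate_response(sim$dwi, fixture("scheme64"),
                                        sim$tensor, 0.7, 8)
      sim
    },
    single_fod = {
      sim <- fixture("single")
      csd_fit(sim$dwi, fixture("scheme64"), sim$response, 8,
              mask = sim$truth$wm_mask)
    },
    single_noisy = {
      # same geometry at b0 SNR 20
      sim <- simulate_dwi(bundle_straight(c(19, 19, -1), c(19, 19, 79), 3.3),
                          fixture("scheme64"), grid_shape = c(20, 20, 40),
                          voxel_size = 2, s0 = 1000, noise_sigma = 50, seed = 5)
      sim$tensor <- fit_tensor(sim$dwi, fixture("scheme64"))
      sim$response <- estimate_response(sim$dwi, fixture("scheme64"),
                                        sim$tensor, 0.7, 8)
      sim$fod <- csd_fit(sim$dwi, fixture("scheme64"), sim$response, 8,
                         mask = dilate_once(sim$truth$wm_mask))
      sim
    },
    crossing = {
      # two orthogonal bundles crossing at the grid center
      b1 <- bundle_straight(c(19, 19, -1), c(19, 19, 79), 3.3,
                            kind = "crossing-component")
      b2 <- bundle_straight(c(-1, 19, 39), c(39, 19, 39), 3.3,
                            kind = "crossing-component")
      sim <- simulate_dwi(list(b1, b2), fixture("scheme64"),
                          grid_shape = c(20, 20, 40), voxel_size = 2,
                          s0 = 1000, noise_sigma = 0, seed = 1)
      sim$cross_mask <- sim$truth$occupancy[, , , 1] > 0.25 &
                        sim$truth$occupancy[, , , 2] > 0.25
      sim
    },
    stop("unknown fixture: ", name)
  )
}

dilate_once <- function(mask) tractrepro:::dilate_mask(mask)

# angle in degrees between a direction and an axis, after antipodal folding
axis_angle <- function(d, axis) {
  acos(min(1, abs(sum(d * axis) / sqrt(sum(d^2)) / sqrt(sum(axis^2))))) * 180 / pi
}

# a plain tractogram object from a list of point matrices (for mapping tests)
manual_tractogram <- function(pts_list, mode = "proximal") {
  structure(list(streamlines = lapply(pts_list, function(p)
    list(points = p, seed_point = p[1, ], termination = c("target-reached",
                                                          "target-reached"),
         reached = TRUE)),
    params = tracking_params(), mode = mode, space = "test", seeds = NULL,
    terminations = NULL, acceptance_rate = 1, partial = FALSE),
    class = "tractogram")
}

# independent density-map oracle: exact segment-box clipping voxel walk.
# For each streamline segment, finds every voxel box the segment passes
# through by slicing the segment at all voxel boundary-plane crossings.
oracle_density <- function(pts_list, grid) {
  counts <- array(0L, grid$dim)
  for (pts in pts_list) {
    v <- world_to_grid_points(grid$grid_to_world, pts)  # continuous voxel
    visited <- integer(0)
    for (i in seq_len(nrow(v) - 1)) {
      a <- v[i, ]; b <- v[i + 1, ]
      ts <- c(0, 1)
      for (ax in 1:3) {
        lo <- floor(min(a[ax], b[ax]) + 0.5)
        hi <- ceiling(max(a[ax], b[ax]) + 0.5)
        bounds <- seq(lo, hi) - 0.5  # voxel boundary planes
        if (abs(b[ax] - a[ax]) > 1e-12) {
          tt <- (bounds - a[ax]) / (b[ax] - a[ax])
          ts <- c(ts, tt[tt > 0 & tt < 1])
        }
      }
      ts <- sort(unique(ts))
      mids <- (ts[-length(ts)] + ts[-1]) / 2
      for (tm in mids) {
        p <- a + tm * (b - a)
        idx <- round(p)
        if (all(idx >= 0) && all(idx < grid$dim)) {
          visited <- c(visited, 1 + idx[1] + grid$dim[1] *
                         (idx[2] + grid$dim[2] * idx[3]))
        }
      }
    }
    if (nrow(v) == 1) {
      idx <- round(v[1, ])
      if (all(idx >= 0) && all(idx < grid$dim))
        visited <- 1 + idx[1] + grid$dim[1] * (idx[2] + grid$dim[2] * idx[3])
    }
    visited <- unique(visited)
    counts[visited] <- counts[visited] + 1L
  }
  counts
}

# brute-force one-way ANOVA ICC oracle (independent of the implementation)
oracle_icc <- function(x) {
  n <- nrow(x); k <- ncol(x)
  mi <- rowMeans(x); g <- mean(x)
  bs <- k * sum((mi - g)^2) / (n - 1)
  ws <- sum(sweep(x, 1, mi)^2) / (n * (k - 1))
  (bs - ws) / (bs + (k - 1) * ws)
}

# brute-force Dice oracle by direct voxel counting
oracle_dice <- function(m1, m2) {
  2 * sum(m1 & m2) / (sum(m1) + sum(m2))
}

expect_step_and_angle_contract <- function(tractogram, step_mm, max_angle_deg) {
  for (sl in tractogram$streamlines) {
    p <- sl$points
    if (nrow(p) < 2) next
    d <- diff(p)
    len <- sqrt(rowSums(d^2))
    expect_lt(max(abs(len - step_mm)), 1e-9)
    if (nrow(d) >= 2) {
      u <- d / len
      cosang <- rowSums(u[-nrow(u), , drop = FALSE] * u[-1, , drop = FALSE])
      expect_lte(max(acos(pmin(1, cosang))) * 180 / pi,
                 max_angle_deg + 1e-6)
    }
  }
  invisible(TRUE)
}
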