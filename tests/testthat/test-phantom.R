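# Synthetic phantom generator: gradient schemes, multi-tensor signal,
# Rician noise, session pairs, and cross-sectional ROIs.

test_that("electrostatic gradient schemes are unit-norm, counted, and improve on random placement", {
  sch <- fixture("scheme64")
  expect_equal(nrow(sch$directions), 64)
  expect_equal(sch$n_b0, 1L)
  expect_lt(max(abs(sqrt(rowSums(sch$directions^2)) - 1)), 1e-9)
  expect_true(all(sch$bvalues > 0))

  # descent never increases the electrostatic objective
  sch6 <- make_gradient_scheme(6, 1200, 1, seed = 0)
  expect_lte(sch6$energy["final"], sch6$energy["initial"])

  # acquisition-scale scheme: 128 directions + 1 b0
  sch128 <- make_gradient_scheme(128, 1200, 1, seed = 7)
  expect_equal(nrow(sch128$directions), 128)
  expect_equal(sch128$n_b0, 1L)
  expect_lt(max(abs(sqrt(rowSums(sch128$directions^2)) - 1)), 1e-9)

  # optimized 12-direction scheme beats 100 random placements on the
  # minimum antipodally folded pairwise angle
  sch12 <- make_gradient_scheme(12, 1000, 1, seed = 1)
  opt_angle <- min_pairwise_angle(sch12$directions)
  set.seed(99)
  rand_angles <- replicate(100, {
    g <- matrix(rnorm(36), ncol = 3)
    min_pairwise_angle(g / sqrt(rowSums(g^2)))
  })
  expect_gt(opt_angle, max(rand_angles))

  expect_error(make_gradient_scheme(5, 1200, 1), "unidentifiable")
})

test_that("noise-free multi-tensor signal matches the closed-form exponential model", {
  sim <- fixture("single")
  sch <- fixture("scheme64")
  occ <- sim$truth$occupancy[, , , 1]
  pure <- which(occ == 1)
  expect_gt(length(pure), 50)

  vi <- arrayInd(pure[11], dim(occ))
  s <- sim$dwi$signal[vi[1], vi[2], vi[3], ]
  # b0 volume is exactly s0 in bundle voxels
  expect_equal(s[1], 1000)
  # diffusion-weighted volumes follow s0 * exp(-b g' D g) for the
  # axially symmetric tensor along z
  pred <- 1000 * exp(-1200 * (0.2e-3 + 1.5e-3 * sch$directions[, 3]^2))
  expect_equal(unname(s[-1]), pred, tolerance = 1e-12)

  expect_error(
    simulate_dwi(bundle_straight(c(19, 19, -30), c(19, 19, 70), 3.3,
                                 name = "runaway"),
                 sch, c(20, 20, 40), 2),
    "runaway")
  expect_error(
    simulate_dwi(bundle_straight(c(19, 19, 8), c(19, 19, 70), 3.3),
                 sch, c(20, 20, 40), 2, eigenvalues = c(0.2e-3, 1.7e-3, 0.2e-3)),
    "eigenvalues")
})

test_that("phantom truth FA/ADC match an independent eigenvalue-formula implementation", {
  sim <- fixture("single")
  occ <- sim$truth$occupancy[, , , 1]
  # independent implementation of the closed forms
  my_fa <- function(l) sqrt(0.5 * ((l[1] - l[2])^2 + (l[2] - l[3])^2 +
                                   (l[3] - l[1])^2) / sum(l^2))
  lam <- c(1.7e-3, 0.2e-3, 0.2e-3)
  pure <- which(occ == 1)
  expect_lt(max(abs(sim$truth$true_fa[pure] - my_fa(lam))), 1e-12)
  expect_lt(max(abs(sim$truth$true_adc[pure] - mean(lam))), 1e-15)
})

test_that("Rician noise yields the configured b0 SNR and vanishes with sigma", {
  sch <- fixture("scheme64")
  bun <- bundle_straight(c(19, 19, -1), c(19, 19, 79), 3.3)
  noisy <- simulate_dwi(bun, sch, c(20, 20, 40), 2, s0 = 1000,
                        noise_sigma = 50, seed = 11)
  wm <- noisy$truth$wm_mask
  expect_gt(sum(wm), 200)
  b0 <- noisy$dwi$signal[, , , 1]
  snr <- mean(b0[wm]) / 50
  expect_lt(abs(snr - 20) / 20, 0.15)

  # mean deviation from the noise-free signal shrinks monotonically with
  # sigma (Rician bias -> 0)
  clean <- fixture("single")$dwi$signal
  devs <- sapply(c(100, 50, 25), function(sg) {
    n <- simulate_dwi(bun, sch, c(20, 20, 40), 2, s0 = 1000,
                      noise_sigma = sg, seed = 21)
    idx <- which(wm)[1:100]
    mean(abs(n$dwi$signal[, , , 1][idx] - clean[, , , 1][idx]))
  })
  expect_true(all(diff(devs) < 0))
})

test_that("simulation is deterministic given the seed, byte-for-byte", {
  sch <- fixture("scheme64")
  bun <- bundle_straight(c(19, 19, -1), c(19, 19, 79), 3.3)
  a <- simulate_dwi(bun, sch, c(20, 20, 40), 2, noise_sigma = 40, seed = 3)
  b <- simulate_dwi(bun, sch, c(20, 20, 40), 2, noise_sigma = 40, seed = 3)
  expect_identical(serialize(a$dwi$signal, NULL), serialize(b$dwi$signal, NULL))
})

test_that("session pairs share truth, carry exact transforms, and differ only by noise", {
  sch <- fixture("scheme64")
  # in-grid margins so the rigidly perturbed session stays inside
  bun <- bundle_straight(c(19, 19, 4), c(19, 19, 74), 3.3)
  sp <- list(grid_shape = c(20, 20, 40), voxel_size = 2, noise_sigma = 40)
  perturb <- rigid_transform(rotation_matrix(c(0, 0, 1), 1.5), c(0.8, -0.6, 0.4))
  pair <- make_session_pair(bun, sch, sp, perturb, seeds = c(10L, 11L))

  # transforms round-trip on the grid corners
  corners <- as.matrix(expand.grid(c(0, 39), c(0, 39), c(0, 79)))
  rt <- transform_points(invert_transform(perturb),
                         transform_points(perturb, corners))
  expect_lt(max(abs(rt - corners)), 1e-6)

  # identity perturbation + equal seeds: bitwise-identical sessions
  expect_warning(
    same <- make_session_pair(bun, sch, sp, rigid_transform(),
                              seeds = c(4L, 4L)),
    "identical")
  expect_identical(same$session_a$signal, same$session_b$signal)

  # identity perturbation, distinct seeds: signals differ voxelwise but the
  # paired in-mask difference is not significant (two draws, one mean)
  pair0 <- make_session_pair(bun, sch, sp, rigid_transform(),
                             seeds = c(12L, 13L))
  wm <- which(pair0$truth$wm_mask)
  d <- pair0$session_a$signal[, , , 2][wm] - pair0$session_b$signal[, , , 2][wm]
  expect_gt(sd(d), 0)
  expect_gt(t.test(d)$p.value, 0.05)

  # a known 1-voxel translation maps session-b voxel centers exactly
  tr <- rigid_transform(translation = c(2, 0, 0))
  pair1 <- make_session_pair(bun, sch, sp, tr, seeds = c(14L, 15L))
  ctr_b <- c(10, 10, 10)
  mapped <- transform_points(pair1$b_to_common, ctr_b)
  expect_lt(max(abs(mapped - (ctr_b + c(2, 0, 0)))), 1e-9)
})

test_that("ROIs are 3-voxel-thick dilated cross-sections and reject empty planes", {
  sim <- fixture("single")
  rois <- make_rois(sim$truth, list(list(axis = 3, index = 20),
                                    list(axis = 3, index = 7),
                                    list(axis = 3, index = 33)))
  # thickness along the slice axis is exactly 3 voxels
  zs <- unique(arrayInd(which(rois$seed), dim(rois$seed))[, 3])
  expect_equal(sort(zs), 20:22)  # 0-based slice 20 -> 1-based 21 +/- 1
  expect_equal(length(rois$targets), 2)
  for (t in rois$targets) expect_gte(sum(t), 9)
  # the two end ROIs are disjoint
  expect_equal(sum(rois$targets[[1]] & rois$targets[[2]]), 0)

  # an x-slice far from the bundle axis has no cross-section
  expect_error(make_rois(sim$truth, list(list(axis = 1, index = 0))),
               "does not intersect")
})
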