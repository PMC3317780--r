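# Probabilistic tracking: curvature geometry, rejection sampling,
# propagation, seed/target logic, whole-mask seeding.

test_that("the curvature-radius chord formula gives the documented angles", {
  expect_equal(max_angle_from_curvature(0.2, 1.0), 2 * asin(0.1) * 180 / pi)
  expect_equal(round(max_angle_from_curvature(0.2, 1.0), 3), 11.478)
  expect_equal(max_angle_from_curvature(0.2, 0.1), 180)
  expect_lt(max_angle_from_curvature(0.2, 1e9), 1e-5)
  expect_error(max_angle_from_curvature(0.2, 0.05), "diameter")
})

test_that("rejection sampling respects the cone, the threshold, and uniformity", {
  params <- tracking_params(max_attempts_per_step = 200)
  theta_max <- max_angle_from_curvature(params$step_mm,
                                        params$curvature_radius_mm)

  # peaked FOD aligned with the previous direction: all accepted directions
  # stay within the curvature cone
  axis <- c(0, 0, 1)
  delta <- drop(sh_basis(matrix(axis, 1, 3), 8)) * 3
  set.seed(1)
  for (i in 1:200) {
    d <- sample_direction(delta, previous_dir = axis, params = params)
    expect_length(d, 3)
    expect_lte(acos(min(1, sum(d * axis))) * 180 / pi, theta_max + 1e-9)
  }

  # FOD uniformly below threshold always fails with the low-amplitude reason
  low <- c(0.05 * sqrt(4 * pi), rep(0, 44))
  set.seed(2)
  d <- sample_direction(low, previous_dir = NULL, params = params)
  expect_length(d, 0)
  expect_equal(attr(d, "reason"), "low-amplitude")

  # isotropic FOD above threshold, no previous direction: accepted
  # directions are uniform on the sphere (mean resultant length test)
  iso <- c(0.5 * sqrt(4 * pi), rep(0, 44))
  set.seed(3)
  draws <- t(replicate(3000, sample_direction(iso, NULL, params)))
  rbar <- sqrt(sum(colMeans(draws)^2))
  # Rayleigh statistic 3 n rbar^2 ~ chi2(3) under uniformity
  pval <- pchisq(3 * nrow(draws) * rbar^2, df = 3, lower.tail = FALSE)
  expect_gt(pval, 0.01)
})

test_that("propagation obeys the step/angle contracts and terminates sensibly", {
  sim <- fixture("single_noisy")
  fod <- sim$fod
  brain <- array(TRUE, c(20, 20, 40))
  params <- tracking_params(n_streamlines = 60)

  # zero-amplitude field: seed-only streamline, low-amplitude termination
  empty <- fod
  empty$coeffs[] <- 0
  set.seed(4)
  sl0 <- propagate(empty, c(19, 19, 40), params, brain_mask = brain,
                   mode = "whole")
  expect_equal(nrow(sl0$points), 1)
  expect_equal(sl0$termination, c("low-amplitude", "low-amplitude"))

  expect_error(propagate(fod, c(100, 100, 100), params,
                         brain_mask = sim$truth$wm_mask, mode = "whole"),
               "outside")

  rois <- make_rois(sim$truth, list(list(axis = 3, index = 20),
                                    list(axis = 3, index = 7),
                                    list(axis = 3, index = 33)))
  tg <- track_tract(fod, rois$seed, rois$targets, params, mode = "proximal",
                    seed = 42, brain_mask = brain)
  expect_equal(length(tg$streamlines), 60)
  expect_step_and_angle_contract(tg, 0.2, max_angle_from_curvature(0.2, 1))

  # proximal retained streamlines overwhelmingly end at the target
  term_ok <- mean(vapply(tg$streamlines, function(s)
    any(s$termination == "target-reached"), logical(1)))
  expect_gte(term_ok, 0.95)
})

test_that("proximal streamlines are truncations of their extended counterparts", {
  sim <- fixture("single_noisy")
  brain <- array(TRUE, c(20, 20, 40))
  params <- tracking_params(n_streamlines = 40)
  rois <- make_rois(sim$truth, list(list(axis = 3, index = 20),
                                    list(axis = 3, index = 7),
                                    list(axis = 3, index = 33)))
  tp <- track_tract(sim$fod, rois$seed, rois$targets, params,
                    mode = "proximal", seed = 7, brain_mask = brain)
  te <- track_tract(sim$fod, rois$seed, rois$targets, params,
                    mode = "extended", seed = 7, brain_mask = brain)
  expect_equal(length(tp$streamlines), length(te$streamlines))
  for (i in seq_along(tp$streamlines)) {
    pp <- tp$streamlines[[i]]$points
    pe <- te$streamlines[[i]]$points
    expect_lte(nrow(pp), nrow(pe))
    # the proximal point set is a contiguous sub-block of the extended one
    # (identical per-streamline RNG substreams; extended only adds points
    # beyond the target truncation)
    off <- which(apply(pe, 1, function(r) all(abs(r - pp[1, ]) < 1e-9)))
    expect_true(length(off) >= 1)
    expect_lt(max(abs(pe[off[1]:(off[1] + nrow(pp) - 1), ] - pp)), 1e-9)
  }
})

test_that("tract tracking enforces ROI retention and flags unreachable targets", {
  sim <- fixture("single_noisy")
  brain <- array(TRUE, c(20, 20, 40))
  rois <- make_rois(sim$truth, list(list(axis = 3, index = 20),
                                    list(axis = 3, index = 7),
                                    list(axis = 3, index = 33)))
  params <- tracking_params(n_streamlines = 30)
  tg <- track_tract(sim$fod, rois$seed, rois$targets, params,
                    mode = "proximal", seed = 9, brain_mask = brain)
  tmask <- rois$targets[[1]] | rois$targets[[2]]
  grid <- map_grid(c(20, 20, 40), sim$fod$grid_to_world)
  for (sl in tg$streamlines) {
    v <- round(world_to_grid_points(grid$grid_to_world, sl$points))
    hit <- any(tmask[1 + v[, 1] + 20 * (v[, 2] + 20 * v[, 3])])
    expect_true(hit)
  }

  # an out-of-bundle target in a low-FOD region: acceptance ~ 0, warning,
  # partial tractogram
  far <- array(FALSE, c(20, 20, 40))
  far[1:2, 1:2, 1:2] <- TRUE
  params_small <- tracking_params(n_streamlines = 5)
  expect_warning(
    bad <- track_tract(sim$fod, rois$seed, list(far), params_small,
                       mode = "proximal", seed = 10, brain_mask = brain),
    "retained")
  expect_true(bad$partial)
  expect_lt(length(bad$streamlines), 5)

  expect_error(track_tract(sim$fod, array(FALSE, c(20, 20, 40)),
                           rois$targets, params, seed = 1), "non-empty")
})

test_that("whole-mask tracking stays in the bundle envelope and is deterministic", {
  sim <- fixture("single_noisy")
  brain <- array(TRUE, c(20, 20, 40))
  params <- tracking_params(n_streamlines = 100)
  wb1 <- track_whole_mask(sim$fod, sim$truth$wm_mask, 150, params, seed = 31,
                          brain_mask = brain)
  wb2 <- track_whole_mask(sim$fod, sim$truth$wm_mask, 150, params, seed = 31,
                          brain_mask = brain)
  expect_identical(serialize(lapply(wb1$streamlines, `[[`, "points"), NULL),
                   serialize(lapply(wb2$streamlines, `[[`, "points"), NULL))

  # streamline points stay within the dilated bundle envelope
  env <- dilate_once(dilate_once(sim$truth$wm_mask))
  grid <- map_grid(c(20, 20, 40), sim$fod$grid_to_world)
  n_in <- 0; n_tot <- 0
  for (sl in wb1$streamlines) {
    v <- round(world_to_grid_points(grid$grid_to_world, sl$points))
    inside <- env[1 + v[, 1] + 20 * (v[, 2] + 20 * v[, 3])]
    n_in <- n_in + sum(inside); n_tot <- n_tot + length(inside)
  }
  expect_gte(n_in / n_tot, 0.99)

  expect_error(track_whole_mask(sim$fod, array(FALSE, c(20, 20, 40)), 10,
                                params, seed = 1), "empty")
})
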