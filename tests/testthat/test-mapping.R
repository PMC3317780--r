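# Density maps, segmentations, super-resolution TDI, transforms, metrics.

test_that("density maps count unique streamline visits per element", {
  grid <- map_grid(c(10, 10, 10), grid_affine(2))
  # x from 1 to 17 mm: the open interior spans voxels 1..8 (the endpoints
  # sit exactly on boundary planes and do not enter voxels 0 / 9)
  line <- cbind(seq(1, 17, 0.2), 5, 5)
  one <- density_map(manual_tractogram(list(line)), grid)
  expect_equal(sum(one$counts > 0), 8)
  expect_true(all(one$counts %in% 0:1))

  two <- density_map(manual_tractogram(list(line, line)), grid)
  expect_true(all(two$counts[two$counts > 0] == 2))

  # U-turn fixture: a streamline re-entering the same element counts once
  uturn <- rbind(c(5, 5, 5), c(6.5, 5, 5), c(5, 5, 5.4))
  u <- density_map(manual_tractogram(list(uturn)), grid)
  expect_equal(max(u$counts), 1)

  expect_error(density_map(manual_tractogram(list()), grid), "empty")
})

test_that("density totals equal the exact segment-box clipping oracle", {
  grid <- map_grid(c(12, 12, 12), grid_affine(2))
  set.seed(8)
  # random jagged streamlines with sub-voxel steps
  pts_list <- replicate(25, {
    n <- sample(5:40, 1)
    start <- runif(3, 4, 20)
    steps <- matrix(rnorm(3 * n, sd = 0.5), ncol = 3)
    sweep(apply(steps, 2, cumsum), 2, start, "+")
  }, simplify = FALSE)
  dm <- density_map(manual_tractogram(pts_list), grid)
  expect_identical(unname(as.integer(dm$counts)),
                   unname(as.integer(oracle_density(pts_list, grid))))
})

test_that("5%-of-max segmentation is inclusive and monotone in the fraction", {
  grid <- map_grid(c(10, 10, 10), grid_affine(2))
  counts <- array(0L, c(10, 10, 10))
  counts[1:3] <- c(100L, 5L, 4L)
  dm <- structure(list(counts = counts, grid_to_world = grid$grid_to_world,
                       n_streamlines_source = 100),
                  class = "density_map")
  seg <- segment_from_density(dm, 0.05)
  expect_identical(which(seg$mask), 1:2)  # 100 and 5 kept, 4 dropped

  uniform <- dm; uniform$counts[1:3] <- 7L
  expect_identical(which(segment_from_density(uniform, 0.05)$mask), 1:3)

  single <- dm; single$counts[] <- 0L; single$counts[42] <- 3L
  expect_identical(which(segment_from_density(single, 0.05)$mask), 42L)

  # raising the fraction never grows the mask
  set.seed(3)
  rnd <- dm; rnd$counts[] <- rpois(1000, 2)
  prev <- segment_from_density(rnd, 0.01)$mask
  for (f in c(0.05, 0.2, 0.5, 0.9)) {
    cur <- segment_from_density(rnd, f)$mask
    expect_true(all(!cur | prev))
    prev <- cur
  }
  empty <- dm; empty$counts[] <- 0L
  expect_error(segment_from_density(empty), "zero")
})

test_that("super-resolution TDI refines counts without smoothing", {
  grid <- map_grid(c(10, 10, 10), grid_affine(2))
  # generic endpoints (not on element boundaries of either grid)
  line <- cbind(seq(1.2, 16.9, 0.1), 5.2, 5.2)
  base <- super_resolution_tdi(manual_tractogram(list(line)), 1, grid)
  ref <- density_map(manual_tractogram(list(line)), grid)
  expect_identical(base$counts, ref$counts)

  sr2 <- super_resolution_tdi(manual_tractogram(list(line)), 2, grid)
  # an axis-aligned line crosses twice as many refined elements
  expect_equal(sum(sr2$counts > 0), 2 * sum(base$counts > 0))

  # refined totals can only split visits, never merge them
  set.seed(4)
  pts_list <- replicate(10, {
    start <- runif(3, 4, 16)
    sweep(apply(matrix(rnorm(45, sd = 0.6), ncol = 3), 2, cumsum), 2,
          start, "+")
  }, simplify = FALSE)
  tg <- manual_tractogram(pts_list)
  expect_gte(sum(super_resolution_tdi(tg, 2, grid)$counts),
             sum(density_map(tg, grid)$counts))
})

test_that("mask resampling under known transforms re-binarizes at 0.01", {
  grid <- map_grid(c(10, 10, 10), grid_affine(2))
  m <- array(FALSE, c(10, 10, 10)); m[4:6, 5, 5] <- TRUE
  seg <- structure(list(mask = m, grid_to_world = grid$grid_to_world,
                        threshold_fraction = 0.05, space = "native"),
                   class = "tract_segmentation")

  ident <- apply_transform_mask(seg, rigid_transform(), grid)
  expect_identical(ident$mask, m)

  shift1 <- apply_transform_mask(seg, rigid_transform(translation = c(2, 0, 0)),
                                 grid)
  expected <- array(FALSE, c(10, 10, 10)); expected[5:7, 5, 5] <- TRUE
  expect_identical(shift1$mask, expected)

  # half-voxel translation of a single-voxel mask: the result equals the
  # 0.01-superlevel set of a brute-force dense interpolation oracle
  m1 <- array(FALSE, c(10, 10, 10)); m1[5, 5, 5] <- TRUE
  seg1 <- structure(list(mask = m1, grid_to_world = grid$grid_to_world,
                         threshold_fraction = 0.05, space = "native"),
                    class = "tract_segmentation")
  half <- apply_transform_mask(seg1, rigid_transform(translation = c(1, 0, 0)),
                               grid)
  centers <- tractrepro:::voxel_centers(c(10, 10, 10), grid$grid_to_world)
  src <- sweep(centers, 2, c(1, 0, 0))  # inverse transform
  vox <- tractrepro:::world_to_grid_points(grid$grid_to_world, src)
  oracle_vals <- apply(vox, 1, function(v) {
    tot <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      i <- floor(v) + c(dx, dy, dz)
      w <- prod(ifelse(c(dx, dy, dz) == 1, v - floor(v), 1 - (v - floor(v))))
      if (all(i >= 0) && all(i < 10))
        tot <- tot + w * m1[i[1] + 1, i[2] + 1, i[3] + 1]
    }
    tot
  })
  expect_identical(as.logical(half$mask), unname(oracle_vals >= 0.01))
})

test_that("streamline mapping to common space preserves rigid geometry", {
  line <- cbind(seq(1, 9, 0.2), 5, 5)
  tg <- manual_tractogram(list(line))
  ident <- map_streamlines_to_common(tg, rigid_transform())
  expect_identical(ident$streamlines[[1]]$points, line)
  expect_equal(ident$space, "common")

  tr <- map_streamlines_to_common(tg, rigid_transform(translation = c(1, 2, 3)))
  d0 <- dist(line)
  d1 <- dist(tr$streamlines[[1]]$points)
  expect_lt(max(abs(d0 - d1)), 1e-9)
})

test_that("tract metrics are exact means and integer-multiple volumes", {
  grid <- map_grid(c(10, 10, 10), grid_affine(2))
  m <- array(FALSE, c(10, 10, 10)); m[1:10] <- TRUE
  seg <- structure(list(mask = m, grid_to_world = grid$grid_to_world,
                        threshold_fraction = 0.05, space = "native"),
                   class = "tract_segmentation")
  fa <- array(0.5, c(10, 10, 10))
  adc <- array(0.8e-3, c(10, 10, 10))
  met <- tract_metrics(seg, fa, adc)
  expect_equal(met$mean_fa, 0.5)
  expect_equal(met$volume_mm3, 10 * 8)

  fa3 <- array(0, c(10, 10, 10)); fa3[1:3] <- c(0.2, 0.4, 0.6)
  m3 <- array(FALSE, c(10, 10, 10)); m3[1:3] <- TRUE
  seg3 <- seg; seg3$mask <- m3
  expect_equal(tract_metrics(seg3, fa3, adc)$mean_fa, 0.4)

  expect_error(tract_metrics(seg, array(0, c(5, 5, 5)), adc), "match")

  # volume is always an integer multiple of the voxel volume
  set.seed(5)
  for (i in 1:5) {
    mr <- array(runif(1000) < 0.3, c(10, 10, 10))
    segr <- seg; segr$mask <- mr
    vol <- tract_metrics(segr, fa, adc)$volume_mm3
    ratio <- vol / tractrepro:::grid_voxel_volume(grid)
    expect_lt(abs(ratio - round(ratio)), 1e-9)
    expect_equal(round(ratio), sum(mr))
  }
})

test_that("group TDI averaging is an exact elementwise mean", {
  grid <- grid_affine(2)
  mk <- function(vals) structure(list(counts = array(vals, c(2, 2, 1)),
                                      grid_to_world = grid,
                                      n_streamlines_source = 10),
                                 class = "density_map")
  a <- mk(c(0, 2, 4, 6)); b <- mk(c(2, 0, 4, 2))
  avg <- tdi_group_average(list(a, b))
  expect_equal(as.numeric(avg$counts), c(1, 1, 4, 4))
  expect_equal(tdi_group_average(list(a))$counts, a$counts + 0)

  set.seed(6)
  maps <- lapply(1:4, function(i) mk(rpois(4, 5)))
  brute <- Reduce(`+`, lapply(maps, function(m) m$counts + 0)) / 4
  expect_lt(max(abs(tdi_group_average(maps)$counts - brute)), 1e-12)

  bad <- mk(1:4); bad$grid_to_world <- grid_affine(1)
  expect_error(tdi_group_average(list(a, bad)), "common grid")
})
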