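# Capsule tube geometry, tissue extraction and raw damage aggregation.

test_that("capsule membership: axis, boundary, and swept-sphere agreement", {
  tube <- trajectory_tube(c(0, 0, 0), c(20, 0, 0), radius = 5)
  mid <- c(10, 0, 0)
  expect_true(point_in_tube(mid, tube))
  expect_false(point_in_tube(mid + c(0, 5 + 1e-6, 0), tube))
  expect_true(point_in_tube(mid + c(0, 5 - 1e-9, 0), tube))
  # hemispherical caps: points beyond the endpoints but within the radius
  expect_true(point_in_tube(c(-4.9, 0, 0), tube))
  expect_false(point_in_tube(c(-5.1, 0, 0), tube))
  # flat caps exclude the cap regions
  flat <- trajectory_tube(c(0, 0, 0), c(20, 0, 0), radius = 5, cap = "flat")
  expect_false(point_in_tube(c(-0.1, 0, 0), flat))
  expect_true(point_in_tube(c(0.1, 0, 0), flat))

  set.seed(31)
  entry <- c(-12, 7, 3); target <- c(15, -5, 9); r <- 5
  tube2 <- trajectory_tube(entry, target, r)
  pts <- matrix(runif(3000, -25, 25), ncol = 3L)
  step <- r / 10
  sweep_verdict <- oracle_swept_sphere(pts, entry, target, r, step)
  analytic <- point_in_tube(pts, tube2)
  # verdicts must agree away from the sampling-induced boundary band
  d <- sqrt(neuroplanr:::segment_dist2(pts, entry, target)$dist2)
  clear <- abs(d - r) > step / 2
  expect_gt(sum(clear), 900L)
  expect_identical(analytic[clear], sweep_verdict[clear])
})

test_that("degenerate tubes are rejected", {
  expect_error(trajectory_tube(c(0, 0, 0), c(0, 0, 0), 5), "zero length")
  expect_error(trajectory_tube(c(0, 0, 0), c(1, 0, 0), 0), "positive")
  expect_error(trajectory_tube(c(0, 0, NA), c(1, 0, 0), 5), "finite")
})

test_that("tissue extraction matches the exhaustive full scan", {
  ph <- phantom32(seed = 21L)
  cache <- scene_cache(ph$parcellation, ph$tractogram)
  set.seed(21)
  for (i in 1:5) {
    entry <- runif(3, -35, 35)
    target <- runif(3, -15, 15)
    tube <- trajectory_tube(entry, target, 5)
    inv <- extract_tissue(tube, ph$parcellation, ph$tractogram,
                          cache = cache)
    ref <- oracle_full_scan(tube, ph$parcellation, ph$tractogram)
    expect_identical(inv$gm_voxels, ref$gm_voxels)
    expect_identical(inv$fiber_indices, ref$fiber_indices)
    expect_equal(unname(inv$gm_volume),
                 unname(inv$gm_voxels) * ph$parcellation$voxel_volume)
  }
})

test_that("tube outside the scene yields an empty inventory", {
  ph <- phantom32(seed = 1L)
  tube <- trajectory_tube(c(200, 200, 200), c(250, 200, 200), 5)
  inv <- extract_tissue(tube, ph$parcellation, ph$tractogram)
  expect_length(inv$gm_voxels, 0L)
  expect_length(inv$fiber_indices, 0L)
  expect_equal(unname(raw_damage(
    inv, compute_gm_scores(ph$fc, ph$sc, ph$parcellation))),
    c(0, 0, 0, 0))
})

test_that("bounding-box pruning is invisible in the result", {
  ph <- phantom32(seed = 12L)
  cache <- scene_cache(ph$parcellation, ph$tractogram)
  set.seed(12)
  for (i in 1:4) {
    tube <- trajectory_tube(runif(3, -40, 40), runif(3, -10, 10), 6)
    a <- extract_tissue(tube, ph$parcellation, cache = cache, prune = TRUE)
    b <- extract_tissue(tube, ph$parcellation, cache = cache, prune = FALSE)
    expect_identical(a$gm_voxels, b$gm_voxels)
    expect_identical(a$fiber_indices, b$fiber_indices)
  }
})

test_that("inventories and damages are monotone in radius", {
  ph <- phantom32(seed = 6L)
  gm <- compute_gm_scores(ph$fc, ph$sc, ph$parcellation)
  fib <- compute_fiber_scores(ph$tractogram, ph$parcellation, gm)
  cache <- scene_cache(ph$parcellation, ph$tractogram)
  entry <- c(40, 10, 8); target <- c(0, -5, 0)
  prev_counts <- NULL; prev_damage <- NULL
  for (r in c(2, 5, 8, 10)) {
    inv <- extract_tissue(trajectory_tube(entry, target, r),
                          ph$parcellation, cache = cache)
    total <- sum(inv$gm_voxels)
    dmg <- raw_damage(inv, gm, fib)
    if (!is.null(prev_counts)) {
      expect_gte(total, prev_counts)
      expect_true(all(dmg >= prev_damage))
    }
    prev_counts <- total; prev_damage <- dmg
  }
})

test_that("translating scene and tube together leaves the inventory unchanged", {
  arr <- array(0L, dim = c(10L, 10L, 10L))
  arr[3:8, 3:8, 3:8] <- 1L
  shift <- c(13, -7, 4)
  parc0 <- parcellation(arr, diag(4))
  aff <- diag(4); aff[1:3, 4L] <- shift
  parc1 <- parcellation(arr, aff)
  entry <- c(-2, 5, 5); target <- c(12, 5, 5)
  inv0 <- extract_tissue(trajectory_tube(entry, target, 3), parc0)
  inv1 <- extract_tissue(trajectory_tube(entry + shift, target + shift, 3),
                         parc1)
  expect_identical(inv0$gm_voxels, inv1$gm_voxels)
})

test_that("raw damage weights volumes by scores and sums fibre scores", {
  # single region, 10 mm^3 intersected, FCGM = 2 -> fcgm_path = 20
  arr <- array(0L, dim = c(10L, 4L, 4L))
  arr[1:10, 1L, 1L] <- 1L
  arr[1L, 2L, 2L] <- 2L
  parc <- parcellation(arr, diag(4))
  fc <- connectivity_matrix(matrix(c(0, 2, 2, 0), 2L))
  sc <- connectivity_matrix(matrix(c(0, 4, 4, 0), 2L),
                            flavour = "structural")
  gm <- compute_gm_scores(fc, sc, parc)
  expect_equal(gm$fcgm, c(2, 2))
  tube <- trajectory_tube(c(-0.5, 0, 0), c(9.5, 0, 0), radius = 0.6)
  inv <- extract_tissue(tube, parc)
  expect_equal(sum(inv$gm_volume), 10)
  dmg <- raw_damage(inv, gm)
  expect_equal(dmg[["fcgm_path"]], 20)

  # random phantom scene equals explicit recomputation
  ph <- phantom32(seed = 14L)
  gm2 <- compute_gm_scores(ph$fc, ph$sc, ph$parcellation)
  fib2 <- compute_fiber_scores(ph$tractogram, ph$parcellation, gm2)
  tube2 <- trajectory_tube(c(30, 12, -8), c(0, 0, 0), 5)
  inv2 <- extract_tissue(tube2, ph$parcellation, ph$tractogram)
  dmg2 <- raw_damage(inv2, gm2, fib2)
  exp_fcgm <- 0; exp_scgm <- 0
  for (lab in names(inv2$gm_volume)) {
    row <- gm2[gm2$label == as.integer(lab), ]
    exp_fcgm <- exp_fcgm + inv2$gm_volume[[lab]] * row$fcgm
    exp_scgm <- exp_scgm + inv2$gm_volume[[lab]] * row$scgm
  }
  exp_fcwm <- 0; exp_scwm <- 0
  for (p in inv2$fiber_indices) {
    exp_fcwm <- exp_fcwm + fib2$fcwm[fib2$index == p]
    exp_scwm <- exp_scwm + fib2$scwm[fib2$index == p]
  }
  expect_equal(unname(dmg2),
               c(exp_fcgm, exp_scgm, exp_fcwm, exp_scwm),
               tolerance = 1e-12)

  # unknown label in the inventory is an error
  inv_bad <- inv
  names(inv_bad$gm_voxels) <- "99"
  names(inv_bad$gm_volume) <- "99"
  expect_error(raw_damage(inv_bad, gm), "absent")
})
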