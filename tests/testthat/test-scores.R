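# Eloquence scores: node-strength formulas for grey-matter regions and
# mean-of-member-regions scores for fibres.

test_that("functional GM score is the unsigned weighted degree", {
  z <- connectivity_matrix(matrix(0, 3L, 3L))
  expect_equal(unname(compute_fcgm(z)), c(0, 0, 0))

  m <- matrix(-0.5, 3L, 3L); diag(m) <- 1
  cm <- connectivity_matrix(m)
  expect_equal(unname(compute_fcgm(cm)), c(1, 1, 1))

  expect_error(compute_fcgm(connectivity_matrix(abs(m),
                                                flavour = "structural")),
               "functional")
})

test_that("structural GM score divides node strength by region volume", {
  arr <- array(0L, dim = c(6L, 4L, 4L))
  arr[1:5, 1L, 1L] <- 1L          # L_1 = 5 mm^3 at 1 mm voxels
  arr[6L, , ] <- 2L
  parc <- parcellation(arr, diag(4))
  sc <- connectivity_matrix(matrix(c(0, 10, 10, 0), 2L),
                            flavour = "structural")
  scgm <- compute_scgm(sc, parc)
  expect_equal(scgm[["1"]], 2)    # 10 fibres / 5 mm^3

  sc2 <- connectivity_matrix(2 * sc$values, flavour = "structural")
  expect_equal(compute_scgm(sc2, parc), 2 * scgm)

  sc3 <- connectivity_matrix(matrix(c(0, 1, 1, 0), 2L),
                             labels = c(1L, 9L), flavour = "structural")
  expect_error(compute_scgm(sc3, parc), "missing.*9")
})

test_that("GM scores match the loop-based recomputation on random input", {
  set.seed(7)
  ph <- phantom32(seed = 7L)
  oracle <- oracle_gm_scores(ph$fc, ph$sc, ph$parcellation)
  gm <- compute_gm_scores(ph$fc, ph$sc, ph$parcellation)
  expect_equal(gm$fcgm, unname(oracle$fcgm), tolerance = 1e-12)
  expect_equal(gm$scgm, unname(oracle$scgm), tolerance = 1e-12)

  a <- matrix(rnorm(100), 10L)
  cm <- connectivity_matrix((a + t(a)) / 2)
  expect_equal(unname(compute_fcgm(cm)),
               sapply(1:10, function(k) sum(abs(cm$values[k, ]))))
})

test_that("fibre-region assignment walks every traversed voxel", {
  parc <- slab_parcellation()   # labels 1|2|3 as x-slabs of 4 voxels each
  # straight line within the first slab
  s1 <- rbind(c(0.2, 2, 2), c(2.8, 2, 2))
  expect_identical(assign_fiber_rois(s1, parc), 1L)
  # long diagonal-ish line crossing slabs 1 and 2 only
  s2 <- rbind(c(0.2, 1, 1), c(6.8, 5, 5))
  expect_identical(assign_fiber_rois(s2, parc), c(1L, 2L))
  # sparse two-vertex streamline spanning all three slabs: resampling must
  # not skip the middle slab
  s3 <- rbind(c(0.2, 2, 2), c(11.5, 2, 2))
  expect_identical(assign_fiber_rois(s3, parc), c(1L, 2L, 3L))
  # entirely outside the volume
  s4 <- rbind(c(-30, -30, -30), c(-20, -30, -30))
  expect_identical(assign_fiber_rois(s4, parc), integer(0))
})

test_that("fibre scores average member-region scores; empty sets score 0", {
  parc <- slab_parcellation()
  fc <- connectivity_matrix(matrix(c(0, .5, 1, .5, 0, 2, 1, 2, 0), 3L))
  sc <- connectivity_matrix(matrix(c(0, 4, 8, 4, 0, 16, 8, 16, 0), 3L),
                            flavour = "structural")
  gm <- compute_gm_scores(fc, sc, parc)
  tr <- tractogram(list(
    rbind(c(0.2, 2, 2), c(2.8, 2, 2)),          # slab 1 only
    rbind(c(0.2, 2, 2), c(6.8, 2, 2)),          # slabs 1 and 2
    rbind(c(-30, -30, -30), c(-20, -30, -30)))) # background
  fib <- compute_fiber_scores(tr, parc, gm)
  expect_equal(fib$fcwm[1L], gm$fcgm[1L])
  expect_equal(fib$scwm[1L], gm$scgm[1L])
  expect_equal(fib$fcwm[2L], mean(gm$fcgm[1:2]))
  expect_equal(fib$scwm[2L], mean(gm$scgm[1:2]))
  expect_true(fib$unassigned[3L])
  expect_identical(fib$fcwm[3L], 0)
  expect_identical(fib$scwm[3L], 0)
  # two-point mean example
  expect_equal(mean(c(1, 3)), 2)
  # fibre scores bracketed by member region scores
  for (p in which(!fib$unassigned)) {
    members <- match(fib$rois[[p]], gm$label)
    expect_gte(fib$fcwm[p], min(gm$fcgm[members]))
    expect_lte(fib$fcwm[p], max(gm$fcgm[members]))
  }
})

test_that("phantom fibre scores equal an independent per-fibre loop", {
  ph <- phantom32(seed = 9L)
  gm <- compute_gm_scores(ph$fc, ph$sc, ph$parcellation)
  fib <- compute_fiber_scores(ph$tractogram, ph$parcellation, gm)
  oracle <- oracle_fiber_scores(ph$tractogram, ph$parcellation,
                                as.list(setNames(gm$fcgm, gm$label)),
                                as.list(setNames(gm$scgm, gm$label)))
  expect_equal(fib$fcwm, unname(oracle[, "fcwm"]), tolerance = 1e-12)
  expect_equal(fib$scwm, unname(oracle[, "scwm"]), tolerance = 1e-12)
  expect_true(all(fib$fcwm >= 0) && all(fib$scwm >= 0))
})

test_that("scores are scale-equivariant and label-order invariant", {
  ph <- phantom32(seed = 4L)
  fcgm <- compute_fcgm(ph$fc)
  scaled <- connectivity_matrix(3.7 * ph$fc$values, labels = ph$fc$labels)
  expect_equal(compute_fcgm(scaled), 3.7 * fcgm, tolerance = 1e-12)

  perm <- sample(length(ph$fc$labels))
  permuted <- connectivity_matrix(ph$fc$values[perm, perm],
                                  labels = ph$fc$labels[perm])
  fcgm_perm <- compute_fcgm(permuted)
  expect_equal(fcgm_perm[names(fcgm)], fcgm, tolerance = 1e-12)
})

test_that("score tables export to CSV with collapsed region sets", {
  ph <- phantom32(seed = 1L)
  gm <- compute_gm_scores(ph$fc, ph$sc, ph$parcellation)
  fib <- compute_fiber_scores(ph$tractogram, ph$parcellation, gm)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_scores(gm, f1); write_scores(fib, f2)
  back <- read.csv(f1)
  expect_equal(back$fcgm, gm$fcgm, tolerance = 1e-6)
  fb <- read.csv(f2)
  expect_equal(nrow(fb), length(ph$tractogram$streamlines))
  expect_true(is.character(fb$rois) || is.logical(fb$rois))
})
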