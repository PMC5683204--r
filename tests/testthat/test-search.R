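# Entry-point grid, min-max normalisation, total score, exhaustive search.

test_that("five-face grid on a 100 mm cube at 10 mm spacing has 521 points", {
  box <- search_box(center = c(0, 0, 0), half_extents = c(50, 50, 50),
                    spacing = 10)
  grid <- build_entry_grid(box)
  expect_equal(nrow(grid), 521L)
  ref <- oracle_surface_grid(c(0, 0, 0), c(50, 50, 50), 10)
  expect_equal(nrow(ref), 521L)
  expect_equal(grid, ref, ignore_attr = TRUE)
  expect_false(any(duplicated(apply(round(grid, 6), 1, paste,
                                    collapse = "/"))))
  # no base-face-interior point: z = -50 implies on an edge of that face
  base <- grid[abs(grid[, 3L] + 50) < 1e-9, , drop = FALSE]
  expect_true(all(abs(abs(base[, 1L]) - 50) < 1e-9 |
                  abs(abs(base[, 2L]) - 50) < 1e-9))
})

test_that("grid degenerates gracefully and rejects oversized spacing", {
  box <- search_box(center = c(0, 0, 0), half_extents = c(50, 50, 50),
                    spacing = 100)
  g <- build_entry_grid(box)   # corners only (base corners shared)
  expect_equal(nrow(g), 8L)
  expect_error(build_entry_grid(
    search_box(center = c(0, 0, 0), half_extents = c(50, 50, 50),
               spacing = 101)), "exceeds")
  # non-divisible spacing: per-axis lattice centred, still on the faces
  box2 <- search_box(center = c(0, 0, 0), half_extents = c(50, 50, 50),
                     spacing = 30)
  g2 <- build_entry_grid(box2)
  expect_true(all(apply(g2, 1L, function(p) any(abs(abs(p) - 50) < 1e-9))))
})

test_that("search box derived from a parcellation contains all labeled voxels", {
  ph <- phantom32(seed = 8L)
  box <- search_box(ph$parcellation, margin = 10)
  vc <- neuroplanr:::labeled_voxel_centers(ph$parcellation)$centers
  for (a in 1:3) {
    expect_lte(max(vc[, a]), box$center[a] + box$half_extents[a])
    expect_gte(min(vc[, a]), box$center[a] - box$half_extents[a])
  }
  expect_error(search_box(ph$parcellation, base_face = "bottom"))
})

test_that("min-max scaling and total score follow the defining formulas", {
  expect_equal(minmax_normalize(c(0, 5, 10)), c(0, 0.5, 1))
  expect_equal(minmax_normalize(c(7, 7, 7)), c(0, 0, 0))
  expect_error(minmax_normalize(numeric(0)), "empty")
  expect_error(minmax_normalize(c(1, NA)), "finite")
  set.seed(99)
  x <- rnorm(50)
  expect_equal(minmax_normalize(x), (x - min(x)) / (max(x) - min(x)))

  expect_equal(total_score(c(0, 0, 0, 0)), 0)
  expect_equal(total_score(c(1, 1, 1, 1)), 4)
  expect_equal(total_score(c(0.2, 0.3, 0.1, 0.4)), 1.0)
  expect_equal(total_score(c(0.2, 0.3, 0.1, 0.4), scale = 100), 100)
})

test_that("normalisation contract and dominance hold for random searches", {
  set.seed(123)
  raw_a <- matrix(rexp(1000 * 4L), ncol = 4L)
  delta <- matrix(rexp(1000 * 4L, rate = 2), ncol = 4L)
  raw_b <- pmax(raw_a - delta, 0)   # b dominated by a, componentwise
  pop <- rbind(raw_a, raw_b)
  norm <- apply(pop, 2L, minmax_normalize)
  expect_true(all(norm >= 0 & norm <= 1))
  expect_equal(unname(apply(norm, 2L, min)), rep(0, 4L))
  expect_equal(unname(apply(norm, 2L, max)), rep(1, 4L))
  t_all <- total_score(norm)
  expect_true(all(t_all >= 0 & t_all <= 4))
  expect_true(all(t_all[1:1000] >= t_all[1001:2000]))
})

test_that("exhaustive search covers the grid and normalises per component", {
  ph <- phantom32(seed = 5L)
  gm <- compute_gm_scores(ph$fc, ph$sc, ph$parcellation)
  fib <- compute_fiber_scores(ph$tractogram, ph$parcellation, gm)
  box <- search_box(ph$parcellation, spacing = 20)
  rmap <- exhaustive_search(c(0, 0, 0), box, ph$parcellation,
                            ph$tractogram, gm, fib)
  grid <- build_entry_grid(box)
  expect_equal(nrow(rmap$entries), nrow(grid))
  for (col in c("fcgm_norm", "scgm_norm", "fcwm_norm", "scwm_norm")) {
    v <- rmap$entries[[col]]
    expect_true(all(v >= 0 & v <= 1))
    rawcol <- rmap$entries[[sub("norm", "path", col)]]
    if (max(rawcol) > min(rawcol)) {
      expect_equal(min(v), 0)
      expect_equal(max(v), 1)
    } else {
      expect_true(all(v == 0))
    }
  }
  expect_true(all(rmap$entries$t_score >= 0 & rmap$entries$t_score <= 4))
  # optimum attains the minimum with the documented tie-breaks
  expect_equal(rmap$entries$t_score[rmap$optimal],
               min(rmap$entries$t_score))
  expect_true(rmap$entries$is_optimal[rmap$optimal])
  # target outside the box is rejected
  expect_error(exhaustive_search(c(500, 0, 0), box, ph$parcellation,
                                 ph$tractogram, gm, fib),
               "outside")
})

test_that("search is deterministic: identical inputs, identical CSV bytes", {
  ph <- phantom32(seed = 10L)
  gm <- compute_gm_scores(ph$fc, ph$sc, ph$parcellation)
  fib <- compute_fiber_scores(ph$tractogram, ph$parcellation, gm)
  box <- search_box(ph$parcellation, spacing = 25)
  run_once <- function() {
    rmap <- exhaustive_search(c(0, 0, 0), box, ph$parcellation,
                              ph$tractogram, gm, fib)
    prefix <- tempfile()
    write_risk_map(rmap, ph$parcellation, prefix)
    paste0(prefix, ".csv")
  }
  f1 <- run_once(); f2 <- run_once()
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("a search with an empty half-space scores those entries zero", {
  # single off-centre block: tubes approaching from the far side of the box
  # still reach the target, but entries whose tubes miss the block entirely
  # have zero raw damage in all components
  arr <- array(0L, dim = c(20L, 20L, 20L))
  arr[2:6, 9:12, 9:12] <- 1L
  arr[7:9, 9:12, 9:12] <- 2L
  aff <- diag(4); aff[1:3, 4L] <- -10
  parc <- parcellation(arr, aff)
  fc <- connectivity_matrix(matrix(c(0, .5, .5, 0), 2L))
  sc <- connectivity_matrix(matrix(c(0, 3, 3, 0), 2L),
                            flavour = "structural")
  gm <- compute_gm_scores(fc, sc, parc)
  fib <- compute_fiber_scores(tractogram(list()), parc, gm)
  box <- search_box(parc, margin = 8, spacing = 10)
  target <- c(-4, 7, 7)   # in empty space, > radius away from the block
  rmap <- exhaustive_search(target, box, parc, tractogram(list()), gm, fib)
  empty <- rowSums(as.matrix(
    rmap$entries[, c("fcgm_path", "scgm_path", "fcwm_path",
                     "scwm_path")])) == 0
  expect_gt(sum(empty), 0L)
  expect_true(all(rmap$entries$t_score[empty] == 0))
})
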