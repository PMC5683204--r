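# Independent reference implementations ("oracles") used to check the
# package's analytic/pruned code paths. These deliberately use different
# constructions than the implementation: the swept-sphere point cloud for
# tube membership, the cylinder-plus-endcap-spheres decomposition of the
# capsule, and explicit elementwise loops for the score formulas.

# membership in the volume swept by a sphere moving along the segment,
# decided by sampling sphere centres at the given step
oracle_swept_sphere <- function(pts, entry, target, radius,
                                step = radius / 10) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3L)
  L <- sqrt(sum((target - entry)^2))
  nc <- max(2L, ceiling(L / step) + 1L)
  ts <- seq(0, 1, length.out = nc)
  centers <- cbind(entry[1L] + ts * (target[1L] - entry[1L]),
                   entry[2L] + ts * (target[2L] - entry[2L]),
                   entry[3L] + ts * (target[3L] - entry[3L]))
  r2 <- radius^2
  vapply(seq_len(nrow(pts)), function(i) {
    d2 <- (centers[, 1L] - pts[i, 1L])^2 + (centers[, 2L] - pts[i, 2L])^2 +
          (centers[, 3L] - pts[i, 3L])^2
    any(d2 <= r2)
  }, logical(1))
}

# exact capsule membership via the finite-cylinder + end-sphere union,
# a different decomposition than the point-to-segment distance
oracle_capsule <- function(pts, entry, target, radius) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3L)
  u <- target - entry
  L <- sqrt(sum(u^2))
  u <- u / L
  pa <- sweep(pts, 2L, entry)
  ax <- as.vector(pa %*% u)
  perp2 <- rowSums(pa^2) - ax^2
  in_cyl <- ax >= 0 & ax <= L & perp2 <= radius^2
  in_cap_a <- rowSums(pa^2) <= radius^2
  pb <- sweep(pts, 2L, target)
  in_cap_b <- rowSums(pb^2) <= radius^2
  in_cyl | in_cap_a | in_cap_b
}

# exhaustive all-voxel / all-fibre scan of a tube, no pruning, no caching
oracle_full_scan <- function(tube, parc, tract = NULL, step = NULL) {
  if (is.null(step)) step <- parc$min_edge / 2
  d <- dim(parc$labels)
  idx <- expand.grid(i = 0:(d[1L] - 1L), j = 0:(d[2L] - 1L),
                     k = 0:(d[3L] - 1L))
  w <- cbind(as.matrix(idx), 1) %*% t(parc$affine)
  inside <- oracle_capsule(w[, 1:3], tube$entry, tube$target, tube$radius)
  labs <- as.vector(parc$labels)[inside]
  labs <- labs[labs > 0L]
  counts <- table(labs)
  gm_voxels <- stats::setNames(as.integer(counts), names(counts))
  fiber_indices <- integer(0)
  if (!is.null(tract)) {
    for (p in seq_along(tract$streamlines)) {
      v <- resample_polyline(tract$streamlines[[p]], step)
      if (any(oracle_capsule(v, tube$entry, tube$target, tube$radius)))
        fiber_indices <- c(fiber_indices, p)
    }
  }
  list(gm_voxels = gm_voxels, fiber_indices = fiber_indices)
}

# node-strength score formulas recomputed with explicit elementwise loops
oracle_gm_scores <- function(fc, sc, parc) {
  n <- length(fc$labels)
  fcgm <- numeric(n)
  scgm <- numeric(n)
  for (k in seq_len(n)) {
    sf <- 0; ss <- 0
    for (j in seq_len(n)) {
      sf <- sf + abs(fc$values[k, j])
      ss <- ss + abs(sc$values[k, j])
    }
    fcgm[k] <- sf
    scgm[k] <- ss / parc$roi_volumes[[as.character(fc$labels[k])]]
  }
  list(fcgm = stats::setNames(fcgm, fc$labels),
       scgm = stats::setNames(scgm, sc$labels))
}

# per-fibre mean-of-member-regions scores, recomputed by an explicit loop
oracle_fiber_scores <- function(tract, parc, fcgm, scgm, step = NULL) {
  n <- length(tract$streamlines)
  out <- matrix(0, n, 2L, dimnames = list(NULL, c("fcwm", "scwm")))
  for (p in seq_len(n)) {
    rois <- assign_fiber_rois(tract$streamlines[[p]], parc, step)
    if (length(rois) == 0L) next
    sf <- 0; ss <- 0
    for (r in rois) {
      sf <- sf + fcgm[[as.character(r)]]
      ss <- ss + scgm[[as.character(r)]]
    }
    out[p, ] <- c(sf, ss) / length(rois)
  }
  out
}

# brute-force enumeration of the five-face lattice of a cube-like box
oracle_surface_grid <- function(center, half_extents, spacing,
                                base_face = "-z") {
  lo <- center - half_extents
  hi <- center + half_extents
  ax <- lapply(1:3, function(a) seq(lo[a], hi[a], by = spacing))
  full <- as.matrix(expand.grid(ax[[1L]], ax[[2L]], ax[[3L]]))
  on_face <- function(a, v) abs(full[, a] - v) < 1e-9
  surface <- on_face(1, lo[1]) | on_face(1, hi[1]) |
             on_face(2, lo[2]) | on_face(2, hi[2]) |
             on_face(3, lo[3]) | on_face(3, hi[3])
  base_axis <- match(substr(base_face, 2L, 2L), c("x", "y", "z"))
  base_at <- if (substr(base_face, 1L, 1L) == "-") lo[base_axis]
             else hi[base_axis]
  others <- setdiff(1:3, base_axis)
  base_interior <- on_face(base_axis, base_at) &
    !(on_face(others[1L], lo[others[1L]]) |
      on_face(others[1L], hi[others[1L]]) |
      on_face(others[2L], lo[others[2L]]) |
      on_face(others[2L], hi[others[2L]]))
  pts <- full[surface & !base_interior, , drop = FALSE]
  pts[order(pts[, 1L], pts[, 2L], pts[, 3L]), , drop = FALSE]
}

# independent ray marching from entry toward target at the given step
oracle_path_length <- function(entry, target, parc, step) {
  L <- sqrt(sum((target - entry)^2))
  tt <- 0
  dirv <- (target - entry) / L
  while (tt <= L) {
    p <- entry + tt * dirv
    if (labels_at(parc, p) > 0L) return(L - tt)
    tt <- tt + step
  }
  if (labels_at(parc, target) > 0L) return(0)
  stop("oracle: ray never enters labeled tissue")
}
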