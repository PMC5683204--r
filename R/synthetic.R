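# Seeded phantom generator. Emulates the four pipeline inputs on a
# desk-scale head phantom: an ellipsoidal "brain" partitioned into angular
# sector regions on a 2 mm isotropic grid, jittered polyline streamline
# bundles between region centroids, a structural matrix that is exactly the
# endpoint-count matrix of the generated streamlines, and a symmetric
# functional matrix of baseline noise with optional amplified hub regions.
# A single integer seed fully determines every output.

#' Specify a phantom scene
#'
#' @param grid_shape voxel grid dimensions (default 64^3).
#' @param voxel_size isotropic voxel edge, mm (default 2).
#' @param n_rois number of angular-sector regions (>= 2, default 8).
#' @param bundles data.frame with columns `roi_a`, `roi_b`, `n_streamlines`
#'   and optionally `jitter` (mm); defaults to one 10-streamline bundle
#'   between each region and its diametric opposite.
#' @param hub_labels integer labels whose functional connectivity is
#'   amplified.
#' @param hub_gain target ratio of a hub's node strength to the strongest
#'   non-hub (default 3.5).
#' @param fc_noise std of the baseline functional edge weights (default
#'   0.1).
#' @param jitter default streamline jitter, mm.
#' @param n_points control points per streamline polyline.
#' @param seed integer seed; fully determines the phantom.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 64L), voxel_size = 2,
                         n_rois = 8L, bundles = NULL,
                         hub_labels = integer(0), hub_gain = 3.5,
                         fc_noise = 0.1, jitter = 1, n_points = 15L,
                         seed = 1L) {
  n_rois <- as.integer(n_rois)
  if (n_rois < 2L) stop("a phantom needs at least 2 regions")
  if (is.null(bundles)) {
    half <- n_rois %/% 2L
    bundles <- data.frame(roi_a = seq_len(half),
                          roi_b = seq_len(half) + half,
                          n_streamlines = 10L)
  }
  if (is.null(bundles$jitter)) bundles$jitter <- jitter
  if (any(bundles$roi_a == bundles$roi_b))
    stop("bundle endpoints must reference two distinct regions")
  if (any(bundles$roi_a < 1L | bundles$roi_a > n_rois |
          bundles$roi_b < 1L | bundles$roi_b > n_rois))
    stop("bundle endpoints reference labels outside 1..n_rois")
  hub_labels <- as.integer(hub_labels)
  if (any(hub_labels < 1L | hub_labels > n_rois))
    stop("hub labels outside 1..n_rois")
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size = voxel_size, n_rois = n_rois,
                 bundles = bundles, hub_labels = hub_labels,
                 hub_gain = hub_gain, fc_noise = fc_noise,
                 jitter = jitter, n_points = as.integer(n_points),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# sector label of world points: wedges of 2*pi/n around the z axis, rotated
# half a wedge so the +x axis is interior to sector 1 and -x interior to the
# diametrically opposite sector (the layout is mirror-symmetric in x)
sector_label <- function(xy, n) {
  phi <- (atan2(xy[, 2L], xy[, 1L]) + pi / n) %% (2 * pi)
  pmin(as.integer(floor(phi / (2 * pi / n))) + 1L, n)
}

#' Generate a phantom scene
#'
#' Builds the labeled ellipsoid volume (semi-axes at 3/4 of the half
#' field-of-view), the streamline bundles, the structural matrix counted
#' from the generated streamline endpoints (hence consistent by
#' construction), and the functional matrix. `ground_truth` records the
#' generator's own bookkeeping — per-region volumes, per-bundle streamline
#' indices, and grey-matter scores recomputed here by explicit loops —
#' against which the analysis modules can be checked end to end.
#'
#' @param spec a [phantom_spec()].
#' @return list of class `phantom` with elements `parcellation`,
#'   `tractogram`, `fc`, `sc`, `ground_truth`, `spec`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  local_seed(spec$seed, {
    d <- spec$grid_shape
    vs <- spec$voxel_size
    affine <- diag(c(vs, vs, vs, 1))
    affine[1:3, 4L] <- -(d * vs) / 2 + vs / 2   # grid centred on the origin
    # world coordinates of all voxel centres
    i <- rep.int(seq_len(d[1L]) - 1L, d[2L] * d[3L])
    j <- rep.int(rep(seq_len(d[2L]) - 1L, each = d[1L]), d[3L])
    k <- rep(seq_len(d[3L]) - 1L, each = d[1L] * d[2L])
    w <- cbind(i * vs + affine[1L, 4L],
               j * vs + affine[2L, 4L],
               k * vs + affine[3L, 4L])
    semi <- 0.75 * (d * vs) / 2
    inside <- (w[, 1L] / semi[1L])^2 + (w[, 2L] / semi[2L])^2 +
              (w[, 3L] / semi[3L])^2 <= 1
    labels <- integer(nrow(w))
    labels[inside] <- sector_label(w[inside, 1:2, drop = FALSE], spec$n_rois)
    parc <- parcellation(array(labels, dim = d), affine)

    centroids <- matrix(0, spec$n_rois, 3L)
    for (r in seq_len(spec$n_rois))
      centroids[r, ] <- colMeans(w[labels == r, , drop = FALSE])

    # streamlines: jittered polylines between (jittered) centroid endpoints;
    # endpoint jitter is rejection-sampled so the endpoint voxel keeps the
    # intended label, making SC match the bundle plan exactly
    sample_endpoint <- function(roi, jit) {
      for (try in 1:50) {
        p <- centroids[roi, ] + stats::rnorm(3L, 0, jit)
        if (labels_at(parc, p) == roi) return(p)
      }
      centroids[roi, ]
    }
    streamlines <- list()
    bundle_indices <- vector("list", nrow(spec$bundles))
    for (b in seq_len(nrow(spec$bundles))) {
      bs <- spec$bundles[b, ]
      idx <- integer(bs$n_streamlines)
      for (s in seq_len(bs$n_streamlines)) {
        p0 <- sample_endpoint(bs$roi_a, bs$jitter)
        p1 <- sample_endpoint(bs$roi_b, bs$jitter)
        t <- seq(0, 1, length.out = spec$n_points)
        line <- outer(1 - t, p0) + outer(t, p1)
        if (spec$n_points > 2L) {
          mid <- 2:(spec$n_points - 1L)
          line[mid, ] <- line[mid, ] +
            matrix(stats::rnorm(length(mid) * 3L, 0, bs$jitter),
                   ncol = 3L)
        }
        streamlines[[length(streamlines) + 1L]] <- line
        idx[s] <- length(streamlines)
      }
      bundle_indices[[b]] <- idx
    }
    tract <- tractogram(streamlines)

    # SC is literally the endpoint-count matrix of the generated streamlines
    scm <- matrix(0, spec$n_rois, spec$n_rois)
    for (s in tract$streamlines) {
      a <- labels_at(parc, s[1L, ])
      b <- labels_at(parc, s[nrow(s), ])
      if (a > 0L && b > 0L && a != b) {
        scm[a, b] <- scm[a, b] + 1
        scm[b, a] <- scm[b, a] + 1
      }
    }
    sc <- connectivity_matrix(scm, labels = seq_len(spec$n_rois),
                              flavour = "structural")

    # FC: symmetric clipped-normal baseline; hub rows/columns replaced by
    # high-magnitude edges, then checked to dominate by the requested gain
    fcm <- matrix(stats::rnorm(spec$n_rois^2, 0, spec$fc_noise),
                  spec$n_rois)
    fcm <- (fcm + t(fcm)) / 2
    fcm <- pmin(pmax(fcm, -1), 1)
    diag(fcm) <- 0
    for (h in spec$hub_labels) {
      mag <- stats::runif(spec$n_rois, 0.6, 0.9)
      sgn <- sample(c(-1, 1), spec$n_rois, replace = TRUE)
      fcm[h, ] <- mag * sgn
      fcm[, h] <- fcm[h, ]
      fcm[h, h] <- 0
    }
    if (length(spec$hub_labels)) {
      # guarantee hub dominance: non-hub strength splits into the fixed
      # hub-edge part e_k and the scalable baseline part b_k; choose the
      # largest baseline scale s with e_k + s*b_k <= H / gain for all k
      nonhub <- setdiff(seq_len(spec$n_rois), spec$hub_labels)
      H <- min(rowSums(abs(fcm))[spec$hub_labels])
      e <- rowSums(abs(fcm[nonhub, spec$hub_labels, drop = FALSE]))
      b <- rowSums(abs(fcm[nonhub, nonhub, drop = FALSE]))
      room <- H / max(spec$hub_gain, 3.2) - e
      if (any(room <= 0))
        stop("hub gain unattainable: hub edges alone exceed the budget")
      s <- min(1, ifelse(b > 0, room / b, 1))
      fcm[nonhub, nonhub] <- fcm[nonhub, nonhub] * s
    }
    fc <- connectivity_matrix(fcm, labels = seq_len(spec$n_rois),
                              flavour = "functional")

    # ground-truth scores recomputed by explicit elementwise loops
    gt_fcgm <- numeric(spec$n_rois)
    gt_scgm <- numeric(spec$n_rois)
    for (kk in seq_len(spec$n_rois)) {
      sfc <- 0; ssc <- 0
      for (jj in seq_len(spec$n_rois)) {
        if (jj == kk) next
        sfc <- sfc + abs(fc$values[kk, jj])
        ssc <- ssc + abs(sc$values[kk, jj])
      }
      gt_fcgm[kk] <- sfc
      gt_scgm[kk] <- ssc / parc$roi_volumes[[as.character(kk)]]
    }

    ground_truth <- list(
      roi_volumes = parc$roi_volumes,
      centroids = centroids,
      bundle_indices = bundle_indices,
      fcgm = stats::setNames(gt_fcgm, seq_len(spec$n_rois)),
      scgm = stats::setNames(gt_scgm, seq_len(spec$n_rois)))

    structure(list(parcellation = parc, tractogram = tract, fc = fc,
                   sc = sc, ground_truth = ground_truth, spec = spec),
              class = "phantom")
  })
}

#' Generate the planted-hub benchmark scene
#'
#' A phantom in which exactly one region (the sector containing the +x
#' axis) is a connectivity hub: its functional and structural node strengths
#' are at least three times every other region's. Two candidate
#' trajectories of mirrored, hence identical, geometry are provided — one
#' entering from +x straight through the hub sector, its twin from -x
#' through the diametrically opposite low-score sector — together with the
#' search box for a full risk-map run. The generator verifies by direct
#' computation that the hub-side trajectory incurs strictly greater raw
#' functional grey-matter damage while both tubes intersect the same total
#' grey-matter volume, and records both trajectories in
#' `$scene`.
#'
#' @param seed integer seed.
#' @param radius tube radius used for the recorded verification, mm.
#' @param ... further arguments passed to [phantom_spec()].
#' @return a `phantom` with an additional `scene` element: `target`,
#'   `entry_hub`, `entry_safe`, `hub_label`, `safe_label`, `radius`, `box`,
#'   and the verified raw damage of both trajectories.
#' @export
make_planted_hub_scene <- function(seed, radius = 5, ...) {
  n_rois <- 8L
  hub <- 1L
  safe <- 5L   # sector containing the -x axis, mirror image of the hub
  bundles <- data.frame(
    roi_a = c(rep(hub, 5L), 2L),
    roi_b = c(3L, 4L, 5L, 6L, 7L, 8L),
    n_streamlines = c(rep(10L, 5L), 4L))
  spec <- phantom_spec(n_rois = n_rois, bundles = bundles,
                       hub_labels = hub, seed = seed, ...)
  ph <- make_phantom(spec)

  gt <- ph$ground_truth
  if (gt$fcgm[hub] < 3 * max(gt$fcgm[-hub]) ||
      gt$scgm[hub] < 3 * max(gt$scgm[-hub]))
    stop("hub construction failed to dominate by 3x")   # nocov

  box <- search_box(ph$parcellation, margin = 10, spacing = 10)
  # target on the mirror plane x = 0, offset from the sector apex (the
  # z axis, where all wedges meet) by more than the tube radius so that
  # trajectories from the safe side never graze the hub wedge
  target <- c(0, 10, 0)
  x_hi <- box$center[1L] + box$half_extents[1L]
  x_lo <- box$center[1L] - box$half_extents[1L]
  entry_hub <- c(x_hi, 10, 0)
  entry_safe <- c(x_lo, 10, 0)

  cache <- scene_cache(ph$parcellation, ph$tractogram)
  gm_scores <- compute_gm_scores(ph$fc, ph$sc, ph$parcellation)
  inv_hub <- extract_tissue(trajectory_tube(entry_hub, target, radius),
                            ph$parcellation, cache = cache)
  inv_safe <- extract_tissue(trajectory_tube(entry_safe, target, radius),
                             ph$parcellation, cache = cache)
  fib_scores <- compute_fiber_scores(ph$tractogram, ph$parcellation,
                                     gm_scores)
  dmg_hub <- raw_damage(inv_hub, gm_scores, fib_scores)
  dmg_safe <- raw_damage(inv_safe, gm_scores, fib_scores)
  if (!(dmg_hub["fcgm_path"] > dmg_safe["fcgm_path"]))
    stop("hub trajectory does not dominate; construction violated")  # nocov

  ph$scene <- list(target = target, entry_hub = entry_hub,
                   entry_safe = entry_safe, hub_label = hub,
                   safe_label = safe, radius = radius, box = box,
                   damage_hub = dmg_hub, damage_safe = dmg_safe,
                   gm_volume_hub = sum(inv_hub$gm_volume),
                   gm_volume_safe = sum(inv_safe$gm_volume))
  ph
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf(
    "<phantom> %d regions, %d streamlines, seed %d\n",
    x$spec$n_rois, length(x$tractogram$streamlines), x$spec$seed))
  invisible(x)
}
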