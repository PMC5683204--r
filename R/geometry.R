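# Trajectory tube geometry. The surgical access path between an entry and a
# target point is modelled as the volume swept by a sphere of the tube
# radius moving along the segment — a capsule (cylinder with hemispherical
# caps). Membership is decided analytically by the point-to-segment
# distance; a flat-capped cylinder is available behind a flag. Tissue
# extraction tallies labeled voxels (by centre) and resampled streamline
# vertices falling inside the tube, pruned to the tube's bounding box.

#' Define a trajectory tube
#'
#' @param entry,target world-mm endpoints of the trajectory; `entry` is the
#'   skin/box side, `target` the lesion side. Must be distinct.
#' @param radius tube radius in mm (> 0); defaults to 5 mm.
#' @param cap `"sphere"` for the capsule swept volume (default) or `"flat"`
#'   for a flat-capped cylinder.
#' @return An object of class `trajectory_tube` with fields `entry`,
#'   `target`, `radius`, `length` (mm) and `cap`.
#' @export
trajectory_tube <- function(entry, target, radius = 5, cap = c("sphere",
                                                               "flat")) {
  cap <- match.arg(cap)
  entry <- as_point(entry, "entry")
  target <- as_point(target, "target")
  if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) ||
      radius <= 0)
    stop("radius must be a positive number (mm)")
  len <- vnorm(entry - target)
  if (len <= 0) stop("entry and target coincide; tube has zero length")
  structure(list(entry = entry, target = target, radius = radius,
                 length = len, cap = cap),
            class = "trajectory_tube")
}

# squared distances from rows of P to the closed segment [a, b]; also returns
# the uncapped axial parameter t in [0, 1] scale for the flat-cap test
segment_dist2 <- function(P, a, b) {
  d <- b - a
  L2 <- sum(d^2)
  pa1 <- P[, 1L] - a[1L]; pa2 <- P[, 2L] - a[2L]; pa3 <- P[, 3L] - a[3L]
  t_raw <- (pa1 * d[1L] + pa2 * d[2L] + pa3 * d[3L]) / L2
  t <- pmin(1, pmax(0, t_raw))
  dx <- pa1 - t * d[1L]; dy <- pa2 - t * d[2L]; dz <- pa3 - t * d[3L]
  list(dist2 = dx * dx + dy * dy + dz * dz, t_raw = t_raw)
}

#' Test whether points lie inside a trajectory tube
#'
#' For the capsule (default), a point is inside iff its distance to the
#' closed segment entry-target is at most the radius. For the flat-capped
#' cylinder, the axial projection must additionally fall between the
#' endpoints and the radial (perpendicular) distance within the radius.
#'
#' @param p n x 3 matrix of world-mm points (or a length-3 vector).
#' @param tube a [trajectory_tube()].
#' @return logical vector, one verdict per point.
#' @export
point_in_tube <- function(p, tube) {
  stopifnot(inherits(tube, "trajectory_tube"))
  if (is.null(dim(p))) p <- matrix(p, ncol = 3L)
  sd <- segment_dist2(p, tube$entry, tube$target)
  if (tube$cap == "sphere") {
    sd$dist2 <= tube$radius^2
  } else {
    inside_axial <- sd$t_raw >= 0 & sd$t_raw <= 1
    d <- tube$target - tube$entry
    pa <- sweep(p, 2L, tube$entry)
    axial <- pa %*% d / tube$length          # signed axial coordinate, mm
    rad2 <- rowSums(pa^2) - as.vector(axial)^2
    inside_axial & rad2 <= tube$radius^2
  }
}

# world-space axis-aligned bounding box of the tube (capsule bound covers the
# flat cylinder too)
tube_bbox <- function(tube) {
  lo <- pmin(tube$entry, tube$target) - tube$radius
  hi <- pmax(tube$entry, tube$target) + tube$radius
  rbind(lo, hi)
}

#' Precompute the voxel/fibre scene for repeated tube queries
#'
#' Collects the world-mm centres and labels of all labeled voxels, and the
#' resampled vertices of all streamlines tagged with their streamline index.
#' Computing this once and passing it to [extract_tissue()] (as
#' [exhaustive_search()] does) avoids redoing the resampling for every
#' candidate trajectory.
#'
#' @param parc a [parcellation()].
#' @param tract a [tractogram()] (or `NULL` for a voxel-only scene).
#' @param step streamline resampling step in mm (default: half the shortest
#'   voxel edge).
#' @return list of class `scene_cache`.
#' @export
scene_cache <- function(parc, tract = NULL, step = NULL) {
  stopifnot(inherits(parc, "parcellation"))
  if (is.null(step)) step <- parc$min_edge / 2
  lvc <- labeled_voxel_centers(parc)
  fiber_points <- matrix(numeric(0), ncol = 3L)
  fiber_ids <- integer(0)
  n_fib <- 0L
  if (!is.null(tract)) {
    stopifnot(inherits(tract, "tractogram"))
    n_fib <- length(tract$streamlines)
    if (n_fib > 0L) {
      res <- lapply(tract$streamlines, resample_polyline, step = step)
      fiber_points <- do.call(rbind, res)
      fiber_ids <- rep.int(seq_len(n_fib),
                           vapply(res, nrow, integer(1)))
    }
  }
  structure(list(vox_centers = lvc$centers, vox_labels = lvc$labels,
                 fiber_points = fiber_points, fiber_ids = fiber_ids,
                 n_fibers = n_fib, step = step),
            class = "scene_cache")
}

#' Extract the tissue inside a trajectory tube
#'
#' Counts every labeled voxel whose centre lies in the tube, converts counts
#' to volumes via the voxel volume, and collects the indices of every
#' streamline with at least one resampled vertex in the tube. Only points in
#' the tube's axis-aligned bounding box are tested (`prune = TRUE`); the
#' result is identical to the full scan.
#'
#' @param tube a [trajectory_tube()].
#' @param parc a [parcellation()].
#' @param tract a [tractogram()] or `NULL`.
#' @param step streamline resampling step in mm.
#' @param cache an optional [scene_cache()] for `parc`/`tract`; built on the
#'   fly when absent.
#' @param prune restrict candidate points to the tube bounding box first.
#' @return An object of class `tissue_inventory`: list with `gm_voxels`
#'   (named integer, label -> voxel count inside the tube), `gm_volume`
#'   (named numeric, mm^3), and `fiber_indices` (sorted integer streamline
#'   indices). A tube entirely outside the scene yields an empty inventory.
#' @export
extract_tissue <- function(tube, parc, tract = NULL, step = NULL,
                           cache = NULL, prune = TRUE) {
  stopifnot(inherits(tube, "trajectory_tube"), inherits(parc, "parcellation"))
  if (is.null(cache)) cache <- scene_cache(parc, tract, step)
  bb <- tube_bbox(tube)

  vc <- cache$vox_centers
  vl <- cache$vox_labels
  if (prune && nrow(vc)) {
    sel <- vc[, 1L] >= bb[1L, 1L] & vc[, 1L] <= bb[2L, 1L] &
           vc[, 2L] >= bb[1L, 2L] & vc[, 2L] <= bb[2L, 2L] &
           vc[, 3L] >= bb[1L, 3L] & vc[, 3L] <= bb[2L, 3L]
    vc <- vc[sel, , drop = FALSE]
    vl <- vl[sel]
  }
  gm_voxels <- integer(0)
  if (nrow(vc)) {
    inside <- point_in_tube(vc, tube)
    if (any(inside)) {
      tab <- table(vl[inside])
      gm_voxels <- stats::setNames(as.integer(tab), names(tab))
      ord <- order(as.integer(names(gm_voxels)))
      gm_voxels <- gm_voxels[ord]
    }
  }

  fp <- cache$fiber_points
  fi <- cache$fiber_ids
  if (prune && nrow(fp)) {
    sel <- fp[, 1L] >= bb[1L, 1L] & fp[, 1L] <= bb[2L, 1L] &
           fp[, 2L] >= bb[1L, 2L] & fp[, 2L] <= bb[2L, 2L] &
           fp[, 3L] >= bb[1L, 3L] & fp[, 3L] <= bb[2L, 3L]
    fp <- fp[sel, , drop = FALSE]
    fi <- fi[sel]
  }
  fiber_indices <- integer(0)
  if (nrow(fp)) {
    inside <- point_in_tube(fp, tube)
    fiber_indices <- sort(unique(fi[inside]))
  }

  structure(list(gm_voxels = gm_voxels,
                 gm_volume = gm_voxels * parc$voxel_volume,
                 fiber_indices = fiber_indices),
            class = "tissue_inventory")
}

#' Raw connectional damage of a trajectory
#'
#' Aggregates the tube's tissue inventory with the eloquence scores into the
#' four raw damage components: `fcgm_path = sum_k V_k * FCGM_k` and
#' `scgm_path = sum_k V_k * SCGM_k` over intersected grey-matter volumes
#' `V_k` (mm^3), and `fcwm_path = sum_p FCWM_p`, `scwm_path = sum_p SCWM_p`
#' over intersected fibres.
#'
#' @param inv a [extract_tissue()] inventory.
#' @param gm_scores a `gm_score_table`.
#' @param fib_scores a `fiber_score_table` (may be `NULL` when the inventory
#'   has no fibres).
#' @return named numeric vector `c(fcgm_path, scgm_path, fcwm_path,
#'   scwm_path)`, all components >= 0.
#' @export
raw_damage <- function(inv, gm_scores, fib_scores = NULL) {
  stopifnot(inherits(inv, "tissue_inventory"),
            inherits(gm_scores, "gm_score_table"))
  out <- c(fcgm_path = 0, scgm_path = 0, fcwm_path = 0, scwm_path = 0)
  if (length(inv$gm_volume)) {
    pos <- match(as.integer(names(inv$gm_volume)), gm_scores$label)
    if (any(is.na(pos)))
      stop("inventory references labels absent from gm_scores: ",
           paste(names(inv$gm_volume)[is.na(pos)], collapse = ", "))
    out["fcgm_path"] <- sum(inv$gm_volume * gm_scores$fcgm[pos])
    out["scgm_path"] <- sum(inv$gm_volume * gm_scores$scgm[pos])
  }
  if (length(inv$fiber_indices)) {
    if (is.null(fib_scores))
      stop("inventory contains fibres but no fiber scores were given")
    stopifnot(inherits(fib_scores, "fiber_score_table"))
    pos <- match(inv$fiber_indices, fib_scores$index)
    if (any(is.na(pos)))
      stop("inventory references streamline indices absent from fib_scores: ",
           paste(inv$fiber_indices[is.na(pos)], collapse = ", "))
    out["fcwm_path"] <- sum(fib_scores$fcwm[pos])
    out["scwm_path"] <- sum(fib_scores$scwm[pos])
  }
  out
}

#' @export
print.trajectory_tube <- function(x, ...) {
  cat(sprintf(
    "<trajectory_tube> length %.1f mm, radius %.1f mm, %s caps\n",
    x$length, x$radius, x$cap))
  invisible(x)
}

#' @export
print.tissue_inventory <- function(x, ...) {
  cat(sprintf("<tissue_inventory> %d region(s), %.1f mm^3 GM, %d fibre(s)\n",
              length(x$gm_voxels), sum(x$gm_volume),
              length(x$fiber_indices)))
  invisible(x)
}
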