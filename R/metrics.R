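# Trajectory bookkeeping for evaluating and comparing planned paths: length
# from the target to the cortical boundary along the trajectory, Euclidean
# distance between entry points on the search box, and the angle between two
# trajectories through a common target.

#' Path length from target to the cortical boundary
#'
#' Marches from the entry toward the target in steps of at most `step` mm
#' and returns the distance from the first labeled (tissue) point
#' encountered to the target — the length of trajectory actually inside the
#' brain, with the outer boundary of the labeled parcellation standing in
#' for the cortical surface. An entry already inside tissue degenerates to
#' the full entry-target distance. Moving the entry farther out along the
#' same ray leaves the result unchanged (up to one marching step).
#'
#' @param entry,target world-mm points; `target` must lie in labeled tissue.
#' @param parc a [parcellation()].
#' @param step marching step, mm (default: half the shortest voxel edge).
#' @return path length in mm.
#' @export
path_length <- function(entry, target, parc, step = NULL) {
  stopifnot(inherits(parc, "parcellation"))
  entry <- as_point(entry, "entry")
  target <- as_point(target, "target")
  if (is.null(step)) step <- parc$min_edge / 2
  if (labels_at(parc, target) == 0L)
    stop("target does not lie inside labeled tissue")
  L <- vnorm(target - entry)
  if (L == 0) return(0)
  nsteps <- ceiling(L / step)
  t <- seq(0, L, length.out = nsteps + 1L)
  dirv <- (target - entry) / L
  pts <- cbind(entry[1L] + t * dirv[1L],
               entry[2L] + t * dirv[2L],
               entry[3L] + t * dirv[3L])
  labs <- labels_at(parc, pts)
  hit <- which(labs > 0L)
  if (length(hit) == 0L) stop("trajectory misses brain")
  L - t[hit[1L]]
}

#' Angle between two trajectories through a common target
#'
#' The angle (degrees, in `[0, 180]`) between the direction vectors
#' entryA-target and entryB-target, via the clamped arccosine of their
#' normalised dot product.
#'
#' @param entry_a,entry_b entry points (must differ from `target`).
#' @param target common target point.
#' @return angle in degrees.
#' @export
angular_distance <- function(entry_a, entry_b, target) {
  u <- as_point(entry_a, "entry_a") - as_point(target, "target")
  v <- as_point(entry_b, "entry_b") - as_point(target, "target")
  nu <- vnorm(u); nv <- vnorm(v)
  if (nu == 0 || nv == 0)
    stop("entry coincides with target; direction undefined")
  cosang <- sum(u * v) / (nu * nv)
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Euclidean distance between two entry points on the box
#'
#' Straight-line (chordal) 3D distance between the two points; reported in
#' mm.
#'
#' @param entry_a,entry_b world-mm points on the search-box surface.
#' @return distance in mm.
#' @export
euclidean_on_box <- function(entry_a, entry_b) {
  vnorm(as_point(entry_a, "entry_a") - as_point(entry_b, "entry_b"))
}

#' Compare two trajectories to a common target
#'
#' Produces one evaluation row per the standard reporting layout: path
#' length and damage for each trajectory, plus the Euclidean distance
#' between the entries and the angular distance between the trajectories.
#' Damage is each trajectory's T_score, i.e. its four raw components
#' normalised against the component ranges of a completed
#' [exhaustive_search()] for the same target (so both trajectories are
#' scored on the search's scale); when `risk_map` is `NULL` only raw
#' components are summed into `damage_*` columns named `*_raw`.
#'
#' @param entry_a,entry_b entry points of trajectories A (e.g. routine) and
#'   B (e.g. proposed).
#' @param target common target point.
#' @param parc a [parcellation()].
#' @param tract a [tractogram()].
#' @param gm_scores,fib_scores score tables.
#' @param radius tube radius, mm.
#' @param risk_map optional completed [exhaustive_search()] for this target
#'   supplying the normalisation ranges.
#' @param cache optional [scene_cache()].
#' @return one-row data.frame of class `trajectory_comparison`.
#' @export
compare_trajectories <- function(entry_a, entry_b, target, parc, tract,
                                 gm_scores, fib_scores, radius = 5,
                                 risk_map = NULL, cache = NULL) {
  entry_a <- as_point(entry_a, "entry_a")
  entry_b <- as_point(entry_b, "entry_b")
  target <- as_point(target, "target")
  if (is.null(cache)) cache <- scene_cache(parc, tract)
  dmg <- function(entry) {
    tube <- trajectory_tube(entry, target, radius)
    raw_damage(extract_tissue(tube, parc, tract, cache = cache),
               gm_scores, fib_scores)
  }
  raw_a <- dmg(entry_a)
  raw_b <- dmg(entry_b)
  out <- data.frame(
    path_length_a = path_length(entry_a, target, parc),
    path_length_b = path_length(entry_b, target, parc),
    euclidean_mm = euclidean_on_box(entry_a, entry_b),
    angular_deg = angular_distance(entry_a, entry_b, target))
  if (!is.null(risk_map)) {
    stopifnot(inherits(risk_map, "risk_map"))
    out$damage_a <- total_score(normalize_with_ranges(
      raw_a, risk_map$component_ranges))
    out$damage_b <- total_score(normalize_with_ranges(
      raw_b, risk_map$component_ranges))
  } else {
    out$damage_a_raw <- sum(raw_a)
    out$damage_b_raw <- sum(raw_b)
  }
  class(out) <- c("trajectory_comparison", "data.frame")
  out
}
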