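# Internal helpers shared across modules: affine transforms, polyline
# resampling, scoped RNG.

#' Apply a 4x4 affine to a set of points
#'
#' @param affine 4x4 numeric matrix mapping homogeneous coordinates.
#' @param pts numeric matrix with one point per row (n x 3), or a length-3
#'   vector.
#' @return n x 3 matrix of transformed points.
#' @keywords internal
#' @noRd
apply_affine <- function(affine, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3L)
  out <- pts %*% t(affine[1:3, 1:3, drop = FALSE])
  out[, 1L] <- out[, 1L] + affine[1L, 4L]
  out[, 2L] <- out[, 2L] + affine[2L, 4L]
  out[, 3L] <- out[, 3L] + affine[3L, 4L]
  out
}

# 0-based continuous voxel indices for world-mm points
world_to_voxel <- function(parc, pts) {
  apply_affine(parc$inverse_affine, pts)
}

# world-mm centers of 0-based voxel indices
voxel_to_world <- function(parc, ijk) {
  apply_affine(parc$affine, ijk)
}

#' Resample a polyline to an approximately uniform arc-length step
#'
#' Vertices are placed at arc-length positions `seq(0, L, by = step)` with the
#' final original endpoint always retained, so no segment of the output is
#' longer than `step`.
#'
#' @param points n x 3 matrix of ordered polyline vertices (world mm).
#' @param step maximum spacing between consecutive output vertices, mm.
#' @return m x 3 matrix of resampled vertices.
#' @export
resample_polyline <- function(points, step) {
  stopifnot(is.matrix(points), ncol(points) == 3L, step > 0)
  n <- nrow(points)
  if (n < 2L) return(points)
  seg <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                         points[-n, , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  total <- s[n]
  if (total <= .Machine$double.eps) return(points[1L, , drop = FALSE])
  at <- seq(0, total, by = step)
  if (at[length(at)] < total) at <- c(at, total)
  # approx() needs strictly increasing x; collapse duplicate vertices
  keep <- c(TRUE, diff(s) > 0)
  su <- s[keep]
  pu <- points[keep, , drop = FALSE]
  cbind(stats::approx(su, pu[, 1L], xout = at)$y,
        stats::approx(su, pu[, 2L], xout = at)$y,
        stats::approx(su, pu[, 3L], xout = at)$y)
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

vnorm <- function(x) sqrt(sum(x^2))

as_point <- function(p, what = "point") {
  p <- as.numeric(p)
  if (length(p) != 3L || any(!is.finite(p)))
    stop(sprintf("'%s' must be a finite length-3 numeric vector", what))
  p
}
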