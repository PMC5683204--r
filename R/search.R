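# Exhaustive entry-point search. Candidate entry points form a lattice on
# five faces of an axis-aligned box enclosing the head (all faces except the
# base, which rests against the skull). Every entry is evaluated as a tube
# to the target; the four raw damage components are min-max normalised
# across the entries of the search and summed into the total damage T_score
# in [0, 4].

#' Define the entry-point search box
#'
#' By default the box is the world-space bounding box of all labeled voxels
#' expanded by `margin` mm, with the base (excluded) face at minimal z
#' (inferior). `center`/`half_extents` may be given directly instead of a
#' parcellation.
#'
#' @param parc a [parcellation()], or `NULL` when `center` and
#'   `half_extents` are supplied.
#' @param margin expansion of the labeled bounding box, mm (default 10).
#' @param spacing grid spacing on the faces, mm (default 10, i.e. the 1 cm
#'   grid).
#' @param base_face excluded face: one of `"-z"` (default), `"+z"`, `"-x"`,
#'   `"+x"`, `"-y"`, `"+y"`.
#' @param center,half_extents explicit box geometry in world mm (length-3
#'   each).
#' @return An object of class `search_box`.
#' @export
search_box <- function(parc = NULL, margin = 10, spacing = 10,
                       base_face = "-z", center = NULL, half_extents = NULL) {
  base_face <- match.arg(base_face, c("-z", "+z", "-x", "+x", "-y", "+y"))
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("spacing must be a positive number (mm)")
  if (is.null(center) || is.null(half_extents)) {
    stopifnot(inherits(parc, "parcellation"))
    vc <- labeled_voxel_centers(parc)$centers
    lo <- apply(vc, 2L, min) - margin
    hi <- apply(vc, 2L, max) + margin
    center <- (lo + hi) / 2
    half_extents <- (hi - lo) / 2
  } else {
    center <- as_point(center, "center")
    half_extents <- as.numeric(half_extents)
    if (length(half_extents) != 3L || any(half_extents <= 0))
      stop("half_extents must be 3 positive numbers (mm)")
  }
  structure(list(center = center, half_extents = half_extents,
                 spacing = spacing, base_face = base_face),
            class = "search_box")
}

#' Enumerate candidate entry points on the five open faces of the box
#'
#' A lattice of `spacing`-mm pitch is laid on each face of the box except
#' the base face; when the spacing does not divide an edge the lattice is
#' centred along that axis. Points shared between faces (edges, corners)
#' appear once; base-face points survive only on its edges (contributed by
#' the adjacent side faces), never in its interior. Ordering is
#' deterministic: lexicographic by (x, y, z).
#'
#' @param box a [search_box()].
#' @return m x 3 matrix of world-mm entry points.
#' @export
build_entry_grid <- function(box) {
  stopifnot(inherits(box, "search_box"))
  lo <- box$center - box$half_extents
  hi <- box$center + box$half_extents
  edge <- hi - lo
  if (box$spacing > min(edge) + 1e-9)
    stop(sprintf("spacing (%g mm) exceeds the smallest box edge (%g mm)",
                 box$spacing, min(edge)))
  axis_coords <- function(a) {
    n <- floor(edge[a] / box$spacing + 1e-9)
    off <- (edge[a] - n * box$spacing) / 2
    lo[a] + off + box$spacing * (0:n)
  }
  coords <- lapply(1:3, axis_coords)
  base_axis <- match(substr(box$base_face, 2L, 2L), c("x", "y", "z"))
  base_at <- if (substr(box$base_face, 1L, 1L) == "-") lo[base_axis]
             else hi[base_axis]
  pts <- list()
  for (a in 1:3) {
    others <- setdiff(1:3, a)
    inface <- as.matrix(expand.grid(coords[[others[1L]]],
                                    coords[[others[2L]]]))
    for (side in c(lo[a], hi[a])) {
      if (a == base_axis && isTRUE(all.equal(side, base_at))) next
      face <- matrix(0, nrow(inface), 3L)
      face[, a] <- side
      face[, others[1L]] <- inface[, 1L]
      face[, others[2L]] <- inface[, 2L]
      pts[[length(pts) + 1L]] <- face
    }
  }
  pts <- do.call(rbind, pts)
  key <- apply(round(pts, 6L), 1L, paste, collapse = "/")
  pts <- pts[!duplicated(key), , drop = FALSE]
  pts[order(pts[, 1L], pts[, 2L], pts[, 3L]), , drop = FALSE]
}

#' Min-max feature scaling
#'
#' `X' = (X - X_min) / (X_max - X_min)`. A degenerate component
#' (`X_max == X_min`) maps to all zeros so it contributes nothing to the
#' ranking.
#'
#' @param values nonempty numeric vector of finite values.
#' @return numeric vector in `[0, 1]`.
#' @export
minmax_normalize <- function(values) {
  if (length(values) == 0L) stop("cannot normalise an empty vector")
  if (any(!is.finite(values))) stop("values must be finite")
  lo <- min(values); hi <- max(values)
  if (hi == lo) return(rep(0, length(values)))
  (values - lo) / (hi - lo)
}

#' Total damage score of a trajectory
#'
#' The sum of the four min-max normalised damage components, in `[0, 4]`.
#' `scale` is a display-only multiplier; it never changes the ranking of
#' trajectories.
#'
#' @param norm numeric vector (or matrix with 4 columns) of normalised
#'   components in `[0, 1]`.
#' @param scale display scale factor (default 1).
#' @return total score(s).
#' @export
total_score <- function(norm, scale = 1) {
  if (is.matrix(norm)) rowSums(norm) * scale else sum(norm) * scale
}

#' Exhaustively evaluate all entry points for one target
#'
#' Runs through every grid point of the search box, models the trajectory
#' entry-target as a tube of the given radius, extracts the intersected
#' tissue, accumulates the four raw damage components, min-max normalises
#' each component across the entries of this search, and sums them into
#' T_score. The optimal entry attains the minimal T_score; ties are broken
#' by smaller entry-target distance, then lexicographic entry coordinates.
#'
#' @param target world-mm target point (must lie inside the box).
#' @param box a [search_box()].
#' @param parc a [parcellation()].
#' @param tract a [tractogram()].
#' @param gm_scores a `gm_score_table`.
#' @param fib_scores a `fiber_score_table`.
#' @param radius tube radius, mm (default 5).
#' @param step streamline/voxel resampling step, mm.
#' @param cache optional [scene_cache()].
#' @param progress_every log progress to stderr every that many entries
#'   (0 = silent).
#' @return An object of class `risk_map`: list with `target`, `radius`,
#'   `box`, `entries` (data.frame: entry coordinates, four raw components,
#'   four normalised components, `t_score`, `path_dist`, `is_optimal`),
#'   `component_ranges` (2 x 4 matrix of min/max per raw component) and
#'   `optimal` (row index of the optimal entry).
#' @export
exhaustive_search <- function(target, box, parc, tract, gm_scores,
                              fib_scores, radius = 5, step = NULL,
                              cache = NULL, progress_every = 0L) {
  stopifnot(inherits(box, "search_box"))
  target <- as_point(target, "target")
  if (any(abs(target - box$center) > box$half_extents + 1e-9))
    stop("target lies outside the search box")
  grid <- build_entry_grid(box)
  if (is.null(cache)) cache <- scene_cache(parc, tract, step)
  n <- nrow(grid)
  raw <- matrix(0, n, 4L,
                dimnames = list(NULL, c("fcgm_path", "scgm_path",
                                        "fcwm_path", "scwm_path")))
  for (i in seq_len(n)) {
    tube <- trajectory_tube(grid[i, ], target, radius)
    inv <- extract_tissue(tube, parc, tract, cache = cache)
    raw[i, ] <- raw_damage(inv, gm_scores, fib_scores)
    if (progress_every > 0L && i %% progress_every == 0L)
      message(sprintf("search: %d/%d entries evaluated", i, n))
  }
  norm <- apply(raw, 2L, minmax_normalize)
  if (n == 1L) norm <- matrix(norm, 1L, 4L)
  colnames(norm) <- c("fcgm_norm", "scgm_norm", "fcwm_norm", "scwm_norm")
  t_score <- total_score(norm)
  path_dist <- sqrt(rowSums(sweep(grid, 2L, target)^2))
  ord <- order(t_score, path_dist, grid[, 1L], grid[, 2L], grid[, 3L])
  optimal <- ord[1L]
  entries <- data.frame(entry_x = grid[, 1L], entry_y = grid[, 2L],
                        entry_z = grid[, 3L], raw, norm,
                        t_score = t_score, path_dist = path_dist,
                        is_optimal = seq_len(n) == optimal)
  ranges <- apply(raw, 2L, range)
  rownames(ranges) <- c("min", "max")
  structure(list(target = target, radius = radius, box = box,
                 entries = entries, component_ranges = ranges,
                 optimal = optimal),
            class = "risk_map")
}

# normalise raw components against the ranges of a completed search
normalize_with_ranges <- function(raw, ranges) {
  out <- numeric(4L)
  for (j in 1:4) {
    lo <- ranges[1L, j]; hi <- ranges[2L, j]
    out[j] <- if (hi == lo) 0 else (raw[j] - lo) / (hi - lo)
  }
  names(out) <- c("fcgm_norm", "scgm_norm", "fcwm_norm", "scwm_norm")
  out
}

#' @export
print.risk_map <- function(x, ...) {
  opt <- x$entries[x$optimal, ]
  cat(sprintf(
    paste0("<risk_map> %d entries, radius %.1f mm; optimal entry ",
           "(%.1f, %.1f, %.1f) with T_score %.4f\n"),
    nrow(x$entries), x$radius, opt$entry_x, opt$entry_y, opt$entry_z,
    opt$t_score))
  invisible(x)
}

#' Write a risk map to CSV and NIfTI
#'
#' Writes `<out_prefix>.csv` with one row per entry point (coordinates, four
#' raw components, four normalised components, `t_score`, `is_optimal`) and
#' `<out_prefix>.nii.gz`, a volume on the parcellation grid in which the
#' voxel nearest each entry point carries its T_score and every other voxel
#' the sentinel -1, so colour mapping can mask the background.
#'
#' @param risk_map a [exhaustive_search()] result.
#' @param parc the [parcellation()] defining the output grid.
#' @param out_prefix path prefix for the two output files.
#' @param scale display-only multiplier applied to the written T_score.
#' @return character vector of the two paths, invisibly.
#' @export
write_risk_map <- function(risk_map, parc, out_prefix, scale = 1) {
  stopifnot(inherits(risk_map, "risk_map"), inherits(parc, "parcellation"))
  if (nrow(risk_map$entries) == 0L) stop("risk map has no entries")
  df <- risk_map$entries
  df$t_score <- df$t_score * scale
  csv_path <- paste0(out_prefix, ".csv")
  utils::write.csv(format(df, digits = 12, trim = TRUE, scientific = FALSE),
                   csv_path, row.names = FALSE, quote = FALSE)

  d <- dim(parc$labels)
  vol <- array(-1, dim = d)
  pts <- as.matrix(df[, c("entry_x", "entry_y", "entry_z")])
  ijk <- round(world_to_voxel(parc, pts))
  ijk[, 1L] <- pmin(pmax(ijk[, 1L], 0L), d[1L] - 1L)
  ijk[, 2L] <- pmin(pmax(ijk[, 2L], 0L), d[2L] - 1L)
  ijk[, 3L] <- pmin(pmax(ijk[, 3L], 0L), d[3L] - 1L)
  lin <- 1L + ijk[, 1L] + d[1L] * (ijk[, 2L] + d[2L] * ijk[, 3L])
  vol[lin] <- df$t_score
  img <- RNifti::asNifti(vol)
  img <- RNifti::`sform<-`(img, structure(parc$affine, code = 2L))
  nii_path <- paste0(out_prefix, ".nii.gz")
  RNifti::writeNifti(img, nii_path, datatype = "double")
  invisible(c(csv = csv_path, nifti = nii_path))
}
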