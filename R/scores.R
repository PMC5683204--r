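# Eloquence scores. Grey-matter regions receive the unsigned weighted degree
# (node strength) of their network node: the functional score FCGM_k is the
# sum of |FC(k, j)| over all regions j, and the structural score SCGM_k is
# the analogous sum over the fibre-count matrix divided by the region volume
# L_k (mm^3), cancelling the effect of region size. A white-matter fibre
# inherits the mean score of the grey-matter regions it intersects.

#' Functional eloquence score per grey-matter region
#'
#' Computes `FCGM_k = sum_j |FC(k, j)|`, the unsigned weighted degree of each
#' atlas region in the functional network. The diagonal is already zero by
#' [connectivity_matrix()] construction, so self-connections never
#' contribute.
#'
#' @param fc a functional [connectivity_matrix()].
#' @return named numeric vector, label -> FCGM (unitless, >= 0).
#' @export
compute_fcgm <- function(fc) {
  stopifnot(inherits(fc, "connectivity_matrix"))
  if (fc$flavour != "functional")
    stop("compute_fcgm() expects a functional matrix, got ", fc$flavour)
  s <- rowSums(abs(fc$values))
  names(s) <- as.character(fc$labels)
  s
}

#' Structural eloquence score per grey-matter region
#'
#' Computes `SCGM_k = sum_j |SC(k, j)| / L_k`, the fibre-count node strength
#' normalised by the region volume `L_k` (mm^3) so that large regions are not
#' favoured merely for their size. Units: fibres per mm^3.
#'
#' @param sc a structural [connectivity_matrix()].
#' @param parc a [parcellation()] supplying `L_k` for every matrix label.
#' @return named numeric vector, label -> SCGM (fibres/mm^3, >= 0).
#' @export
compute_scgm <- function(sc, parc) {
  stopifnot(inherits(sc, "connectivity_matrix"),
            inherits(parc, "parcellation"))
  if (sc$flavour != "structural")
    stop("compute_scgm() expects a structural matrix, got ", sc$flavour)
  key <- as.character(sc$labels)
  missing <- key[!key %in% names(parc$roi_volumes)]
  if (length(missing))
    stop("labels missing from parcellation: ",
         paste(missing, collapse = ", "))
  s <- rowSums(abs(sc$values)) / parc$roi_volumes[key]
  names(s) <- key
  s
}

#' Combined grey-matter score table
#'
#' One record per atlas label present in both connectivity matrices and the
#' parcellation, carrying the functional and structural eloquence scores.
#'
#' @param fc functional [connectivity_matrix()].
#' @param sc structural [connectivity_matrix()].
#' @param parc a [parcellation()].
#' @return data.frame with columns `label`, `fcgm`, `scgm`, class
#'   `gm_score_table`.
#' @export
compute_gm_scores <- function(fc, sc, parc) {
  fcgm <- compute_fcgm(fc)
  scgm <- compute_scgm(sc, parc)
  common <- intersect(names(fcgm), names(scgm))
  common <- common[common %in% names(parc$roi_volumes)]
  common <- as.character(sort(as.integer(common)))
  out <- data.frame(label = as.integer(common),
                    fcgm = unname(fcgm[common]),
                    scgm = unname(scgm[common]))
  class(out) <- c("gm_score_table", "data.frame")
  out
}

#' Grey-matter regions intersected by a streamline
#'
#' The streamline is resampled to a uniform arc-length step no larger than
#' `step` (default: half the shortest voxel edge, so no traversed voxel can
#' be skipped between sparse vertices), each resampled vertex is mapped to
#' its containing voxel, and the set of distinct nonzero labels is returned.
#' Each region counts once regardless of dwell length; a streamline entirely
#' in background or outside the volume yields an empty set.
#'
#' @param streamline n x 3 matrix of world-mm vertices.
#' @param parc a [parcellation()].
#' @param step resampling step in mm.
#' @return sorted integer vector of intersected labels (possibly empty).
#' @export
assign_fiber_rois <- function(streamline, parc, step = NULL) {
  stopifnot(inherits(parc, "parcellation"))
  if (is.null(step)) step <- parc$min_edge / 2
  pts <- resample_polyline(as.matrix(streamline), step)
  labs <- labels_at(parc, pts)
  sort(unique(labs[labs > 0L]))
}

#' Eloquence scores per white-matter fibre
#'
#' For fibre `p` intersecting regions `ROIs = {GM_1, ..., GM_m}`, the
#' functional score `FCWM_p` is the arithmetic mean of `FCGM_i` over the
#' member regions, and `SCWM_p` likewise for `SCGM_i`. Fibres intersecting
#' no region (m = 0) score 0 and are flagged `unassigned` rather than
#' dropped, so streamline indices stay stable.
#'
#' @param tract a [tractogram()].
#' @param parc a [parcellation()].
#' @param gm_scores a [compute_gm_scores()] table covering every label in
#'   `parc`.
#' @param step resampling step in mm for the voxel walk (default: half the
#'   shortest voxel edge).
#' @return data.frame of class `fiber_score_table` with columns `index`,
#'   `n_rois`, `rois` (list column of integer labels), `fcwm`, `scwm`,
#'   `unassigned`.
#' @export
compute_fiber_scores <- function(tract, parc, gm_scores, step = NULL) {
  stopifnot(inherits(tract, "tractogram"),
            inherits(gm_scores, "gm_score_table"))
  missing <- setdiff(parc$roi_labels, gm_scores$label)
  if (length(missing))
    stop("gm_scores is missing parcellation labels: ",
         paste(missing, collapse = ", "))
  fcgm <- stats::setNames(gm_scores$fcgm, gm_scores$label)
  scgm <- stats::setNames(gm_scores$scgm, gm_scores$label)
  n <- length(tract$streamlines)
  rois <- vector("list", n)
  fcwm <- numeric(n)
  scwm <- numeric(n)
  for (p in seq_len(n)) {
    r <- assign_fiber_rois(tract$streamlines[[p]], parc, step)
    rois[[p]] <- r
    if (length(r)) {
      key <- as.character(r)
      fcwm[p] <- mean(fcgm[key])
      scwm[p] <- mean(scgm[key])
    }
  }
  out <- data.frame(index = seq_len(n),
                    n_rois = lengths(rois),
                    fcwm = fcwm, scwm = scwm,
                    unassigned = lengths(rois) == 0L)
  out$rois <- rois
  class(out) <- c("fiber_score_table", "data.frame")
  out
}

#' Export a score table as CSV
#'
#' Grey-matter tables are written label-keyed; fibre tables index-keyed, with
#' the intersected-region set collapsed to a `;`-separated string.
#'
#' @param scores a `gm_score_table` or `fiber_score_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  df <- as.data.frame(scores)
  if (!is.null(df$rois))
    df$rois <- vapply(df$rois, paste, character(1), collapse = ";")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
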