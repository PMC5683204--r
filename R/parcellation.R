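# Labelled parcellation volumes: integer label array + voxel-to-world affine.
# World mm is the single internal coordinate frame; voxel indices are 0-based
# and a voxel's world position is its centre.

#' Construct a parcellation from a label array and affine
#'
#' @param label_volume 3D array of integer region labels; 0 is background.
#'   Floating-point input is accepted if every value is within `1e-6` of an
#'   integer.
#' @param affine 4x4 voxel-index (0-based) to world-mm transform; must be
#'   invertible.
#' @return An object of class `parcellation`: list with `labels` (integer 3D
#'   array), `affine`, `inverse_affine`, `voxel_volume` (mm^3),
#'   `min_edge` (shortest voxel edge, mm), `roi_volumes` (named numeric,
#'   label -> volume in mm^3) and `roi_labels` (sorted integer labels).
#' @export
parcellation <- function(label_volume, affine) {
  if (length(dim(label_volume)) != 3L)
    stop("label volume must be a 3D array")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("affine must be a 4x4 matrix")
  inv <- tryCatch(solve(affine), error = function(e)
    stop("affine is not invertible"))

  v <- as.vector(label_volume)
  if (!is.integer(v)) {
    r <- round(v)
    if (max(abs(v - r)) > 1e-6)
      stop("label volume is not integer-valued")
    v <- as.integer(r)
  }
  if (any(v < 0)) stop("negative labels are not allowed")
  labels <- array(v, dim = dim(label_volume))

  counts <- table(labels[labels > 0L])
  if (length(counts) == 0L) stop("no labeled voxels in parcellation")
  voxel_volume <- abs(det(affine[1:3, 1:3]))
  edges <- sqrt(colSums(affine[1:3, 1:3]^2))
  roi_labels <- sort(as.integer(names(counts)))
  roi_volumes <- as.numeric(counts[as.character(roi_labels)]) * voxel_volume
  names(roi_volumes) <- as.character(roi_labels)

  structure(list(labels = labels, affine = affine, inverse_affine = inv,
                 voxel_volume = voxel_volume, min_edge = min(edges),
                 roi_volumes = roi_volumes, roi_labels = roi_labels,
                 cache = new.env(parent = emptyenv())),
            class = "parcellation")
}

#' Read a parcellation from a NIfTI-1 file
#'
#' The label data must be integer-valued (after a safe rounding check) and
#' contain at least one nonzero label. Per-region volumes are computed as
#' voxel count times voxel volume.
#'
#' @param path path to a NIfTI file.
#' @return A [parcellation()] object.
#' @export
read_parcellation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  parcellation(array(as.vector(img), dim = dim(img)), matrix(aff, 4L, 4L))
}

#' Write a parcellation to a NIfTI-1 file
#'
#' @param parc a `parcellation`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_parcellation <- function(parc, path) {
  stopifnot(inherits(parc, "parcellation"))
  img <- RNifti::asNifti(parc$labels)
  img <- RNifti::`sform<-`(img, structure(parc$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = "int32")
  invisible(path)
}

#' Look up region labels at world-mm points
#'
#' Each point is mapped through the inverse affine to a 0-based voxel index,
#' rounded to the nearest voxel (voxel centres). Points outside the volume
#' return 0 (background).
#'
#' @param parc a `parcellation`.
#' @param pts n x 3 matrix of world-mm points (or a length-3 vector).
#' @return integer vector of labels (0 = background or out of volume).
#' @export
labels_at <- function(parc, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3L)
  ijk <- round(world_to_voxel(parc, pts))
  d <- dim(parc$labels)
  inside <- ijk[, 1L] >= 0 & ijk[, 1L] < d[1L] &
            ijk[, 2L] >= 0 & ijk[, 2L] < d[2L] &
            ijk[, 3L] >= 0 & ijk[, 3L] < d[3L]
  out <- integer(nrow(ijk))
  if (any(inside)) {
    lin <- 1L + ijk[inside, 1L] + d[1L] * (ijk[inside, 2L] + d[2L] * ijk[inside, 3L])
    out[inside] <- parc$labels[lin]
  }
  out
}

# World-mm centres and labels of all labeled voxels, cached on the object.
labeled_voxel_centers <- function(parc) {
  if (!is.null(parc$cache$lvc)) return(parc$cache$lvc)
  idx <- which(parc$labels > 0L)
  d <- dim(parc$labels)
  idx0 <- idx - 1L
  i <- idx0 %% d[1L]
  j <- (idx0 %/% d[1L]) %% d[2L]
  k <- idx0 %/% (d[1L] * d[2L])
  centers <- voxel_to_world(parc, cbind(i, j, k))
  res <- list(centers = centers, labels = as.integer(parc$labels[idx]),
              linear = idx)
  parc$cache$lvc <- res
  res
}

#' @export
print.parcellation <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf(
    "<parcellation> %dx%dx%d voxels, %.3g mm^3/voxel, %d regions\n",
    d[1L], d[2L], d[3L], x$voxel_volume, length(x$roi_labels)))
  invisible(x)
}
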