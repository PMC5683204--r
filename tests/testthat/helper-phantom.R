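# Shared fixtures: phantoms are generated in code at test time, never stored.

# desk-scale phantom for fast unit tests (32^3 voxels, 2 mm isotropic)
phantom32 <- function(seed = 1L, ...) {
  make_phantom(phantom_spec(grid_shape = c(32L, 32L, 32L), seed = seed, ...))
}

# hand-built parcellation: axis-aligned slabs of the given labels along x
slab_parcellation <- function(dims = c(12L, 8L, 8L), voxel = 1,
                              slab_labels = c(1L, 2L, 3L)) {
  arr <- array(0L, dim = dims)
  nx <- dims[1L] %/% length(slab_labels)
  for (s in seq_along(slab_labels))
    arr[((s - 1L) * nx + 1L):(s * nx), , ] <- slab_labels[s]
  aff <- diag(c(voxel, voxel, voxel, 1))
  parcellation(arr, aff)
}

# spherical single-label phantom centred on the origin
sphere_parcellation <- function(radius_mm = 40, dims = c(64L, 64L, 64L),
                                voxel = 2) {
  aff <- diag(c(voxel, voxel, voxel, 1))
  aff[1:3, 4L] <- -(dims * voxel) / 2 + voxel / 2
  idx <- expand.grid(i = 0:(dims[1L] - 1L), j = 0:(dims[2L] - 1L),
                     k = 0:(dims[3L] - 1L))
  w <- as.matrix(idx) * voxel +
    matrix(aff[1:3, 4L], nrow(idx), 3L, byrow = TRUE)
  arr <- array(as.integer(sqrt(rowSums(w^2)) <= radius_mm), dim = dims)
  parcellation(arr, aff)
}
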