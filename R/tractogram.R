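# Tractograms: ordered 3D polylines ("streamlines") in world mm. Readers and
# writers for the two de-facto standard streamline formats, TCK (MRtrix) and
# TRK (TrackVis v2), are implemented here directly on top of R's binary I/O;
# both store float32 coordinates, so round-trips are exact to well below
# 1e-4 mm at brain-scale coordinates. The streamline index (position in the
# list) is the stable identifier used throughout the pipeline.

#' Construct a tractogram from a list of polylines
#'
#' @param streamlines list of n x 3 numeric matrices (n >= 2), world mm.
#'   Single-point streamlines are dropped with a warning; an empty tractogram
#'   is allowed.
#' @return An object of class `tractogram`: list with `streamlines`.
#' @export
tractogram <- function(streamlines = list()) {
  streamlines <- lapply(streamlines, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 3L) stop("each streamline must be an n x 3 matrix")
    storage.mode(m) <- "double"
    if (any(!is.finite(m))) stop("streamline coordinates must be finite")
    m
  })
  npts <- vapply(streamlines, nrow, integer(1))
  if (any(npts < 2L)) {
    warning(sum(npts < 2L), " streamline(s) with fewer than 2 points dropped")
    streamlines <- streamlines[npts >= 2L]
  }
  structure(list(streamlines = streamlines), class = "tractogram")
}

#' @export
length.tractogram <- function(x) length(x$streamlines)

#' @export
print.tractogram <- function(x, ...) {
  n <- length(x$streamlines)
  pts <- if (n) sum(vapply(x$streamlines, nrow, integer(1))) else 0L
  cat(sprintf("<tractogram> %d streamlines, %d points\n", n, pts))
  invisible(x)
}

#' Read a tractogram from a TCK or TRK file
#'
#' Dispatches on the file extension. Streamline points are expressed in world
#' mm on load (TCK stores them natively; TRK voxel-mm coordinates are mapped
#' through the header's voxel-to-RAS transform), so they share the frame of
#' [read_parcellation()] output.
#'
#' @param path path to a `.tck` or `.trk` file.
#' @return A [tractogram()].
#' @export
read_tractogram <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         tck = read_tck(path),
         trk = read_trk(path),
         stop("unsupported tractogram extension '.", ext,
              "' (expected .tck or .trk)"))
}

#' @rdname read_tractogram
#' @export
read_tck <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(magic, "mrtrix tracks"))
    stop("not a TCK file (bad magic line): ", path)
  datatype <- NULL
  offset <- NULL
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("TCK header missing END line: ", path)
    if (identical(line, "END")) break
    kv <- regmatches(line, regexec("^([^:]+):\\s*(.*)$", line))[[1L]]
    if (length(kv) == 3L) {
      key <- trimws(kv[2L]); val <- trimws(kv[3L])
      if (key == "datatype") datatype <- val
      if (key == "file") {
        parts <- strsplit(val, "\\s+")[[1L]]
        if (parts[1L] != ".") stop("external TCK data files unsupported")
        offset <- as.integer(parts[2L])
      }
    }
  }
  if (is.null(offset)) stop("TCK header has no 'file' field: ", path)
  spec <- switch(datatype,
                 Float32LE = list(size = 4L, endian = "little"),
                 Float32BE = list(size = 4L, endian = "big"),
                 Float64LE = list(size = 8L, endian = "little"),
                 Float64BE = list(size = 8L, endian = "big"),
                 stop("unsupported TCK datatype: ", datatype))
  seek(con, offset)
  nmax <- (file.size(path) - offset) %/% spec$size
  raw <- readBin(con, "double", n = nmax, size = spec$size,
                 endian = spec$endian)
  m <- matrix(raw[seq_len(3L * (length(raw) %/% 3L))], ncol = 3L, byrow = TRUE)
  streamlines <- list()
  cur_start <- 1L
  i <- 1L
  while (i <= nrow(m)) {
    if (is.nan(m[i, 1L]) || is.infinite(m[i, 1L])) {
      if (i > cur_start)
        streamlines[[length(streamlines) + 1L]] <- m[cur_start:(i - 1L), ,
                                                     drop = FALSE]
      if (is.infinite(m[i, 1L])) break
      cur_start <- i + 1L
    }
    i <- i + 1L
  }
  if (length(streamlines) == 0L)
    warning("empty tractogram: ", path)
  tractogram(streamlines)
}

#' Write a tractogram to a TCK file
#'
#' Coordinates are written as little-endian float32 in world mm, streamlines
#' separated by NaN triplets and terminated by an Inf triplet, per the MRtrix
#' track-file layout.
#'
#' @param tract a [tractogram()].
#' @param path output `.tck` path.
#' @return `path`, invisibly.
#' @export
write_tck <- function(tract, path) {
  stopifnot(inherits(tract, "tractogram"))
  n <- length(tract$streamlines)
  make_header <- function(offset) {
    paste0("mrtrix tracks\n",
           "datatype: Float32LE\n",
           sprintf("count: %d\n", n),
           sprintf("file: . %d\n", offset),
           "END\n")
  }
  offset <- nchar(make_header(0L), type = "bytes")
  # fixed point: the offset's own digit count feeds back into the header size
  repeat {
    h <- make_header(offset)
    if (nchar(h, type = "bytes") == offset) break
    offset <- nchar(h, type = "bytes")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(h, con, eos = NULL)
  for (s in tract$streamlines) {
    writeBin(as.numeric(t(s)), con, size = 4L, endian = "little")
    writeBin(rep(NaN, 3L), con, size = 4L, endian = "little")
  }
  writeBin(rep(Inf, 3L), con, size = 4L, endian = "little")
  invisible(path)
}

# --- TRK (TrackVis) ---------------------------------------------------------

trk_axcodes <- function(affine) {
  pos <- c("R", "A", "S"); neg <- c("L", "P", "I")
  codes <- character(3L)
  for (j in 1:3) {
    col <- affine[1:3, j]
    i <- which.max(abs(col))
    codes[j] <- if (col[i] >= 0) pos[i] else neg[i]
  }
  paste(codes, collapse = "")
}

#' @rdname read_tractogram
#' @export
read_trk <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 1000L)
  if (length(hdr) < 1000L) stop("truncated TRK header: ", path)
  rd <- function(what, n, size, at, endian) {
    readBin(hdr[(at + 1L):length(hdr)], what, n = n, size = size,
            endian = endian)
  }
  endian <- "little"
  hdr_size <- rd("integer", 1L, 4L, 996L, endian)
  if (hdr_size != 1000L) {
    endian <- "big"
    hdr_size <- rd("integer", 1L, 4L, 996L, endian)
    if (hdr_size != 1000L) stop("not a TRK file (bad hdr_size): ", path)
  }
  magic <- rawToChar(hdr[1:5])
  if (magic != "TRACK") stop("not a TRK file (bad magic): ", path)
  voxel_size <- rd("double", 3L, 4L, 12L, endian)
  n_scalars <- rd("integer", 1L, 2L, 36L, endian)
  n_properties <- rd("integer", 1L, 2L, 238L, endian)
  vox_to_ras <- matrix(rd("double", 16L, 4L, 440L, endian), 4L, 4L,
                       byrow = TRUE)
  version <- rd("integer", 1L, 4L, 992L, endian)
  if (version < 2L || all(vox_to_ras == 0))
    stop("TRK file lacks a voxel-to-RAS transform (version < 2): ", path)
  vo_raw <- hdr[509:512]
  voxel_order <- rawToChar(vo_raw[vo_raw != as.raw(0)])
  if (nzchar(voxel_order) && voxel_order != trk_axcodes(vox_to_ras))
    stop("TRK voxel_order '", voxel_order,
         "' disagrees with the voxel-to-RAS transform; unsupported")
  n_count <- rd("integer", 1L, 4L, 988L, endian)

  # voxmm -> world: scale to voxel indices, shift to centre convention,
  # then apply vox_to_ras
  to_world <- function(m) {
    v <- sweep(m, 2L, voxel_size, "/") - 0.5
    apply_affine(vox_to_ras, v)
  }
  streamlines <- list()
  repeat {
    np <- readBin(con, "integer", n = 1L, size = 4L, endian = endian)
    if (length(np) == 0L) break
    vals <- readBin(con, "double", n = np * (3L + n_scalars), size = 4L,
                    endian = endian)
    if (length(vals) < np * (3L + n_scalars))
      stop("truncated TRK track data: ", path)
    if (n_properties > 0L)
      readBin(con, "double", n = n_properties, size = 4L, endian = endian)
    pts <- matrix(vals, ncol = 3L + n_scalars, byrow = TRUE)[, 1:3,
                                                             drop = FALSE]
    streamlines[[length(streamlines) + 1L]] <- to_world(pts)
    if (n_count > 0L && length(streamlines) == n_count) break
  }
  if (length(streamlines) == 0L) warning("empty tractogram: ", path)
  tractogram(streamlines)
}

#' Write a tractogram to a TRK file
#'
#' TRK stores coordinates in corner-origin voxel-mm, so a reference
#' [parcellation()] (or an explicit affine) is needed to define the voxel
#' grid; world-mm points are mapped through the inverse of its affine on
#' write and recovered through the header transform on read.
#'
#' @param tract a [tractogram()].
#' @param path output `.trk` path.
#' @param reference a `parcellation` supplying the voxel grid, or `NULL` to
#'   use `affine` and `dim` directly.
#' @param affine,dim voxel-to-world transform and grid dimensions, used when
#'   `reference` is `NULL` (defaults: identity, 1 mm isotropic, dim 1,1,1).
#' @return `path`, invisibly.
#' @export
write_trk <- function(tract, path, reference = NULL,
                      affine = diag(4), dim = c(1L, 1L, 1L)) {
  stopifnot(inherits(tract, "tractogram"))
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "parcellation"))
    affine <- reference$affine
    dim <- dim(reference$labels)
  }
  voxel_size <- sqrt(colSums(affine[1:3, 1:3]^2))
  inv <- solve(affine)
  to_voxmm <- function(m) sweep(apply_affine(inv, m) + 0.5, 2L, voxel_size,
                                "*")
  con <- file(path, "wb")
  on.exit(close(con))
  wchar <- function(s, width) {
    r <- charToRaw(s)
    writeBin(c(r, rep(as.raw(0), width - length(r))), con)
  }
  wchar("TRACK", 6L)
  writeBin(as.integer(dim), con, size = 2L, endian = "little")
  writeBin(as.numeric(voxel_size), con, size = 4L, endian = "little")
  writeBin(numeric(3L), con, size = 4L, endian = "little")     # origin
  writeBin(0L, con, size = 2L, endian = "little")              # n_scalars
  writeBin(rep(as.raw(0), 200L), con)                          # scalar names
  writeBin(0L, con, size = 2L, endian = "little")              # n_properties
  writeBin(rep(as.raw(0), 200L), con)                          # property names
  writeBin(as.numeric(t(affine)), con, size = 4L, endian = "little")
  writeBin(rep(as.raw(0), 444L), con)                          # reserved
  wchar(trk_axcodes(affine), 4L)
  writeBin(rep(as.raw(0), 4L), con)                            # pad2
  writeBin(numeric(6L), con, size = 4L, endian = "little")     # orientation
  writeBin(rep(as.raw(0), 2L), con)                            # pad1
  writeBin(rep(as.raw(0), 6L), con)                            # invert/swap
  writeBin(length(tract$streamlines), con, size = 4L, endian = "little")
  writeBin(2L, con, size = 4L, endian = "little")              # version
  writeBin(1000L, con, size = 4L, endian = "little")           # hdr_size
  for (s in tract$streamlines) {
    writeBin(nrow(s), con, size = 4L, endian = "little")
    writeBin(as.numeric(t(to_voxmm(s))), con, size = 4L, endian = "little")
  }
  invisible(path)
}
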