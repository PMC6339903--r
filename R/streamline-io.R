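# TRK (TrackVis) and TCK (MRtrix) tractogram I/O.
#
# TRK stores points in "voxel-mm" (voxel index * voxel size, corner
# origin); conversion to world RAS mm uses the header's vox_to_ras
# affine:  rasmm = A %*% (voxmm / voxel_size - 0.5).
# TCK stores points in scanner (world mm) space directly.
# Both are little-endian float32 on disk.

#' Read a tractogram (TRK or TCK) as a streamline bundle
#'
#' The dialect is detected from the file extension and verified against
#' the file magic. All points are returned in world RAS millimetres
#' regardless of the on-disk convention; streamline order is preserved.
#'
#' @param path Path to a `.trk` or `.tck` file.
#' @param name Bundle label for the result; defaults to the file stem.
#' @param space Frame tag for the result.
#' @return A `streamline_bundle`. An empty tractogram is returned with
#'   zero streamlines and a warning.
#' @export
read_streamlines <- function(path, name = NULL, space = "synthetic") {
  if (!file.exists(path)) stop("tractogram not found: ", path)
  if (is.null(name)) {
    name <- sub("\\.(trk|tck)$", "", basename(path), ignore.case = TRUE)
  }
  ext <- tolower(tools::file_ext(path))
  streamlines <- switch(ext,
    trk = read_trk_streamlines(path),
    tck = read_tck_streamlines(path),
    stop("unsupported tractogram extension '.", ext, "' (expected .trk or .tck)")
  )
  if (length(streamlines) == 0L) {
    warning("tractogram '", basename(path), "' contains no streamlines")
    return(structure(list(streamlines = list(), name = name, space = space),
                     class = "streamline_bundle"))
  }
  streamline_bundle(streamlines, name = name, space = space)
}

#' Write a streamline bundle to TRK or TCK
#'
#' The format is chosen from the file extension. For TRK a grid geometry
#' (voxel size, dimensions and voxel-to-world affine) is embedded in the
#' header; world coordinates are converted to the TRK voxel-mm
#' convention on write.
#'
#' @param bundle A `streamline_bundle` (world RAS mm).
#' @param path Output path ending in `.trk` or `.tck`.
#' @param voxel_size Length-3 voxel dimensions for the TRK header.
#' @param dim Length-3 integer grid dimensions for the TRK header.
#' @param affine 4x4 voxel-to-world affine for the TRK header.
#' @return `path`, invisibly.
#' @export
write_streamlines <- function(bundle, path, voxel_size = c(1, 1, 1),
                              dim = c(100L, 100L, 100L), affine = diag(4)) {
  stopifnot(inherits(bundle, "streamline_bundle"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    trk = write_trk_streamlines(bundle$streamlines, path, voxel_size, dim, affine),
    tck = write_tck_streamlines(bundle$streamlines, path),
    stop("unsupported tractogram extension '.", ext, "'")
  )
  invisible(path)
}

read_trk_streamlines <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 6L)
  if (!identical(rawToChar(magic[1:5]), "TRACK")) {
    stop("TRK format error in field 'id_string': not a TrackVis file")
  }
  dim3 <- readBin(con, "integer", n = 3L, size = 2L, endian = "little")
  voxel_size <- readBin(con, "double", n = 3L, size = 4L, endian = "little")
  invisible(readBin(con, "double", n = 3L, size = 4L, endian = "little")) # origin
  n_scalars <- readBin(con, "integer", n = 1L, size = 2L, endian = "little")
  invisible(readBin(con, "raw", n = 200L))
  n_properties <- readBin(con, "integer", n = 1L, size = 2L, endian = "little")
  invisible(readBin(con, "raw", n = 200L))
  vox_to_ras <- matrix(readBin(con, "double", n = 16L, size = 4L, endian = "little"),
                       nrow = 4L, byrow = TRUE)
  invisible(readBin(con, "raw", n = 444L + 4L + 4L + 24L + 2L + 6L))
  n_count <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  version <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  hdr_size <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (!identical(hdr_size, 1000L)) {
    stop("TRK format error in field 'hdr_size': expected 1000, got ", hdr_size)
  }
  if (version > 2L) {
    stop("TRK format error in field 'version': unsupported version ", version)
  }
  if (all(vox_to_ras == 0)) {
    stop("TRK format error in field 'vox_to_ras': affine is all zeros (pre-v2 file)")
  }
  if (any(voxel_size <= 0)) {
    stop("TRK format error in field 'voxel_size': non-positive voxel size")
  }
  streamlines <- list()
  repeat {
    npts <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    if (length(npts) == 0L) break
    if (npts < 0L) stop("TRK format error in field 'n_points': negative count")
    vals <- readBin(con, "double", n = npts * (3L + n_scalars), size = 4L,
                    endian = "little")
    if (length(vals) < npts * (3L + n_scalars)) {
      stop("TRK format error: truncated streamline data (field 'points')")
    }
    if (n_properties > 0L) {
      props <- readBin(con, "double", n = n_properties, size = 4L, endian = "little")
      if (length(props) < n_properties) {
        stop("TRK format error: truncated streamline data (field 'properties')")
      }
    }
    m <- matrix(vals, ncol = 3L + n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    # voxmm -> voxel (corner origin) -> world RAS
    vox <- sweep(m, 2L, voxel_size, "/") - 0.5
    streamlines[[length(streamlines) + 1L]] <- apply_affine(vox_to_ras, vox)
  }
  if (n_count > 0L && length(streamlines) != n_count) {
    stop("TRK format error in field 'n_count': header says ", n_count,
         " streamlines, file contains ", length(streamlines))
  }
  streamlines
}

write_trk_streamlines <- function(streamlines, path, voxel_size, dim, affine) {
  check_affine(affine)
  voxel_size <- as.double(voxel_size)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("TRACK"), as.raw(0L)), con)
  writeBin(as.integer(dim), con, size = 2L, endian = "little")
  writeBin(voxel_size, con, size = 4L, endian = "little")
  writeBin(c(0, 0, 0), con, size = 4L, endian = "little")        # origin
  writeBin(0L, con, size = 2L, endian = "little")                # n_scalars
  writeBin(raw(200L), con)
  writeBin(0L, con, size = 2L, endian = "little")                # n_properties
  writeBin(raw(200L), con)
  writeBin(as.double(t(affine)), con, size = 4L, endian = "little")
  writeBin(raw(444L), con)                                       # reserved
  writeBin(c(charToRaw("RAS"), as.raw(0L)), con)                 # voxel_order
  writeBin(raw(4L), con)                                         # pad2
  writeBin(c(1, 0, 0, 0, 1, 0), con, size = 4L, endian = "little")
  writeBin(raw(2L), con)                                         # pad1
  writeBin(raw(6L), con)                                         # invert/swap flags
  writeBin(length(streamlines), con, size = 4L, endian = "little")
  writeBin(2L, con, size = 4L, endian = "little")                # version
  writeBin(1000L, con, size = 4L, endian = "little")             # hdr_size
  inv <- solve(affine)
  for (s in streamlines) {
    s <- as_points(s)
    vox <- apply_affine(inv, s)
    voxmm <- sweep(vox + 0.5, 2L, voxel_size, "*")
    writeBin(nrow(s), con, size = 4L, endian = "little")
    writeBin(as.double(t(voxmm)), con, size = 4L, endian = "little")
  }
  invisible(path)
}

read_tck_streamlines <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  first <- readLines(con, n = 1L)
  if (!identical(first, "mrtrix tracks")) {
    stop("TCK format error in field 'magic': not an MRtrix track file")
  }
  datatype <- NULL
  offset <- NULL
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("TCK format error: header missing END")
    if (identical(line, "END")) break
    kv <- regmatches(line, regexpr(":", line), invert = TRUE)[[1]]
    if (length(kv) == 2L) {
      key <- trimws(kv[1]); val <- trimws(kv[2])
      if (key == "datatype") datatype <- val
      if (key == "file") {
        parts <- strsplit(val, "\\s+")[[1]]
        offset <- as.integer(parts[length(parts)])
      }
    }
  }
  if (is.null(offset)) stop("TCK format error in field 'file': missing data offset")
  if (is.null(datatype) || datatype != "Float32LE") {
    stop("TCK format error in field 'datatype': only Float32LE is supported, got ",
         if (is.null(datatype)) "<missing>" else datatype)
  }
  seek(con, offset)
  vals <- readBin(con, "double", n = file.size(path), size = 4L, endian = "little")
  if (length(vals) %% 3L != 0L) {
    stop("TCK format error: streamline data is not a whole number of triplets")
  }
  pts <- matrix(vals, ncol = 3L, byrow = TRUE)
  streamlines <- list()
  start <- 1L
  i <- 1L
  terminated <- FALSE
  while (i <= nrow(pts)) {
    row <- pts[i, ]
    if (all(is.nan(row))) {
      if (i > start) {
        streamlines[[length(streamlines) + 1L]] <- pts[start:(i - 1L), , drop = FALSE]
      }
      start <- i + 1L
    } else if (all(is.infinite(row))) {
      if (i > start) {
        streamlines[[length(streamlines) + 1L]] <- pts[start:(i - 1L), , drop = FALSE]
      }
      terminated <- TRUE
      break
    }
    i <- i + 1L
  }
  if (!terminated) {
    stop("TCK format error: missing end-of-file (Inf,Inf,Inf) marker")
  }
  streamlines
}

write_tck_streamlines <- function(streamlines, path) {
  body_lines <- c(
    "mrtrix tracks",
    sprintf("count: %d", length(streamlines)),
    "datatype: Float32LE"
  )
  # the header must state its own byte length in the 'file' entry
  offset <- 0L
  repeat {
    lines <- c(body_lines, sprintf("file: . %d", offset), "END")
    need <- sum(nchar(lines, type = "bytes")) + length(lines)  # + newlines
    if (need == offset) break
    offset <- need
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  for (s in streamlines) {
    writeBin(as.double(t(as_points(s))), con, size = 4L, endian = "little")
    writeBin(rep(NaN, 3L), con, size = 4L, endian = "little")
  }
  writeBin(rep(Inf, 3L), con, size = 4L, endian = "little")
  invisible(path)
}
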