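#' Create a streamline bundle
#'
#' A bundle is an ordered collection of streamlines (3-D polylines), each
#' an n x 3 matrix of points in world RAS millimetres.
#'
#' @param streamlines List of numeric matrices, each with >= 2 rows and 3
#'   columns (x, y, z in mm).
#' @param name Bundle label (e.g. "AF_L").
#' @param space Frame tag: "time1", "time2" or "synthetic".
#' @return An object of class `streamline_bundle`.
#' @export
#' @examples
#' b <- streamline_bundle(list(cbind(0:2, 0, 0)), name = "demo")
#' n_streamlines(b)
streamline_bundle <- function(streamlines, name = "", space = "synthetic") {
  if (!is.list(streamlines)) stop("streamlines must be a list of matrices")
  streamlines <- lapply(streamlines, as_points)
  for (i in seq_along(streamlines)) {
    s <- streamlines[[i]]
    if (nrow(s) < 2L) {
      stop("streamline ", i, " has fewer than 2 points")
    }
    if (any(!is.finite(s))) {
      stop("streamline ", i, " contains non-finite coordinates")
    }
  }
  structure(
    list(streamlines = streamlines, name = name, space = space),
    class = "streamline_bundle"
  )
}

#' @export
print.streamline_bundle <- function(x, ...) {
  np <- sum(vapply(x$streamlines, nrow, integer(1)))
  cat(sprintf("<streamline_bundle '%s'> %d streamlines, %d points, space=%s\n",
              x$name, length(x$streamlines), np, x$space))
  invisible(x)
}

#' Number of streamlines in a bundle
#' @param bundle A `streamline_bundle`.
#' @return Integer count.
#' @export
n_streamlines <- function(bundle) {
  stopifnot(inherits(bundle, "streamline_bundle"))
  length(bundle$streamlines)
}

#' Apply an affine transform to every point of a bundle
#'
#' Used to transport Time-1 bundles into Time-2 space before computing
#' overlap, mirroring inter-session linear registration.
#'
#' @param bundle A `streamline_bundle`.
#' @param m Invertible 4x4 affine matrix.
#' @param space Frame tag for the result (default "time2").
#' @return A `streamline_bundle` with identical streamline and point
#'   counts and transformed coordinates.
#' @export
transform_streamlines <- function(bundle, m, space = "time2") {
  stopifnot(inherits(bundle, "streamline_bundle"))
  check_affine(m)
  if (abs(det(m[1:3, 1:3])) < .Machine$double.eps * 64) {
    stop("transform is singular")
  }
  out <- lapply(bundle$streamlines, function(s) apply_affine(m, s))
  streamline_bundle(out, name = bundle$name, space = space)
}

#' Length of one streamline
#'
#' Sum of Euclidean segment lengths of the polyline.
#'
#' @param polyline n x 3 matrix of points (n >= 2), in mm.
#' @return Length in mm.
#' @export
#' @examples
#' streamline_length(rbind(c(0, 0, 0), c(3, 4, 0)))  # 5
streamline_length <- function(polyline) {
  p <- as_points(polyline)
  if (nrow(p) < 2L) stop("a streamline needs at least 2 points")
  d <- diff(p)
  sum(sqrt(rowSums(d * d)))
}

#' Mean length of streamlines (MLS) of a bundle
#'
#' @param bundle A non-empty `streamline_bundle`.
#' @return Mean streamline length in mm.
#' @export
mean_length <- function(bundle) {
  stopifnot(inherits(bundle, "streamline_bundle"))
  if (n_streamlines(bundle) == 0L) stop("bundle has no streamlines")
  mean(vapply(bundle$streamlines, streamline_length, numeric(1)))
}

# Resample a polyline at equal arc-length steps, by linear
# interpolation against cumulative arc length. Sample positions are the
# two endpoints plus the midpoints of ceiling(L / step) equal
# subdivisions; the midpoint rule makes the position set symmetric
# under reversal of the polyline, so voxel visitation does not depend
# on streamline orientation.
resample_polyline <- function(p, step) {
  p <- as_points(p)
  d <- diff(p)
  seg <- sqrt(rowSums(d * d))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total == 0) return(p[1L, , drop = FALSE])
  m <- max(1, ceiling(total / step))
  at <- c(0, (seq_len(m) - 0.5) * total / m, total)
  # cumulative arc length may repeat where consecutive points coincide
  keep <- !duplicated(s)
  cbind(
    approx(s[keep], p[keep, 1L], xout = at)$y,
    approx(s[keep], p[keep, 2L], xout = at)$y,
    approx(s[keep], p[keep, 3L], xout = at)$y
  )
}
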