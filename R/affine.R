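#' Read a 4x4 affine transform from a plain-text file
#'
#' The file must contain 16 whitespace-separated numbers forming a 4x4
#' matrix in row-major order, with last row (0, 0, 0, 1) to within 1e-6.
#' The matrix is interpreted as mapping Time-1 world millimetre
#' coordinates to Time-2 world millimetre coordinates.
#'
#' @param path Path to the text file.
#' @return A 4x4 numeric matrix.
#' @export
#' @examples
#' f <- tempfile()
#' writeLines(apply(format(diag(4)), 1, paste, collapse = " "), f)
#' read_affine(f)
read_affine <- function(path) {
  if (!file.exists(path)) {
    stop("affine file not found: ", path)
  }
  vals <- scan(path, what = numeric(), quiet = TRUE)
  if (length(vals) != 16L) {
    stop("affine file must contain exactly 16 numbers, got ", length(vals))
  }
  m <- matrix(vals, nrow = 4L, byrow = TRUE)
  check_affine(m)
  m
}

#' Write a 4x4 affine transform to a plain-text file
#'
#' @param m A 4x4 numeric matrix with last row (0, 0, 0, 1).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_affine <- function(m, path) {
  check_affine(m)
  lines <- apply(m, 1L, function(r) paste(formatC(r, format = "g", digits = 17), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

check_affine <- function(m) {
  if (!is.matrix(m) || !all(dim(m) == c(4L, 4L)) || !is.numeric(m)) {
    stop("affine must be a numeric 4x4 matrix")
  }
  if (any(!is.finite(m))) stop("affine contains non-finite values")
  if (max(abs(m[4L, ] - c(0, 0, 0, 1))) > 1e-6) {
    stop("last row of affine must be (0, 0, 0, 1); got (",
         paste(format(m[4L, ]), collapse = ", "), ")")
  }
  invisible(m)
}

#' Apply a 4x4 affine to a matrix of 3-D points
#'
#' @param m 4x4 affine matrix.
#' @param pts n x 3 numeric matrix of points (rows are points).
#' @return n x 3 matrix of transformed points.
#' @export
apply_affine <- function(m, pts) {
  check_affine(m)
  pts <- as_points(pts)
  out <- pts %*% t(m[1:3, 1:3, drop = FALSE])
  out[, 1L] <- out[, 1L] + m[1L, 4L]
  out[, 2L] <- out[, 2L] + m[2L, 4L]
  out[, 3L] <- out[, 3L] + m[3L, 4L]
  out
}

as_points <- function(pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3L, byrow = TRUE)
  if (ncol(pts) != 3L) stop("points must have 3 columns (x, y, z)")
  storage.mode(pts) <- "double"
  pts
}

#' Test two affines for equality within tolerance
#'
#' @param a,b 4x4 matrices.
#' @param tol Maximum absolute elementwise difference (default 1e-4,
#'   accommodating text-file round-off).
#' @return Logical scalar.
#' @export
affines_equal <- function(a, b, tol = 1e-4) {
  max(abs(a - b)) <= tol
}

# 0-based voxel indices of world points under a voxel->world affine
# (half-open cells: index = floor of inverse-affine image).
world_to_voxel <- function(affine, pts) {
  inv <- solve(affine)
  vox <- apply_affine(inv, as_points(pts))
  storage.mode(vox) <- "double"
  floor(vox)
}

# voxel (0-based index) centre -> world
voxel_to_world <- function(affine, idx) {
  apply_affine(affine, as_points(idx))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Derive a reproducible sub-seed from a master seed and string tokens
#'
#' Sub-seeds are a deterministic hash of the master seed and the tokens
#' (e.g. subject, bundle, metric, session), so simulation output does not
#' depend on call order. The result is a non-negative integer below 2^31.
#'
#' @param master Integer master seed.
#' @param ... Character or numeric tokens identifying the draw.
#' @return Integer scalar in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  tokens <- paste(c(master, ...), collapse = "\x1f")
  codes <- utf8ToInt(tokens)
  h <- as.double(master %% 2147483647L)
  for (c in codes) {
    h <- (h * 31 + c) %% 2147483647
  }
  as.integer(h)
}
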