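#' Construct a streamline density map object from an array
#'
#' A density map is a 3-D grid of non-negative streamline visitation
#' weights together with the 4x4 voxel-to-world affine of the grid. The
#' voxel volume is `|det|` of the affine's 3x3 block.
#'
#' @param data 3-D numeric array of non-negative weights.
#' @param affine 4x4 voxel-to-world (RAS mm) affine; voxel indices are
#'   0-based.
#' @return An object of class `density_map`.
#' @export
as_density_map <- function(data, affine = diag(4)) {
  if (length(dim(data)) != 3L) stop("density map data must be a 3-D array")
  if (any(!is.finite(data))) stop("density map contains non-finite values")
  if (any(data < 0)) stop("density map contains negative weights")
  check_affine(affine)
  vv <- abs(det(affine[1:3, 1:3]))
  if (vv <= 0) stop("degenerate grid: affine 3x3 block is singular")
  structure(
    list(data = data, affine = affine, voxel_volume = vv),
    class = "density_map"
  )
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("<density_map> %s grid, voxel volume %.4g mm^3, %d nonzero voxels, total weight %.4g\n",
              paste(dim(x$data), collapse = "x"), x$voxel_volume,
              sum(x$data > 0), sum(x$data)))
  invisible(x)
}

#' Rasterize a bundle into a streamline density map
#'
#' Each streamline is resampled at a fixed arc-length step and assigned
#' to the 0-based voxels containing the resampled points; the voxels are
#' deduplicated per streamline, so a streamline contributes at most 1 to
#' any voxel and each voxel's weight is the number of distinct
#' streamlines visiting it.
#'
#' @param bundle A `streamline_bundle` in the grid's world frame.
#' @param shape Integer length-3 grid dimensions.
#' @param affine 4x4 voxel-to-world affine of the grid.
#' @param step Resampling step in mm; default 0.2 x smallest voxel
#'   dimension.
#' @return A `density_map` with integral weights.
#' @export
density_map <- function(bundle, shape, affine = diag(4), step = NULL) {
  stopifnot(inherits(bundle, "streamline_bundle"))
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) stop("shape must be 3 positive integers")
  check_affine(affine)
  if (abs(det(affine[1:3, 1:3])) < .Machine$double.eps * 64) {
    stop("degenerate grid: affine 3x3 block is singular")
  }
  if (is.null(step)) {
    zoom <- sqrt(colSums(affine[1:3, 1:3]^2))
    step <- 0.2 * min(zoom)
  }
  if (step <= 0) stop("step must be positive")
  counts <- array(0, dim = shape)
  if (n_streamlines(bundle) == 0L) {
    warning("empty bundle: returning all-zero density map")
    return(as_density_map(counts, affine))
  }
  inv <- solve(affine)
  for (s in bundle$streamlines) {
    pts <- resample_polyline(s, step)
    vox <- floor(apply_affine(inv, pts))
    inside <- vox[, 1L] >= 0 & vox[, 1L] < shape[1L] &
      vox[, 2L] >= 0 & vox[, 2L] < shape[2L] &
      vox[, 3L] >= 0 & vox[, 3L] < shape[3L]
    if (!any(inside)) next
    vox <- vox[inside, , drop = FALSE]
    lin <- unique(1 + vox[, 1L] + shape[1L] * (vox[, 2L] + shape[2L] * vox[, 3L]))
    counts[lin] <- counts[lin] + 1
  }
  as_density_map(counts, affine)
}

#' Bundle volume from a density map
#'
#' Volume is the count of voxels with weight > 0 times the voxel volume.
#'
#' @param map A `density_map`.
#' @return Volume in mm^3 (0 for an all-zero map).
#' @export
bundle_volume <- function(map) {
  stopifnot(inherits(map, "density_map"))
  sum(map$data > 0) * map$voxel_volume
}

#' Construct a scalar volume (e.g. an FA map) on a voxel grid
#'
#' Like [as_density_map()] but without the non-negativity requirement,
#' for scalar maps aggregated along a tract.
#'
#' @param data 3-D numeric array.
#' @param affine 4x4 voxel-to-world affine.
#' @return An object of class `scalar_volume`.
#' @export
scalar_volume <- function(data, affine = diag(4)) {
  if (length(dim(data)) != 3L) stop("scalar volume data must be a 3-D array")
  check_affine(affine)
  structure(list(data = data, affine = affine), class = "scalar_volume")
}

#' Mean of a scalar map over a tract's support
#'
#' Aggregates a scalar volume over the voxels visited by a bundle,
#' either weighted by streamline count (`weighted = TRUE`, default;
#' consistent with the weighting rationale of the weighted Dice
#' coefficient) or as a plain mask mean.
#'
#' @param scalar A `scalar_volume` on the same grid as `map`.
#' @param map A `density_map` of the tract.
#' @param weighted If `TRUE`, returns `sum(W * s) / sum(W)` over the
#'   support; otherwise the unweighted mean of `s` over voxels with
#'   `W > 0`.
#' @param tol Affine agreement tolerance (see [affines_equal()]).
#' @return Scalar value.
#' @export
mean_scalar_along_tract <- function(scalar, map, weighted = TRUE, tol = 1e-4) {
  stopifnot(inherits(scalar, "scalar_volume"), inherits(map, "density_map"))
  if (!identical(dim(scalar$data), dim(map$data))) {
    stop("scalar map and density map have different grid shapes")
  }
  if (!affines_equal(scalar$affine, map$affine, tol)) {
    stop("scalar map and density map affines disagree beyond tolerance")
  }
  sup <- map$data > 0
  if (!any(sup)) stop("tract support is empty")
  if (weighted) {
    sum(map$data[sup] * scalar$data[sup]) / sum(map$data[sup])
  } else {
    mean(scalar$data[sup])
  }
}

#' Read a streamline density map from a NIfTI-1 file
#'
#' @param path Path to a 3-D NIfTI file with non-negative values.
#' @return A `density_map`.
#' @export
read_density_map <- function(path) {
  img <- RNifti::readNifti(path)
  d <- as.array(img)
  if (length(dim(d)) != 3L) {
    stop("density map must be 3-D; got ", length(dim(d)), "-D image")
  }
  if (any(d < 0)) stop("density map contains negative values")
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  arr <- d
  attributes(arr) <- list(dim = dim(d))
  as_density_map(arr, aff)
}

#' Read a scalar volume from a NIfTI-1 file
#'
#' @param path Path to a 3-D NIfTI file.
#' @return A `scalar_volume`.
#' @export
read_scalar_volume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- as.array(img)
  if (length(dim(d)) != 3L) stop("scalar volume must be 3-D")
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  arr <- d
  attributes(arr) <- list(dim = dim(d))
  scalar_volume(arr, aff)
}

#' Write a density map or scalar volume to NIfTI-1
#'
#' Data are stored as 64-bit floats with the grid affine in the sform,
#' so integer count maps round-trip exactly.
#'
#' @param map A `density_map` or `scalar_volume`.
#' @param path Output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_density_map <- function(map, path) {
  stopifnot(inherits(map, "density_map") || inherits(map, "scalar_volume"))
  img <- RNifti::asNifti(map$data, internal = FALSE)
  zoom <- sqrt(colSums(map$affine[1:3, 1:3]^2))
  attr(img, "pixdim") <- zoom
  img <- RNifti::`sform<-`(img, structure(map$affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(map$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}
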