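test_that("density maps round-trip through NIfTI exactly", {
  set.seed(3)
  d <- array(as.double(sample(0:9, 1000, replace = TRUE)), c(10, 10, 10))
  aff <- rbind(c(1.5, 0, 0, -20), c(0, 1, 0, 4), c(0, 0, 2.25, 0), c(0, 0, 0, 1))
  m <- as_density_map(d, aff)
  f <- tempfile(fileext = ".nii.gz")
  write_density_map(m, f)
  got <- read_density_map(f)
  expect_identical(got$data, d)
  expect_lt(max(abs(got$affine - aff)), 1e-4)
  # anisotropic voxels: volume is the product of the three spacings
  expect_equal(got$voxel_volume, 1.5 * 1 * 2.25)
})

test_that("invalid density map inputs are rejected", {
  d <- array(1, c(4, 4, 4)); d[2, 2, 2] <- -1
  expect_error(as_density_map(d), "negative")

  f <- tempfile(fileext = ".nii.gz")
  img <- RNifti::asNifti(array(1, c(3, 3, 3, 2)))
  RNifti::writeNifti(img, f)
  expect_error(read_density_map(f), "3-D")
})

test_that("density mapping counts distinct visiting streamlines", {
  # straight line along +x through 5 unit voxels, sampled densely
  line <- cbind(seq(0.1, 4.9, by = 0.2), 0.5, 0.5)
  one <- density_map(streamline_bundle(list(line)), c(5, 5, 5))
  expect_equal(sum(one$data > 0), 5)
  expect_true(all(one$data[, 1, 1] == 1))

  two <- density_map(streamline_bundle(list(line, line)), c(5, 5, 5))
  expect_equal(sum(two$data > 0), 5)
  expect_true(all(two$data[, 1, 1] == 2))

  expect_warning(empty <- density_map(streamline_bundle(list()), c(5, 5, 5)),
                 "empty bundle")
  expect_equal(sum(empty$data), 0)
})

test_that("density mapping matches the supersampling oracle", {
  set.seed(21)
  for (rep in 1:5) {
    poly <- random_polyline(8)
    b <- streamline_bundle(list(poly))
    got <- density_map(b, c(10, 10, 10), step = 0.01)
    ref <- oracle_density(b, c(10, 10, 10), step = 0.01)
    expect_identical(got$data, ref)
  }
  # non-identity grid affine
  aff <- rbind(c(2, 0, 0, -3), c(0, 2, 0, -3), c(0, 0, 2, -3), c(0, 0, 0, 1))
  poly <- random_polyline(6, lo = -1, hi = 14)
  b <- streamline_bundle(list(poly))
  got <- density_map(b, c(8, 8, 8), affine = aff, step = 0.01)
  expect_identical(got$data, oracle_density(b, c(8, 8, 8), affine = aff, step = 0.01))
})

test_that("default-step density closely tracks a 0.01 mm supersampling reference", {
  # the default 0.2 x voxel step misses corner-clipped voxels whose
  # chord is shorter than the step; on jagged random polylines (a
  # worst case relative to smooth tractography streamlines) that loss
  # stays a bounded fraction of the support, and coarse sampling never
  # adds voxels the fine reference lacks
  set.seed(27)
  for (i in 1:5) {
    b <- streamline_bundle(list(random_polyline(8)))
    coarse <- density_map(b, c(10, 10, 10))$data
    fine <- oracle_density(b, c(10, 10, 10), step = 0.01)
    expect_true(all(fine[coarse > 0] > 0))          # no spurious voxels
    missed <- sum(fine > 0) - sum(coarse > 0)
    expect_lte(missed / sum(fine > 0), 0.25)
  }
})

test_that("density is invariant to streamline order and reversal", {
  set.seed(33)
  polys <- lapply(1:4, function(i) random_polyline(7))
  base <- density_map(streamline_bundle(polys), c(10, 10, 10))
  shuffled <- density_map(streamline_bundle(polys[c(3, 1, 4, 2)]), c(10, 10, 10))
  expect_identical(base$data, shuffled$data)
  reversed <- density_map(
    streamline_bundle(lapply(polys, function(p) p[nrow(p):1, ])), c(10, 10, 10))
  expect_identical(base$data, reversed$data)
})

test_that("bundle volume counts supported voxels times voxel volume", {
  d <- array(0, c(6, 6, 6)); d[sample(216, 10)] <- 2
  expect_equal(bundle_volume(as_density_map(d)), 10)
  aff2 <- diag(c(2, 2, 2, 1))
  d3 <- array(0, c(6, 6, 6)); d3[1:3] <- 1
  expect_equal(bundle_volume(as_density_map(d3, aff2)), 3 * 8)
  expect_equal(bundle_volume(as_density_map(array(0, c(4, 4, 4)))), 0)
})

test_that("volume is monotone under adding streamlines", {
  set.seed(9)
  polys <- lapply(1:6, function(i) random_polyline(6))
  vols <- vapply(1:6, function(k) {
    bundle_volume(density_map(streamline_bundle(polys[1:k]), c(10, 10, 10)))
  }, numeric(1))
  expect_true(all(diff(vols) >= 0))
})

test_that("along-tract scalar means honour density weighting", {
  w <- array(0, c(4, 4, 4)); s <- array(0.5, c(4, 4, 4))
  w[1, 1, 1] <- 3; w[2, 1, 1] <- 1
  s[1, 1, 1] <- 0.2; s[2, 1, 1] <- 0.6
  dm <- as_density_map(w)
  sv <- scalar_volume(s)
  expect_equal(mean_scalar_along_tract(sv, dm, weighted = TRUE), 0.3)
  expect_equal(mean_scalar_along_tract(sv, dm, weighted = FALSE), 0.4)

  # constant scalar: both modes return the constant
  sc <- scalar_volume(array(7, c(4, 4, 4)))
  expect_equal(mean_scalar_along_tract(sc, dm, weighted = TRUE), 7)
  expect_equal(mean_scalar_along_tract(sc, dm, weighted = FALSE), 7)

  # equal weights: weighted equals unweighted
  w2 <- array(0, c(4, 4, 4)); w2[1:5] <- 2
  set.seed(2); s2 <- array(runif(64), c(4, 4, 4))
  expect_equal(
    mean_scalar_along_tract(scalar_volume(s2), as_density_map(w2), TRUE),
    mean_scalar_along_tract(scalar_volume(s2), as_density_map(w2), FALSE)
  )

  # mismatched grids are refused
  expect_error(
    mean_scalar_along_tract(scalar_volume(array(1, c(3, 3, 3))), dm),
    "shapes")
  expect_error(
    mean_scalar_along_tract(scalar_volume(s, diag(c(2, 2, 2, 1))), dm),
    "affine")
  expect_error(
    mean_scalar_along_tract(sv, as_density_map(array(0, c(4, 4, 4)))),
    "empty")
})

test_that("streamline and bundle lengths are exact", {
  expect_equal(streamline_length(rbind(c(0, 0, 0), c(3, 4, 0))), 5)
  expect_equal(streamline_length(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))), 2)
  expect_error(streamline_length(rbind(c(0, 0, 0))), "2 points")

  set.seed(8)
  p <- matrix(rnorm(150), ncol = 3)
  acc <- 0
  for (i in 1:(nrow(p) - 1)) acc <- acc + sqrt(sum((p[i + 1, ] - p[i, ])^2))
  expect_equal(streamline_length(p), acc, tolerance = 1e-12)

  b <- streamline_bundle(list(rbind(c(0, 0, 0), c(5, 0, 0)),
                              rbind(c(0, 0, 0), c(0, 7, 0))))
  expect_equal(mean_length(b), 6)
  expect_error(mean_length(streamline_bundle(list())), "no streamlines")

  # rigid invariance of mean length
  set.seed(12)
  b2 <- streamline_bundle(lapply(1:5, function(i) matrix(rnorm(30), ncol = 3)))
  th <- 0.7
  rot <- diag(4)
  rot[1:3, 1:3] <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rot[1:3, 4] <- c(4, -2, 9)
  expect_equal(mean_length(transform_streamlines(b2, rot)), mean_length(b2),
               tolerance = 1e-9)
})

test_that("affine transport of bundles composes and inverts", {
  set.seed(14)
  b <- streamline_bundle(lapply(1:3, function(i) matrix(runif(24, 0, 20), ncol = 3)))
  tr <- diag(4); tr[1:3, 4] <- c(10, 0, 0)
  shifted <- transform_streamlines(b, tr)
  expect_equal(shifted$streamlines[[1]][, 1], b$streamlines[[1]][, 1] + 10)
  expect_equal(shifted$streamlines[[2]][, 2:3], b$streamlines[[2]][, 2:3])

  ident <- transform_streamlines(b, diag(4))
  expect_equal(ident$streamlines, b$streamlines)

  a1 <- diag(4); a1[1:3, 1:3] <- diag(c(2, 1, 0.5)); a1[1:3, 4] <- c(1, 2, 3)
  a2 <- diag(4); a2[1:3, 1:3] <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3); a2[1:3, 4] <- c(-4, 0, 2)
  seq_applied <- transform_streamlines(transform_streamlines(b, a1), a2)
  composed <- transform_streamlines(b, a2 %*% a1)
  expect_equal(seq_applied$streamlines, composed$streamlines, tolerance = 1e-9)

  fwd_back <- transform_streamlines(transform_streamlines(b, a1), solve(a1))
  expect_equal(fwd_back$streamlines, b$streamlines, tolerance = 1e-6)

  sing <- diag(4); sing[1, 1] <- 0
  expect_error(transform_streamlines(b, sing), "singular")
})
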