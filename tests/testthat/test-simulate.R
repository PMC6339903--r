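test_that("population ICC of a spec is the variance ratio", {
  expect_equal(true_icc(metric_sim_spec(sigma_b = 1, sigma_s = 0, sigma_e = 0)), 1.0)
  expect_equal(true_icc(metric_sim_spec(sigma_b = 0, sigma_s = 1, sigma_e = 1)), 0.0)
  expect_equal(true_icc(metric_sim_spec(sigma_b = 2, sigma_s = 1, sigma_e = 1)), 4 / 6)
  expect_equal(true_icc(metric_sim_spec(sigma_b = 3, sigma_s = 0, sigma_e = 1)), 0.9)
  expect_error(true_icc(metric_sim_spec(sigma_b = 0, sigma_s = 0, sigma_e = 0)),
               "undefined")
  expect_error(metric_sim_spec(sigma_b = -1), "non-negative")
  expect_error(metric_sim_spec(n_subjects = 2), "at least 3")

  spec <- metric_spec_from_icc(0.85, total_sd = 2)
  expect_equal(true_icc(spec), 0.85)
  expect_equal(spec$sigma_b^2 + spec$sigma_s^2 + spec$sigma_e^2, 4)
})

test_that("metric simulation is reproducible and respects degenerate SDs", {
  spec <- metric_sim_spec(n_subjects = 10, mu = 5, sigma_b = 2, sigma_s = 0,
                          sigma_e = 0, seed = 99)
  t1 <- simulate_metric_table(spec)
  t2 <- simulate_metric_table(spec)
  expect_identical(t1$values, t2$values)
  # no within-subject variance: sessions identical, ICC exactly 1
  expect_equal(t1$values[, 1], t1$values[, 2])
  expect_equal(as.numeric(icc_a1(t1)), 1.0)

  t3 <- simulate_metric_table(metric_sim_spec(seed = 100))
  expect_false(identical(t3$values, t1$values))
})

test_that("subject-mean variance matches the closed form at large n", {
  spec <- metric_sim_spec(n_subjects = 10000, mu = 3, sigma_b = 1.5,
                          sigma_s = 0.4, sigma_e = 0.8, seed = 17)
  t <- simulate_metric_table(spec)
  v <- var(rowMeans(t$values))
  expected <- spec$sigma_b^2 + spec$sigma_e^2 / 2
  expect_lt(abs(v - expected) / expected, 0.05)
})

test_that("ICC estimator recovers the generating variance ratio", {
  grid <- c(0.5, 0.9)
  for (target in grid) {
    ests <- vapply(1:200, function(r) {
      spec <- metric_spec_from_icc(target, n_subjects = 18,
                                   seed = derive_seed(2024L, "rec", target, r))
      as.numeric(icc_a1(simulate_metric_table(spec)))
    }, numeric(1))
    expect_lt(abs(mean(ests) - target), 0.05)
  }
})

test_that("bundle pairs honour counts, seeds and the session shift", {
  spec <- bundle_sim_spec(default_centerline("UF_L"), n_streamlines = 50,
                          session_shift = 0, seed = 31)
  pair <- simulate_bundle_pair(spec, independent_sessions = FALSE)
  expect_equal(n_streamlines(pair$session1), 50)
  expect_equal(n_streamlines(pair$session2), 50)
  # same sub-seed and zero shift: sessions coincide, overlap is perfect
  expect_identical(pair$session1$streamlines, pair$session2$streamlines)
  aff <- grid_affine(spec)
  w1 <- density_map(pair$session1, spec$grid_shape, aff)
  w2 <- density_map(pair$session2, spec$grid_shape, aff)
  expect_equal(wdsc(w1, w2)$wdsc, 1.0)

  # independent sessions differ
  pair2 <- simulate_bundle_pair(spec)
  expect_false(identical(pair2$session1$streamlines, pair2$session2$streamlines))
  expect_gt(sum(density_map(pair2$session2, spec$grid_shape, aff)$data), 0)

  # increasing shift strictly degrades overlap (shared sub-seed isolates
  # the displacement effect)
  vals <- vapply(c(0, 1, 2, 4), function(sh) {
    sp <- bundle_sim_spec(default_centerline("UF_L"), n_streamlines = 30,
                          session_shift = sh, seed = 31)
    pr <- simulate_bundle_pair(sp, independent_sessions = FALSE)
    wdsc(density_map(pr$session1, sp$grid_shape, aff),
         density_map(pr$session2, sp$grid_shape, aff))$wdsc
  }, numeric(1))
  expect_equal(vals[1], 1.0)
  expect_true(all(diff(vals) < 0))

  # a shift pushing the centerline out of the grid is refused
  expect_error(
    simulate_bundle_pair(bundle_sim_spec(default_centerline("UF_L"),
                                         session_shift = 50, seed = 1)),
    "exits the grid")
})

test_that("cohort generation is deterministic and honours missingness", {
  root1 <- tempfile(); root2 <- tempfile()
  spec <- cohort_sim_spec(n_subjects = 5, seed = 123)
  simulate_cohort(spec, root1, write_bundles = FALSE)
  simulate_cohort(spec, root2, write_bundles = FALSE)
  expect_identical(readLines(file.path(root1, "metrics.csv")),
                   readLines(file.path(root2, "metrics.csv")))

  df <- read.csv(file.path(root1, "metrics.csv"))
  # 7 metrics x 8 bundles x 2 sessions per subject, minus the missing UF_R
  expect_equal(nrow(df), 5 * 2 * 8 * 7 - 2 * 7)
  expect_equal(sort(unique(df$metric)),
               sort(c("FA", "MD", "AD", "RD", "NuFO", "volume", "MLS")))
  uf <- df[df$bundle == "UF_R", ]
  expect_false("sub-05" %in% uf$subject)
  tabs <- read_metric_table(file.path(root1, "metrics.csv"))
  expect_equal(length(tabs[["UF_R|FA"]]$complete_subjects), 4)
})
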