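test_that("two-way mean squares match hand-computed cases", {
  t <- metric_table(rbind(c(1, 2), c(3, 4), c(5, 6), c(7, 8)))
  ms <- anova_mean_squares(t)
  expect_equal(ms$msr, 40 / 3)
  expect_equal(ms$msc, 2)
  expect_equal(ms$mse, 0)

  # identical columns: no session, no interaction variance
  t2 <- metric_table(cbind(c(1, 5, 9), c(1, 5, 9)))
  ms2 <- anova_mean_squares(t2)
  expect_equal(ms2$msc, 0)
  expect_equal(ms2$mse, 0)

  expect_error(anova_mean_squares(metric_table(rbind(c(1, 2), c(3, 4)))),
               "at least 3")
})

test_that("mean squares agree with independent ANOVA oracles", {
  set.seed(61)
  for (i in 1:20) {
    v <- matrix(rnorm(20, 5, 2), 10, 2)
    ms <- anova_mean_squares(metric_table(v))
    ref <- oracle_anova(v)
    expect_equal(ms$msr, ref$msr, tolerance = 1e-10)
    expect_equal(ms$msc, ref$msc, tolerance = 1e-10)
    expect_equal(ms$mse, ref$mse, tolerance = 1e-10)

    # full two-way ANOVA via stats::aov as a second, independent route
    df <- data.frame(y = c(v), subj = factor(rep(1:10, 2)),
                     sess = factor(rep(1:2, each = 10)))
    tab <- summary(stats::aov(y ~ subj + sess, data = df))[[1]]
    expect_equal(ms$msr, tab["subj", "Mean Sq"], tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(ms$msc, tab["sess", "Mean Sq"], tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(ms$mse, tab["Residuals", "Mean Sq"], tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("ICC(A,1) evaluates the absolute-agreement formula", {
  t <- metric_table(rbind(c(1, 2), c(3, 4), c(5, 6), c(7, 8)))
  expect_equal(as.numeric(icc_a1(t)), 40 / 43)

  # duplicated sessions with subject spread: perfect agreement
  t2 <- metric_table(cbind(c(1, 5, 9, 2), c(1, 5, 9, 2)))
  expect_equal(as.numeric(icc_a1(t2)), 1.0)
  expect_warning(ci <- icc_confidence_interval(t2), "degenerate")
  expect_equal(ci, c(1, 1))

  expect_error(icc_a1(metric_table(matrix(3, 4, 2))), "undefined")
})

test_that("ICC is invariant to affine rescaling and column swap", {
  set.seed(62)
  v <- matrix(rnorm(36, 10, 3), 18, 2)
  t <- metric_table(v)
  base <- as.numeric(icc_a1(t))
  expect_equal(as.numeric(icc_a1(metric_table(v + 100))), base, tolerance = 1e-12)
  expect_equal(as.numeric(icc_a1(metric_table(v * -2.5))), base, tolerance = 1e-12)

  swapped <- metric_table(v[, 2:1])
  expect_equal(as.numeric(icc_a1(swapped)), base, tolerance = 1e-12)
  expect_equal(icc_confidence_interval(swapped), icc_confidence_interval(t),
               tolerance = 1e-12)
  ba <- bland_altman(t); bs <- bland_altman(swapped)
  expect_equal(bs$mean_diff, -ba$mean_diff)
  expect_equal(bs$sd_diff, ba$sd_diff)
})

test_that("estimate, CI and p match the reference implementation", {
  set.seed(63)
  tables <- lapply(1:25, function(i) {
    n <- sample(4:25, 1)
    sb <- runif(1, 0.2, 3)
    matrix(rnorm(n, 0, sb), n, 2) + matrix(rnorm(2 * n), n, 2)
  })
  ref <- reference_icc(tables)
  for (i in seq_along(tables)) {
    t <- metric_table(tables[[i]])
    expect_equal(as.numeric(icc_a1(t)), ref$icc[i], tolerance = 1e-8)
    expect_equal(icc_significance(t), ref$pval[i], tolerance = 1e-8)
    ci <- icc_confidence_interval(t)
    expect_equal(ci[1], ref$ci_low[i], tolerance = 1e-6)
    expect_equal(ci[2], ref$ci_high[i], tolerance = 1e-6)
    expect_lte(ci[1], as.numeric(icc_a1(t)))
    expect_gte(ci[2], as.numeric(icc_a1(t)))
  }
})

test_that("significance detects overwhelming between-subject variance", {
  set.seed(64)
  s1 <- seq(1, 18)
  t <- metric_table(cbind(s1, s1 + rnorm(18, 0, 1e-6)))
  expect_lt(icc_significance(t), 1e-6)

  t0 <- metric_table(rbind(c(1, 2), c(3, 4), c(5, 6), c(7, 8)))
  expect_warning(p <- icc_significance(t0), "degenerate")
  expect_equal(p, 0)
})

test_that("reliability categories follow the published bins", {
  expect_equal(classify_icc(0.95), "excellent")
  expect_equal(classify_icc(0.75), "excellent")
  expect_equal(classify_icc(0.741), "good")
  expect_equal(classify_icc(0.60), "good")
  expect_equal(classify_icc(0.41), "fair")
  expect_equal(classify_icc(0.58), "fair")
  expect_equal(classify_icc(0.39), "poor")
  expect_equal(classify_icc(-0.3), "poor")
  expect_error(classify_icc(1.2), "exceed 1")
})

test_that("Bland-Altman summaries match hand arithmetic", {
  t <- metric_table(rbind(c(1, 2), c(2, 2), c(3, 5)))
  ba <- bland_altman(t)
  expect_equal(ba$mean_diff, -1)
  expect_equal(ba$sd_diff, 1)
  expect_equal(ba$loa_low, -3)
  expect_equal(ba$loa_high, 1)
  expect_equal(ba$fraction_within, 1.0)
  expect_equal(ba$n_outside, 0L)
  expect_equal(ba$pair_means, c(1.5, 2, 4), ignore_attr = TRUE)
  expect_equal(ba$pair_diffs, c(-1, 0, -2), ignore_attr = TRUE)

  ident <- bland_altman(metric_table(cbind(c(1, 4, 6), c(1, 4, 6))))
  expect_equal(ident$mean_diff, 0)
  expect_equal(ident$sd_diff, 0)
  expect_equal(ident$fraction_within, 1.0)

  expect_error(bland_altman(metric_table(matrix(1:9, 3, 3))), "2 sessions")
})

test_that("pairwise-complete handling drops subjects missing a session", {
  v <- matrix(rnorm(36, 5), 18, 2)
  v[4, 2] <- NA
  t <- metric_table(v)
  expect_equal(t$n, 18)
  expect_equal(length(t$complete_subjects), 17)
  expect_equal(attr(icc_a1(t), "ms")$n, 17)
  expect_equal(bland_altman(t)$n, 17)
})
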