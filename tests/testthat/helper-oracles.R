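# Independent oracles used by the tests. Each reimplements the checked
# quantity with deliberately plain code (scalar loops, no shared
# helpers from the package internals beyond exported constructors).

# Brute-force streamline density: walk each polyline segment by
# segment, emit sample points at the endpoints and at the midpoints of
# ceiling(L / step) equal arc-length subdivisions, map each to its
# 0-based voxel by explicit inverse-affine arithmetic, deduplicate per
# streamline, count.
oracle_density <- function(bundle, shape, affine = diag(4), step = 0.01) {
  inv <- solve(affine)
  counts <- array(0, dim = shape)
  for (s in bundle$streamlines) {
    seg_len <- numeric(nrow(s) - 1L)
    for (i in seq_len(nrow(s) - 1L)) {
      seg_len[i] <- sqrt(sum((s[i + 1L, ] - s[i, ])^2))
    }
    total <- sum(seg_len)
    m <- max(1, ceiling(total / step))
    at <- c(0, (seq_len(m) - 0.5) * total / m, total)
    cum <- c(0, cumsum(seg_len))
    seen <- character(0)
    for (a in at) {
      i <- findInterval(a, cum, rightmost.closed = TRUE)
      i <- min(max(i, 1L), nrow(s) - 1L)
      frac <- if (seg_len[i] > 0) (a - cum[i]) / seg_len[i] else 0
      p <- s[i, ] + frac * (s[i + 1L, ] - s[i, ])
      hom <- inv %*% c(p, 1)
      v <- floor(hom[1:3])
      if (any(v < 0) || any(v >= shape)) next
      key <- paste(v, collapse = ",")
      if (!(key %in% seen)) {
        seen <- c(seen, key)
        counts[v[1] + 1L, v[2] + 1L, v[3] + 1L] <-
          counts[v[1] + 1L, v[2] + 1L, v[3] + 1L] + 1
      }
    }
  }
  counts
}

# Hand two-way crossed ANOVA sums of squares, loop-coded.
oracle_anova <- function(v) {
  n <- nrow(v); k <- ncol(v)
  grand <- sum(v) / (n * k)
  ssr <- 0
  for (i in seq_len(n)) ssr <- ssr + k * (sum(v[i, ]) / k - grand)^2
  ssc <- 0
  for (j in seq_len(k)) ssc <- ssc + n * (sum(v[, j]) / n - grand)^2
  sst <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) sst <- sst + (v[i, j] - grand)^2
  sse <- max(sst - ssr - ssc, 0)
  list(msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)))
}

# ICC(A,1) from the hand ANOVA, evaluated directly from the printed
# formula.
oracle_icc <- function(v) {
  n <- nrow(v); k <- ncol(v)
  ms <- oracle_anova(v)
  (ms$msr - ms$mse) /
    (ms$msr + (k - 1) * ms$mse + (k / n) * (ms$msc - ms$mse))
}

# Reference ICC implementation: pingouin's absolute-agreement
# single-measure estimate and p-value, plus a scipy-based confidence
# interval coded independently in Python. Tables are batched through a
# single python call. `tables` is a list of n x 2 matrices; returns a
# data frame with one row per table.
reference_icc <- function(tables) {
  input <- tempfile(fileext = ".csv")
  output <- tempfile(fileext = ".csv")
  rows <- do.call(rbind, lapply(seq_along(tables), function(i) {
    v <- tables[[i]]
    data.frame(table = i, subj = rep(seq_len(nrow(v)), 2),
               sess = rep(1:2, each = nrow(v)), y = c(v))
  }))
  write.csv(rows, input, row.names = FALSE)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, pandas as pd, numpy as np",
    "import pingouin as pg",
    "from scipy.stats import f as fdist",
    "df = pd.read_csv(sys.argv[1])",
    "out = []",
    "for tid, g in df.groupby('table'):",
    "    res = pg.intraclass_corr(g, targets='subj', raters='sess', ratings='y')",
    "    row = res[res['Type'] == 'ICC(A,1)'].iloc[0]",
    "    wide = g.pivot(index='subj', columns='sess', values='y').values",
    "    n, k = wide.shape",
    "    grand = wide.mean()",
    "    msr = k * ((wide.mean(axis=1) - grand) ** 2).sum() / (n - 1)",
    "    msc = n * ((wide.mean(axis=0) - grand) ** 2).sum() / (k - 1)",
    "    sse = ((wide - grand) ** 2).sum() - (n-1)*msr - (k-1)*msc",
    "    mse = max(sse, 0.0) / ((n - 1) * (k - 1))",
    "    est = (msr - mse) / (msr + (k-1)*mse + k/n*(msc - mse))",
    "    a = k * est / (n * (1 - est))",
    "    b = 1 + k * est * (n - 1) / (n * (1 - est))",
    "    v = (a*msc + b*mse)**2 / ((a*msc)**2/(k-1) + (b*mse)**2/((n-1)*(k-1)))",
    "    fl = fdist.ppf(0.975, n - 1, v)",
    "    fu = fdist.ppf(0.975, v, n - 1)",
    "    lo = n*(msr - fl*mse) / (fl*(k*msc + (k*n-k-n)*mse) + n*msr)",
    "    hi = n*(fu*msr - mse) / (k*msc + (k*n-k-n)*mse + n*fu*msr)",
    "    out.append((tid, row['ICC'], row['pval'], lo, hi))",
    "pd.DataFrame(out, columns=['table','icc','pval','ci_low','ci_high']).to_csv(sys.argv[2], index=False)"
  ), script)
  status <- system2("python", c(script, input, output),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L || !file.exists(output)) {
    stop("python reference ICC oracle failed")
  }
  read.csv(output)
}

# random density map on a small grid with given support density
random_map <- function(shape = c(6, 6, 6), p = 0.3, max_w = 5) {
  d <- array(0, dim = shape)
  on <- runif(prod(shape)) < p
  d[on] <- sample.int(max_w, sum(on), replace = TRUE)
  as_density_map(d)
}

# random smooth-ish polyline inside [lo, hi]^3
random_polyline <- function(n_pts = 10, lo = 1, hi = 9) {
  cbind(runif(n_pts, lo, hi), runif(n_pts, lo, hi), runif(n_pts, lo, hi))
}
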