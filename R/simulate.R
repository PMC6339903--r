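# Synthetic paired-session cohort with known ground truth.
#
# Metric tables follow the two-way variance-components model the ICC
# analysis assumes:
#
#   y_ij = mu + b_i + s_j + e_ij,
#   b_i ~ N(0, sigma_b^2)   between-subject effects
#   s_j ~ N(0, sigma_s^2)   session effects (random, so the
#                           absolute-agreement population ICC has the
#                           closed form used by true_icc)
#   e_ij ~ N(0, sigma_e^2)  residual
#
# Bundles are tubes of streamlines around a parametric centerline, with
# smooth per-streamline lateral offsets; session 2 is an independent
# draw around a centerline displaced by a controllable shift, which
# dials the spatial overlap between sessions.

DEFAULT_BUNDLES <- c("AF_L", "AF_R", "ILF_L", "ILF_R",
                     "IFOF_L", "IFOF_R", "UF_L", "UF_R")
DEFAULT_METRICS <- c("FA", "MD", "AD", "RD", "NuFO", "volume", "MLS")

#' Specification for one simulated metric table
#'
#' @param n_subjects Number of subjects (>= 3; default 18).
#' @param mu Grand mean of the measure.
#' @param sigma_b Between-subject SD.
#' @param sigma_s Session-effect SD.
#' @param sigma_e Residual SD.
#' @param seed RNG seed for [simulate_metric_table()].
#' @return An object of class `metric_sim_spec`.
#' @export
metric_sim_spec <- function(n_subjects = 18L, mu = 0, sigma_b = 1,
                            sigma_s = 0, sigma_e = 0.5, seed = 1L) {
  if (n_subjects < 3L) stop("n_subjects must be at least 3")
  if (any(c(sigma_b, sigma_s, sigma_e) < 0)) stop("SDs must be non-negative")
  structure(
    list(n_subjects = as.integer(n_subjects), k_sessions = 2L, mu = mu,
         sigma_b = sigma_b, sigma_s = sigma_s, sigma_e = sigma_e,
         seed = as.integer(seed)),
    class = "metric_sim_spec"
  )
}

#' Metric simulation spec from a target population ICC
#'
#' Splits a total variance into between-subject and within-subject
#' parts so that the population ICC equals `icc`; the session effect
#' takes `session_share` of the within-subject variance.
#'
#' @param icc Target population ICC in `[0, 1)`.
#' @param mu Grand mean.
#' @param total_sd Total SD `sqrt(sigma_b^2 + sigma_s^2 + sigma_e^2)`.
#' @param session_share Share of within-subject variance assigned to
#'   the session effect (default 0.1).
#' @inheritParams metric_sim_spec
#' @return A `metric_sim_spec` with `true_icc(spec) == icc`.
#' @export
metric_spec_from_icc <- function(icc, mu = 0, total_sd = 1, n_subjects = 18L,
                                 session_share = 0.1, seed = 1L) {
  if (icc < 0 || icc >= 1) stop("target icc must be in [0, 1)")
  tot <- total_sd^2
  within <- (1 - icc) * tot
  metric_sim_spec(
    n_subjects = n_subjects, mu = mu,
    sigma_b = sqrt(icc * tot),
    sigma_s = sqrt(session_share * within),
    sigma_e = sqrt((1 - session_share) * within),
    seed = seed
  )
}

#' Population ICC of a metric simulation spec
#'
#' The ratio of between-subject variance to total variance:
#' `sigma_b^2 / (sigma_b^2 + sigma_s^2 + sigma_e^2)`.
#'
#' @param spec A `metric_sim_spec`.
#' @return Value in `[0, 1]`.
#' @export
true_icc <- function(spec) {
  stopifnot(inherits(spec, "metric_sim_spec"))
  tot <- spec$sigma_b^2 + spec$sigma_s^2 + spec$sigma_e^2
  if (tot == 0) stop("all SDs are zero: population ICC undefined")
  spec$sigma_b^2 / tot
}

#' Simulate one paired-session metric table
#'
#' Draws from the two-way model `y_ij = mu + b_i + s_j + e_ij`.
#' Reproducible given the spec's seed.
#'
#' @param spec A `metric_sim_spec`.
#' @param bundle,metric Labels for the resulting table.
#' @return A `metric_table` of dimension `n_subjects` x 2.
#' @export
simulate_metric_table <- function(spec, bundle = "", metric = "") {
  stopifnot(inherits(spec, "metric_sim_spec"))
  n <- spec$n_subjects
  k <- spec$k_sessions
  v <- with_seed(spec$seed, {
    b <- rnorm(n, 0, spec$sigma_b)
    s <- rnorm(k, 0, spec$sigma_s)
    e <- matrix(rnorm(n * k, 0, spec$sigma_e), n, k)
    spec$mu + outer(b, s, "+") + e
  })
  metric_table(v, bundle = bundle, metric = metric,
               subjects = sprintf("sub-%02d", seq_len(n)),
               sessions = c("ses-1", "ses-2"))
}

#' Specification for one simulated bundle pair
#'
#' @param centerline m x 3 matrix of control points of the bundle's
#'   centerline, in world mm inside the grid.
#' @param n_streamlines Streamlines per session (default 30).
#' @param streamline_jitter_sd SD (mm) of the smooth lateral offsets
#'   giving the tube its width (default 1).
#' @param session_shift Displacement (mm) of the session-2 centerline,
#'   emulating imperfect between-session reconstruction (default 0.6).
#' @param shift_dir Length-3 direction of the shift (normalised
#'   internally; default +x).
#' @param grid_shape Length-3 grid dimensions (default 40^3).
#' @param voxel_size Isotropic voxel size in mm (default 1).
#' @param seed RNG seed.
#' @return An object of class `bundle_sim_spec`.
#' @export
bundle_sim_spec <- function(centerline, n_streamlines = 30L,
                            streamline_jitter_sd = 1.0, session_shift = 0.6,
                            shift_dir = c(1, 0, 0), grid_shape = c(40L, 40L, 40L),
                            voxel_size = 1.0, seed = 1L) {
  centerline <- as_points(centerline)
  if (n_streamlines < 1L) stop("n_streamlines must be at least 1")
  if (voxel_size <= 0) stop("voxel_size must be positive")
  if (session_shift < 0) stop("session_shift must be non-negative")
  structure(
    list(centerline = centerline, n_streamlines = as.integer(n_streamlines),
         streamline_jitter_sd = streamline_jitter_sd,
         session_shift = session_shift,
         shift_dir = shift_dir / sqrt(sum(shift_dir^2)),
         grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
         seed = as.integer(seed)),
    class = "bundle_sim_spec"
  )
}

#' Voxel-to-world affine of a bundle simulation grid
#' @param spec A `bundle_sim_spec`.
#' @return 4x4 affine (isotropic scaling, origin at the grid corner).
#' @export
grid_affine <- function(spec) {
  a <- diag(c(rep(spec$voxel_size, 3L), 1))
  a
}

# one session's tube: n smooth noisy offsets of the centerline
simulate_tube <- function(centerline, n_streamlines, jitter_sd, seed) {
  base <- resample_polyline(centerline, 1.0)
  u <- seq(0, 1, length.out = nrow(base))
  with_seed(seed, {
    lapply(seq_len(n_streamlines), function(i) {
      const <- rnorm(3L, 0, jitter_sd / sqrt(2))
      bow <- rnorm(3L, 0, jitter_sd / sqrt(2))
      off <- cbind(
        const[1] + bow[1] * sin(pi * u),
        const[2] + bow[2] * sin(pi * u),
        const[3] + bow[3] * sin(pi * u)
      )
      base + off
    })
  })
}

#' Simulate a paired-session bundle
#'
#' Session 1 is a tube of noisy streamlines around the centerline;
#' session 2 is the same construction from an independent sub-seed
#' around the centerline displaced by `session_shift` (set
#' `independent_sessions = FALSE` to reuse the session-1 sub-seed, in
#' which case a zero shift reproduces session 1 exactly).
#'
#' @param spec A `bundle_sim_spec`.
#' @param independent_sessions Draw session 2 from its own sub-seed
#'   (default `TRUE`).
#' @param name Bundle label.
#' @return List with elements `session1` and `session2`, both
#'   `streamline_bundle`s lying inside the grid.
#' @export
simulate_bundle_pair <- function(spec, independent_sessions = TRUE, name = "") {
  stopifnot(inherits(spec, "bundle_sim_spec"))
  extent <- spec$grid_shape * spec$voxel_size
  margin <- 3 * spec$streamline_jitter_sd
  c2 <- spec$centerline +
    matrix(spec$session_shift * spec$shift_dir, nrow(spec$centerline), 3L,
           byrow = TRUE)
  for (cl in list(spec$centerline, c2)) {
    if (any(cl < margin) || any(sweep(cl, 2L, extent - margin) > 0)) {
      stop("centerline (after shift) exits the grid or its safety margin")
    }
  }
  s1 <- derive_seed(spec$seed, "session1")
  s2 <- if (independent_sessions) derive_seed(spec$seed, "session2") else s1
  list(
    session1 = streamline_bundle(
      simulate_tube(spec$centerline, spec$n_streamlines,
                    spec$streamline_jitter_sd, s1),
      name = name, space = "time1"),
    session2 = streamline_bundle(
      simulate_tube(c2, spec$n_streamlines, spec$streamline_jitter_sd, s2),
      name = name, space = "time2")
  )
}

#' Default centerline curve for a named bundle
#'
#' Distinct curved centerlines for the eight default bundles, inside a
#' 40 mm isotropic grid. These are coarse geometric stand-ins (arcs
#' with per-bundle phase and laterality), not anatomical trajectories.
#'
#' @param bundle Bundle name (e.g. "AF_L"); unknown names hash to one
#'   of the eight shapes.
#' @param extent Grid extent in mm (default 40).
#' @return A 25 x 3 matrix of centerline points.
#' @export
default_centerline <- function(bundle, extent = 40) {
  i <- match(bundle, DEFAULT_BUNDLES)
  if (is.na(i)) i <- 1L + (sum(utf8ToInt(bundle)) %% 8L)
  u <- seq(0, 1, length.out = 25L)
  c0 <- extent / 2
  amp <- extent / 5
  phase <- (i - 1) * pi / 4
  lr <- if (grepl("_R$", bundle)) 1 else -1
  cbind(
    c0 + lr * amp * 0.55 + amp * 0.3 * sin(2 * pi * u + phase) * lr,
    c0 + amp * (2 * u - 1) * 0.9,
    c0 + amp * 0.8 * sin(pi * u + phase / 2) * cos(phase)
  )
}

#' Specification of a full synthetic paired-session cohort
#'
#' Defaults emulate the study conditions the analyses assume: 18
#' subjects x 2 sessions x 8 bundles (AF, ILF, IFOF, UF left/right) x 7
#' metrics (FA, MD, AD, RD, NuFO, volume, MLS), with the right UF
#' absent for one subject in both sessions.
#'
#' @param n_subjects Number of subjects (default 18).
#' @param bundles Bundle names.
#' @param metrics Metric names; defaults carry plausible tractometry
#'   scales (FA ~0.45, MD ~0.80 um^2/ms, ...).
#' @param true_icc Target population ICC shared by all metric tables
#'   (default 0.85).
#' @param session_share Share of within-subject variance due to the
#'   session effect (default 0.1).
#' @param session_shift Bundle displacement between sessions in mm
#'   (default 0.6).
#' @param n_streamlines Streamlines per bundle per session.
#' @param missing List of `list(subject =, bundle =)` entries absent in
#'   both sessions; default: last subject's `UF_R`.
#' @param seed Master seed; all sub-seeds are derived from it by
#'   hashing, not call order.
#' @return An object of class `cohort_sim_spec`.
#' @export
cohort_sim_spec <- function(n_subjects = 18L, bundles = DEFAULT_BUNDLES,
                            metrics = DEFAULT_METRICS, true_icc = 0.85,
                            session_share = 0.1, session_shift = 0.6,
                            n_streamlines = 30L, missing = NULL, seed = 1L) {
  subjects <- sprintf("sub-%02d", seq_len(n_subjects))
  if (is.null(missing)) {
    missing <- if ("UF_R" %in% bundles) {
      list(list(subject = subjects[n_subjects], bundle = "UF_R"))
    } else list()
  }
  scales <- list(
    FA = c(mu = 0.45, sd = 0.035), MD = c(mu = 0.80, sd = 0.05),
    AD = c(mu = 1.20, sd = 0.07), RD = c(mu = 0.60, sd = 0.05),
    NuFO = c(mu = 1.60, sd = 0.12), volume = c(mu = 9000, sd = 900),
    MLS = c(mu = 90, sd = 7)
  )
  metric_specs <- list()
  for (b in bundles) {
    for (m in metrics) {
      sc <- if (m %in% names(scales)) scales[[m]] else c(mu = 1, sd = 0.1)
      metric_specs[[paste(b, m, sep = "|")]] <- metric_spec_from_icc(
        icc = true_icc, mu = sc[["mu"]], total_sd = sc[["sd"]],
        n_subjects = n_subjects, session_share = session_share,
        seed = derive_seed(seed, "metric", b, m)
      )
    }
  }
  bundle_specs <- list()
  for (b in bundles) {
    bundle_specs[[b]] <- bundle_sim_spec(
      centerline = default_centerline(b),
      n_streamlines = n_streamlines,
      session_shift = session_shift,
      seed = derive_seed(seed, "bundle", b)
    )
  }
  structure(
    list(subjects = subjects, bundles = bundles, metrics = metrics,
         metric_specs = metric_specs, bundle_specs = bundle_specs,
         missing = missing, seed = as.integer(seed)),
    class = "cohort_sim_spec"
  )
}

is_missing_entry <- function(spec, subject, bundle) {
  for (m in spec$missing) {
    if (identical(m$subject, subject) && identical(m$bundle, bundle)) return(TRUE)
  }
  FALSE
}

#' Write a synthetic cohort to disk in the pipeline's directory layout
#'
#' Produces `<root>/<subject>/<session>/<bundle>.tck` streamline files
#' and `<bundle>.nii.gz` density maps, per-subject
#' `affine_t1_to_t2.txt` (identity by default), `<root>/metrics.csv`
#' and `<root>/cohort.yaml` describing the layout and grids. Output is
#' deterministic given the master seed: per-subject/bundle/metric
#' sub-seeds are derived by hashing, so regeneration is byte-identical.
#'
#' @param spec A `cohort_sim_spec`.
#' @param out_dir Output directory (created if needed).
#' @param write_bundles Write streamline/density files (default `TRUE`;
#'   set to `FALSE` for metric-only cohorts, which is much faster).
#' @return `out_dir`, invisibly.
#' @export
simulate_cohort <- function(spec, out_dir, write_bundles = TRUE) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sessions <- c("ses-1", "ses-2")

  # metrics.csv, fixed row order: bundle, metric, subject, session
  rows <- list()
  for (b in spec$bundles) {
    for (m in spec$metrics) {
      t <- simulate_metric_table(spec$metric_specs[[paste(b, m, sep = "|")]],
                                 bundle = b, metric = m)
      for (i in seq_len(t$n)) {
        subject <- rownames(t$values)[i]
        if (is_missing_entry(spec, subject, b)) next
        for (j in 1:2) {
          rows[[length(rows) + 1L]] <- data.frame(
            subject = subject, session = sessions[j], bundle = b, metric = m,
            value = sprintf("%.12g", t$values[i, j]),
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  metrics_df <- do.call(rbind, rows)
  write.csv(metrics_df, file.path(out_dir, "metrics.csv"),
            row.names = FALSE, quote = FALSE)

  grids <- list()
  for (b in spec$bundles) {
    bs <- spec$bundle_specs[[b]]
    grids[[b]] <- list(shape = as.integer(bs$grid_shape),
                       voxel_size = bs$voxel_size)
  }
  yaml::write_yaml(
    list(subjects = spec$subjects, sessions = sessions,
         bundles = spec$bundles, metrics = spec$metrics,
         seed = spec$seed, grids = grids),
    file.path(out_dir, "cohort.yaml")
  )

  for (subject in spec$subjects) {
    sdir <- file.path(out_dir, subject)
    dir.create(sdir, showWarnings = FALSE)
    write_affine(diag(4), file.path(sdir, "affine_t1_to_t2.txt"))
    if (!write_bundles) next
    for (ses in sessions) dir.create(file.path(sdir, ses), showWarnings = FALSE)
    for (b in spec$bundles) {
      if (is_missing_entry(spec, subject, b)) next
      bs <- spec$bundle_specs[[b]]
      pair_spec <- bs
      pair_spec$seed <- derive_seed(spec$seed, "pair", subject, b)
      pair <- simulate_bundle_pair(pair_spec, name = b)
      aff <- grid_affine(bs)
      for (j in 1:2) {
        bnd <- pair[[j]]
        write_streamlines(bnd, file.path(sdir, sessions[j], paste0(b, ".tck")))
        dm <- density_map(bnd, bs$grid_shape, aff)
        write_density_map(dm, file.path(sdir, sessions[j], paste0(b, ".nii.gz")))
      }
    }
  }
  invisible(out_dir)
}
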