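# Orchestration: run the overlap and agreement analyses over a cohort
# directory and emit a reliability report shaped like the classic
# per-bundle x per-metric reliability tables (one wDSC column plus
# ICC [95% CI] per metric).

#' Per-bundle spatial overlap analysis of a cohort
#'
#' For every subject with both sessions of a bundle: read the Time-1
#' streamlines, apply the subject's Time-1 to Time-2 affine, rasterize
#' both sessions onto the Time-2 grid, and compute the weighted Dice
#' coefficient. The Time-2 grid is taken from the stored Time-2 density
#' map when present, else from the layout's grid configuration. The
#' stored Time-2 density map, when present, is used directly as the
#' Time-2 weights.
#'
#' @param layout A `cohort_layout`.
#' @param threshold wDSC acceptability threshold (default 0.70).
#' @return List with `per_subject` (data frame: bundle, subject, wdsc,
#'   dsc) and `summary` (per bundle: n_used, n_skipped, mean/median/
#'   min/max wDSC, acceptability category of the mean), plus `skipped`
#'   listing (subject, bundle) pairs without both sessions.
#' @export
run_overlap_analysis <- function(layout, threshold = 0.70) {
  stopifnot(inherits(layout, "cohort_layout"))
  ses <- layout$session_labels
  per <- list()
  skipped <- list()
  for (b in layout$bundle_names) {
    for (subject in layout$subject_ids) {
      p1 <- streamline_path(layout, subject, ses[1], b)
      p2 <- streamline_path(layout, subject, ses[2], b)
      if (is.na(p1) || is.na(p2)) {
        skipped[[length(skipped) + 1L]] <-
          data.frame(subject = subject, bundle = b, stringsAsFactors = FALSE)
        next
      }
      d2_path <- density_path(layout, subject, ses[2], b)
      if (!is.na(d2_path)) {
        wj <- read_density_map(d2_path)
        shape <- dim(wj$data)
        aff <- wj$affine
      } else {
        g <- layout$grids[[b]]
        if (is.null(g)) {
          stop("no Time-2 density map and no grid configured for bundle ", b)
        }
        shape <- as.integer(g$shape)
        aff <- diag(c(rep(g$voxel_size, 3L), 1))
        wj <- density_map(read_streamlines(p2, space = "time2"), shape, aff)
      }
      b1 <- read_streamlines(p1, space = "time1")
      t12 <- read_affine(affine_path(layout, subject))
      wi <- density_map(transform_streamlines(b1, t12), shape, aff)
      ov <- wdsc(wi, wj, threshold = threshold)
      per[[length(per) + 1L]] <- data.frame(
        bundle = b, subject = subject, wdsc = ov$wdsc, dsc = ov$dsc,
        stringsAsFactors = FALSE
      )
    }
  }
  per_subject <- if (length(per)) do.call(rbind, per) else
    data.frame(bundle = character(), subject = character(),
               wdsc = numeric(), dsc = numeric())
  summ <- list()
  for (b in layout$bundle_names) {
    vals <- per_subject$wdsc[per_subject$bundle == b]
    n_skip <- sum(vapply(skipped, function(s) s$bundle == b, logical(1)))
    if (length(vals) == 0L) {
      summ[[b]] <- data.frame(
        bundle = b, n_used = 0L, n_skipped = n_skip, mean_wdsc = NA_real_,
        median_wdsc = NA_real_, min_wdsc = NA_real_, max_wdsc = NA_real_,
        category = "not_analyzable", stringsAsFactors = FALSE
      )
    } else {
      summ[[b]] <- data.frame(
        bundle = b, n_used = length(vals), n_skipped = n_skip,
        mean_wdsc = mean(vals), median_wdsc = median(vals),
        min_wdsc = min(vals), max_wdsc = max(vals),
        category = classify_overlap(mean(vals), threshold),
        stringsAsFactors = FALSE
      )
    }
  }
  list(per_subject = per_subject, summary = do.call(rbind, summ),
       skipped = if (length(skipped)) do.call(rbind, skipped) else NULL)
}

#' Per-(bundle, metric) scalar agreement analysis of a cohort
#'
#' Reads the cohort's metric CSV and computes, for every bundle x
#' metric combination of the layout, the ICC(A,1) estimate with
#' confidence interval, significance and category, and the Bland-Altman
#' summary, on pairwise-complete subjects. Combinations with fewer than
#' 3 complete subjects yield an NA row with a reason code.
#'
#' @param layout A `cohort_layout`.
#' @param alpha Level for ICC confidence intervals.
#' @param loa_multiplier Bland-Altman limits-of-agreement SD multiplier.
#' @return List with `table` (one row per bundle x metric) and `points`
#'   (per-subject Bland-Altman coordinates).
#' @export
run_agreement_analysis <- function(layout, alpha = 0.05, loa_multiplier = 2.0) {
  stopifnot(inherits(layout, "cohort_layout"))
  mp <- metrics_path(layout)
  if (is.na(mp)) stop("cohort has no metrics.csv")
  tables <- read_metric_table(mp, session_levels = layout$session_labels)
  rows <- list()
  pts <- list()
  for (b in layout$bundle_names) {
    for (m in layout$metric_names) {
      key <- paste(b, m, sep = "|")
      t <- tables[[key]]
      na_row <- data.frame(
        bundle = b, metric = m, n_used = NA_integer_, icc = NA_real_,
        ci_low = NA_real_, ci_high = NA_real_, p_value = NA_real_,
        category = NA_character_, mean_diff = NA_real_, sd_diff = NA_real_,
        loa_low = NA_real_, loa_high = NA_real_, fraction_within = NA_real_,
        n_outside = NA_integer_, reason = "", stringsAsFactors = FALSE
      )
      if (is.null(t)) {
        na_row$reason <- "no_data"
        rows[[key]] <- na_row
        next
      }
      if (length(t$complete_subjects) < 3L) {
        na_row$n_used <- length(t$complete_subjects)
        na_row$reason <- "insufficient_subjects"
        rows[[key]] <- na_row
        next
      }
      ic <- icc_report(t, alpha = alpha)
      ba <- bland_altman(t, m = loa_multiplier)
      rows[[key]] <- data.frame(
        bundle = b, metric = m, n_used = ic$n, icc = ic$icc,
        ci_low = ic$ci_low, ci_high = ic$ci_high, p_value = ic$p_value,
        category = ic$category, mean_diff = ba$mean_diff,
        sd_diff = ba$sd_diff, loa_low = ba$loa_low, loa_high = ba$loa_high,
        fraction_within = ba$fraction_within, n_outside = ba$n_outside,
        reason = "", stringsAsFactors = FALSE
      )
      pts[[key]] <- data.frame(
        bundle = b, metric = m,
        subject = names(ba$pair_means) %||% as.character(seq_along(ba$pair_means)),
        pair_mean = unname(ba$pair_means), pair_diff = unname(ba$pair_diffs),
        stringsAsFactors = FALSE
      )
    }
  }
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       points = if (length(pts))
         do.call(rbind, c(pts, list(make.row.names = FALSE))) else NULL)
}

significance_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "***",
                              ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}

#' Assemble and write the reliability report
#'
#' Writes `report.csv` (long form: one row per bundle for the overlap
#' section, one per bundle x metric for the agreement section),
#' `report.md` (a per-bundle table with a wDSC column and ICC [95% CI]
#' per metric) and `blandaltman_points.csv` (per-subject plot
#' coordinates). Ordering is deterministic: bundles then metrics in the
#' layout's fixed list order.
#'
#' @param overlap Result of [run_overlap_analysis()].
#' @param agreement Result of [run_agreement_analysis()].
#' @param out_dir Output directory (created if needed).
#' @param layout Optional `cohort_layout` for provenance (seed, root).
#' @return Object of class `reliability_report` with fields `overlap`,
#'   `agreement`, `status` ("complete" or "partial") and `exit_status`
#'   (0 complete, 2 partial).
#' @export
build_report <- function(overlap, agreement, out_dir, layout = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ag <- agreement$table
  ov <- overlap$summary
  partial <- any(ov$category == "not_analyzable") || any(ag$reason != "")

  long <- rbind(
    data.frame(
      section = "wdsc", bundle = ov$bundle, metric = "",
      n_used = ov$n_used, value = ov$mean_wdsc,
      ci_low = NA_real_, ci_high = NA_real_, p_value = NA_real_,
      category = ov$category,
      extra1 = ov$median_wdsc, extra2 = ov$min_wdsc, extra3 = ov$max_wdsc,
      stringsAsFactors = FALSE
    ),
    data.frame(
      section = "icc", bundle = ag$bundle, metric = ag$metric,
      n_used = ag$n_used, value = ag$icc,
      ci_low = ag$ci_low, ci_high = ag$ci_high, p_value = ag$p_value,
      category = ifelse(is.na(ag$category), "NA", ag$category),
      extra1 = NA_real_, extra2 = NA_real_, extra3 = NA_real_,
      stringsAsFactors = FALSE
    ),
    data.frame(
      section = "bland_altman", bundle = ag$bundle, metric = ag$metric,
      n_used = ag$n_used, value = ag$mean_diff,
      ci_low = ag$loa_low, ci_high = ag$loa_high, p_value = NA_real_,
      category = ifelse(is.na(ag$fraction_within), "NA",
                        ifelse(ag$fraction_within >= 0.95, "good", "check")),
      extra1 = ag$sd_diff, extra2 = ag$fraction_within,
      extra3 = as.numeric(ag$n_outside),
      stringsAsFactors = FALSE
    )
  )
  write.csv(long, file.path(out_dir, "report.csv"), row.names = FALSE)
  if (!is.null(agreement$points)) {
    write.csv(agreement$points, file.path(out_dir, "blandaltman_points.csv"),
              row.names = FALSE)
  }

  md <- c("# Test-retest reliability report", "")
  if (!is.null(layout)) {
    md <- c(md, sprintf("Cohort: %s (%d subjects; seed %s)", layout$root,
                        length(layout$subject_ids),
                        layout$seed %||% "unknown"), "")
  }
  metrics <- unique(ag$metric)
  header <- paste0("| Bundle | n | wDSC | ",
                   paste(metrics, collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", length(metrics) + 3L), collapse = "|"), "|")
  md <- c(md, header, sep)
  for (b in ov$bundle) {
    cells <- vapply(metrics, function(m) {
      r <- ag[ag$bundle == b & ag$metric == m, ]
      if (nrow(r) == 0L || is.na(r$icc)) return("NA")
      sprintf("%.2f%s [%.2f, %.2f]", r$icc, significance_stars(r$p_value),
              r$ci_low, r$ci_high)
    }, character(1))
    o <- ov[ov$bundle == b, ]
    md <- c(md, paste0(
      "| ", b, " | ", o$n_used, " | ",
      if (is.na(o$mean_wdsc)) "NA" else sprintf("%.2f", o$mean_wdsc), " | ",
      paste(cells, collapse = " | "), " |"))
  }
  md <- c(md, "",
          "Stars: *** p < 0.001, ** p < 0.01, * p < 0.05 (ICC F-test vs 0).",
          "wDSC is the across-subject mean weighted Dice coefficient;",
          "acceptability threshold 0.70.")
  writeLines(md, file.path(out_dir, "report.md"))

  structure(
    list(overlap = overlap, agreement = agreement,
         status = if (partial) "partial" else "complete",
         exit_status = if (partial) 2L else 0L,
         out_dir = out_dir),
    class = "reliability_report"
  )
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf("<reliability_report> %s; %d wDSC rows, %d agreement rows -> %s\n",
              x$status, nrow(x$overlap$summary), nrow(x$agreement$table),
              x$out_dir))
  invisible(x)
}

#' Run the full test-retest reliability pipeline on a cohort directory
#'
#' Convenience wrapper: assemble the layout, run the overlap and
#' agreement analyses and write the report.
#'
#' @param cohort_root Cohort directory (layout of [cohort_layout()]).
#' @param out_dir Report output directory.
#' @param wdsc_threshold wDSC acceptability threshold.
#' @param alpha ICC confidence level parameter.
#' @param loa_multiplier Bland-Altman SD multiplier.
#' @param config Optional layout config override.
#' @return A `reliability_report`, invisibly.
#' @export
run_reliability <- function(cohort_root, out_dir, wdsc_threshold = 0.70,
                            alpha = 0.05, loa_multiplier = 2.0, config = NULL) {
  layout <- cohort_layout(cohort_root, config = config)
  message("overlap analysis: ", length(layout$bundle_names), " bundles x ",
          length(layout$subject_ids), " subjects")
  ov <- run_overlap_analysis(layout, threshold = wdsc_threshold)
  if (!is.null(ov$skipped)) {
    message("skipped ", nrow(ov$skipped), " (subject, bundle) pairs without both sessions")
  }
  message("agreement analysis: ", length(layout$bundle_names), " bundles x ",
          length(layout$metric_names), " metrics")
  ag <- run_agreement_analysis(layout, alpha = alpha,
                               loa_multiplier = loa_multiplier)
  invisible(build_report(ov, ag, out_dir, layout = layout))
}
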