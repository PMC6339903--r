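#' Describe a cohort directory as a layout object
#'
#' The expected layout is
#' `<root>/<subject>/<session>/<bundle>.(trk|tck|nii.gz)` with
#' `<root>/metrics.csv` and `<root>/<subject>/affine_t1_to_t2.txt`. If
#' `<root>/cohort.yaml` exists its `subjects`, `sessions`, `bundles`,
#' `metrics` and `grids` entries override discovery; a config list may
#' also be passed directly. Exactly two sessions are required. Assembly
#' is deterministic: the same tree yields the identical layout.
#'
#' @param root Cohort root directory.
#' @param config Optional named list overriding the YAML config.
#' @return An object of class `cohort_layout`.
#' @export
cohort_layout <- function(root, config = NULL) {
  if (!dir.exists(root)) stop("cohort root does not exist: ", root)
  yaml_path <- file.path(root, "cohort.yaml")
  cfg <- if (!is.null(config)) config
         else if (file.exists(yaml_path)) yaml::read_yaml(yaml_path)
         else list()
  subjects <- cfg$subjects %||%
    sort(basename(Filter(dir.exists, list.dirs(root, recursive = FALSE))))
  sessions <- cfg$sessions %||% {
    ses <- unique(unlist(lapply(subjects, function(s) {
      basename(Filter(dir.exists, list.dirs(file.path(root, s), recursive = FALSE)))
    })))
    sort(ses)
  }
  if (length(sessions) != 2L) {
    stop("a cohort must have exactly 2 sessions; found ",
         length(sessions), ": ", paste(sessions, collapse = ", "))
  }
  bundles <- cfg$bundles %||% DEFAULT_BUNDLES
  metrics <- cfg$metrics %||% DEFAULT_METRICS
  structure(
    list(root = root, subject_ids = subjects, session_labels = sessions,
         bundle_names = bundles, metric_names = metrics,
         grids = cfg$grids, seed = cfg$seed),
    class = "cohort_layout"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cohort_layout <- function(x, ...) {
  cat(sprintf("<cohort_layout> %d subjects x sessions (%s) x %d bundles, %d metrics at %s\n",
              length(x$subject_ids), paste(x$session_labels, collapse = ", "),
              length(x$bundle_names), length(x$metric_names), x$root))
  invisible(x)
}

# at most one matching file; absence -> NA (recorded, not fatal)
resolve_one <- function(dir, stem, exts) {
  cands <- file.path(dir, paste0(stem, exts))
  hit <- cands[file.exists(cands)]
  if (length(hit) > 1L) {
    stop("ambiguous files for ", stem, " in ", dir, ": ",
         paste(basename(hit), collapse = ", "))
  }
  if (length(hit) == 0L) NA_character_ else hit
}

#' Resolve the streamline file for (subject, session, bundle)
#' @param layout A `cohort_layout`.
#' @param subject,session,bundle Identifiers.
#' @return File path, or `NA` if absent.
#' @export
streamline_path <- function(layout, subject, session, bundle) {
  resolve_one(file.path(layout$root, subject, session), bundle,
              c(".trk", ".tck"))
}

#' Resolve the density-map file for (subject, session, bundle)
#' @inheritParams streamline_path
#' @return File path, or `NA` if absent.
#' @export
density_path <- function(layout, subject, session, bundle) {
  resolve_one(file.path(layout$root, subject, session), bundle,
              c(".nii.gz", ".nii"))
}

#' Resolve a subject's Time-1 to Time-2 affine file
#' @inheritParams streamline_path
#' @return File path, or `NA` if absent.
#' @export
affine_path <- function(layout, subject) {
  p <- file.path(layout$root, subject, "affine_t1_to_t2.txt")
  if (file.exists(p)) p else NA_character_
}

#' Path of the cohort's metric CSV
#' @param layout A `cohort_layout`.
#' @return File path, or `NA` if absent.
#' @export
metrics_path <- function(layout) {
  p <- file.path(layout$root, "metrics.csv")
  if (file.exists(p)) p else NA_character_
}
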