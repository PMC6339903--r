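#' Create a metric table (subjects x sessions) for one bundle and metric
#'
#' @param values n x k numeric matrix: rows are subjects, columns are
#'   sessions. Missing cells are `NA`.
#' @param bundle,metric Labels.
#' @param subjects Optional subject identifiers (row names).
#' @param sessions Optional session labels (column names).
#' @return An object of class `metric_table` with fields `values`, `n`
#'   (total subjects), `k` (sessions), `complete_subjects` (row indices
#'   with no missing cell), `bundle`, `metric`.
#' @export
metric_table <- function(values, bundle = "", metric = "",
                         subjects = NULL, sessions = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (ncol(values) < 2L) stop("a metric table needs k >= 2 sessions")
  if (any(is.infinite(values))) stop("metric table contains non-finite values")
  if (!is.null(subjects)) rownames(values) <- subjects
  if (!is.null(sessions)) colnames(values) <- sessions
  complete <- which(rowSums(is.na(values)) == 0L)
  structure(
    list(
      values = values,
      n = nrow(values),
      k = ncol(values),
      complete_subjects = complete,
      bundle = bundle,
      metric = metric
    ),
    class = "metric_table"
  )
}

#' @export
print.metric_table <- function(x, ...) {
  cat(sprintf("<metric_table %s/%s> n = %d subjects (%d complete), k = %d sessions\n",
              x$bundle, x$metric, x$n, length(x$complete_subjects), x$k))
  invisible(x)
}

# complete-case n x k matrix used by all agreement statistics
complete_values <- function(t, min_n = 3L) {
  stopifnot(inherits(t, "metric_table"))
  v <- t$values[t$complete_subjects, , drop = FALSE]
  if (nrow(v) < min_n) {
    stop("need at least ", min_n, " complete subjects; have ", nrow(v),
         " for ", t$bundle, "/", t$metric)
  }
  v
}

#' Read per-bundle, per-metric measurement tables from a CSV file
#'
#' The CSV must have columns `subject`, `session`, `bundle`, `metric`,
#' `value` (UTF-8, header row). One `metric_table` is built per
#' (bundle, metric) combination; a subject missing a session for some
#' bundle appears as an `NA` cell and is dropped from analyses of that
#' table only (pairwise-complete handling).
#'
#' @param path CSV file path.
#' @param session_levels Optional length-2 ordering of session labels;
#'   defaults to sorted unique labels.
#' @return Named list of `metric_table` objects, names `bundle|metric`.
#' @export
read_metric_table <- function(path, session_levels = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  needed <- c("subject", "session", "bundle", "metric", "value")
  if (!all(needed %in% names(df))) {
    stop("metric CSV must have columns ", paste(needed, collapse = ", "))
  }
  key <- paste(df$subject, df$session, df$bundle, df$metric, sep = "\x1f")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1L, ]
    stop("duplicate metric row for subject=", d$subject, " session=", d$session,
         " bundle=", d$bundle, " metric=", d$metric)
  }
  val <- suppressWarnings(as.numeric(df$value))
  bad <- is.na(val) & !is.na(df$value) & nzchar(trimws(df$value))
  if (any(bad)) {
    stop("non-numeric value in metric CSV: '", df$value[bad][1L], "'")
  }
  if (anyNA(val)) stop("missing value field in metric CSV")
  df$value <- val
  sessions <- if (is.null(session_levels)) sort(unique(df$session)) else session_levels
  if (length(sessions) != 2L) {
    stop("expected exactly 2 sessions, found: ", paste(sessions, collapse = ", "))
  }
  subjects <- sort(unique(df$subject))
  out <- list()
  for (b in sort(unique(df$bundle))) {
    for (m in sort(unique(df$metric))) {
      sub <- df[df$bundle == b & df$metric == m, , drop = FALSE]
      if (nrow(sub) == 0L) next
      v <- matrix(NA_real_, nrow = length(subjects), ncol = 2L,
                  dimnames = list(subjects, sessions))
      v[cbind(match(sub$subject, subjects), match(sub$session, sessions))] <- sub$value
      present <- rowSums(!is.na(v)) > 0L
      v <- v[present, , drop = FALSE]
      out[[paste(b, m, sep = "|")]] <- metric_table(v, bundle = b, metric = m)
    }
  }
  out
}
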