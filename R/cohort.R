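# Cohort container: patients x (symptom items, remission outcome, optional
# binary moderator such as study membership).

new_cohort_table <- function(scores, outcome, moderator = NULL, ids = NULL,
                             scale, discretized = TRUE) {
  structure(
    list(
      scores = scores,
      outcome = outcome,
      moderator = moderator,
      ids = ids,
      scale = scale,
      discretized = discretized
    ),
    class = "cohort_table"
  )
}

#' Construct a validated cohort table
#'
#' Bundles per-patient symptom scores, a binary remission outcome
#' (0 = not remitted, 1 = remitted), and an optional binary moderator (e.g.
#' study membership). All invariants are checked: scores must be integers
#' inside each item's admissible range, outcome and moderator must be strictly
#' 0/1, and all components must have the same number of rows.
#'
#' @param scores Integer matrix or data frame, patients x items; columns must
#'   match the scale's item labels (and are reordered to them if named).
#' @param outcome Binary vector, one element per patient.
#' @param moderator Optional binary vector, one element per patient.
#' @param ids Optional patient identifiers.
#' @param scale A [symptom_scale()]; defaults to [hrsd17_scale()].
#'
#' @return An object of class `cohort_table`.
#' @export
cohort_table <- function(scores, outcome, moderator = NULL, ids = NULL,
                         scale = hrsd17_scale()) {
  scores <- as.matrix(scores)
  if (!is.null(colnames(scores))) {
    missing_cols <- setdiff(scale_labels(scale), colnames(scores))
    if (length(missing_cols)) {
      stop_noa("missing item column(s): %s", paste(missing_cols, collapse = ", "))
    }
    scores <- scores[, scale_labels(scale), drop = FALSE]
  } else {
    if (ncol(scores) != n_items(scale)) {
      stop_noa("scores has %d columns but the scale has %d items",
               ncol(scores), n_items(scale))
    }
    colnames(scores) <- scale_labels(scale)
  }
  n <- nrow(scores)
  if (n < 1L) stop_noa("cohort is empty (0 rows)")
  validate_scores(scores, scale)
  outcome <- validate_binary(outcome, n, "outcome")
  if (!is.null(moderator)) moderator <- validate_binary(moderator, n, "moderator")
  if (!is.null(ids) && length(ids) != n) {
    stop_noa("ids has length %d but there are %d patients", length(ids), n)
  }
  storage.mode(scores) <- "integer"
  new_cohort_table(scores, outcome, moderator, ids, scale)
}

validate_scores <- function(scores, scale, rows = seq_len(nrow(scores))) {
  items <- scale$items
  for (j in seq_len(ncol(scores))) {
    v <- scores[, j]
    bad <- which(!is.na(v) & (v != round(v) | v < items$min_score[j] |
                                v > items$max_score[j]))
    if (length(bad)) {
      stop_noa("row %d: item '%s' score %s outside [%d, %d]",
               rows[bad[1]], items$label[j], format(v[bad[1]]),
               items$min_score[j], items$max_score[j])
    }
  }
  invisible(TRUE)
}

validate_binary <- function(x, n, what) {
  x <- as.integer(x)
  if (length(x) != n) {
    stop_noa("%s has length %d but there are %d patients", what, length(x), n)
  }
  if (any(is.na(x)) || !all(x %in% c(0L, 1L))) {
    stop_noa("%s must contain only 0/1", what)
  }
  x
}

#' Number of patients in a cohort
#' @param cohort A [cohort_table()].
#' @return Integer row count.
#' @export
n_patients <- function(cohort) nrow(cohort$scores)

#' Read a cohort table from a delimited text file
#'
#' Expects a header row with one column per scale item (matching labels), a
#' binary outcome column, and optionally a binary moderator column and an id
#' column. Any other column is a schema error. Rows with a missing item or
#' outcome value (or moderator value, when the moderator column is present)
#' are dropped and the count is reported (complete-case analysis).
#'
#' @param path Path to a comma- or tab-delimited UTF-8 file with header.
#' @param scale A [symptom_scale()]; defaults to [hrsd17_scale()].
#' @param delim Field delimiter, `","` (default) or `"\t"`.
#' @param outcome_col,moderator_col,id_col Column names for the outcome
#'   (required in the file), moderator and ids (both optional).
#'
#' @return A validated [cohort_table()].
#' @export
load_cohort <- function(path, scale = hrsd17_scale(), delim = ",",
                        outcome_col = "remission", moderator_col = "study",
                        id_col = "id") {
  delim <- match.arg(delim, c(",", "\t"))
  reader <- if (delim == ",") read.csv else read.delim
  df <- reader(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) stop_noa("empty cohort: '%s' has a header but no rows", path)

  known <- c(scale_labels(scale), outcome_col, moderator_col, id_col)
  unknown <- setdiff(names(df), known)
  if (length(unknown)) {
    stop_noa("unknown column(s) in '%s': %s", path, paste(unknown, collapse = ", "))
  }
  missing_cols <- setdiff(c(scale_labels(scale), outcome_col), names(df))
  if (length(missing_cols)) {
    stop_noa("missing column(s) in '%s': %s", path,
             paste(missing_cols, collapse = ", "))
  }

  scores <- as.matrix(df[, scale_labels(scale), drop = FALSE])
  if (!is.numeric(scores)) stop_noa("non-numeric symptom score in '%s'", path)
  # Range violations are errors, not missingness: check observed values first,
  # reporting the original data row number.
  validate_scores(scores, scale)

  outcome <- df[[outcome_col]]
  moderator <- if (moderator_col %in% names(df)) df[[moderator_col]] else NULL
  ids <- if (id_col %in% names(df)) df[[id_col]] else NULL

  complete <- stats::complete.cases(scores, outcome,
                                    if (is.null(moderator)) rep(0L, nrow(df)) else moderator)
  n_dropped <- sum(!complete)
  if (n_dropped > 0L) {
    message(sprintf("load_cohort: dropped %d of %d rows with missing values (complete-case analysis)",
                    n_dropped, nrow(df)))
  }
  if (!any(complete)) stop_noa("empty cohort: all %d rows have missing values", nrow(df))

  cohort_table(
    scores = scores[complete, , drop = FALSE],
    outcome = outcome[complete],
    moderator = if (is.null(moderator)) NULL else moderator[complete],
    ids = if (is.null(ids)) NULL else ids[complete],
    scale = scale
  )
}

#' Write a cohort table to a delimited text file
#'
#' Inverse of [load_cohort()]: writes item columns (scale order), the
#' `remission` column, and `study`/`id` columns when present.
#'
#' @param cohort A [cohort_table()].
#' @param path Output file path.
#' @param delim Field delimiter, `","` (default) or `"\t"`.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(cohort, path, delim = ",") {
  delim <- match.arg(delim, c(",", "\t"))
  df <- as.data.frame(cohort$scores)
  df$remission <- cohort$outcome
  if (!is.null(cohort$moderator)) df$study <- cohort$moderator
  if (!is.null(cohort$ids)) df$id <- cohort$ids
  write.table(df, path, sep = delim, row.names = FALSE, quote = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d patients, %d items%s\n",
              n_patients(x), n_items(x$scale),
              if (!is.null(x$moderator)) ", with moderator" else ""))
  cat(sprintf("  remission: %d/%d (%.1f%%)\n", sum(x$outcome),
              n_patients(x), 100 * mean(x$outcome)))
  if (!x$discretized) cat("  (continuous latent values, not discretized)\n")
  invisible(x)
}
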