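#' Construct a marker table
#'
#' The universal data container of the pipeline: a subjects x markers matrix of
#' continuous measurements (missing entries allowed, as `NA`), plus the
#' per-subject ADAS-cog score and the binary MCI-to-AD conversion label.
#'
#' @param values numeric matrix, subjects in rows, markers in columns; row and
#'   column names are the subject and marker identifiers.
#' @param adas numeric vector of ADAS-cog scores, one per subject, in
#'   `[0, 85]` (higher is worse cognition).
#' @param label integer vector of conversion indicators (1 = converted to AD
#'   within the follow-up window, 0 = stable MCI).
#' @param source character vector tagging each marker's modality: `"MRI"`,
#'   `"plasma"` or `"unknown"`.
#' @return an object of class `marker_table`.
#' @export
marker_table <- function(values, adas, label,
                         source = rep("unknown", ncol(values))) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_validation("`values` must be a numeric matrix")
  }
  n <- nrow(values)
  p <- ncol(values)
  if (is.null(rownames(values))) rownames(values) <- sprintf("S%04d", seq_len(n))
  if (is.null(colnames(values))) colnames(values) <- sprintf("M%03d", seq_len(p))
  if (anyDuplicated(colnames(values))) {
    stop_validation("marker names must be unique")
  }
  if (anyDuplicated(rownames(values))) {
    stop_validation("subject ids must be unique")
  }
  if (length(adas) != n) stop_validation("`adas` must have one entry per subject")
  if (length(label) != n) stop_validation("`label` must have one entry per subject")
  label <- as.integer(label)
  if (!all(label %in% c(0L, 1L))) {
    stop_validation("`label` must be binary 0/1")
  }
  if (length(source) != p) {
    stop_validation("`source` must have one entry per marker")
  }
  structure(
    list(values = values,
         adas = as.numeric(adas),
         label = label,
         source = as.character(source)),
    class = "marker_table"
  )
}

#' @export
print.marker_table <- function(x, ...) {
  cat(sprintf("marker_table: %d subjects x %d markers\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  converters: %d / %d (%.1f%%)\n",
              sum(x$label), length(x$label), 100 * mean(x$label)))
  cat(sprintf("  missing entries: %d\n", sum(is.na(x$values))))
  cat(sprintf("  ADAS-cog: mean %.2f (converters %.2f, non-converters %.2f)\n",
              mean(x$adas), mean(x$adas[x$label == 1L]),
              mean(x$adas[x$label == 0L])))
  invisible(x)
}

#' @export
dim.marker_table <- function(x) dim(x$values)

n_subjects <- function(t) nrow(t$values)
marker_names <- function(t) colnames(t$values)
subject_ids <- function(t) rownames(t$values)

# Row / column subsetting that keeps all aligned fields together.
subset_subjects <- function(t, idx) {
  marker_table(t$values[idx, , drop = FALSE], t$adas[idx], t$label[idx],
               t$source)
}

subset_markers <- function(t, keep) {
  idx <- if (is.character(keep)) match(keep, marker_names(t)) else keep
  marker_table(t$values[, idx, drop = FALSE], t$adas, t$label, t$source[idx])
}

#' Convert a marker table to a data frame
#'
#' @param x a `marker_table`.
#' @param row.names,optional,... ignored; present for S3 compatibility.
#' @return a data.frame with columns `subject_id`, one per marker, `ADAS` and
#'   `CONVERT`.
#' @export
as.data.frame.marker_table <- function(x, row.names = NULL, optional = FALSE,
                                       ...) {
  df <- data.frame(subject_id = rownames(x$values),
                   x$values,
                   ADAS = x$adas,
                   CONVERT = x$label,
                   check.names = FALSE,
                   row.names = NULL)
  df
}

#' Write a marker table to CSV
#'
#' @param t a `marker_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_marker_table <- function(t, path) {
  utils::write.csv(as.data.frame(t), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a marker table from CSV
#'
#' Reads a subjects x markers CSV, validates it, and coerces any non-numeric
#' marker cell (e.g. `"NA"`, `"."`, free text) to a missing entry, counting
#' the coercions.
#'
#' @param path CSV file with one header row.
#' @param schema named list mapping column roles to column names; must name
#'   `subject`, `adas` and `label`. An optional `source` entry may map marker
#'   names to modality tags.
#' @return a `marker_table`; the number of cells coerced to missing is
#'   attached as attribute `n_coerced`.
#' @export
load_table <- function(path,
                       schema = list(subject = "subject_id", adas = "ADAS",
                                     label = "CONVERT")) {
  if (!file.exists(path)) stop_data("file not found: %s", path)
  for (role in c("subject", "adas", "label")) {
    if (is.null(schema[[role]])) {
      stop_validation("schema must name the `%s` column", role)
    }
  }
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  for (role in c("subject", "adas", "label")) {
    if (!schema[[role]] %in% names(df)) {
      stop_validation("mandatory column `%s` (role %s) absent from %s",
                      schema[[role]], role, path)
    }
  }
  ids <- as.character(df[[schema$subject]])
  if (anyDuplicated(ids)) stop_validation("duplicate subject ids in %s", path)
  marker_cols <- setdiff(names(df), unlist(schema[c("subject", "adas", "label")]))
  n_coerced <- 0L
  vals <- matrix(NA_real_, nrow(df), length(marker_cols),
                 dimnames = list(ids, marker_cols))
  for (j in seq_along(marker_cols)) {
    col <- df[[marker_cols[j]]]
    num <- suppressWarnings(as.numeric(col))
    # cells that were present (not already NA) but not parseable as numbers
    n_coerced <- n_coerced + sum(is.na(num) & !is.na(col) &
                                   !(trimws(as.character(col)) %in% c("NA", "")))
    vals[, j] <- num
  }
  src <- if (!is.null(schema$source)) {
    unname(unlist(schema$source)[marker_cols])
  } else {
    rep("unknown", length(marker_cols))
  }
  src[is.na(src)] <- "unknown"
  t <- marker_table(vals, as.numeric(df[[schema$adas]]),
                    as.integer(df[[schema$label]]), src)
  attr(t, "n_coerced") <- n_coerced
  t
}
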