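#' Drop over-missing markers
#'
#' Removes every marker whose fraction of missing entries exceeds
#' `max_missing`, mirroring the data-checking stage in which markers with too
#' many missing entries are deleted before selection.
#'
#' @param t a [marker_table()].
#' @param max_missing maximum tolerated missing fraction per marker, in
#'   `[0, 1)`; default 0.10.
#' @return a list with elements `table` (markers in their original order,
#'   over-missing columns removed) and `report` (a cleaning report: dropped
#'   markers with their missing fractions, and the threshold used).
#' @export
filter_missing <- function(t, max_missing = 0.10) {
  stopifnot(inherits(t, "marker_table"))
  if (!is.numeric(max_missing) || max_missing < 0 || max_missing >= 1) {
    stop_validation("`max_missing` must be in [0, 1)")
  }
  frac <- colMeans(is.na(t$values))
  drop <- frac > max_missing
  if (all(drop)) {
    stop_data("all %d markers exceed the missingness threshold %.2f",
              ncol(t$values), max_missing)
  }
  report <- list(
    dropped_markers = data.frame(marker = marker_names(t)[drop],
                                 missing_fraction = unname(frac[drop]),
                                 stringsAsFactors = FALSE),
    imputed_cells = 0L,
    thresholds_used = list(max_missing = max_missing)
  )
  list(table = subset_markers(t, which(!drop)), report = report)
}

#' Per-marker medians over observed values
#'
#' @param t a [marker_table()].
#' @return named numeric vector of medians, one per marker.
#' @export
marker_medians <- function(t) {
  stopifnot(inherits(t, "marker_table"))
  apply(t$values, 2L, stats::median, na.rm = TRUE)
}

#' Median-impute missing marker entries
#'
#' Each missing cell is replaced by that marker's median over observed values.
#' During cross-validation, pass `medians` computed from the training fold so
#' no test-fold information leaks into the fill values.
#'
#' @param t a [marker_table()].
#' @param medians optional named vector of fill values per marker (e.g. from
#'   [marker_medians()] on a training fold); defaults to the medians of `t`
#'   itself.
#' @return a `marker_table` with no missing entries; the number of imputed
#'   cells is attached as attribute `n_imputed`.
#' @export
impute_median <- function(t, medians = NULL) {
  stopifnot(inherits(t, "marker_table"))
  if (is.null(medians)) medians <- marker_medians(t)
  medians <- medians[marker_names(t)]
  if (anyNA(medians)) {
    bad <- marker_names(t)[is.na(medians)]
    stop_data(paste0("marker(s) with no observed values: %s; ",
                     "run filter_missing() first"),
              paste(bad, collapse = ", "))
  }
  vals <- t$values
  n_imputed <- 0L
  for (j in seq_len(ncol(vals))) {
    miss <- is.na(vals[, j])
    if (any(miss)) {
      vals[miss, j] <- medians[j]
      n_imputed <- n_imputed + sum(miss)
    }
  }
  out <- marker_table(vals, t$adas, t$label, t$source)
  attr(out, "n_imputed") <- n_imputed
  out
}

#' Write a cleaning report to JSON
#'
#' @param report the `report` element of [filter_missing()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cleaning_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
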