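#' Fit a quantile discretization model
#'
#' Per-marker quantile cut points (default tertiles) computed on training
#' subjects only; applying the model maps values to bin indices, with values
#' outside the training range falling into the extreme bins. Markers with too
#' few distinct values fall back to fewer bins with a warning; a constant
#' marker yields a single bin.
#'
#' @param t a [marker_table()] with no missing entries (impute first); only
#'   `markers` are used.
#' @param bins target number of bins per marker (>= 2).
#' @param markers marker names to fit; default all.
#' @return an object of class `discretization_model`: per-marker cut points
#'   and bin counts, plus the training subject ids.
#' @export
discretize_fit <- function(t, bins = 3L, markers = marker_names(t)) {
  stopifnot(inherits(t, "marker_table"))
  bins <- check_count(bins, "bins", min = 2L)
  cuts <- vector("list", length(markers))
  names(cuts) <- markers
  for (m in markers) {
    x <- t$values[, m]
    x <- x[!is.na(x)]
    q <- stats::quantile(x, probs = seq_len(bins - 1L) / bins, names = FALSE,
                         type = 7)
    q <- unique(q)
    # a cut equal to the extremes produces an empty extreme bin; drop it
    q <- q[q > min(x) & q < max(x)]
    if (length(q) < bins - 1L) {
      warning(sprintf(
        "marker %s: only %d distinct cut(s) available; using %d bin(s)",
        m, length(q), length(q) + 1L))
    }
    cuts[[m]] <- q
  }
  structure(list(cuts = cuts,
                 n_bins = vapply(cuts, function(q) length(q) + 1L, integer(1)),
                 fitted_on = subject_ids(t)),
            class = "discretization_model")
}

#' Apply a discretization model
#'
#' @param model a [discretize_fit()] result.
#' @param t a [marker_table()] containing the model's markers.
#' @return integer matrix of 1-based bin indices (subjects x markers);
#'   missing values stay `NA`.
#' @export
discretize_apply <- function(model, t) {
  stopifnot(inherits(model, "discretization_model"),
            inherits(t, "marker_table"))
  markers <- names(model$cuts)
  absent <- setdiff(markers, marker_names(t))
  if (length(absent) > 0L) {
    stop_validation("markers absent from table: %s",
                    paste(absent, collapse = ", "))
  }
  out <- matrix(NA_integer_, n_subjects(t), length(markers),
                dimnames = list(subject_ids(t), markers))
  for (m in markers) {
    x <- t$values[, m]
    out[, m] <- findInterval(x, model$cuts[[m]]) + 1L
    out[is.na(x), m] <- NA_integer_
  }
  out
}

# Attach the discretized conversion label as an extra column, producing the
# node set over which network structure is learned.
discrete_frame <- function(model, t, conv_node = "CONVERT") {
  d <- discretize_apply(model, t)
  cbind(d, matrix(t$label + 1L, ncol = 1L,
                  dimnames = list(subject_ids(t), conv_node)))
}

# Cardinality (number of states) per column of a discrete matrix given a
# discretization model; the conversion node is binary.
discrete_cardinality <- function(model, conv_node = "CONVERT") {
  c(model$n_bins, stats::setNames(2L, conv_node))
}
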