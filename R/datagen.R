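#' Specify a synthetic MCI cohort
#'
#' Defaults emulate the cohort shape the pipeline targets: 316 MCI subjects of
#' whom 99 convert to AD within follow-up, a few hundred continuous markers of
#' which a small informative subset carries the conversion signal, an ADAS-cog
#' score (0-85) higher in converters (group means 22.36 vs 16.94), and missing
#' entries concentrated in a subset of marker columns.
#'
#' @param n_subjects number of subjects.
#' @param n_markers total number of continuous markers.
#' @param n_informative number of markers whose distribution shifts with the
#'   conversion state.
#' @param converter_fraction expected fraction of converters, in (0,1).
#' @param missing_fraction per-cell missingness rate inside affected marker
#'   columns, in `[0,1)`.
#' @param missing_marker_fraction fraction of marker columns that receive
#'   missing entries, in `[0,1]`.
#' @param effect_size standardized mean difference (Cohen's d) of each
#'   informative marker between converters and non-converters; must be below
#'   about 2.6 (see Details).
#' @param adas_noise_sd standard deviation (score points) of the Gaussian
#'   noise added to the ADAS-cog score.
#' @param seed integer seed; all output is a deterministic function of the
#'   spec including the seed.
#'
#' @details Informative markers are generated from a discrete-latent ground
#' truth: the conversion node is a Bernoulli root, each informative marker has
#' a binary latent state that is a noisy child of the conversion node
#' (`P(state = 1) = 0.9` for converters, `0.1` for non-converters), and the
#' observed value is Gaussian around a state-dependent mean. The gap between
#' the two state means is calibrated so the between-label Cohen's d of the
#' observed marker equals `effect_size`; the mixture variance caps the
#' attainable d just below 2.67. Uninformative markers are i.i.d. standard
#' normal. ADAS-cog is an affine function of the mean of the informative
#' markers plus noise, calibrated so the expected group means match 22.36
#' (converters) and 16.94 (non-converters), then clipped to `[0, 85]`.
#'
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 316L,
                        n_markers = 200L,
                        n_informative = 10L,
                        converter_fraction = 99 / 316,
                        missing_fraction = 0.05,
                        missing_marker_fraction = 0.10,
                        effect_size = 1.0,
                        adas_noise_sd = 4.2,
                        seed = 1L) {
  n_subjects <- check_count(n_subjects, "n_subjects", min = 4L)
  n_markers <- check_count(n_markers, "n_markers", min = 1L)
  n_informative <- check_count(n_informative, "n_informative", min = 0L)
  if (n_informative > n_markers) {
    stop_validation("`n_informative` (%d) must not exceed `n_markers` (%d)",
                    n_informative, n_markers)
  }
  check_proportion(converter_fraction, "converter_fraction",
                   open_left = TRUE, open_right = TRUE)
  check_proportion(missing_fraction, "missing_fraction", open_right = TRUE)
  check_proportion(missing_marker_fraction, "missing_marker_fraction")
  if (!is.numeric(effect_size) || effect_size < 0 || effect_size >= 2.6) {
    stop_validation("`effect_size` must be in [0, 2.6) (got %s)",
                    format(effect_size))
  }
  if (!is.numeric(adas_noise_sd) || adas_noise_sd < 0) {
    stop_validation("`adas_noise_sd` must be non-negative")
  }
  seed <- check_count(seed, "seed", min = 0L)
  structure(list(n_subjects = n_subjects, n_markers = n_markers,
                 n_informative = n_informative,
                 converter_fraction = converter_fraction,
                 missing_fraction = missing_fraction,
                 missing_marker_fraction = missing_marker_fraction,
                 effect_size = effect_size, adas_noise_sd = adas_noise_sd,
                 seed = seed),
            class = "cohort_spec")
}

# Latent-state emission probabilities: P(S=1 | converter) and
# P(S=1 | non-converter). Fixed; the mean gap is calibrated around them.
P_STATE_CONV <- 0.9
P_STATE_STAB <- 0.1

# ADAS-cog calibration targets (score points, converters / non-converters).
ADAS_MEAN_CONV <- 22.36
ADAS_MEAN_STAB <- 16.94
ADAS_MAX <- 85

# Mean gap between the two latent-state emission means giving Cohen's d = d
# for the observed marker: within-label variance is 1 + gap^2 * p(1-p) with
# p(1-p) = 0.09 for both labels, and the between-label mean difference is
# 0.8 * gap.
state_mean_gap <- function(d) {
  if (d == 0) return(0)
  gap <- (P_STATE_CONV - P_STATE_STAB)
  pq <- P_STATE_CONV * (1 - P_STATE_CONV)
  sqrt(d^2 / (gap^2 - pq * d^2))
}

#' Generate a synthetic cohort with known ground truth
#'
#' @param spec a [cohort_spec()].
#' @return a list with elements `table` (a [marker_table()]) and
#'   `ground_truth` (the generating DAG as an edge list, the informative
#'   marker names, the columns seeded with missing entries, and the
#'   generating parameters).
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) {
    stop_validation("`spec` must be a cohort_spec")
  }
  with_seed(spec$seed, {
    n <- spec$n_subjects
    p <- spec$n_markers
    k <- spec$n_informative

    label <- stats::rbinom(n, 1L, spec$converter_fraction)
    # guard against a degenerate all-one-class draw at tiny n
    if (sum(label) == 0L) label[1L] <- 1L
    if (sum(label) == n) label[1L] <- 0L

    m_names <- sprintf("M%03d", seq_len(p))
    source <- rep(c("MRI", "plasma"), length.out = p)
    informative <- sort(sample.int(p, k))

    gap <- state_mean_gap(spec$effect_size)
    values <- matrix(stats::rnorm(n * p), n, p,
                     dimnames = list(sprintf("S%04d", seq_len(n)), m_names))
    states <- matrix(0L, n, k)
    if (k > 0) {
      pr <- ifelse(label == 1L, P_STATE_CONV, P_STATE_STAB)
      for (j in seq_len(k)) {
        s <- stats::rbinom(n, 1L, pr)
        states[, j] <- s
        values[, informative[j]] <- values[, informative[j]] + gap * s
      }
    }

    # ADAS-cog: affine in the mean informative-marker value, calibrated so the
    # expected group means hit the 22.36 / 16.94 targets, then clipped.
    if (k > 0 && gap > 0) {
      slope <- (ADAS_MEAN_CONV - ADAS_MEAN_STAB) /
        ((P_STATE_CONV - P_STATE_STAB) * gap)
      intercept <- ADAS_MEAN_STAB - slope * P_STATE_STAB * gap
      signal <- rowMeans(values[, informative, drop = FALSE])
    } else {
      slope <- 0
      intercept <- (ADAS_MEAN_CONV + ADAS_MEAN_STAB) / 2
      signal <- numeric(n)
    }
    adas <- intercept + slope * signal + stats::rnorm(n, 0, spec$adas_noise_sd)
    adas <- pmin(pmax(adas, 0), ADAS_MAX)

    # MCAR missingness confined to a sampled subset of marker columns
    n_miss_cols <- round(spec$missing_marker_fraction * p)
    miss_cols <- if (n_miss_cols > 0) sort(sample.int(p, n_miss_cols)) else integer(0)
    for (j in miss_cols) {
      hit <- stats::runif(n) < spec$missing_fraction
      values[hit, j] <- NA_real_
    }

    conv_node <- "CONVERT"
    dag_edges <- if (k > 0) {
      data.frame(from = conv_node, to = m_names[informative],
                 stringsAsFactors = FALSE)
    } else {
      data.frame(from = character(0), to = character(0))
    }

    list(
      table = marker_table(values, adas, label, source),
      ground_truth = list(
        dag = dag_edges,
        informative_markers = m_names[informative],
        missing_columns = m_names[miss_cols],
        generating_params = list(
          state_prob = c(converter = P_STATE_CONV,
                         nonconverter = P_STATE_STAB),
          state_mean_gap = gap,
          adas_intercept = intercept,
          adas_slope = slope,
          spec = unclass(spec))
      )
    )
  })
}

#' Write the ground truth of a synthetic cohort to JSON
#'
#' @param gt the `ground_truth` element returned by [generate_cohort()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(gt, path) {
  jsonlite::write_json(
    list(edges = gt$dag, informative_markers = gt$informative_markers,
         missing_columns = gt$missing_columns),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
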