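#' Export a DAG as a DOT file
#'
#' @param dag a [bn_dag()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dag_dot <- function(dag, path) {
  stopifnot(inherits(dag, "bn_dag"))
  lines <- c("digraph bn {",
             sprintf("  \"%s\";", dag$nodes),
             if (nrow(dag$edges) > 0) {
               sprintf("  \"%s\" -> \"%s\";", dag$edges$from, dag$edges$to)
             },
             "}")
  writeLines(lines, path)
  invisible(path)
}

#' Export / import a DAG as a JSON edge list
#'
#' @param dag a [bn_dag()].
#' @param path file path.
#' @return `write_dag_json` returns `path` invisibly; `read_dag_json` the
#'   [bn_dag()].
#' @export
write_dag_json <- function(dag, path) {
  stopifnot(inherits(dag, "bn_dag"))
  jsonlite::write_json(list(nodes = dag$nodes, edges = dag$edges), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dag_json
#' @export
read_dag_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- if (length(obj$edges) == 0) {
    data.frame(from = character(0), to = character(0))
  } else {
    as.data.frame(obj$edges)
  }
  bn_dag(obj$nodes, edges)
}

#' Assemble a run configuration
#'
#' Accepts either a path to a YAML/JSON config file or named arguments.
#' Exactly one of `input` (a cohort CSV) and `simulate` (a [cohort_spec()]
#' or a list of its fields) must be supplied.
#'
#' @param path optional YAML or JSON file of settings.
#' @param ... settings overriding the file: `input`, `simulate`, `out_dir`,
#'   plus any [cv_config()] field and the risk-rule fields `high`/`low`.
#' @return a `run_config` list.
#' @export
run_config <- function(path = NULL, ...) {
  cfg <- list()
  if (!is.null(path)) {
    cfg <- if (grepl("\\.ya?ml$", path)) {
      yaml::read_yaml(path)
    } else {
      jsonlite::read_json(path, simplifyVector = TRUE)
    }
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  if (!is.null(cfg$input) && !is.null(cfg$simulate)) {
    stop_validation("config sets both `input` and `simulate`; choose one")
  }
  if (is.null(cfg$input) && is.null(cfg$simulate)) cfg$simulate <- list()
  defaults <- list(out_dir = "mcinet-run", seed = 1L, alpha = 0.05,
                   max_missing = 0.10, bins = 3L, score = "bdeu", ess = 1,
                   ci_alpha = 0.05, k = 10L, selection = "inside",
                   lasso_penalty = "cv", threshold = 0.5, max_sx = 3L,
                   high = 11L, low = 48L)
  for (nm in names(defaults)) if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  structure(cfg, class = "run_config")
}

#' Run the full pipeline
#'
#' Orchestrates generate-or-load, cleaning, two-stage selection, structure
#' learning, cross-validated evaluation, and risk-subgroup disruption
#' profiling; writes every artifact plus a manifest into `out_dir`. The same
#' configuration and seed reproduce identical outputs.
#'
#' @param config a [run_config()].
#' @return the output directory, invisibly; the fitted objects are attached
#'   as attribute `results`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)

  # --- data ---------------------------------------------------------------
  ground_truth <- NULL
  if (!is.null(config$simulate)) {
    spec_args <- config$simulate
    if (is.null(spec_args$seed)) {
      spec_args$seed <- derive_seed(config$seed, "datagen")
    }
    spec <- do.call(cohort_spec, spec_args)
    gen <- generate_cohort(spec)
    t <- gen$table
    ground_truth <- gen$ground_truth
    write_marker_table(t, out("cohort.csv"))
    write_ground_truth(ground_truth, out("ground_truth.json"))
  } else {
    t <- load_table(config$input)
  }

  # --- cleaning + selection on the full table (the interpretable model) ----
  filt <- filter_missing(t, config$max_missing)
  tc <- filt$table
  t_imp <- impute_median(tc)
  cvcfg <- cv_config(alpha = config$alpha, max_missing = config$max_missing,
                     bins = config$bins, score = config$score,
                     ess = config$ess, ci_alpha = config$ci_alpha,
                     k = config$k, seed = derive_seed(config$seed, "evalx"),
                     selection = config$selection,
                     lasso_penalty = config$lasso_penalty,
                     threshold = config$threshold, max_sx = config$max_sx)
  fit <- fit_pipeline(tc, cvcfg)
  if (is.null(fit)) {
    stop_data("stage select/bn: no predictive structure on the full table; check the input data")
  }
  sel <- fit$selection
  funnel <- list(
    input_markers = ncol(t$values),
    after_missingness_filter = ncol(tc$values),
    anova_survivors = if (!is.null(sel)) length(sel$anova_survivors) else ncol(tc$values),
    lasso_survivors = if (!is.null(sel)) length(sel$lasso_survivors) else ncol(tc$values),
    connected_markers = length(setdiff(fit$pruned$dag$nodes, "CONVERT")),
    arcs = nrow(fit$pruned$dag$edges))
  jsonlite::write_json(
    list(funnel = funnel,
         dropped_overmissing = filt$report$dropped_markers,
         anova_p = if (!is.null(sel)) as.list(sel$anova_p),
         anova_survivors = if (!is.null(sel)) sel$anova_survivors,
         lasso_survivors = if (!is.null(sel)) sel$lasso_survivors,
         chosen_penalty = if (!is.null(sel)) sel$chosen_penalty,
         removed_disconnected = fit$pruned$removed),
    out("selection.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(sel)) {
    writeLines(sel$lasso_survivors, out("survivors.txt"))
  }
  write_dag_json(fit$pruned$dag, out("dag.json"))
  write_dag_dot(fit$pruned$dag, out("dag.dot"))

  # --- cross-validated evaluation -----------------------------------------
  cv <- cross_validate(t, cvcfg)
  utils::write.csv(cv$roc$points, out("roc.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(auc = cv$roc$auc, metrics = cv$metrics,
         fold = cv$fold,
         flagged_folds = which(vapply(cv$folds, `[[`, logical(1), "flagged"))),
    out("metrics.json"), auto_unbox = TRUE, digits = NA)

  # --- disruption profiling on model-predicted risk ------------------------
  probs <- score_pipeline(fit, tc)
  grp <- split_by_risk(probs, "topk",
                       high = min(config$high, floor(n_subjects(tc) / 4)),
                       low = min(config$low, floor(n_subjects(tc) / 4)))
  profile <- subgroup_profile(t_imp, grp$high, grp$low, alpha = config$alpha)
  jsonlite::write_json(
    list(high_ids = profile$high_ids, low_ids = profile$low_ids,
         significant_panel = profile$significant_panel,
         panel_used = profile$panel_used,
         group_means = profile$group_means,
         comparison_p = as.list(profile$comparison_p)),
    out("disruption.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(profile$balance_map, out("balance_map.csv"),
                   row.names = FALSE)

  # --- manifest -------------------------------------------------------------
  manifest <- list(package = "mcinet",
                   version = as.character(utils::packageVersion("mcinet")),
                   config = unclass(config))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)

  res <- list(table = t, ground_truth = ground_truth, fit = fit, cv = cv,
              probabilities = probs, groups = grp, profile = profile,
              funnel = funnel)
  invisible(structure(config$out_dir, results = res))
}
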