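#' Deterministic (stratified) k-fold assignment
#'
#' Fold sizes differ by at most one overall; under stratification the
#' per-class counts per fold also differ by at most one (remainder folds are
#' chosen greedily to keep overall fold sizes balanced).
#'
#' @param labels binary 0/1 vector.
#' @param k number of folds (>= 2).
#' @param stratified balance class counts across folds; default TRUE.
#' @param seed integer seed; the assignment is a pure function of
#'   `(labels, k, stratified, seed)`.
#' @return a list with `fold` (per-subject fold index in 1..k), `k`,
#'   `stratified` and `seed`.
#' @export
kfold <- function(labels, k = 10L, stratified = TRUE, seed = 1L) {
  k <- check_count(k, "k", min = 2L)
  labels <- as.integer(labels)
  n <- length(labels)
  if (n < k) stop_validation("fewer subjects (%d) than folds (%d)", n, k)
  fold <- integer(n)
  with_seed(seed, {
    if (stratified) {
      if (any(table(factor(labels, levels = c(0L, 1L))) < k)) {
        stop_validation("each class must have at least k = %d members for stratification", k)
      }
      totals <- rep(0L, k)
      for (cl in c(0L, 1L)) {
        idx <- which(labels == cl)
        idx <- idx[sample.int(length(idx))]
        base <- length(idx) %/% k
        rem <- length(idx) %% k
        sizes <- rep(base, k)
        if (rem > 0L) {
          # give the +1s to the folds currently smallest (ties: lowest index)
          extra <- order(totals, seq_len(k))[seq_len(rem)]
          sizes[extra] <- sizes[extra] + 1L
        }
        f <- rep(seq_len(k), times = sizes)
        fold[idx] <- f
        totals <- totals + sizes
      }
    } else {
      idx <- sample.int(n)
      sizes <- rep(n %/% k, k)
      rem <- n %% k
      if (rem > 0L) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
      fold[idx] <- rep(seq_len(k), times = sizes)
    }
  })
  list(fold = fold, k = k, stratified = stratified, seed = seed)
}

#' ROC curve and AUC
#'
#' Threshold sweep over the unique scores; tied scores are grouped so the
#' trapezoid-rule area equals the Mann-Whitney statistic with the half-credit
#' tie convention.
#'
#' @param probabilities numeric scores (higher = more likely positive).
#' @param labels binary 0/1 vector.
#' @return a list with `points` (data.frame of FPR/TPR, starting at (0,0) and
#'   ending at (1,1)) and `auc`.
#' @export
roc_auc <- function(probabilities, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop_data("both classes must be present to compute a ROC curve")
  }
  stopifnot(length(probabilities) == length(labels))
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  o <- order(probabilities, decreasing = TRUE)
  s <- probabilities[o]; l <- labels[o]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(l); fp <- cumsum(1L - l)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / np)
  fpr <- c(0, fp[last] / nn)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(FPR = fpr, TPR = tpr), auc = auc)
}

#' Classification metrics at a threshold
#'
#' A subject is called a converter when its score is at or above the
#' threshold. Accuracy is correct calls over all subjects, sensitivity is
#' correct converter calls over converters, specificity is correct
#' non-converter calls over non-converters.
#'
#' @inheritParams roc_auc
#' @param threshold decision threshold on the score; default 0.5.
#' @return a list with the confusion counts (`TP`, `FP`, `TN`, `FN`),
#'   `accuracy`, `sensitivity`, `specificity` and the threshold.
#' @export
classification_metrics <- function(probabilities, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop_data("both classes must be present to compute metrics")
  }
  pred <- as.integer(probabilities >= threshold)
  TP <- sum(pred == 1L & labels == 1L)
  FP <- sum(pred == 1L & labels == 0L)
  TN <- sum(pred == 0L & labels == 0L)
  FN <- sum(pred == 0L & labels == 1L)
  list(TP = TP, FP = FP, TN = TN, FN = FN,
       accuracy = (TP + TN) / length(labels),
       sensitivity = TP / (TP + FN),
       specificity = TN / (TN + FP),
       threshold = threshold)
}

#' Default pipeline configuration for cross-validation
#'
#' @param alpha ANOVA screen level.
#' @param max_missing missingness threshold of [filter_missing()].
#' @param bins discretization bins.
#' @param score structure score, `"bdeu"` or `"bic"`.
#' @param ess BDeu equivalent sample size.
#' @param ci_alpha skeleton-phase significance level.
#' @param k CV folds.
#' @param seed global seed.
#' @param selection `"inside"` (fit the marker funnel on each training fold;
#'   leakage-free, the default), `"outside"` (one global selection before CV)
#'   or `"none"`.
#' @param lasso_penalty `"cv"` or a fixed penalty.
#' @param threshold classification threshold on the conversion posterior.
#' @param max_sx conditioning-set size cap of the skeleton phase.
#' @return a named list of settings.
#' @export
cv_config <- function(alpha = 0.05, max_missing = 0.10, bins = 3L,
                      score = "bdeu", ess = 1, ci_alpha = 0.05, k = 10L,
                      seed = 1L, selection = c("inside", "outside", "none"),
                      lasso_penalty = "cv", threshold = 0.5, max_sx = 3L) {
  list(alpha = alpha, max_missing = max_missing, bins = bins, score = score,
       ess = ess, ci_alpha = ci_alpha, k = k, seed = seed,
       selection = match.arg(selection), lasso_penalty = lasso_penalty,
       threshold = threshold, max_sx = max_sx)
}

# Fit the full model chain on a training table; returns everything needed to
# score new subjects. `markers` = NULL means run selection internally.
fit_pipeline <- function(train, config, markers = NULL, conv_node = "CONVERT") {
  medians <- marker_medians(train)
  train_imp <- impute_median(train, medians)
  selection <- NULL
  if (is.null(markers)) {
    if (config$selection == "none") {
      markers <- marker_names(train)
    } else {
      selection <- tryCatch(
        select_markers(train_imp, alpha = config$alpha,
                       penalty_rule = config$lasso_penalty,
                       seed = config$seed),
        mcinet_data_error = function(e) NULL)
      if (is.null(selection)) return(NULL)  # nothing survives: caller flags fold
      markers <- selection$lasso_survivors
      if (length(markers) == 0L) {
        markers <- selection$anova_survivors
        warning("lasso eliminated every marker; falling back to ANOVA survivors")
      }
    }
  }
  model <- discretize_fit(train_imp, bins = config$bins, markers = markers)
  dd <- discrete_frame(model, train_imp, conv_node)
  card <- discrete_cardinality(model, conv_node)
  dag <- mmhc(dd, card, ci_alpha = config$ci_alpha, score = config$score,
              ess = config$ess, max_sx = config$max_sx)
  pruned <- tryCatch(prune_disconnected(dag, conv_node),
                     mcinet_data_error = function(e) NULL)
  if (is.null(pruned)) return(NULL)  # conversion node isolated
  net <- fit_cpts(pruned$dag, dd, card, ess = config$ess,
                  state_labels = stats::setNames(list(c("0", "1")), conv_node))
  list(medians = medians, selection = selection, markers = markers,
       model = model, dag = dag, pruned = pruned, net = net,
       prevalence = mean(train$label))
}

score_pipeline <- function(fit, test) {
  test_imp <- impute_median(test, fit$medians)
  predict_conversion(fit$net, fit$model, test_imp)
}

#' Cross-validated out-of-fold conversion probabilities
#'
#' For each fold, imputation, marker selection (when `selection = "inside"`),
#' discretization, structure learning and CPT fitting are all fit on the
#' training subjects only; the held-out subjects are then scored, so every
#' subject receives exactly one out-of-fold probability. A fold whose learned
#' network leaves the conversion node isolated (or where no marker survives
#' selection) is flagged and its subjects are scored with the training-fold
#' prevalence.
#'
#' @param t a [marker_table()].
#' @param config a [cv_config()].
#' @return a list with `probabilities` (per-subject out-of-fold P(convert)),
#'   `fold` (fold index per subject), `folds` (per-fold artifacts: selected
#'   markers, learned DAG, flagged status), `roc`, `metrics` and the
#'   resolved `config`.
#' @export
cross_validate <- function(t, config = cv_config()) {
  stopifnot(inherits(t, "marker_table"))
  filt <- filter_missing(t, config$max_missing)
  t <- filt$table

  global_markers <- NULL
  if (config$selection == "outside") {
    sel <- select_markers(impute_median(t), alpha = config$alpha,
                          penalty_rule = config$lasso_penalty,
                          seed = config$seed)
    global_markers <- sel$lasso_survivors
    if (length(global_markers) == 0L) global_markers <- sel$anova_survivors
  }

  fa <- kfold(t$label, k = config$k, stratified = TRUE, seed = config$seed)
  probs <- rep(NA_real_, n_subjects(t))
  names(probs) <- subject_ids(t)
  fold_art <- vector("list", config$k)
  for (f in seq_len(config$k)) {
    tr_idx <- which(fa$fold != f)
    te_idx <- which(fa$fold == f)
    train <- subset_subjects(t, tr_idx)
    test <- subset_subjects(t, te_idx)
    fit <- fit_pipeline(train, config, markers = global_markers)
    if (is.null(fit)) {
      warning(sprintf("fold %d: no predictive structure; scoring with training prevalence", f))
      probs[te_idx] <- mean(train$label)
      fold_art[[f]] <- list(flagged = TRUE, markers = character(0),
                            dag = NULL, removed = character(0))
      next
    }
    probs[te_idx] <- score_pipeline(fit, test)
    fold_art[[f]] <- list(flagged = FALSE, markers = fit$markers,
                          dag = fit$pruned$dag, removed = fit$pruned$removed)
  }
  roc <- roc_auc(probs, t$label)
  list(probabilities = probs,
       labels = t$label,
       fold = fa$fold,
       folds = fold_art,
       roc = roc,
       metrics = classification_metrics(probs, t$label, config$threshold),
       cleaning = filt$report,
       config = config)
}
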