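#' Split subjects into high- and low-risk groups by predicted probability
#'
#' Either the `k` highest and `k'` lowest predicted conversion probabilities
#' (`rule = "topk"`; the defaults of 11 highest vs 48 lowest suit a
#' ~300-subject cohort) or explicit
#' probability cutoffs. Ties at a boundary are broken by subject-id order, so
#' membership is deterministic.
#'
#' @param probabilities named numeric vector of conversion probabilities.
#' @param rule `"topk"` or `"cutoff"`.
#' @param high for `"topk"` the high-risk group size; for `"cutoff"` the
#'   lower bound of the high-risk group (inclusive).
#' @param low for `"topk"` the low-risk group size; for `"cutoff"` the upper
#'   bound of the low-risk group (inclusive).
#' @return a list with `high` and `low` subject-id vectors (disjoint).
#' @export
split_by_risk <- function(probabilities, rule = c("topk", "cutoff"),
                          high = 11L, low = 48L) {
  rule <- match.arg(rule)
  if (is.null(names(probabilities))) {
    names(probabilities) <- sprintf("S%04d", seq_along(probabilities))
  }
  ids <- names(probabilities)
  if (rule == "topk") {
    high <- check_count(high, "high")
    low <- check_count(low, "low")
    if (high + low > length(probabilities)) {
      stop_validation("high + low exceeds the number of subjects")
    }
    ord <- order(-probabilities, ids)
    high_ids <- ids[ord][seq_len(high)]
    ord2 <- order(probabilities, ids)
    low_ids <- ids[ord2][seq_len(low)]
    if (length(intersect(high_ids, low_ids)) > 0L) {
      stop_validation("high and low groups overlap; reduce group sizes")
    }
  } else {
    if (low >= high) {
      stop_validation("cutoffs overlap: low bound (%g) must be below high bound (%g)",
                      low, high)
    }
    high_ids <- ids[probabilities >= high]
    low_ids <- ids[probabilities <= low]
    if (length(high_ids) == 0L || length(low_ids) == 0L) {
      stop_validation("a risk group is empty under the given cutoffs")
    }
  }
  list(high = high_ids, low = low_ids)
}

#' State vectors of at-risk subjects against a reference group
#'
#' For each at-risk subject, the state vector is the marker panel z-scored
#' against the reference ("normal") group: `z_i = (x_i - mu_i) / sigma_i`
#' with `mu`, `sigma` the reference-group mean and sample standard deviation
#' (ddof = 1). Zero-variance reference markers are dropped with a warning.
#'
#' @param t a [marker_table()] with no missing entries on the panel.
#' @param panel character vector of marker names.
#' @param risk_ids subject ids of the at-risk group.
#' @param reference_ids subject ids of the reference group (>= 2).
#' @return a list with `panel` (markers kept), `z` (risk-subjects x panel
#'   matrix), `reference_mean` and `reference_sd`.
#' @export
make_states <- function(t, panel, risk_ids, reference_ids) {
  stopifnot(inherits(t, "marker_table"))
  if (length(reference_ids) < 2L) {
    stop_validation("reference group needs at least 2 subjects")
  }
  absent <- setdiff(panel, marker_names(t))
  if (length(absent) > 0L) {
    stop_validation("panel markers absent: %s", paste(absent, collapse = ", "))
  }
  ref <- t$values[reference_ids, panel, drop = FALSE]
  mu <- colMeans(ref)
  sdv <- apply(ref, 2L, stats::sd)
  bad <- sdv == 0 | is.na(sdv)
  if (any(bad)) {
    warning("zero-variance reference marker(s) dropped: ",
            paste(panel[bad], collapse = ", "))
    panel <- panel[!bad]; mu <- mu[!bad]; sdv <- sdv[!bad]
    if (length(panel) == 0L) stop_data("no usable markers left in panel")
  }
  x <- t$values[risk_ids, panel, drop = FALSE]
  z <- sweep(sweep(x, 2L, mu), 2L, sdv, "/")
  list(panel = panel, z = z, reference_mean = mu, reference_sd = sdv)
}

# Leave-one-out state vectors for the reference group itself: each member is
# z-scored against the remaining reference subjects, so its own values never
# enter the mean/sd it is compared to.
loo_states <- function(t, panel, reference_ids) {
  if (length(reference_ids) < 3L) {
    stop_validation("leave-one-out reference needs at least 3 subjects")
  }
  z <- matrix(NA_real_, length(reference_ids), length(panel),
              dimnames = list(reference_ids, panel))
  for (id in reference_ids) {
    others <- setdiff(reference_ids, id)
    ref <- t$values[others, panel, drop = FALSE]
    mu <- colMeans(ref)
    sdv <- apply(ref, 2L, stats::sd)
    sdv[sdv == 0] <- NA_real_
    z[id, ] <- (t$values[id, panel] - mu) / sdv
  }
  keep <- !apply(z, 2L, anyNA)
  if (!all(keep)) {
    warning("zero-variance leave-one-out reference marker(s) dropped: ",
            paste(panel[!keep], collapse = ", "))
  }
  list(panel = panel[keep], z = z[, keep, drop = FALSE])
}

#' Network-balance disruption parameters U, K and Phi
#'
#' For a subject's state z-vector over the marker panel:
#' `K = |mean(z)|` measures the consistent (same-direction) multi-marker
#' shift, `Phi = population sd(z)` the inconsistent (dispersed) variation,
#' and `U = rms(z)` responds to both comprehensively, with the exact
#' decomposition `U^2 = K^2 + Phi^2`. A subject at the reference state
#' (z = 0) has U = K = Phi = 0. The signed mean is reported alongside so the
#' direction of the consistent shift is not lost.
#'
#' @param z numeric state vector (non-empty).
#' @return a list with `U`, `K`, `Phi` and `signed_mean`.
#' @export
disruption <- function(z) {
  z <- as.numeric(z)
  if (length(z) == 0L || anyNA(z)) {
    stop_validation("z must be non-empty with no missing values")
  }
  m <- mean(z)
  phi <- sqrt(mean((z - m)^2))
  list(U = sqrt(mean(z^2)), K = abs(m), Phi = phi, signed_mean = m)
}

#' Subgroup disruption profile
#'
#' Compares the high-risk and low-risk subgroups: a per-marker ANOVA between
#' the two groups defines the significant panel (p < alpha); each subject's
#' state vector over that panel is z-scored against the low-risk (reference)
#' group; U, K and Phi are computed per subject and compared between groups
#' by one-way ANOVA; and the balance-map table (per-marker ratio of group
#' mean to reference mean, 1 on every axis for the reference group — a
#' regular polygon on a radar plot) is exported for plotting.
#'
#' @param t a [marker_table()] with no missing entries among its markers.
#' @param high_ids,low_ids disjoint subject-id groups; at least 2 high-risk
#'   and 3 low-risk (reference) subjects.
#' @param alpha significance level of the marker ANOVA; default 0.05.
#' @return a `subgroup_result` list: the groups, per-marker p-values, the
#'   significant panel, per-subject disruption parameters, group-comparison
#'   p-values for U/K/Phi, and the balance-map table.
#' @export
subgroup_profile <- function(t, high_ids, low_ids, alpha = 0.05) {
  stopifnot(inherits(t, "marker_table"))
  if (length(intersect(high_ids, low_ids)) > 0L) {
    stop_validation("high and low groups must be disjoint")
  }
  if (length(high_ids) < 2L || length(low_ids) < 3L) {
    stop_validation("need >= 2 high-risk and >= 3 low-risk subjects")
  }
  sub_idx <- match(c(high_ids, low_ids), subject_ids(t))
  if (anyNA(sub_idx)) stop_validation("unknown subject id in groups")
  sub <- subset_subjects(t, sub_idx)
  grp <- c(rep(1L, length(high_ids)), rep(0L, length(low_ids)))
  sub$label <- grp  # reuse the ANOVA screen machinery on the subgroup contrast
  screen <- suppressWarnings(anova_screen(sub, alpha))
  panel <- screen$anova_survivors
  panel_warning <- FALSE
  if (length(panel) == 0L) {
    warning("no marker separates the subgroups at alpha = ", alpha,
            "; profiling over the full panel")
    panel <- marker_names(t)
    panel_warning <- TRUE
  }

  states_high <- make_states(t, panel, high_ids, low_ids)
  # reference-group members are scored against the other reference subjects
  # (leave-one-out): scoring a subject against statistics it contributed to
  # shrinks its own deviations and would bias the group comparison of U
  states_low <- loo_states(t, states_high$panel, low_ids)
  common <- intersect(states_high$panel, states_low$panel)
  states_high$panel <- common
  states_high$z <- states_high$z[, common, drop = FALSE]
  states_high$reference_mean <- states_high$reference_mean[common]
  states_low$z <- states_low$z[, common, drop = FALSE]
  per_subject <- function(st, group) {
    do.call(rbind, lapply(rownames(st$z), function(id) {
      d <- disruption(st$z[id, ])
      data.frame(subject_id = id, group = group, U = d$U, K = d$K,
                 Phi = d$Phi, signed_mean = d$signed_mean,
                 stringsAsFactors = FALSE)
    }))
  }
  params <- rbind(per_subject(states_high, "high"),
                  per_subject(states_low, "low"))

  cmp_p <- vapply(c("U", "K", "Phi"), function(v) {
    x <- params[[v]]
    g <- factor(params$group, levels = c("low", "high"))
    if (stats::var(x) == 0) return(1)
    stats::oneway.test(x ~ g, var.equal = TRUE)$p.value
  }, numeric(1))

  ref_mean <- states_high$reference_mean
  high_mean <- colMeans(t$values[high_ids, states_high$panel, drop = FALSE])
  balance <- data.frame(marker = states_high$panel,
                        high_ratio = unname(high_mean / ref_mean),
                        low_ratio = 1,
                        stringsAsFactors = FALSE)

  structure(list(high_ids = high_ids, low_ids = low_ids,
                 anova_p = screen$anova_p,
                 significant_panel = if (panel_warning) character(0) else panel,
                 panel_used = states_high$panel,
                 params = params,
                 group_means = stats::aggregate(params[c("U", "K", "Phi")],
                                                list(group = params$group),
                                                mean),
                 comparison_p = cmp_p,
                 balance_map = balance),
            class = "subgroup_result")
}
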