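#' ANOVA screen of markers between converters and non-converters
#'
#' First selection stage: a one-way ANOVA F-test per marker between the two
#' label groups; survivors are the markers with p below `alpha` (raw p-values,
#' no multiplicity correction, matching the screening design; an optional
#' Benjamini-Hochberg adjustment is available).
#'
#' @param t a [marker_table()] (missing entries are dropped per marker).
#' @param alpha significance level for survival; default 0.05.
#' @param adjust `"none"` (default) for raw p-values or `"BH"` for
#'   Benjamini-Hochberg adjusted p-values.
#' @return a list with `anova_p` (named p-value vector), `anova_survivors`
#'   (marker names with p < alpha) and `alpha`.
#' @export
anova_screen <- function(t, alpha = 0.05, adjust = c("none", "BH")) {
  stopifnot(inherits(t, "marker_table"))
  adjust <- match.arg(adjust)
  g <- factor(t$label, levels = c(0L, 1L))
  if (any(table(g) < 2L)) {
    stop_data("each label group needs at least 2 subjects")
  }
  pvals <- vapply(seq_len(ncol(t$values)), function(j) {
    x <- t$values[, j]
    ok <- !is.na(x)
    xs <- x[ok]; gs <- g[ok]
    if (length(unique(gs)) < 2L || any(table(gs) < 2L)) return(NA_real_)
    # classic equal-variance one-way ANOVA; degenerate zero-variance case
    # (F = 0/0) is mapped to p = 1
    if (stats::var(xs) == 0) {
      warning(sprintf("marker %s has zero variance; p set to 1",
                      marker_names(t)[j]))
      return(1)
    }
    ft <- stats::oneway.test(xs ~ gs, var.equal = TRUE)
    p <- unname(ft$p.value)
    if (is.na(p)) {
      # zero within-group variance with identical means
      warning(sprintf("degenerate F = 0/0 for marker %s; p set to 1",
                      marker_names(t)[j]))
      p <- 1
    }
    p
  }, numeric(1))
  names(pvals) <- marker_names(t)
  p_used <- if (adjust == "BH") stats::p.adjust(pvals, "BH") else pvals
  list(anova_p = pvals,
       anova_p_adjusted = if (adjust == "BH") p_used else NULL,
       anova_survivors = marker_names(t)[!is.na(p_used) & p_used < alpha],
       alpha = alpha)
}

#' LARS path for the lasso
#'
#' Traces the full piecewise-linear lasso coefficient path by least angle
#' regression with the lasso modification: predictors enter the active set at
#' equiangular knots and are dropped when a coefficient crosses zero. The
#' objective is `(1/2) * sum((y - X b)^2) + lambda * sum(|b|)`.
#'
#' @param X numeric design matrix with standardized columns (mean 0, common
#'   scale); no constant columns.
#' @param y centered numeric response.
#' @param max_steps safety cap on path steps.
#' @return an object of class `lars_path`: `lambda` (knot penalties, strictly
#'   decreasing, starting at `max |X'y|` and ending at 0 when the final active
#'   set admits an OLS solution) and `beta` (p x length(lambda) coefficient
#'   matrix at the knots; the path is linear in lambda between knots).
#' @export
lars_path <- function(X, y, max_steps = 8L * ncol(X) + 10L) {
  X <- as.matrix(X)
  if (!is.numeric(X) || !is.numeric(y) || nrow(X) != length(y)) {
    stop_validation("X must be numeric with rows matching length(y)")
  }
  n <- nrow(X); p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("V%d", seq_len(p))
  xty <- drop(crossprod(X, y))
  lambda_max <- max(abs(xty))
  knots_lambda <- lambda_max
  knots_beta <- matrix(0, p, 1L, dimnames = list(colnames(X), NULL))
  if (lambda_max < 1e-12) {
    # response orthogonal to every column: the path is identically zero
    return(structure(list(lambda = c(lambda_max, 0), var_names = colnames(X),
                          beta = cbind(knots_beta, 0)),
                     class = "lars_path"))
  }

  active <- which(abs(abs(xty) - lambda_max) < 1e-9 * max(1, lambda_max))
  active <- active[order(colnames(X)[active])]
  lambda <- lambda_max
  max_active <- min(n - 1L, p)

  for (step in seq_len(max_steps)) {
    XA <- X[, active, drop = FALSE]
    G <- crossprod(XA)
    qrG <- qr(G)
    if (qrG$rank < length(active)) {
      warning("rank-deficient active set; dropping last-entered predictor and stopping path")
      active <- active[-length(active)]
      break
    }
    # current correlations determine the sign vector on the active set
    r <- y - X %*% knots_beta[, ncol(knots_beta)]
    cA <- drop(crossprod(XA, r))
    s <- sign(cA)
    s[s == 0] <- 1
    a_vec <- solve(qrG, xty[active])      # OLS on active set
    b_vec <- solve(qrG, s)                # direction per unit lambda
    # beta_A(lam) = a_vec - lam * b_vec for lam in (next_knot, lambda]

    # candidate: an active coefficient crosses zero
    lam_zero <- a_vec / b_vec
    drop_ok <- is.finite(lam_zero) & lam_zero > 1e-10 &
      lam_zero < lambda - 1e-10
    lam_drop <- if (any(drop_ok)) max(lam_zero[drop_ok]) else -Inf

    # candidate: an inactive predictor reaches the active correlation
    inactive <- setdiff(seq_len(p), active)
    lam_in <- -Inf
    enter_j <- integer(0)
    if (length(inactive) > 0) {
      Xi <- X[, inactive, drop = FALSE]
      u <- drop(crossprod(Xi, y - X[, active, drop = FALSE] %*% a_vec))
      v <- drop(crossprod(Xi, X[, active, drop = FALSE] %*% b_vec))
      # |u + lam*v| = lam  =>  lam = u/(1-v) or -u/(1+v)
      cand <- cbind(u / (1 - v), -u / (1 + v))
      cand[!is.finite(cand) | cand <= 1e-10 | cand >= lambda - 1e-10] <- -Inf
      best <- max(cand)
      if (is.finite(best)) {
        lam_in <- best
        hits <- which(apply(cand, 1L, function(z) any(abs(z - best) < 1e-9)))
        enter_j <- inactive[hits]
      }
    }

    nxt <- max(lam_drop, lam_in, 0)
    beta_next <- numeric(p)
    beta_next[active] <- a_vec - nxt * b_vec
    knots_lambda <- c(knots_lambda, nxt)
    knots_beta <- cbind(knots_beta, beta_next)
    lambda <- nxt

    if (nxt <= 0) break
    if (lam_drop >= lam_in) {
      gone <- active[abs(a_vec - nxt * b_vec) < 1e-9]
      active <- setdiff(active, gone)
      if (length(active) == 0L) {
        # restart from the remaining correlations if anything is left
        r <- y - X %*% beta_next
        ct <- abs(drop(crossprod(X, r)))
        if (max(ct) < nxt - 1e-9) break
        active <- which(abs(ct - max(ct)) < 1e-9)
      }
    } else {
      if (length(active) >= max_active) break
      enter_j <- enter_j[order(colnames(X)[enter_j])]
      active <- c(active, enter_j[1L])
    }
  }
  structure(list(lambda = knots_lambda, var_names = colnames(X),
                 beta = knots_beta),
            class = "lars_path")
}

#' Coefficients along a LARS path at arbitrary penalties
#'
#' Linear interpolation between path knots (the lasso path is piecewise linear
#' in the penalty). Penalties above the first knot give the zero vector;
#' penalties below the last knot return the last knot's coefficients.
#'
#' @param path a [lars_path()] object.
#' @param lambda numeric vector of penalty values.
#' @return p x length(lambda) coefficient matrix.
#' @export
lars_coef <- function(path, lambda) {
  stopifnot(inherits(path, "lars_path"))
  kl <- path$lambda
  out <- matrix(0, nrow(path$beta), length(lambda),
                dimnames = list(path$var_names, NULL))
  for (i in seq_along(lambda)) {
    lam <- lambda[i]
    if (lam >= kl[1L]) next
    if (lam <= kl[length(kl)]) {
      out[, i] <- path$beta[, length(kl)]
      next
    }
    hi <- max(which(kl >= lam))
    lo <- hi + 1L
    w <- (kl[hi] - lam) / (kl[hi] - kl[lo])
    out[, i] <- (1 - w) * path$beta[, hi] + w * path$beta[, lo]
  }
  out
}

#' Second-stage lasso selection against ADAS-cog
#'
#' Regresses the ADAS-cog score on the ANOVA-surviving markers with an
#' L1 penalty solved by [lars_path()]. Markers are standardized internally;
#' reported coefficients are on the original scale. The penalty is chosen by
#' 10-fold cross-validation over the path (minimum mean squared prediction
#' error) unless a fixed value is given.
#'
#' @param t a [marker_table()] with no missing entries among `survivors`.
#' @param survivors character vector of marker names to offer to the lasso
#'   (typically `anova_survivors` from [anova_screen()]).
#' @param penalty_rule `"cv"` (default) or a single non-negative number used
#'   as a fixed penalty on the standardized scale.
#' @param n_folds folds for the CV rule.
#' @param seed seed for the CV fold assignment.
#' @return a list with the fitted `path`, `chosen_penalty`,
#'   `coefficients` (original scale, at the chosen penalty),
#'   `lasso_survivors` (markers with nonzero coefficient) and `cv_mse`
#'   (NULL under a fixed penalty).
#' @export
lasso_select <- function(t, survivors, penalty_rule = "cv", n_folds = 10L,
                         seed = 1L) {
  stopifnot(inherits(t, "marker_table"))
  if (length(survivors) == 0L) stop_validation("`survivors` must be non-empty")
  missing_m <- setdiff(survivors, marker_names(t))
  if (length(missing_m) > 0L) {
    stop_validation("survivors absent from table: %s",
                    paste(missing_m, collapse = ", "))
  }
  X <- t$values[, survivors, drop = FALSE]
  if (anyNA(X)) stop_data("impute missing entries before lasso selection")
  y <- t$adas
  n <- nrow(X)

  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  if (any(sdv == 0)) {
    warning("constant marker(s) removed before lasso: ",
            paste(survivors[sdv == 0], collapse = ", "))
    survivors <- survivors[sdv > 0]
    X <- X[, survivors, drop = FALSE]
    mu <- mu[survivors]; sdv <- sdv[survivors]
    if (length(survivors) == 0L) stop_data("no non-constant survivors left")
  }
  Xs <- scale(X, center = mu, scale = sdv)
  yc <- y - mean(y)

  path <- lars_path(Xs, yc)

  cv_mse <- NULL
  if (identical(penalty_rule, "cv")) {
    if (n < n_folds) {
      stop_data("fewer than %d subjects; use a fixed penalty instead", n_folds)
    }
    lam_max <- path$lambda[1L]
    grid <- exp(seq(log(lam_max), log(max(lam_max * 1e-3, 1e-8)),
                    length.out = 50L))
    folds <- kfold(t$label, k = n_folds, stratified = all(table(t$label) >= n_folds),
                   seed = seed)$fold
    err <- matrix(NA_real_, n_folds, length(grid))
    for (f in seq_len(n_folds)) {
      tr <- folds != f
      mu_f <- colMeans(X[tr, , drop = FALSE])
      sd_f <- apply(X[tr, , drop = FALSE], 2L, stats::sd)
      sd_f[sd_f == 0] <- 1
      Xtr <- scale(X[tr, , drop = FALSE], mu_f, sd_f)
      ybar <- mean(y[tr])
      pf <- lars_path(Xtr, y[tr] - ybar)
      B <- lars_coef(pf, grid)
      Xte <- scale(X[!tr, , drop = FALSE], mu_f, sd_f)
      pred <- sweep(Xte %*% B, 2L, -ybar)  # adds the training mean back
      err[f, ] <- colMeans((y[!tr] - pred)^2)
    }
    cv_mse <- colMeans(err)
    chosen <- grid[which.min(cv_mse)]
  } else {
    chosen <- as.numeric(penalty_rule)
    if (is.na(chosen) || chosen < 0) {
      stop_validation("penalty_rule must be \"cv\" or a non-negative number")
    }
  }

  beta_std <- drop(lars_coef(path, chosen))
  nz <- abs(beta_std) > 1e-10
  if (!any(nz)) {
    warning("chosen penalty shrinks every coefficient to zero; no lasso survivors")
  }
  coef_orig <- beta_std / sdv
  list(path = path,
       chosen_penalty = chosen,
       coefficients = coef_orig,
       lasso_survivors = survivors[nz],
       cv_mse = cv_mse)
}

#' Run both selection stages
#'
#' Convenience wrapper: [anova_screen()] then [lasso_select()] on the
#' survivors, returning the combined funnel record.
#'
#' @inheritParams anova_screen
#' @inheritParams lasso_select
#' @return a `selection_result` list: per-marker ANOVA p-values, survivors at
#'   each stage, the lasso path and chosen penalty.
#' @export
select_markers <- function(t, alpha = 0.05, penalty_rule = "cv", seed = 1L) {
  stage1 <- anova_screen(t, alpha)
  if (length(stage1$anova_survivors) == 0L) {
    stop_data("no markers pass the ANOVA screen at alpha = %g", alpha)
  }
  stage2 <- lasso_select(t, stage1$anova_survivors, penalty_rule, seed = seed)
  structure(c(stage1, stage2), class = "selection_result")
}
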