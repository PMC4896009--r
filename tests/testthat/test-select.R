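make_table <- function(vals, adas = NULL, label) {
  if (is.null(adas)) adas <- runif(nrow(vals), 5, 30)
  marker_table(vals, adas, label)
}

test_that("two-group ANOVA matches the squared-t closed form", {
  # worked case: [1,2] vs [3,4] gives F = 8, p = P(F_{1,2} > 8) ~ 0.10557
  vals <- matrix(c(1, 2, 3, 4), 4, 1, dimnames = list(NULL, "m"))
  t <- make_table(vals, label = c(0, 0, 1, 1))
  scr <- anova_screen(t)
  expect_equal(unname(scr$anova_p["m"]), 2 * pt(2 * sqrt(2), df = 2,
                                                lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(unname(scr$anova_p["m"]), 0.1055728, tolerance = 1e-6)

  # random datasets: ANOVA p equals two-sample t-test p (equal variances)
  set.seed(31)
  for (r in 1:25) {
    n <- sample(6:30, 1)
    lab <- c(rep(0, ceiling(n / 2)), rep(1, floor(n / 2)))
    x <- rnorm(n) + 0.5 * lab
    tt <- t.test(x[lab == 1], x[lab == 0], var.equal = TRUE)
    t2 <- make_table(matrix(x, ncol = 1, dimnames = list(NULL, "m")),
                     label = lab)
    expect_equal(unname(anova_screen(t2)$anova_p["m"]), tt$p.value,
                 tolerance = 1e-12)
  }
})

test_that("identical groups give F = 0 and p = 1", {
  vals <- matrix(c(1, 2, 3, 1, 2, 3), 6, 1, dimnames = list(NULL, "m"))
  t <- make_table(vals, label = c(0, 0, 0, 1, 1, 1))
  expect_equal(unname(anova_screen(t)$anova_p["m"]), 1, tolerance = 1e-12)
  # degenerate 0/0 case: constant marker
  vals2 <- matrix(rep(2, 6), 6, 1, dimnames = list(NULL, "m"))
  t2 <- make_table(vals2, label = c(0, 0, 0, 1, 1, 1))
  expect_warning(scr <- anova_screen(t2), "zero variance|degenerate")
  expect_equal(unname(scr$anova_p["m"]), 1)
})

test_that("ANOVA screen has full power on strongly informative markers", {
  g <- generate_cohort(cohort_spec(n_subjects = 1000, n_markers = 40,
                                   n_informative = 8, effect_size = 1.5,
                                   missing_fraction = 0, seed = 19))
  scr <- anova_screen(g$table, alpha = 0.05)
  expect_true(all(g$ground_truth$informative_markers %in%
                    scr$anova_survivors))
})

test_that("screen p-values are invariant to subject order and marker scale", {
  g <- tiny_cohort(seed = 23)
  t <- g$table
  p1 <- anova_screen(t)$anova_p
  set.seed(1)
  perm <- sample(n_subjects(t))
  tp <- marker_table(t$values[perm, ], t$adas[perm], t$label[perm], t$source)
  p2 <- anova_screen(tp)$anova_p
  expect_equal(p1, p2, tolerance = 1e-12)
  ts <- t
  ts$values[, 1] <- ts$values[, 1] * 1000
  p3 <- anova_screen(ts)$anova_p
  expect_equal(p1, p3, tolerance = 1e-10)
})

test_that("LARS path matches the orthogonal-design soft-threshold form", {
  x <- matrix(c(-1, 0, 1), 3, 1)
  y <- c(-2, 0, 2)
  path <- lars_path(x, y)
  # beta(lambda) = sign(b) max(|b| - lambda, 0) / sum(x^2), b = 4, sum = 2
  expect_equal(drop(lars_coef(path, 1)), 1.5, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(drop(lars_coef(path, 4)), 0, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(drop(lars_coef(path, 5)), 0, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(drop(lars_coef(path, 0)), 2, tolerance = 1e-12,
               ignore_attr = TRUE)

  # two orthogonal predictors soft-threshold independently
  X <- cbind(a = c(-1, 0, 1, 0), b = c(0, -1, 0, 1))
  y2 <- c(-3, -1, 3, 1)
  path2 <- lars_path(X, y2)
  for (lam in c(0, 1, 2.5, 5, 7)) {
    expected <- sign(crossprod(X, y2)) *
      pmax(abs(crossprod(X, y2)) - lam, 0) / colSums(X^2)
    expect_equal(drop(lars_coef(path2, lam)), drop(expected),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("a response orthogonal to all columns yields the zero path", {
  X <- cbind(a = c(-1, 1, -1, 1), b = c(-1, -1, 1, 1))
  y <- c(1, -1, -1, 1)  # orthogonal to both columns
  path <- lars_path(X, y)
  expect_true(all(abs(path$beta) < 1e-12))
})

test_that("the path is piecewise linear and starts at all-zero", {
  set.seed(77)
  X <- scale(matrix(rnorm(40 * 5), 40, 5))
  y <- drop(X %*% c(2, -1, 0, 0, 0.5)) + rnorm(40)
  y <- y - mean(y)
  path <- lars_path(X, y)
  expect_true(all(diff(path$lambda) < 0))
  expect_true(all(path$beta[, 1] == 0))
  # interior points interpolate their knots linearly
  for (k in seq_len(length(path$lambda) - 1)) {
    mid <- (path$lambda[k] + path$lambda[k + 1]) / 2
    expect_equal(drop(lars_coef(path, mid)),
                 drop((path$beta[, k] + path$beta[, k + 1]) / 2),
                 tolerance = 1e-9)
  }
})

test_that("lasso selection at zero penalty recovers OLS survivors", {
  set.seed(12)
  n <- 50
  vals <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("M", 1:4)))
  adas <- 10 + 2 * vals[, 1] - 3 * vals[, 3] + rnorm(n, 0, 0.5)
  t <- marker_table(vals, adas, rep(c(0, 1), n / 2))
  res <- lasso_select(t, paste0("M", 1:4), penalty_rule = 0)
  ols <- coef(lm(adas ~ vals))[-1]
  expect_setequal(res$lasso_survivors, paste0("M", 1:4)[abs(ols) > 1e-10])
  expect_equal(unname(res$coefficients), unname(ols), tolerance = 1e-6)
})

test_that("a penalty at or above max|X'y| empties the survivor set", {
  set.seed(14)
  vals <- matrix(rnorm(40 * 3), 40, 3, dimnames = list(NULL, paste0("M", 1:3)))
  t <- marker_table(vals, 10 + vals[, 1] + rnorm(40, 0, 0.1),
                    rep(c(0, 1), 20))
  Xs <- scale(vals)
  lam_max <- max(abs(crossprod(Xs, t$adas - mean(t$adas))))
  expect_warning(res <- lasso_select(t, paste0("M", 1:3),
                                     penalty_rule = lam_max * 1.01),
                 "zero")
  expect_length(res$lasso_survivors, 0)
})

test_that("CV-tuned lasso recovers most ADAS-informative markers", {
  hits <- 0L
  total <- 0L
  for (s in 1:5) {
    g <- generate_cohort(cohort_spec(n_subjects = 1000, n_markers = 50,
                                     n_informative = 6, effect_size = 1.2,
                                     missing_fraction = 0, seed = 100 + s))
    scr <- anova_screen(g$table)
    res <- lasso_select(g$table, scr$anova_survivors, seed = s)
    hits <- hits + length(intersect(res$lasso_survivors,
                                    g$ground_truth$informative_markers))
    total <- total + length(g$ground_truth$informative_markers)
  }
  expect_gte(hits / total, 5 / 6)
})

test_that("the selection funnel is monotone", {
  g <- generate_cohort(cohort_spec(n_subjects = 300, n_markers = 60,
                                   n_informative = 8, effect_size = 1.2,
                                   missing_fraction = 0, seed = 41))
  sel <- select_markers(g$table, seed = 2)
  expect_lte(length(sel$lasso_survivors), length(sel$anova_survivors))
  expect_lte(length(sel$anova_survivors), ncol(g$table$values))
  expect_true(all(sel$lasso_survivors %in% sel$anova_survivors))
})
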