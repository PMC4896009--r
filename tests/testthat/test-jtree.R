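test_that("CPT fitting matches counts, smoothing and the uniform fallback", {
  nodes <- c("P", "X")
  dag <- bn_dag(nodes, data.frame(from = "P", to = "X"))
  d <- cbind(P = c(1L, 1L, 1L, 2L), X = c(2L, 2L, 1L, 2L))
  card <- setNames(c(2L, 2L), nodes)

  # parentless binary node, ess = 0: raw MLE
  net0 <- fit_cpts(dag, d, card, ess = 0)
  expect_equal(net0$cpts$P$values, c(0.75, 0.25))
  # child CPT given the observed parent config equals raw frequencies
  expect_equal(net0$cpts$X$values[1:2], c(1 / 3, 2 / 3))

  # unseen parent configuration with ess = 1 falls back to uniform
  d2 <- cbind(P = rep(1L, 4), X = c(1L, 2L, 1L, 2L))
  net1 <- fit_cpts(dag, d2, card, ess = 1)
  expect_equal(net1$cpts$X$values[3:4], c(0.5, 0.5))
  # CPT columns sum to one
  expect_equal(sum(net1$cpts$P$values), 1, tolerance = 1e-9)
  expect_equal(colSums(matrix(net1$cpts$X$values, 2)), c(1, 1),
               tolerance = 1e-9)
})

test_that("a chain yields the textbook clique tree", {
  dag <- bn_dag(c("A", "B", "C"),
                data.frame(from = c("A", "B"), to = c("B", "C")))
  d <- sample_recovery(500, 1)[, c("A", "B", "C")]
  net <- fit_cpts(dag, d, setNames(rep(2L, 3), c("A", "B", "C")))
  jt <- build_junction_tree(net)
  expect_setequal(lapply(jt$cliques, paste, collapse = ","),
                  list("A,B", "B,C"))
  expect_identical(jt$separators[[1]], "B")
})

test_that("a single-node network has one clique holding its CPT", {
  dag <- bn_dag("A")
  d <- matrix(c(1L, 2L, 1L), ncol = 1, dimnames = list(NULL, "A"))
  net <- fit_cpts(dag, d, c(A = 2L), ess = 0)
  jt <- build_junction_tree(net)
  expect_length(jt$cliques, 1)
  expect_equal(jt$potentials[[1]]$values, net$cpts$A$values)
})

test_that("clique marginals match brute-force enumeration", {
  set.seed(90)
  worst <- 0
  for (r in 1:20) {
    net <- random_binary_net(sample(3:8, 1))
    jt <- build_junction_tree(net)
    for (v in net$dag$nodes) {
      oracle <- enum_query(net, v)
      post <- query(jt, v)
      worst <- max(worst, 0.5 * sum(abs(post$distribution - oracle)))
    }
  }
  expect_lt(worst, 1e-10)
})

test_that("posteriors under evidence match enumeration, including full evidence", {
  set.seed(91)
  worst <- 0
  for (r in 1:10) {
    net <- random_binary_net(6)
    jt <- build_junction_tree(net)
    for (q in 1:5) {
      target <- sample(net$dag$nodes, 1)
      others <- setdiff(net$dag$nodes, target)
      nev <- sample(seq_along(others), 1)
      ev <- as.list(setNames(sample(1:2, nev, TRUE),
                             sample(others, nev)))
      post <- query(jt, target, ev)
      oracle <- enum_query(net, target, ev)
      worst <- max(worst, 0.5 * sum(abs(post$distribution - oracle)))
      expect_equal(sum(post$distribution), 1, tolerance = 1e-9)
    }
    # evidence fixing all non-target nodes: posterior is the joint slice
    target <- net$dag$nodes[1]
    ev_all <- as.list(setNames(sample(1:2, length(net$dag$nodes) - 1, TRUE),
                               setdiff(net$dag$nodes, target)))
    expect_equal(unname(query(jt, target, ev_all)$distribution),
                 enum_query(net, target, ev_all), tolerance = 1e-10)
  }
  expect_lt(worst, 1e-10)
})

test_that("calibration is idempotent and separator marginals agree", {
  set.seed(92)
  net <- random_binary_net(6)
  jt <- build_junction_tree(net)
  jt2 <- calibrate(jt)
  for (i in seq_along(jt$beliefs)) {
    expect_equal(jt$beliefs[[i]]$values, jt2$beliefs[[i]]$values,
                 tolerance = 1e-12)
  }
  for (e in seq_len(nrow(jt$tree))) {
    sep <- jt$separators[[e]]
    if (length(sep) == 0) next
    m1 <- mcinet:::factor_marginalize(jt$beliefs[[jt$tree$from[e]]], sep)
    m2 <- mcinet:::factor_marginalize(jt$beliefs[[jt$tree$to[e]]], sep)
    expect_equal(m1$values, m2$values, tolerance = 1e-9)
  }
})

test_that("impossible evidence and misuse raise the documented errors", {
  d <- cbind(A = c(1L, 1L, 2L, 2L), B = c(1L, 1L, 2L, 2L))
  dag <- bn_dag(c("A", "B"), data.frame(from = "A", to = "B"))
  net <- fit_cpts(dag, d, c(A = 2L, B = 2L), ess = 0)
  jt <- build_junction_tree(net)
  # A and B are deterministically equal with ess = 0: opposite states impossible
  expect_error(query(jt, "A", list(B = 1L, A = 2L)), "must not appear")
  net2 <- fit_cpts(dag, d, c(A = 2L, B = 2L), ess = 0)
  jt2 <- build_junction_tree(net2)
  p <- query(jt2, "A", list(B = 1L))
  expect_equal(unname(p$distribution), c(1, 0))

  # a state with zero probability under the fitted joint is inconsistent
  d3 <- cbind(A = rep(1L, 6), B = rep(c(1L, 2L), 3))
  net3 <- fit_cpts(dag, d3, c(A = 2L, B = 2L), ess = 0)
  jt3 <- build_junction_tree(net3)
  expect_error(query(jt3, "B", list(A = 2L)), "zero probability")
})

test_that("queries with no evidence return priors on parentless nodes", {
  set.seed(93)
  net <- random_binary_net(4)
  jt <- build_junction_tree(net)
  roots <- setdiff(net$dag$nodes, net$dag$edges$to)
  for (v in roots) {
    expect_equal(unname(query(jt, v)$distribution),
                 net$cpts[[v]]$values, tolerance = 1e-10)
  }
})

test_that("predicted conversion probabilities separate true converters", {
  g <- generate_cohort(cohort_spec(n_subjects = 1000, n_markers = 20,
                                   n_informative = 6, effect_size = 1.5,
                                   missing_fraction = 0, seed = 33))
  t <- g$table
  model <- discretize_fit(t, bins = 3,
                          markers = g$ground_truth$informative_markers)
  dd <- mcinet:::discrete_frame(model, t)
  card <- mcinet:::discrete_cardinality(model)
  dag <- mmhc(dd, card)
  pruned <- prune_disconnected(dag, "CONVERT")
  net <- fit_cpts(pruned$dag, dd, card,
                  state_labels = list(CONVERT = c("0", "1")))
  probs <- predict_conversion(net, model, t)
  expect_gt(mean(probs[t$label == 1L]), mean(probs[t$label == 0L]))
  # determinism: an identical subject gets an identical probability
  t2 <- t
  t2$values[2, ] <- t2$values[1, ]
  probs2 <- predict_conversion(net, model, t2)
  expect_equal(unname(probs2[1]), unname(probs2[2]), tolerance = 1e-12)
})
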