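card2 <- function(nodes) setNames(rep(2L, length(nodes)), nodes)

test_that("G2 test detects perfect dependence and respects the null", {
  set.seed(50)
  x <- sample(1:2, 200, TRUE)
  d <- cbind(X = x, Y = x)
  expect_lt(as.numeric(ci_test(d, "X", "Y", card = card2(c("X", "Y")))), 1e-6)

  # under independence the rejection rate at 0.05 stays within binomial bounds
  rej <- 0L
  reps <- 200L
  for (r in seq_len(reps)) {
    d <- cbind(X = sample(1:2, 400, TRUE), Y = sample(1:2, 400, TRUE))
    p <- as.numeric(ci_test(d, "X", "Y", card = card2(c("X", "Y"))))
    if (p < 0.05) rej <- rej + 1L
  }
  bounds <- qbinom(c(0.005, 0.995), reps, 0.05)
  expect_gte(rej, bounds[1])
  expect_lte(rej, bounds[2])
})

test_that("G2 conditioning separates a chain and flags unreliable tests", {
  ok <- 0L
  for (s in 1:20) {
    d <- sample_recovery(5000, 400 + s)[, c("A", "B", "C")]
    p <- as.numeric(ci_test(d, "A", "C", "B", card = card2(c("A", "B", "C"))))
    if (p > 0.05) ok <- ok + 1L
  }
  expect_gte(ok, 18L)

  # n below 5 * df is declared unreliable and treated as independence
  d <- cbind(X = rep(1:2, 2), Y = rep(1:2, each = 2))
  p <- ci_test(d, "X", "Y", card = card2(c("X", "Y")))
  expect_false(attr(p, "reliable"))
  expect_equal(as.numeric(p), 1)

  expect_error(ci_test(d, "X", "X", card = card2(c("X", "Y"))), "differ")
})

test_that("MMPC recovers chain and collider skeletons", {
  set.seed(60)
  d <- sample_recovery(5000, 1)[, c("A", "B", "C")]
  pc <- mmpc(d, card2(c("A", "B", "C")))
  expect_identical(pc$A, "B")
  expect_setequal(pc$B, c("A", "C"))
  expect_identical(pc$C, "B")

  # collider A -> C <- B with A independent of B
  n <- 5000
  a <- rbinom(n, 1, 0.5) + 1L
  b <- rbinom(n, 1, 0.5) + 1L
  pC <- ifelse(a == 2L & b == 2L, 0.9, ifelse(a == 2L | b == 2L, 0.55, 0.05))
  cc <- ifelse(runif(n) < pC, 2L, 1L)
  d2 <- cbind(A = a, B = b, C = cc)
  pc2 <- mmpc(d2, card2(c("A", "B", "C")))
  expect_setequal(pc2$C, c("A", "B"))
  expect_identical(pc2$A, "C")
  expect_identical(pc2$B, "C")

  # fully independent columns give empty PC sets
  d3 <- cbind(A = sample(1:2, 2000, TRUE), B = sample(1:2, 2000, TRUE),
              C = sample(1:2, 2000, TRUE))
  pc3 <- mmpc(d3, card2(c("A", "B", "C")))
  expect_true(all(lengths(pc3) == 0))
})

test_that("hill climbing finds the score optimum among all 3-node DAGs", {
  set.seed(70)
  d <- sample_recovery(5000, 9)[, c("A", "B", "C")]
  card <- card2(c("A", "B", "C"))
  skel <- list(A = c("B", "C"), B = c("A", "C"), C = c("A", "B"))
  dag <- hill_climb(d, skel, card)

  # oracle: enumerate every DAG on 3 labelled nodes (25 of them) and score
  nodes <- c("A", "B", "C")
  pairs <- t(combn(nodes, 2))
  best_score <- -Inf
  states <- expand.grid(e1 = 0:2, e2 = 0:2, e3 = 0:2)  # 0 none, 1 fwd, 2 rev
  n_dags <- 0L
  for (r in seq_len(nrow(states))) {
    edges <- data.frame(from = character(0), to = character(0))
    for (k in 1:3) {
      s <- states[r, k]
      if (s == 1) edges <- rbind(edges, data.frame(from = pairs[k, 1], to = pairs[k, 2]))
      if (s == 2) edges <- rbind(edges, data.frame(from = pairs[k, 2], to = pairs[k, 1]))
    }
    g <- tryCatch(bn_dag(nodes, edges), error = function(e) NULL)
    if (is.null(g)) next
    n_dags <- n_dags + 1L
    A <- matrix(0L, 3, 3, dimnames = list(nodes, nodes))
    if (nrow(g$edges) > 0) A[cbind(g$edges$from, g$edges$to)] <- 1L
    sc <- sum(vapply(nodes, function(v)
      mcinet:::score_family(d, v, rownames(A)[A[, v] == 1L], card), numeric(1)))
    if (sc > best_score) {
      best_score <- sc
      best_pattern <- cpdag(g)
    }
  }
  expect_identical(n_dags, 25L)
  expect_equal(attr(dag, "score"), best_score, tolerance = 1e-9)
  expect_identical(shd(cpdag(dag), best_pattern), 0L)
  # the optimum lies in the Markov equivalence class of the chain A-B-C
  chain <- bn_dag(nodes, data.frame(from = c("A", "B"), to = c("B", "C")))
  expect_identical(shd(cpdag(dag), cpdag(chain)), 0L)
})

test_that("an empty skeleton forces an empty DAG and scores never decrease", {
  set.seed(71)
  d <- sample_recovery(2000, 2)[, c("A", "B", "C")]
  card <- card2(c("A", "B", "C"))
  dag0 <- hill_climb(d, list(A = character(0), B = character(0),
                             C = character(0)), card)
  expect_identical(nrow(dag0$edges), 0L)
  empty_score <- sum(vapply(c("A", "B", "C"), function(v)
    mcinet:::score_family(d, v, character(0), card), numeric(1)))
  full <- hill_climb(d, list(A = c("B", "C"), B = c("A", "C"),
                             C = c("A", "B")), card)
  expect_gte(attr(full, "score"), empty_score)
})

test_that("pruning removes exactly the isolated nodes and guards the anchor", {
  dag <- bn_dag(c("X", "Y", "Z", "CONVERT"),
                data.frame(from = c("X", "CONVERT"), to = c("CONVERT", "Y")))
  res <- prune_disconnected(dag, "CONVERT")
  expect_identical(res$removed, "Z")
  expect_setequal(res$dag$nodes, c("X", "Y", "CONVERT"))

  full <- bn_dag(c("A", "B"), data.frame(from = "A", to = "B"))
  res2 <- prune_disconnected(full, "B")
  expect_length(res2$removed, 0)

  lonely <- bn_dag(c("A", "B", "CONVERT"),
                   data.frame(from = "A", to = "B"))
  expect_error(prune_disconnected(lonely, "CONVERT"), "isolated")
})

test_that("CPDAG orientation keeps v-structures and drops reversible arcs", {
  chain <- bn_dag(c("A", "B", "C"), data.frame(from = c("A", "B"),
                                               to = c("B", "C")))
  P <- cpdag(chain)
  expect_true(P["A", "B"] == 1L && P["B", "A"] == 1L)  # undirected
  # collider on the same skeleton: A -> B <- C
  collider <- bn_dag(c("A", "B", "C"), data.frame(from = c("A", "C"),
                                                  to = c("B", "B")))
  P2 <- cpdag(collider)
  expect_true(P2["A", "B"] == 1L && P2["B", "A"] == 0L)
  expect_true(P2["C", "B"] == 1L && P2["B", "C"] == 0L)
  # same skeleton, both edge marks differ: SHD 2
  expect_identical(shd(P, P2), 2L)
})

test_that("the learned DAG is acyclic whatever the data", {
  set.seed(80)
  for (r in 1:5) {
    nn <- sample(4:6, 1)
    net <- random_binary_net(nn)
    d <- sample_from_net(net, 800)
    dag <- mmhc(d, card2(net$dag$nodes))
    expect_s3_class(dag, "bn_dag")  # constructor rejects cycles
  }
})
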