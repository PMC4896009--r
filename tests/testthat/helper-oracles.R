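# Independent oracles and fixture builders shared across tests.
# These deliberately use brute force / closed forms, not the package's own
# code paths, so agreement is evidence of correctness.

# Brute-force posterior by enumerating the full joint of a bayes_net.
enum_query <- function(net, target, evidence = list()) {
  nodes <- net$dag$nodes
  grid <- expand.grid(lapply(net$card, seq_len))
  names(grid) <- nodes
  pr <- rep(1, nrow(grid))
  for (v in nodes) {
    f <- net$cpts[[v]]
    idx <- rep(1, nrow(grid))
    mult <- 1
    for (k in seq_along(f$vars)) {
      idx <- idx + (grid[[f$vars[k]]] - 1) * mult
      mult <- mult * f$card[k]
    }
    pr <- pr * f$values[idx]
  }
  keep <- rep(TRUE, nrow(grid))
  for (v in names(evidence)) keep <- keep & grid[[v]] == evidence[[v]]
  p <- tapply(pr[keep], factor(grid[[target]][keep],
                               levels = seq_len(net$card[[target]])), sum)
  p <- as.numeric(p)
  p[is.na(p)] <- 0
  p / sum(p)
}

# A random binary network: random DAG (via a random topological order) with
# random strictly positive CPTs.
random_binary_net <- function(n_nodes, edge_prob = 0.4) {
  nodes <- LETTERS[seq_len(n_nodes)]
  ord <- sample(nodes)
  from <- character(0); to <- character(0)
  if (n_nodes >= 2) {
    for (i in 2:n_nodes) {
      for (j in seq_len(i - 1)) {
        if (stats::runif(1) < edge_prob) {
          from <- c(from, ord[j]); to <- c(to, ord[i])
        }
      }
    }
  }
  dag <- bn_dag(nodes, data.frame(from = from, to = to))
  card <- stats::setNames(rep(2L, n_nodes), nodes)
  dummy <- matrix(sample(1:2, 50 * n_nodes, TRUE), 50, n_nodes,
                  dimnames = list(NULL, nodes))
  net <- fit_cpts(dag, dummy, card, ess = 1)
  for (v in nodes) {
    f <- net$cpts[[v]]
    m <- matrix(stats::runif(length(f$values), 0.05, 1), nrow = f$card[1])
    m <- sweep(m, 2, colSums(m), "/")
    net$cpts[[v]]$values <- as.numeric(m)
  }
  net
}

# Forward-sample n observations from a bayes_net (ancestral order).
sample_from_net <- function(net, n) {
  nodes <- net$dag$nodes
  A <- matrix(0L, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  if (nrow(net$dag$edges) > 0) {
    A[cbind(net$dag$edges$from, net$dag$edges$to)] <- 1L
  }
  ord <- character(0)
  left <- nodes
  while (length(left) > 0) {
    roots <- left[colSums(A[ord, left, drop = FALSE]) ==
                    colSums(A[, left, drop = FALSE])]
    ord <- c(ord, roots[1])
    left <- setdiff(left, roots[1])
  }
  out <- matrix(NA_integer_, n, length(nodes), dimnames = list(NULL, nodes))
  for (v in ord) {
    f <- net$cpts[[v]]
    pa <- setdiff(f$vars, v)
    r <- net$card[[v]]
    pidx <- rep(1L, n)
    mult <- 1L
    for (pv in pa) {
      k <- match(pv, f$vars)
      pidx <- pidx + (out[, pv] - 1L) * prod(f$card[seq_len(k - 1L)])
    }
    u <- stats::runif(n)
    for (cfg in unique(pidx)) {
      rows <- pidx == cfg
      probs <- f$values[(cfg - 1L) + seq_len(r)]
      # pidx already points at the first cell of the config block
      out[rows, v] <- findInterval(u[rows], cumsum(probs) / sum(probs)) + 1L
    }
  }
  out
}

# Fixed 6-node ground-truth DAG with strong CPTs (chain + fork + collider +
# one isolated node) used for structure-recovery tests.
recovery_truth <- function() {
  nodes <- c("A", "B", "C", "D", "E", "F")
  bn_dag(nodes, data.frame(from = c("A", "B", "A", "C", "D"),
                           to = c("B", "C", "D", "E", "E")))
}

sample_recovery <- function(n, seed) {
  set.seed(seed)
  nodes <- c("A", "B", "C", "D", "E", "F")
  d <- matrix(1L, n, 6, dimnames = list(NULL, nodes))
  flip <- function(par, p11 = 0.85) {
    ifelse(stats::runif(n) < ifelse(par == 2L, p11, 1 - p11), 2L, 1L)
  }
  d[, "A"] <- stats::rbinom(n, 1, 0.5) + 1L
  d[, "B"] <- flip(d[, "A"])
  d[, "C"] <- flip(d[, "B"])
  d[, "D"] <- flip(d[, "A"])
  pE <- ifelse(d[, "C"] == 2L & d[, "D"] == 2L, 0.9,
               ifelse(d[, "C"] == 2L | d[, "D"] == 2L, 0.6, 0.1))
  d[, "E"] <- ifelse(stats::runif(n) < pE, 2L, 1L)
  d[, "F"] <- stats::rbinom(n, 1, 0.5) + 1L
  d
}

# Pooled-SD Cohen's d between label groups of one marker column.
cohens_d <- function(t, marker) {
  x1 <- t$values[t$label == 1L, marker]
  x0 <- t$values[t$label == 0L, marker]
  x1 <- x1[!is.na(x1)]; x0 <- x0[!is.na(x0)]
  sp <- sqrt(((length(x1) - 1) * stats::var(x1) +
                (length(x0) - 1) * stats::var(x0)) /
               (length(x1) + length(x0) - 2))
  (mean(x1) - mean(x0)) / sp
}

# A tiny fully observed cohort for plumbing tests.
tiny_cohort <- function(seed = 1, ...) {
  generate_cohort(cohort_spec(n_subjects = 60, n_markers = 12,
                              n_informative = 4, effect_size = 1.5,
                              missing_fraction = 0, seed = seed, ...))
}
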