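#' Directed acyclic graph over discrete nodes
#'
#' @param nodes character vector of node names.
#' @param edges two-column data.frame (`from`, `to`) of directed arcs.
#' @return object of class `bn_dag`.
#' @export
bn_dag <- function(nodes, edges = data.frame(from = character(0),
                                             to = character(0))) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop_validation("duplicate node names")
  edges <- data.frame(from = as.character(edges$from),
                      to = as.character(edges$to), stringsAsFactors = FALSE)
  if (nrow(edges) > 0) {
    if (!all(edges$from %in% nodes) || !all(edges$to %in% nodes)) {
      stop_validation("edge endpoint not in node set")
    }
    if (any(edges$from == edges$to)) stop_validation("self-loop in edge list")
    if (anyDuplicated(paste(edges$from, edges$to))) {
      stop_validation("duplicate edges")
    }
  }
  g <- structure(list(nodes = nodes, edges = edges), class = "bn_dag")
  if (!is_acyclic(adjacency(g))) stop_validation("edge list contains a cycle")
  g
}

#' @export
print.bn_dag <- function(x, ...) {
  cat(sprintf("bn_dag: %d nodes, %d arcs\n", length(x$nodes), nrow(x$edges)))
  invisible(x)
}

adjacency <- function(dag) {
  A <- matrix(0L, length(dag$nodes), length(dag$nodes),
              dimnames = list(dag$nodes, dag$nodes))
  if (nrow(dag$edges) > 0) A[cbind(dag$edges$from, dag$edges$to)] <- 1L
  A
}

adjacency_to_dag <- function(A) {
  idx <- which(A == 1L, arr.ind = TRUE)
  bn_dag(rownames(A),
         data.frame(from = rownames(A)[idx[, 1L]],
                    to = colnames(A)[idx[, 2L]], stringsAsFactors = FALSE))
}

parents_of <- function(A, j) rownames(A)[A[, j] == 1L]

# Kahn's algorithm on an adjacency matrix.
is_acyclic <- function(A) {
  indeg <- colSums(A)
  queue <- which(indeg == 0L)
  seen <- 0L
  A <- A  # local copy
  while (length(queue) > 0L) {
    v <- queue[1L]; queue <- queue[-1L]
    seen <- seen + 1L
    kids <- which(A[v, ] == 1L)
    A[v, kids] <- 0L
    indeg[kids] <- indeg[kids] - 1L
    queue <- c(queue, kids[indeg[kids] == 0L])
  }
  seen == nrow(A)
}

#' G-squared conditional-independence test
#'
#' Likelihood-ratio test of `x` independent of `y` given the set `z` on a
#' discrete data matrix, with degrees of freedom
#' `(|x|-1) (|y|-1) * prod(|z_i|)` counted from the full state spaces.
#' Following standard constraint-based practice, a test with fewer than
#' `5 * df` observations is declared unreliable and reported as independence
#' (p = 1).
#'
#' @param data integer matrix of 1-based states, columns named.
#' @param x,y column names of the two tested nodes.
#' @param z character vector of conditioning nodes (may be empty).
#' @param card named integer vector of state-space sizes per column.
#' @return the p-value, with attributes `statistic`, `df` and `reliable`.
#' @export
ci_test <- function(data, x, y, z = character(0), card) {
  if (x == y) stop_validation("x and y must differ")
  if (x %in% z || y %in% z) stop_validation("z must exclude x and y")
  n <- nrow(data)
  rx <- card[[x]]; ry <- card[[y]]
  qz <- if (length(z) > 0) prod(card[z]) else 1L
  df <- (rx - 1L) * (ry - 1L) * qz
  if (n < 5L * df) {
    return(structure(1, statistic = NA_real_, df = df, reliable = FALSE))
  }
  zi <- rep(1L, n)
  if (length(z) > 0) {
    mult <- 1L
    for (v in z) {
      zi <- zi + (data[, v] - 1L) * mult
      mult <- mult * card[[v]]
    }
  }
  idx <- data[, x] + rx * (data[, y] - 1L) + rx * ry * (zi - 1L)
  counts <- tabulate(idx, rx * ry * qz)
  dim(counts) <- c(rx, ry, qz)
  g2 <- 0
  for (k in seq_len(qz)) {
    o <- counts[, , k]
    nk <- sum(o)
    if (nk == 0) next
    e <- outer(rowSums(o), colSums(o)) / nk
    nz <- o > 0
    g2 <- g2 + 2 * sum(o[nz] * log(o[nz] / e[nz]))
  }
  structure(stats::pchisq(g2, df, lower.tail = FALSE),
            statistic = g2, df = df, reliable = TRUE)
}

# all subsets of `set` with size 0..max_size, as a list (deterministic order)
subsets_upto <- function(set, max_size) {
  out <- list(character(0))
  for (s in seq_len(min(max_size, length(set)))) {
    cmb <- utils::combn(set, s, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

# max over subsets S of `cond` of p(x _||_ target | S): the "min association"
max_pvalue <- function(data, target, x, cond, card, max_sx) {
  pmax_ <- 0
  for (S in subsets_upto(cond, max_sx)) {
    p <- as.numeric(ci_test(data, x, target, S, card))
    if (p > pmax_) pmax_ <- p
    if (pmax_ >= 1) break
  }
  pmax_
}

#' Max-min parents-children skeleton discovery
#'
#' The constraint phase of MMHC: for each node, grow a candidate
#' parent-children (CPC) set with the max-min heuristic (add the variable
#' whose weakest association with the target over all conditioning subsets of
#' the current CPC is strongest, while significant), then shrink it by
#' removing any member separable from the target given some subset of the
#' rest. The result is symmetrized with the AND rule: `x` stays in `PC(y)`
#' only if `y` is in `PC(x)`.
#'
#' @param data integer matrix of 1-based discrete states, columns named.
#' @param card named integer vector of per-column state counts.
#' @param alpha significance level of the G-squared test.
#' @param max_sx maximum conditioning-set size (caps the subset search).
#' @return named list of character vectors: the PC set of every node.
#' @export
mmpc <- function(data, card, alpha = 0.05, max_sx = 3L) {
  nodes <- colnames(data)
  if (length(nodes) < 2L) stop_validation("need at least 2 nodes")
  pc <- vector("list", length(nodes))
  names(pc) <- nodes
  for (tgt in nodes) {
    cpc <- character(0)
    candidates <- setdiff(nodes, tgt)
    repeat {
      rem <- setdiff(candidates, cpc)
      if (length(rem) == 0L) break
      best <- NULL; best_p <- Inf
      for (xv in rem) {
        p <- max_pvalue(data, tgt, xv, cpc, card, max_sx)
        if (p < best_p - 1e-15 ||
            (abs(p - best_p) <= 1e-15 && !is.null(best) && xv < best)) {
          best <- xv; best_p <- p
        }
      }
      if (best_p < alpha) {
        cpc <- c(cpc, best)
      } else {
        break
      }
    }
    # backward: drop members separable given a subset of the others
    changed <- TRUE
    while (changed) {
      changed <- FALSE
      for (xv in cpc) {
        p <- max_pvalue(data, tgt, xv, setdiff(cpc, xv), card, max_sx)
        if (p >= alpha) {
          cpc <- setdiff(cpc, xv)
          changed <- TRUE
          break
        }
      }
    }
    pc[[tgt]] <- sort(cpc)
  }
  # symmetry (AND rule)
  for (a in nodes) {
    pc[[a]] <- pc[[a]][vapply(pc[[a]], function(b) a %in% pc[[b]], logical(1))]
  }
  pc
}

# decomposable family scores ------------------------------------------------

# counts of node states per parent configuration
family_counts <- function(data, node, parents, card) {
  n <- nrow(data)
  r <- card[[node]]
  q <- if (length(parents) > 0) prod(card[parents]) else 1L
  pidx <- rep(1L, n)
  if (length(parents) > 0) {
    mult <- 1L
    for (v in parents) {
      pidx <- pidx + (data[, v] - 1L) * mult
      mult <- mult * card[[v]]
    }
  }
  counts <- tabulate(data[, node] + r * (pidx - 1L), r * q)
  dim(counts) <- c(r, q)
  counts
}

score_family <- function(data, node, parents, card, score = "bdeu", ess = 1) {
  counts <- family_counts(data, node, parents, card)
  r <- nrow(counts); q <- ncol(counts)
  if (score == "bdeu") {
    a_jk <- ess / (r * q)
    a_j <- ess / q
    nj <- colSums(counts)
    sum(lgamma(a_j) - lgamma(a_j + nj)) +
      sum(lgamma(a_jk + counts) - lgamma(a_jk))
  } else if (score == "bic") {
    nj <- colSums(counts)
    nz <- counts > 0
    ll <- sum(counts[nz] * log(counts[nz] /
                                 rep(nj, each = r)[as.vector(nz)]))
    ll - 0.5 * log(nrow(data)) * q * (r - 1)
  } else {
    stop_validation("unknown score: %s", score)
  }
}

#' Score-based DAG search restricted to a skeleton
#'
#' Greedy hill climbing over arc additions, deletions and reversals,
#' maximizing a decomposable network score (BDeu by default, BIC optional).
#' Additions are restricted to pairs allowed by the `skeleton` (the MMPC
#' output), the MMHC design. All tie-breaks are lexicographic in
#' (operation, from, to), so the search is deterministic.
#'
#' @inheritParams mmpc
#' @param skeleton named list of PC sets as returned by [mmpc()]; additions
#'   are restricted to these pairs.
#' @param score `"bdeu"` or `"bic"`.
#' @param ess equivalent sample size of the BDeu prior.
#' @return a [bn_dag()] with attributes `score` (total network score) and
#'   `score_type`.
#' @export
hill_climb <- function(data, skeleton, card, score = c("bdeu", "bic"),
                       ess = 1) {
  score <- match.arg(score)
  nodes <- colnames(data)
  A <- matrix(0L, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  cache <- new.env(parent = emptyenv())
  fam_score <- function(node, parents) {
    key <- paste(node, paste(sort(parents), collapse = ","), sep = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    s <- score_family(data, node, sort(parents), card, score, ess)
    cache[[key]] <- s
    s
  }
  node_score <- vapply(nodes, function(v) fam_score(v, character(0)),
                       numeric(1))

  allowed <- matrix(FALSE, length(nodes), length(nodes),
                    dimnames = list(nodes, nodes))
  for (a in nodes) allowed[a, skeleton[[a]]] <- TRUE

  repeat {
    best <- NULL
    best_delta <- 1e-9
    for (i in seq_along(nodes)) {
      for (j in seq_along(nodes)) {
        if (i == j) next
        a <- nodes[i]; b <- nodes[j]
        if (A[i, j] == 1L) {
          # deletion a -> b
          d <- fam_score(b, setdiff(parents_of(A, j), a)) - node_score[j]
          if (d > best_delta) {
            best <- list(op = "delete", i = i, j = j); best_delta <- d
          }
          # reversal a -> b  =>  b -> a
          A2 <- A; A2[i, j] <- 0L; A2[j, i] <- 1L
          if (is_acyclic(A2)) {
            d <- (fam_score(b, setdiff(parents_of(A, j), a)) - node_score[j]) +
              (fam_score(a, c(parents_of(A, i), b)) - node_score[i])
            if (d > best_delta) {
              best <- list(op = "reverse", i = i, j = j); best_delta <- d
            }
          }
        } else if (allowed[a, b] && A[j, i] == 0L) {
          # addition a -> b
          A2 <- A; A2[i, j] <- 1L
          if (is_acyclic(A2)) {
            d <- fam_score(b, c(parents_of(A, j), a)) - node_score[j]
            if (d > best_delta) {
              best <- list(op = "add", i = i, j = j); best_delta <- d
            }
          }
        }
      }
    }
    if (is.null(best)) break
    i <- best$i; j <- best$j
    if (best$op == "add") {
      A[i, j] <- 1L
    } else if (best$op == "delete") {
      A[i, j] <- 0L
    } else {
      A[i, j] <- 0L; A[j, i] <- 1L
      node_score[i] <- fam_score(nodes[i], parents_of(A, i))
    }
    node_score[j] <- fam_score(nodes[j], parents_of(A, j))
    stopifnot(is_acyclic(A))
  }
  dag <- adjacency_to_dag(A)
  attr(dag, "score") <- sum(vapply(seq_along(nodes), function(j)
    fam_score(nodes[j], parents_of(A, j)), numeric(1)))
  attr(dag, "score_type") <- score
  dag
}

#' Learn a network structure with MMHC
#'
#' Max-min hill-climbing: [mmpc()] builds the candidate skeleton by
#' conditional-independence testing, then [hill_climb()] orients and prunes
#' it by score-based search.
#'
#' @inheritParams hill_climb
#' @param ci_alpha significance level of the skeleton phase.
#' @param max_sx conditioning-set size cap in the skeleton phase.
#' @return a [bn_dag()].
#' @export
mmhc <- function(data, card, ci_alpha = 0.05, score = "bdeu", ess = 1,
                 max_sx = 3L) {
  skel <- mmpc(data, card, alpha = ci_alpha, max_sx = max_sx)
  hill_climb(data, skel, card, score = score, ess = ess)
}

#' Remove nodes disconnected from the network
#'
#' Markers that fail to connect to the network during structure learning are
#' eliminated from the prediction model; the removal list feeds the selection
#' report.
#'
#' @param dag a [bn_dag()].
#' @param anchor the conversion node; it must remain connected.
#' @return list with `dag` (isolated nodes removed) and `removed` (their
#'   names).
#' @export
prune_disconnected <- function(dag, anchor) {
  stopifnot(inherits(dag, "bn_dag"))
  if (!anchor %in% dag$nodes) stop_validation("anchor %s not in DAG", anchor)
  deg <- stats::setNames(rep(0L, length(dag$nodes)), dag$nodes)
  if (nrow(dag$edges) > 0) {
    tab <- table(c(dag$edges$from, dag$edges$to))
    deg[names(tab)] <- as.integer(tab)
  }
  isolated <- names(deg)[deg == 0L]
  if (anchor %in% isolated) {
    stop_data("conversion node %s is isolated: no predictive structure learned",
              anchor)
  }
  keep <- setdiff(dag$nodes, isolated)
  list(dag = bn_dag(keep, dag$edges), removed = isolated)
}

# CPDAG and structural Hamming distance --------------------------------------

#' Completed PDAG of a DAG
#'
#' Skeleton plus compelled arcs: v-structure arcs, closed under Meek's
#' orientation rules R1-R3. Represented as a matrix with `P[a,b] = P[b,a] = 1`
#' for an undirected edge and `P[a,b] = 1, P[b,a] = 0` for a compelled arc.
#'
#' @param dag a [bn_dag()].
#' @return the pattern matrix.
#' @export
cpdag <- function(dag) {
  A <- adjacency(dag)
  n <- nrow(A)
  sk <- (A + t(A)) > 0
  P <- matrix(0L, n, n, dimnames = dimnames(A))
  P[sk] <- 1L  # start fully undirected
  # v-structures: a -> c <- b with a, b non-adjacent
  for (cc in seq_len(n)) {
    pa <- which(A[, cc] == 1L)
    if (length(pa) < 2L) next
    for (u in seq_along(pa)) {
      for (v in seq_len(u - 1L)) {
        a <- pa[u]; b <- pa[v]
        if (!sk[a, b]) {
          P[a, cc] <- 1L; P[cc, a] <- 0L
          P[b, cc] <- 1L; P[cc, b] <- 0L
        }
      }
    }
  }
  # Meek rules to a fixpoint
  repeat {
    changed <- FALSE
    und <- which(P == 1L & t(P) == 1L, arr.ind = TRUE)
    for (r in seq_len(nrow(und))) {
      a <- und[r, 1L]; b <- und[r, 2L]
      if (!(P[a, b] == 1L && P[b, a] == 1L)) next
      orient <- FALSE
      # R1: c -> a, c and b non-adjacent
      for (cc in which(P[, a] == 1L & P[a, ] == 0L)) {
        if (!sk[cc, b]) { orient <- TRUE; break }
      }
      # R2: directed path a -> c -> b
      if (!orient) {
        for (cc in which(P[a, ] == 1L & P[, a] == 0L)) {
          if (P[cc, b] == 1L && P[b, cc] == 0L) { orient <- TRUE; break }
        }
      }
      # R3: a - c -> b and a - d -> b with c, d non-adjacent
      if (!orient) {
        mid <- which(P[a, ] == 1L & P[, a] == 1L & P[, b] == 1L & P[b, ] == 0L)
        if (length(mid) >= 2L) {
          for (u in seq_along(mid)) {
            for (v in seq_len(u - 1L)) {
              if (!sk[mid[u], mid[v]]) { orient <- TRUE; break }
            }
            if (orient) break
          }
        }
      }
      if (orient) {
        P[a, b] <- 1L; P[b, a] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  P
}

#' Structural Hamming distance between two CPDAGs
#'
#' Counts node pairs whose edge mark differs (absent / undirected / directed
#' either way); each differing pair contributes 1.
#'
#' @param P1,P2 pattern matrices from [cpdag()] over the same node set.
#' @return integer distance.
#' @export
shd <- function(P1, P2) {
  stopifnot(identical(dimnames(P1), dimnames(P2)))
  n <- nrow(P1)
  d <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      m1 <- c(P1[i, j], P1[j, i])
      m2 <- c(P2[i, j], P2[j, i])
      if (!all(m1 == m2)) d <- d + 1L
    }
  }
  d
}
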