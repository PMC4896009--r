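#' Build a junction tree for exact inference
#'
#' Moralizes the DAG, triangulates with the min-fill heuristic (lexicographic
#' tie-break), extracts the maximal elimination cliques, joins them by a
#' maximum-weight spanning tree on separator sizes (the junction-tree
#' theorem guarantees the running-intersection property), assigns each CPT to
#' the first clique containing its family, and calibrates by two-pass
#' sum-product message passing. Disconnected components are joined through
#' empty separators so a single tree covers the whole network.
#'
#' @param net a [fit_cpts()] result.
#' @return an object of class `junction_tree`: cliques, tree edges with
#'   separators, initial potentials and calibrated clique beliefs.
#' @export
build_junction_tree <- function(net) {
  stopifnot(inherits(net, "bayes_net"))
  nodes <- net$dag$nodes
  A <- adjacency(net$dag)
  # moral graph: skeleton + married parents
  M <- (A + t(A)) > 0
  for (v in nodes) {
    pa <- parents_of(A, v)
    if (length(pa) > 1L) {
      M[pa, pa] <- TRUE
    }
  }
  diag(M) <- FALSE

  # min-fill triangulation, recording elimination cliques
  W <- M
  remaining <- nodes
  cliques <- list()
  while (length(remaining) > 0L) {
    fill <- vapply(remaining, function(v) {
      nb <- remaining[W[v, remaining]]
      if (length(nb) < 2L) return(0L)
      sub <- W[nb, nb, drop = FALSE]
      sum(!sub[upper.tri(sub)])
    }, integer(1))
    v <- remaining[order(fill, remaining)][1L]
    nb <- remaining[W[v, remaining]]
    if (length(nb) > 1L) W[nb, nb] <- TRUE
    diag(W) <- FALSE
    cliques[[length(cliques) + 1L]] <- sort(c(v, nb))
    remaining <- setdiff(remaining, v)
  }
  # keep maximal cliques only (first occurrence wins, deterministic)
  keep <- rep(TRUE, length(cliques))
  for (i in seq_along(cliques)) {
    for (j in seq_along(cliques)) {
      if (i != j && keep[i] && keep[j] &&
          all(cliques[[i]] %in% cliques[[j]]) &&
          (length(cliques[[i]]) < length(cliques[[j]]) || i > j)) {
        keep[i] <- FALSE
      }
    }
  }
  cliques <- cliques[keep]
  nc <- length(cliques)

  # maximum-weight spanning tree on separator sizes (Prim, deterministic);
  # zero-weight links are allowed so disconnected components still join up
  tree_from <- integer(0); tree_to <- integer(0)
  if (nc > 1L) {
    in_tree <- c(TRUE, rep(FALSE, nc - 1L))
    while (!all(in_tree)) {
      best_w <- -1L; best <- NULL
      for (i in which(in_tree)) {
        for (j in which(!in_tree)) {
          w <- length(intersect(cliques[[i]], cliques[[j]]))
          if (w > best_w) { best_w <- w; best <- c(i, j) }
        }
      }
      tree_from <- c(tree_from, best[1L]); tree_to <- c(tree_to, best[2L])
      in_tree[best[2L]] <- TRUE
    }
  }
  separators <- lapply(seq_along(tree_from), function(e)
    intersect(cliques[[tree_from[e]]], cliques[[tree_to[e]]]))

  # assign each CPT to the first clique containing its family
  assignment <- integer(length(nodes))
  names(assignment) <- nodes
  for (v in nodes) {
    fam <- net$cpts[[v]]$vars
    hit <- which(vapply(cliques, function(cl) all(fam %in% cl), logical(1)))
    stopifnot(length(hit) > 0L)
    assignment[v] <- hit[1L]
  }
  potentials <- lapply(seq_len(nc), function(i) {
    fs <- net$cpts[names(assignment)[assignment == i]]
    base <- dfactor(cliques[[i]], unname(net$card[cliques[[i]]]),
                    rep(1, prod(net$card[cliques[[i]]])))
    factor_product_list(c(list(base), unname(fs)))
  })

  jt <- structure(list(cliques = cliques,
                       tree = data.frame(from = tree_from, to = tree_to),
                       separators = separators,
                       potentials = potentials,
                       card = net$card,
                       state_spaces = net$state_spaces,
                       beliefs = NULL, calibrated = FALSE),
                  class = "junction_tree")
  calibrate(jt)
}

neighbors_of_clique <- function(jt, i) {
  e1 <- which(jt$tree$from == i)
  e2 <- which(jt$tree$to == i)
  data.frame(edge = c(e1, e2), nb = c(jt$tree$to[e1], jt$tree$from[e2]))
}

#' Calibrate a junction tree
#'
#' Shafer-Shenoy two-pass sum-product message passing from the stored initial
#' potentials; recalibrating an already calibrated tree recomputes identical
#' beliefs (the messages are a pure function of the potentials).
#'
#' @param jt a [build_junction_tree()] result.
#' @param evidence optional named list/vector mapping node names to 1-based
#'   state indices, entered as likelihood findings before message passing.
#' @return the tree with calibrated `beliefs` (one factor per clique) and the
#'   evidence probability in `attr(, "p_evidence")`.
#' @export
calibrate <- function(jt, evidence = NULL) {
  pots <- jt$potentials
  if (!is.null(evidence) && length(evidence) > 0L) {
    for (v in names(evidence)) {
      st <- evidence[[v]]
      hit <- which(vapply(jt$cliques, function(cl) v %in% cl, logical(1)))[1L]
      if (is.na(hit)) stop_validation("evidence node %s not in tree", v)
      if (st < 1L || st > jt$card[[v]]) {
        stop_validation("evidence state %s invalid for node %s", st, v)
      }
      pots[[hit]] <- factor_reduce(pots[[hit]], v, st)
    }
  }
  nc <- length(jt$cliques)
  if (nc == 1L) {
    z <- sum(pots[[1L]]$values)
    jt$beliefs <- pots
    jt$calibrated <- TRUE
    attr(jt, "p_evidence") <- z
    return(jt)
  }
  # message schedule: collect towards clique 1, then distribute
  msgs <- vector("list", 2L * nrow(jt$tree))  # edge e: msg from->to at e, to->from at e+nE
  nE <- nrow(jt$tree)
  # orient the tree from root 1 by BFS
  parent <- rep(NA_integer_, nc); parent_edge <- rep(NA_integer_, nc)
  order_bfs <- integer(0)
  queue <- 1L
  visited <- rep(FALSE, nc); visited[1L] <- TRUE
  while (length(queue) > 0L) {
    u <- queue[1L]; queue <- queue[-1L]
    order_bfs <- c(order_bfs, u)
    nbs <- neighbors_of_clique(jt, u)
    for (r in seq_len(nrow(nbs))) {
      w <- nbs$nb[r]
      if (!visited[w]) {
        visited[w] <- TRUE
        parent[w] <- u; parent_edge[w] <- nbs$edge[r]
        queue <- c(queue, w)
      }
    }
  }
  msg_in <- function(i, exclude_edge) {
    nbs <- neighbors_of_clique(jt, i)
    out <- list()
    for (r in seq_len(nrow(nbs))) {
      e <- nbs$edge[r]
      if (!is.na(exclude_edge) && e == exclude_edge) next
      key <- if (jt$tree$to[e] == i) e else e + nE
      out[[length(out) + 1L]] <- msgs[[key]]
    }
    out
  }
  # upward pass (leaves to root)
  for (u in rev(order_bfs)) {
    if (is.na(parent[u])) next
    e <- parent_edge[u]
    inc <- msg_in(u, e)
    f <- factor_product_list(c(list(pots[[u]]), inc))
    m <- factor_marginalize(f, jt$separators[[e]])
    key <- if (jt$tree$from[e] == u) e else e + nE
    msgs[[key]] <- m
  }
  # downward pass (root to leaves)
  for (u in order_bfs) {
    nbs <- neighbors_of_clique(jt, u)
    for (r in seq_len(nrow(nbs))) {
      w <- nbs$nb[r]
      if (is.na(parent[w]) || parent[w] != u) next
      e <- nbs$edge[r]
      inc <- msg_in(u, e)
      f <- factor_product_list(c(list(pots[[u]]), inc))
      m <- factor_marginalize(f, jt$separators[[e]])
      key <- if (jt$tree$from[e] == u) e else e + nE
      msgs[[key]] <- m
    }
  }
  beliefs <- lapply(seq_len(nc), function(i) {
    factor_product_list(c(list(pots[[i]]), msg_in(i, NA_integer_)))
  })
  z <- sum(beliefs[[1L]]$values)
  jt$beliefs <- beliefs
  jt$calibrated <- TRUE
  attr(jt, "p_evidence") <- z
  jt
}

#' Query a marginal from a junction tree
#'
#' Enters the evidence as likelihood findings, recalibrates, and returns the
#' normalized posterior of the target node.
#'
#' @param jt a calibrated [build_junction_tree()] result.
#' @param target node name to query.
#' @param evidence named list/vector of 1-based state indices (may be empty);
#'   must not include `target`.
#' @return a `posterior`: list with `target`, `distribution` (named
#'   probability vector over the target's states) and `evidence`.
#' @export
query <- function(jt, target, evidence = NULL) {
  stopifnot(inherits(jt, "junction_tree"))
  if (!is.null(evidence) && target %in% names(evidence)) {
    stop_validation("target %s must not appear in evidence", target)
  }
  hit <- which(vapply(jt$cliques, function(cl) target %in% cl, logical(1)))[1L]
  if (is.na(hit)) stop_validation("target %s not in tree", target)
  jt2 <- calibrate(jt, evidence)
  z <- attr(jt2, "p_evidence")
  if (!is.finite(z) || z <= 0) {
    stop_data("evidence has zero probability under the model")
  }
  marg <- factor_marginalize(jt2$beliefs[[hit]], target)
  p <- marg$values / sum(marg$values)
  names(p) <- jt$state_spaces[[target]]
  structure(list(target = target, distribution = p,
                 evidence = evidence),
            class = "bn_posterior")
}

#' Predict conversion probabilities for subjects
#'
#' Discretizes each subject's markers with the (training-fitted)
#' discretization model, enters the states of markers present in the network
#' as evidence (markers absent from the network, and missing values, are
#' simply omitted — the junction tree marginalizes them), queries the
#' conversion node and returns its posterior probability of conversion.
#'
#' @param net a [fit_cpts()] result containing the conversion node.
#' @param model the [discretize_fit()] model used at training time.
#' @param subjects a [marker_table()].
#' @param conv_node name of the conversion node.
#' @return numeric vector of `P(convert)` per subject, named by subject id.
#' @export
predict_conversion <- function(net, model, subjects, conv_node = "CONVERT") {
  stopifnot(inherits(net, "bayes_net"))
  if (!conv_node %in% net$dag$nodes) {
    stop_validation("conversion node %s not in network", conv_node)
  }
  if (!identical(net$state_spaces[[conv_node]], c("0", "1"))) {
    stop_validation("conversion node %s must have states c(\"0\", \"1\")",
                    conv_node)
  }
  jt <- build_junction_tree(net)
  usable <- intersect(names(model$cuts), setdiff(net$dag$nodes, conv_node))
  disc <- discretize_apply(model, subjects)
  out <- vapply(seq_len(n_subjects(subjects)), function(i) {
    ev <- as.list(disc[i, usable])
    ev <- ev[!vapply(ev, is.na, logical(1))]
    post <- query(jt, conv_node, ev)
    unname(post$distribution[["1"]])
  }, numeric(1))
  names(out) <- subject_ids(subjects)
  out
}
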