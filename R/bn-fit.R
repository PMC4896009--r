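#' Fit conditional probability tables
#'
#' Dirichlet-uniform smoothed CPT estimates: the probability of child state k
#' under parent configuration j is
#' `(n_jk + ess/(r*q)) / (n_j + ess/q)` with `r` child states and `q` parent
#' configurations, so `ess = 0` gives raw frequencies and an unseen parent
#' configuration falls back to the uniform distribution (for `ess > 0`).
#'
#' @param dag a [bn_dag()].
#' @param data integer matrix of 1-based discrete states covering every node.
#' @param card named integer vector of per-node state counts.
#' @param ess equivalent sample size of the Dirichlet prior; default 1.
#' @param state_labels optional named list of per-node state labels.
#' @return an object of class `bayes_net`: the DAG, per-node CPT arrays
#'   (child dimension first, then parents in sorted order) and state spaces.
#' @export
fit_cpts <- function(dag, data, card, ess = 1, state_labels = NULL) {
  stopifnot(inherits(dag, "bn_dag"))
  absent <- setdiff(dag$nodes, colnames(data))
  if (length(absent) > 0) {
    stop_validation("nodes absent from data: %s", paste(absent, collapse = ", "))
  }
  A <- adjacency(dag)
  cpts <- vector("list", length(dag$nodes))
  names(cpts) <- dag$nodes
  for (v in dag$nodes) {
    pa <- sort(parents_of(A, v))
    counts <- family_counts(data, v, pa, card)
    r <- nrow(counts); q <- ncol(counts)
    probs <- (counts + ess / (r * q)) /
      rep(colSums(counts) + ess / q, each = r)
    if (ess == 0) {
      # unseen configurations are 0/0; define them as uniform
      bad <- !is.finite(probs)
      probs[bad] <- 1 / r
    }
    cpts[[v]] <- dfactor(c(v, pa), c(card[[v]], unname(card[pa])),
                         as.numeric(probs))
  }
  spaces <- lapply(dag$nodes, function(v) {
    if (!is.null(state_labels) && !is.null(state_labels[[v]])) {
      state_labels[[v]]
    } else {
      as.character(seq_len(card[[v]]))
    }
  })
  names(spaces) <- dag$nodes
  structure(list(dag = dag, cpts = cpts,
                 card = card[dag$nodes], state_spaces = spaces),
            class = "bayes_net")
}

#' @export
print.bayes_net <- function(x, ...) {
  cat(sprintf("bayes_net: %d nodes, %d arcs; states per node: %s\n",
              length(x$dag$nodes), nrow(x$dag$edges),
              paste(range(x$card), collapse = "-")))
  invisible(x)
}
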