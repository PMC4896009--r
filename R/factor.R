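# Discrete factors (potentials) for exact inference: a factor is a list with
# `vars` (character), `card` (integer cardinalities, same order) and `values`
# (numeric array of length prod(card), column-major in `vars` order).

dfactor <- function(vars, card, values) {
  stopifnot(length(vars) == length(card),
            length(values) == prod(card))
  list(vars = as.character(vars), card = as.integer(card),
       values = as.numeric(values))
}

# strides of each var inside a factor's column-major layout
factor_strides <- function(card) {
  if (length(card) == 0L) return(integer(0))
  cumprod(c(1L, card[-length(card)]))
}

# Map cells of a factor over `vars`/`card` onto the corresponding cells of a
# sub-factor `f` (f$vars must be a subset of vars). Returns the index vector.
map_index <- function(vars, card, f) {
  ncell <- prod(card)
  if (length(f$vars) == 0L) return(rep(1L, ncell))
  pos <- match(f$vars, vars)
  stopifnot(!anyNA(pos))
  big_str <- factor_strides(card)
  f_str <- factor_strides(f$card)
  idx <- rep(1, ncell)
  cells <- seq_len(ncell) - 1L
  for (k in seq_along(pos)) {
    coord <- (cells %/% big_str[pos[k]]) %% card[pos[k]]
    idx <- idx + coord * f_str[k]
  }
  as.integer(idx)
}

factor_product <- function(f1, f2) {
  vars <- union(f1$vars, f2$vars)
  card <- integer(length(vars))
  card[match(f1$vars, vars)] <- f1$card
  card[match(f2$vars, vars)] <- f2$card
  dfactor(vars, card,
          f1$values[map_index(vars, card, f1)] *
            f2$values[map_index(vars, card, f2)])
}

factor_product_list <- function(fs) {
  if (length(fs) == 0L) return(dfactor(character(0), integer(0), 1))
  out <- fs[[1L]]
  for (f in fs[-1L]) out <- factor_product(out, f)
  out
}

# Sum out all vars not in `keep`; result vars are ordered as in `keep`.
factor_marginalize <- function(f, keep) {
  keep <- intersect(keep, f$vars)
  if (length(keep) == length(f$vars) && all(keep == f$vars)) return(f)
  out_card <- f$card[match(keep, f$vars)]
  out <- dfactor(keep, out_card, numeric(prod(out_card)))
  idx <- map_index(f$vars, f$card, out)
  # every output cell is hit (the map is surjective), so rowsum's groups are
  # exactly 1..prod(out_card) in order
  out$values <- as.numeric(rowsum(f$values, idx))
  out
}

# multiply an evidence indicator (var fixed to state) into a factor
factor_reduce <- function(f, var, state) {
  pos <- match(var, f$vars)
  if (is.na(pos)) return(f)
  ind <- dfactor(var, f$card[pos],
                 as.numeric(seq_len(f$card[pos]) == state))
  factor_product(f, ind)
}
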