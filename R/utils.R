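#' @keywords internal
"_PACKAGE"

# Run `expr` under a private RNG stream so package functions never disturb the
# caller's .Random.seed, and are reproducible given their own `seed` argument.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Per-stage seeds fanned out from one global seed by a deterministic counter,
# kept inside the 32-bit integer range.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offsets <- c(datagen = 1L, dataprep = 2L, select = 3L, bn = 4L,
               evalx = 5L, disrupt = 6L)
  off <- offsets[[stage]]
  as.integer((as.integer(seed) %% 1999999973L) + off * 7919L) %% 2147483647L
}

stop_validation <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("mcinet_validation_error", "mcinet_error")))
}

stop_data <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("mcinet_data_error", "mcinet_error")))
}

check_proportion <- function(x, name, open_left = FALSE, open_right = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      x < 0 || x > 1 ||
      (open_left && x == 0) || (open_right && x == 1)) {
    stop_validation("`%s` must be a proportion in %s0, 1%s (got %s)",
                    name, if (open_left) "(" else "[",
                    if (open_right) ")" else "]", format(x))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x)) {
    stop_validation("`%s` must be an integer >= %d (got %s)",
                    name, min, format(x))
  }
  invisible(as.integer(x))
}
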